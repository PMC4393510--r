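#' End-to-end multi-sample SV discovery
#'
#' Composes the pipeline stages: per-library fragment-size profiling,
#' discordant-pair extraction with routing-key partitioning, memory-bounded
#' external sort of each partition, sweep-line clustering with per-library
#' cutoffs, call finalization and support filtering.
#'
#' @param sample_sheet Path or data.frame: `sample_id`, `role`, `pair_id`,
#'   `path` and, optionally, `depth` (used for the default cluster cap).
#' @param workdir Directory for spill/run/sorted intermediates.
#' @param k_mad MAD multiplier for the discordance cutoff (default 8).
#' @param min_mapq Minimum mapping quality (default 20).
#' @param n_profile Pairs sampled per file for profiling (default 1e6).
#' @param min_observations Minimum spans per library profile (default 1000).
#' @param memory_records External-sort memory budget in records
#'   (default 500000).
#' @param cluster_cap Cluster depth cap; default derives from the sheet's
#'   `depth` column via [default_cluster_cap()] (100 when absent).
#' @param min_support Minimum total support for reported calls (default 4).
#' @param profiles Optional precomputed profile table (bypasses profiling,
#'   mirroring pipelines where library statistics are known upfront).
#' @return List: `calls` (filtered), `all_calls`, `profiles`, `reports`,
#'   `drop_log`, `manifest`.
#' @export
sv_discover <- function(sample_sheet, workdir, k_mad = 8, min_mapq = 20,
                        n_profile = 1e6, min_observations = 1000,
                        memory_records = 500000L, cluster_cap = NULL,
                        min_support = 4L, profiles = NULL) {
  sheet <- read_sample_sheet(sample_sheet)
  dir.create(workdir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(profiles)) {
    profiles <- profile_libraries(sheet, k_mad = k_mad,
                                  n_profile = n_profile,
                                  min_observations = min_observations,
                                  min_mapq = min_mapq)
  }
  write_profiles(profiles, file.path(workdir, "profiles.tsv"))
  ex <- extract_discordants(sheet, profiles, min_mapq = min_mapq,
                            workdir = workdir)
  manifest <- sort_partitions(workdir, memory_records = memory_records)
  if (is.null(cluster_cap)) {
    cluster_cap <- if ("depth" %in% names(sheet))
      default_cluster_cap(sheet$depth) else 100L
  }
  cl <- cluster_partitions(manifest, profiles, cluster_cap = cluster_cap,
                           sample_ids = sheet$sample_id)
  calls <- filter_calls(cl$calls, min_support = min_support)
  list(calls = calls, all_calls = cl$calls, profiles = profiles,
       reports = ex$reports, drop_log = cl$drop_log, manifest = manifest)
}
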