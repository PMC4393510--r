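#' Median and (unscaled) median absolute deviation
#'
#' Computes the fragment-size location and dispersion statistics used to set
#' each library's discordance cutoff. The median uses the lower-median
#' convention for even-length input and the MAD is the plain median of
#' absolute deviations, with no normal-consistency scaling: cutoffs are
#' quoted directly in MAD units.
#'
#' @param values Numeric vector of non-negative fragment spans (bp).
#' @return Named list with elements `median` and `mad`.
#' @examples
#' median_and_mad(c(290, 295, 300, 305, 310))  # median 300, mad 5
#' @export
median_and_mad <- function(values) {
  if (length(values) == 0)
    .stopf("median_and_mad: no observations")
  if (any(is.na(values)))
    .stopf("median_and_mad: NA observations")
  m <- lower_median(values)
  list(median = m, mad = lower_median(abs(values - m)))
}

#' Estimate a library fragment-size profile
#'
#' Summarises the outer spans of properly oriented (+/-) same-chromosome
#' pairs of one sequencing library into a profile: median, MAD and the
#' maximum concordant span `median + k_mad * mad` (rounded half-up). Pairs
#' whose span exceeds that cutoff are treated as discordant for this
#' library, which absorbs both intra- and inter-sample differences in
#' insert-size distributions when libraries are co-analysed.
#'
#' @param spans Integer vector of outer fragment spans (bp) from properly
#'   oriented pairs.
#' @param k_mad Positive multiplier on the MAD (typical values 5 or 8).
#' @param sample_id,library_id Provenance identifiers stored in the profile.
#' @param min_observations Minimum number of spans required (default 1000;
#'   lower it for small experiments).
#' @return A one-row `data.table` with columns `sample_id`, `library_id`,
#'   `median`, `mad`, `k_mad`, `max_concordant_span`, `n`.
#' @export
estimate_library_profile <- function(spans, k_mad, sample_id, library_id,
                                     min_observations = 1000) {
  if (k_mad <= 0) .stopf("k_mad must be positive")
  if (length(spans) < min_observations)
    .stopf("library %s/%s: %d spans, need at least %d",
           sample_id, library_id, length(spans), min_observations)
  mm <- median_and_mad(spans)
  data.table::data.table(
    sample_id = sample_id,
    library_id = library_id,
    median = as.integer(mm$median),
    mad = as.integer(mm$mad),
    k_mad = as.numeric(k_mad),
    max_concordant_span = as.integer(round_half_up(mm$median + k_mad * mm$mad)),
    n = length(spans)
  )
}

.assert_profile_table <- function(profiles) {
  req <- c("sample_id", "library_id", "median", "mad", "k_mad",
           "max_concordant_span", "n")
  missing <- setdiff(req, names(profiles))
  if (length(missing) > 0)
    .stopf("profile table is missing columns: %s", paste(missing, collapse = ", "))
  if (anyDuplicated(profiles[, c("sample_id", "library_id")]))
    .stopf("duplicate (sample_id, library_id) in profile table")
  invisible(profiles)
}

#' Classify canonicalized pairs as concordant, discordant or excluded
#'
#' A pair is discordant if its ends map to different chromosomes, if its
#' orientation after coordinate ordering is anything other than (+,-), or if
#' it is (+,-) but its outer span exceeds the library's maximum concordant
#' span. Undersized (+,-) pairs (span below `median - k_mad * mad`) are
#' excluded rather than clustered: they signal insertions, which this
#' caller does not model. Everything else is concordant.
#'
#' @param pairs Canonicalized pair table (see [canonicalize_pairs()]).
#' @param profiles Profile table covering every (sample_id, library_id) in
#'   `pairs`.
#' @return Character vector of labels `"concordant"`, `"discordant"` or
#'   `"excluded"`, one per pair.
#' @export
classify_alignment_pairs <- function(pairs, profiles) {
  .assert_pair_table(pairs)
  .assert_profile_table(profiles)
  pairs <- data.table::as.data.table(pairs)
  profiles <- data.table::as.data.table(profiles)
  idx <- profiles[pairs, on = c("sample_id", "library_id"), which = TRUE]
  if (anyNA(idx)) {
    bad <- unique(pairs[is.na(idx), paste(sample_id, library_id, sep = "/")])
    .stopf("no profile for read group(s): %s", paste(bad, collapse = ", "))
  }
  w <- profiles$max_concordant_span[idx]
  lo <- profiles$median[idx] - profiles$k_mad[idx] * profiles$mad[idx]
  span <- pmax(pairs$end1, pairs$end2) - pairs$start1
  inter <- pairs$chrom1 != pairs$chrom2
  fr <- !inter & pairs$strand1 == "+" & pairs$strand2 == "-"
  out <- rep("discordant", nrow(pairs))
  out[fr & span <= w & span >= lo] <- "concordant"
  out[fr & span < lo] <- "excluded"
  out
}

#' Profile every library of a cohort from its alignment files
#'
#' For each sample in the sheet, reads up to `n_profile` mated pairs passing
#' the quality filters, keeps properly oriented (+,-) same-chromosome pairs,
#' and estimates a fragment-size profile per read group (library).
#'
#' @param sample_sheet Path or data.frame: columns `sample_id`, `role`,
#'   `pair_id`, `path` (SAM or BAM).
#' @param k_mad MAD multiplier defining the discordance cutoff (default 8).
#' @param n_profile Maximum number of pairs sampled per file (default 1e6).
#' @param min_observations Minimum spans per library (default 1000).
#' @param min_mapq Minimum mapping quality for profiled reads (default 20).
#' @return Profile `data.table`, one row per (sample, library).
#' @export
profile_libraries <- function(sample_sheet, k_mad = 8, n_profile = 1e6,
                              min_observations = 1000, min_mapq = 20) {
  sheet <- read_sample_sheet(sample_sheet)
  out <- vector("list", nrow(sheet))
  for (i in seq_len(nrow(sheet))) {
    rd <- read_alignment_pairs(sheet$path[i], sample_id = sheet$sample_id[i],
                               min_mapq = min_mapq)
    pairs <- rd$pairs
    proper <- pairs[pairs$chrom1 == pairs$chrom2 &
                      pairs$strand1 == "+" & pairs$strand2 == "-", ]
    if (nrow(proper) > n_profile) proper <- proper[seq_len(n_profile), ]
    spans <- pmax(proper$end1, proper$end2) - proper$start1
    libs <- split(spans, proper$library_id)
    out[[i]] <- data.table::rbindlist(lapply(names(libs), function(lib) {
      estimate_library_profile(libs[[lib]], k_mad = k_mad,
                               sample_id = sheet$sample_id[i], library_id = lib,
                               min_observations = min_observations)
    }))
  }
  data.table::rbindlist(out)
}

#' Write / read a profile table as TSV
#' @param profiles Profile table.
#' @param path Output (input) file path.
#' @export
write_profiles <- function(profiles, path) {
  .assert_profile_table(profiles)
  data.table::fwrite(profiles, path, sep = "\t")
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  p <- data.table::fread(path, sep = "\t", header = TRUE,
                         colClasses = list(character = c("sample_id", "library_id")))
  .assert_profile_table(p)
  p
}
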