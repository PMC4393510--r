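# Memory-bounded external sort of routing-key partitions.
#
# Records are sorted by the full tuple (start1, end1, chrom2, start2,
# sample_id, read_id) — a total order, so pipelines are bit-reproducible:
# sorting only by the left-most coordinate would leave tie order to chance.
# Run files reuse the spill TSV dialect, and both stages move verbatim text
# lines so the merged output is byte-identical whatever the memory budget.

# Column positions of the sort-key fields in the spill dialect.
.KEY_NUM <- c(start1 = 2L, end1 = 3L, start2 = 6L)
.KEY_CHR <- c(chrom2 = 5L, sample_id = 9L, read_id = 11L)

# Build a radix-comparable key string per line (numbers zero-padded).
.sort_keys <- function(lines) {
  f <- data.table::tstrsplit(lines, "\t", fixed = TRUE)
  sprintf("%012d\r%012d\r%s\r%012d\r%s\r%s",
          as.integer(f[[2L]]), as.integer(f[[3L]]), f[[5L]],
          as.integer(f[[6L]]), f[[9L]], f[[11L]])
}

.pair_header <- function() paste(PAIR_COLS, collapse = "\t")

#' Split a partition into sorted runs under a memory budget
#'
#' Reads the spill file at most `memory_budget` records at a time, sorts
#' each chunk by the full sort key and writes it as a run file. The
#' concatenation of all runs is a permutation of the input.
#'
#' @param spill_file Partition spill file (TSV dialect with header).
#' @param memory_budget Maximum number of records held in memory (>= 1).
#' @param run_dir Directory for run files (created if needed).
#' @return Character vector of run file paths (possibly empty).
#' @export
sort_partition <- function(spill_file, memory_budget, run_dir = tempfile()) {
  if (memory_budget < 1) .stopf("memory_budget must be >= 1")
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  con <- file(spill_file, open = "r")
  on.exit(close(con), add = TRUE)
  header <- readLines(con, n = 1L)
  if (length(header) == 0) return(character())
  runs <- character()
  repeat {
    chunk <- readLines(con, n = memory_budget)
    if (length(chunk) == 0) break
    o <- order(.sort_keys(chunk), method = "radix")
    run <- file.path(run_dir, sprintf("run-%05d.tsv", length(runs) + 1L))
    writeLines(c(header, chunk[o]), run)
    runs <- c(runs, run)
  }
  runs
}

# Merge up to this many runs at once; beyond it, merge hierarchically so the
# number of open connections stays bounded.
.MERGE_FAN_IN <- 32L

#' k-way merge of sorted runs
#'
#' Streams the run files, holding one record per run, and repeatedly emits
#' the smallest head. Detects unsorted runs (an adjacent inversion) and
#' errors naming the offending run. True duplicate records are preserved.
#'
#' @param run_files Character vector of sorted run files.
#' @param out Output file path for the merged, globally sorted partition.
#' @return `out`, invisibly. With zero runs an empty (header-only) file is
#'   written.
#' @export
kway_merge <- function(run_files, out) {
  if (length(run_files) > .MERGE_FAN_IN) {
    groups <- split(run_files,
                    ceiling(seq_along(run_files) / .MERGE_FAN_IN))
    tmp <- vapply(groups, function(g) {
      t <- tempfile(fileext = ".tsv")
      kway_merge(g, t)
      t
    }, character(1))
    on.exit(unlink(tmp), add = TRUE)
    return(kway_merge(tmp, out))
  }
  k <- length(run_files)
  if (k == 0) {
    writeLines(.pair_header(), out)
    return(invisible(out))
  }
  cons <- lapply(run_files, function(f) file(f, open = "r"))
  on.exit(lapply(cons, close), add = TRUE)
  for (con in cons) readLines(con, n = 1L)  # skip headers

  heads <- character(k)
  keys <- character(k)
  alive <- logical(k)
  for (i in seq_len(k)) {
    l <- readLines(cons[[i]], n = 1L)
    if (length(l) == 1L) {
      heads[i] <- l; keys[i] <- .sort_keys(l); alive[i] <- TRUE
    }
  }
  sink_con <- file(out, open = "w")
  on.exit(close(sink_con), add = TRUE)
  writeLines(.pair_header(), sink_con)
  buf <- character(0)
  while (any(alive)) {
    live <- which(alive)
    # smallest key among live heads; ties go to the lowest run index
    i <- live[order(keys[live], method = "radix")[1L]]
    buf <- c(buf, heads[i])
    if (length(buf) >= 8192L) {
      writeLines(buf, sink_con); buf <- character(0)
    }
    l <- readLines(cons[[i]], n = 1L)
    if (length(l) == 1L) {
      nk <- .sort_keys(l)
      if (order(c(keys[i], nk), method = "radix")[1L] == 2L)  # nk < old head
        .stopf("run %s is not sorted", run_files[i])
      heads[i] <- l; keys[i] <- nk
    } else {
      alive[i] <- FALSE
    }
  }
  if (length(buf) > 0) writeLines(buf, sink_con)
  invisible(out)
}

#' Sort every partition of a workdir
#'
#' Convenience wrapper: for each spill file in the manifest, runs
#' [sort_partition()] then [kway_merge()], producing
#' `workdir/sorted/partition-NNNN.tsv`.
#'
#' @param workdir Working directory containing `partitions.tsv` and `spill/`.
#' @param memory_records Memory budget in records (default 500000).
#' @return Updated manifest with a `sorted_file` column.
#' @export
sort_partitions <- function(workdir, memory_records = 500000L) {
  manifest <- data.table::fread(file.path(workdir, "partitions.tsv"),
                                sep = "\t", header = TRUE)
  sorted_dir <- file.path(workdir, "sorted")
  dir.create(sorted_dir, recursive = TRUE, showWarnings = FALSE)
  manifest[, sorted_file := file.path(sorted_dir, basename(file))]
  for (j in seq_len(nrow(manifest))) {
    runs <- sort_partition(manifest$file[j], memory_records,
                           run_dir = tempfile("runs"))
    kway_merge(runs, manifest$sorted_file[j])
    unlink(runs)
  }
  manifest
}

#' Read a sorted partition back into a pair table
#' @param path Sorted partition TSV.
#' @return Pair table (`data.table`).
#' @export
read_pair_file <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(
                            character = c("chrom1", "strand1", "chrom2",
                                          "strand2", "sample_id",
                                          "library_id", "read_id"),
                            integer = PAIR_INT_COLS))
  if (nrow(dt) == 0) return(.empty_pair_table())
  dt
}
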