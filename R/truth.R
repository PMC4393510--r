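# Truth-set evaluation: breakpoint probe intervals, exclusion regions and a
# support-threshold ROC sweep, for validated deletion truth sets.

.probe <- function(center, width) {
  lo <- pmax(0L, as.integer(center) - as.integer(floor(width / 2)))
  data.table::data.table(lo = lo, hi = lo + as.integer(width))
}

#' Probe intervals of a predicted breakpoint
#'
#' Represents each predicted breakpoint as two fixed-width intervals (200 bp
#' by default) centered on the midpoints of the call's two breakpoint
#' intervals, clipped at the chromosome origin, so that calls from tools
#' with different native resolutions are comparable.
#'
#' @param calls Call table (needs `chrom1`, `start1`, `end1`, `chrom2`,
#'   `start2`, `end2`).
#' @param width Probe width in bp (default 200).
#' @return `data.table`: `chrom1`, `p1_lo`, `p1_hi`, `chrom2`, `p2_lo`,
#'   `p2_hi`, one row per call.
#' @export
call_probe_intervals <- function(calls, width = 200L) {
  if (width <= 0) .stopf("width must be positive")
  p1 <- .probe(floor((calls$start1 + calls$end1) / 2), width)
  p2 <- .probe(floor((calls$start2 + calls$end2) / 2), width)
  data.table::data.table(chrom1 = calls$chrom1, p1_lo = p1$lo, p1_hi = p1$hi,
                         chrom2 = calls$chrom2, p2_lo = p2$lo, p2_hi = p2$hi)
}

#' Probe intervals of truth-set deletions
#'
#' Same probe construction, centered on the two edges (`start`, `end`) of
#' each truth deletion.
#'
#' @param truth `data.table` with `chrom`, `start`, `end`, `id`
#'   (0-based half-open; `end > start`).
#' @param width Probe width in bp (default 200).
#' @return `data.table`: `chrom`, `p1_lo`, `p1_hi`, `p2_lo`, `p2_hi`, `id`.
#' @export
truth_probe_intervals <- function(truth, width = 200L) {
  if (width <= 0) .stopf("width must be positive")
  if (any(truth$end <= truth$start))
    .stopf("truth deletions must have end > start")
  p1 <- .probe(truth$start, width)
  p2 <- .probe(truth$end, width)
  data.table::data.table(chrom = truth$chrom, p1_lo = p1$lo, p1_hi = p1$hi,
                         p2_lo = p2$lo, p2_hi = p2$hi, id = truth$id)
}

.overlaps_regions <- function(chrom, lo, hi, regions) {
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(lo + 1L, hi))
  s <- GenomicRanges::GRanges(regions$chrom,
                              IRanges::IRanges(regions$start + 1L,
                                               regions$end))
  IRanges::overlapsAny(q, s)
}

#' Drop calls or truth entries overlapping exclusion regions
#'
#' An entry is dropped if either of its probe intervals overlaps any
#' exclusion region by at least 1 bp (half-open semantics: touching
#' endpoints do not overlap). Exclusion lists typically mark regions of
#' excessively high read depth.
#'
#' @param items Call table or truth table.
#' @param regions `data.table` with `chrom`, `start`, `end` (0-based
#'   half-open), or NULL for no exclusions.
#' @param width Probe width used to test overlap (default 200).
#' @param type `"calls"` or `"truth"`.
#' @return Filtered `items`.
#' @export
apply_exclusions <- function(items, regions, width = 200L,
                             type = c("calls", "truth")) {
  type <- match.arg(type)
  if (is.null(regions) || nrow(regions) == 0) return(items)
  if (type == "calls") {
    pr <- call_probe_intervals(items, width)
    hit <- .overlaps_regions(pr$chrom1, pr$p1_lo, pr$p1_hi, regions) |
      .overlaps_regions(pr$chrom2, pr$p2_lo, pr$p2_hi, regions)
  } else {
    pr <- truth_probe_intervals(items, width)
    hit <- .overlaps_regions(pr$chrom, pr$p1_lo, pr$p1_hi, regions) |
      .overlaps_regions(pr$chrom, pr$p2_lo, pr$p2_hi, regions)
  }
  items[!hit, ]
}

#' ROC sweep of deletion calls against a truth set
#'
#' For each minimum-support threshold, filters the calls with
#' [filter_calls()] and counts true and false positives. A call matches a
#' truth deletion iff both of its probe intervals intersect both of the
#' truth deletion's probe intervals (on the same chromosome). TP counts
#' distinct truth deletions detected — two calls hitting the same deletion
#' credit it once — and FP counts kept calls matching no truth deletion.
#'
#' @param calls Deletion-class call table (exclusions already applied).
#' @param truth Truth deletion table (`chrom`, `start`, `end`, `id`),
#'   non-overlapping.
#' @param support_range Integer vector of minimum-support thresholds
#'   (default 4:10).
#' @param require_sample Optional sample that must contribute >= 1 pair.
#' @param width Probe width (default 200).
#' @return `data.table`: `min_support`, `tp`, `fp`.
#' @export
roc_curve <- function(calls, truth, support_range = 4:10,
                      require_sample = NULL, width = 200L) {
  tg <- GenomicRanges::GRanges(truth$chrom,
                               IRanges::IRanges(truth$start + 1L, truth$end))
  if (length(tg) > 1 &&
      any(IRanges::overlapsAny(tg, tg, type = "any") &
          GenomicRanges::countOverlaps(tg, tg) > 1))
    .stopf("truth set contains overlapping deletions")

  cp <- call_probe_intervals(calls, width)
  tp <- truth_probe_intervals(truth, width)
  g <- function(chrom, lo, hi) GenomicRanges::GRanges(
    chrom, IRanges::IRanges(lo + 1L, hi))
  h1 <- GenomicRanges::findOverlaps(g(cp$chrom1, cp$p1_lo, cp$p1_hi),
                                    g(tp$chrom, tp$p1_lo, tp$p1_hi))
  h2 <- GenomicRanges::findOverlaps(g(cp$chrom2, cp$p2_lo, cp$p2_hi),
                                    g(tp$chrom, tp$p2_lo, tp$p2_hi))
  k1 <- paste(S4Vectors::queryHits(h1), S4Vectors::subjectHits(h1))
  k2 <- paste(S4Vectors::queryHits(h2), S4Vectors::subjectHits(h2))
  both <- intersect(k1, k2)
  hit <- do.call(rbind, lapply(strsplit(both, " "), as.integer))
  call_truth <- if (is.null(hit))
    data.table::data.table(call = integer(), truth = integer()) else
    data.table::data.table(call = hit[, 1], truth = hit[, 2])

  out <- data.table::data.table(min_support = as.integer(support_range),
                                tp = NA_integer_, fp = NA_integer_)
  for (i in seq_along(support_range)) {
    kept <- filter_calls(calls, support_range[i], require_sample)
    kept_idx <- which(calls$call_id %in% kept$call_id)
    m <- call_truth[call_truth$call %in% kept_idx, ]
    out$tp[i] <- length(unique(m$truth))
    out$fp[i] <- sum(!(kept_idx %in% call_truth$call))
  }
  out
}

#' Read a BED file of regions or truth deletions
#'
#' @param path BED path (chrom, start, end, optional name).
#' @return `data.table` with `chrom`, `start`, `end` and, if present, `id`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0)
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), id = character()))
  f <- strsplit(lines, "\t", fixed = TRUE)
  out <- data.table::data.table(
    chrom = vapply(f, `[`, "", 1),
    start = as.integer(vapply(f, `[`, "", 2)),
    end = as.integer(vapply(f, `[`, "", 3))
  )
  if (all(lengths(f) >= 4)) out$id <- vapply(f, `[`, "", 4)
  out
}

#' Write truth deletions (or regions) as BED
#' @param x `data.table` with `chrom`, `start`, `end` and optionally `id`.
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  cols <- intersect(c("chrom", "start", "end", "id"), names(x))
  data.table::fwrite(x[, cols, with = FALSE], path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}
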