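#' Candidate-breakpoint rectangles of discordant pairs
#'
#' Each discordant pair constrains the two breakpoints of the
#' rearrangement it supports to a rectangle: the product of one candidate
#' interval per end, whose width is the pair's own library cutoff
#' `W = max_concordant_span`. For an end mapped to `[s, e)` on the `+`
#' strand the breakpoint must lie in `[e, s + W)` (to the right of the
#' mapped bases, within fragment reach); on the `-` strand, in
#' `[e - W, s)`. Screening with each library's own `W` is what lets pairs
#' from libraries with different insert-size distributions corroborate the
#' same SV.
#'
#' @param pairs Canonicalized pair table.
#' @param profiles Profile table covering every (sample, library).
#' @return `data.table` with columns `lo1`, `hi1`, `lo2`, `hi2`
#'   (0-based half-open), one row per pair.
#' @export
breakpoint_rectangles <- function(pairs, profiles) {
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
  if (any(w <= pairs$end1 - pairs$start1) || any(w <= pairs$end2 - pairs$start2))
    .stopf(paste("degenerate profile: max_concordant_span does not exceed a",
                 "mapped read length"))
  r <- data.table::data.table(
    lo1 = ifelse(pairs$strand1 == "+", pairs$end1, pairs$end1 - w),
    hi1 = ifelse(pairs$strand1 == "+", pairs$start1 + w, pairs$start1),
    lo2 = ifelse(pairs$strand2 == "+", pairs$end2, pairs$end2 - w),
    hi2 = ifelse(pairs$strand2 == "+", pairs$start2 + w, pairs$start2)
  )
  r[, `:=`(lo1 = as.integer(lo1), hi1 = as.integer(hi1),
           lo2 = as.integer(lo2), hi2 = as.integer(hi2))]
  r
}

#' Are two breakpoint rectangles compatible?
#'
#' Two pairs can support the same breakpoint iff their candidate intervals
#' overlap on both sides. Reflexive and symmetric.
#'
#' @param a,b One-row rectangle tables (or lists) with `lo1`, `hi1`, `lo2`,
#'   `hi2`.
#' @return Logical scalar.
#' @export
rectangles_compatible <- function(a, b) {
  min(a$hi1, b$hi1) > max(a$lo1, b$lo1) &&
    min(a$hi2, b$hi2) > max(a$lo2, b$lo2)
}

#' Sweep-line greedy clustering of one sorted partition
#'
#' Walks the pairs of one routing-key partition in sweep order, maintaining
#' a list of open clusters. Each cluster tracks the running intersection of
#' its members' rectangles and its rectangle footprint on side 1. For each
#' incoming pair: clusters whose side-1 footprint the sweep has passed are
#' closed (no later pair can overlap them); among the remaining clusters
#' whose running intersections stay non-empty with the pair added, the pair
#' joins the one with the largest `min(side-1 overlap, side-2 overlap)`,
#' ties going to the oldest cluster; otherwise it seeds a new cluster. A
#' cluster that reaches `cluster_cap` members is marked `dropped_depth` and
#' stops growing: such pile-ups arise in poorly assembled reference regions
#' and yield false positives, so they are logged and never emitted as calls.
#'
#' The stream must arrive sorted by the sort key; internally pairs are
#' re-ordered (stably) by their rectangle lower bound on side 1, so that the
#' sweep position is monotone even when libraries with different cutoffs
#' mix within one partition.
#'
#' @param pairs Pair table for a single routing key, sorted by sort key.
#' @param profiles Profile table.
#' @param cluster_cap Maximum members per cluster (see
#'   [default_cluster_cap()]).
#' @return List with `clusters` (list of closed clusters: `members` = row
#'   indices into `pairs`, intervals, `state`) and `dropped` (the
#'   depth-capped ones, same shape).
#' @export
sweep_cluster <- function(pairs, profiles, cluster_cap = 100L) {
  .assert_pair_table(pairs)
  if (cluster_cap < 1) .stopf("cluster_cap must be >= 1")
  n <- nrow(pairs)
  if (n == 0) return(list(clusters = list(), dropped = list()))
  if (length(unique(paste(pairs$chrom1, pairs$chrom2, pairs$strand1,
                          pairs$strand2))) != 1)
    .stopf("sweep_cluster expects a single routing key per partition")
  if (is.unsorted(pairs$start1))
    .stopf("partition is not sorted by left-most coordinate")

  rect <- breakpoint_rectangles(pairs, profiles)
  ord <- order(rect$lo1, seq_len(n), method = "radix")

  open <- list()    # each: list(members, lo1, hi1, lo2, hi2, fp_hi1, born)
  closed <- list()
  dropped <- list()
  born <- 0L
  for (i in ord) {
    p <- list(lo1 = rect$lo1[i], hi1 = rect$hi1[i],
              lo2 = rect$lo2[i], hi2 = rect$hi2[i])
    # close clusters the sweep has passed
    if (length(open) > 0) {
      passed <- vapply(open, function(cl) cl$fp_hi1 <= p$lo1, logical(1))
      closed <- c(closed, open[passed])
      open <- open[!passed]
    }
    # score compatible clusters
    best <- 0L
    best_score <- -1L
    for (j in seq_along(open)) {
      cl <- open[[j]]
      ov1 <- min(cl$hi1, p$hi1) - max(cl$lo1, p$lo1)
      ov2 <- min(cl$hi2, p$hi2) - max(cl$lo2, p$lo2)
      if (ov1 > 0 && ov2 > 0) {
        score <- min(ov1, ov2)
        if (score > best_score ||
            (score == best_score && cl$born < open[[best]]$born)) {
          best <- j
          best_score <- score
        }
      }
    }
    if (best > 0L) {
      cl <- open[[best]]
      cl$members <- c(cl$members, i)
      cl$lo1 <- max(cl$lo1, p$lo1); cl$hi1 <- min(cl$hi1, p$hi1)
      cl$lo2 <- max(cl$lo2, p$lo2); cl$hi2 <- min(cl$hi2, p$hi2)
      cl$fp_hi1 <- max(cl$fp_hi1, p$hi1)
      if (length(cl$members) >= cluster_cap) {
        cl$state <- "dropped_depth"
        dropped <- c(dropped, list(cl))
        open[[best]] <- NULL
      } else {
        open[[best]] <- cl
      }
    } else {
      born <- born + 1L
      open <- c(open, list(list(
        members = i, lo1 = p$lo1, hi1 = p$hi1, lo2 = p$lo2, hi2 = p$hi2,
        fp_hi1 = p$hi1, born = born, state = "open"
      )))
      if (cluster_cap == 1L) {
        cl <- open[[length(open)]]
        cl$state <- "dropped_depth"
        dropped <- c(dropped, list(cl))
        open[[length(open)]] <- NULL
      }
    }
  }
  closed <- c(closed, open)
  closed <- lapply(closed, function(cl) { cl$state <- "closed"; cl })
  list(clusters = closed, dropped = dropped)
}

#' Default depth cap for clusters
#'
#' Scales with the aggregate sequencing depth of the cohort: with more input
#' data, legitimate clusters legitimately grow deeper. Never below 100.
#'
#' @param mean_depths Numeric vector of per-sample mean depths.
#' @return Integer cap.
#' @export
default_cluster_cap <- function(mean_depths) {
  as.integer(max(100, round_half_up(10 * sum(mean_depths))))
}

#' Finalize a closed cluster into an SV call
#'
#' The call's breakpoint intervals are the final running intersections of
#' its members' rectangles; per-sample support is tallied from member
#' provenance; outer footprints record the extreme mapped coordinates.
#'
#' @param cluster A closed cluster from [sweep_cluster()].
#' @param pairs The pair table the cluster indexes into.
#' @param call_id Identifier for the call.
#' @param sample_levels Sample order used in the support string; defaults to
#'   order of first appearance in `pairs`.
#' @return One-row `data.table`: `call_id`, `svclass`, `chrom1`, `start1`,
#'   `end1`, `chrom2`, `start2`, `end2`, `strand1`, `strand2`,
#'   `total_support`, `support` (string `"sample:count;..."`), plus outer
#'   footprint columns.
#' @export
finalize_call <- function(cluster, pairs, call_id = "call",
                          sample_levels = NULL) {
  if (!identical(cluster$state, "closed"))
    .stopf("cannot finalize a %s cluster", cluster$state)
  m <- pairs[cluster$members, ]
  if (is.null(sample_levels)) sample_levels <- unique(pairs$sample_id)
  sup <- table(factor(m$sample_id, levels = sample_levels))
  sup <- sup[sup > 0]
  rk <- routing_key(m[1, ])
  data.table::data.table(
    call_id = call_id,
    svclass = rk$svclass,
    chrom1 = m$chrom1[1], start1 = cluster$lo1, end1 = cluster$hi1,
    chrom2 = m$chrom2[1], start2 = cluster$lo2, end2 = cluster$hi2,
    strand1 = m$strand1[1], strand2 = m$strand2[1],
    total_support = length(cluster$members),
    support = paste(sprintf("%s:%d", names(sup), as.integer(sup)),
                    collapse = ";"),
    fp_start1 = min(m$start1), fp_end1 = max(m$end1),
    fp_start2 = min(m$start2), fp_end2 = max(m$end2)
  )
}

#' Cluster every sorted partition and emit finalized calls
#'
#' @param manifest Manifest from [sort_partitions()] (needs `sorted_file`).
#' @param profiles Profile table.
#' @param cluster_cap Depth cap per cluster.
#' @param sample_ids Sample order used for the support string (sample-sheet
#'   order); defaults to order of first appearance.
#' @return List with `calls` (data.table) and `drop_log` (data.table:
#'   partition file, dropped cluster sizes).
#' @export
cluster_partitions <- function(manifest, profiles, cluster_cap = 100L,
                               sample_ids = NULL) {
  calls <- list()
  drops <- list()
  counter <- 0L
  abbrev <- c(deletion = "DEL", tandem_duplication = "DUP",
              inversion = "INV", translocation = "TRA")
  for (j in seq_len(nrow(manifest))) {
    pairs <- read_pair_file(manifest$sorted_file[j])
    if (nrow(pairs) == 0) next
    if (!is.null(sample_ids))
      pairs$sample_id <- as.character(pairs$sample_id)
    res <- sweep_cluster(pairs, profiles, cluster_cap = cluster_cap)
    lev <- if (is.null(sample_ids)) unique(pairs$sample_id) else
      c(intersect(sample_ids, unique(pairs$sample_id)),
        setdiff(unique(pairs$sample_id), sample_ids))
    for (cl in res$clusters) {
      counter <- counter + 1L
      id <- sprintf("%s_%06d", abbrev[[manifest$svclass[j]]], counter)
      calls[[length(calls) + 1L]] <-
        finalize_call(cl, pairs, id, sample_levels = lev)
    }
    if (length(res$dropped) > 0) {
      drops[[length(drops) + 1L]] <- data.table::data.table(
        partition = manifest$sorted_file[j],
        n_members = vapply(res$dropped, function(cl) length(cl$members),
                           integer(1))
      )
    }
  }
  calls <- if (length(calls) > 0) data.table::rbindlist(calls) else
    .empty_call_table()
  if (!is.null(sample_ids))
    data.table::setattr(calls, "sample_ids", sample_ids)
  drop_log <- if (length(drops) > 0) data.table::rbindlist(drops) else
    data.table::data.table(partition = character(), n_members = integer())
  list(calls = calls, drop_log = drop_log)
}

.empty_call_table <- function() {
  data.table::data.table(
    call_id = character(), svclass = character(),
    chrom1 = character(), start1 = integer(), end1 = integer(),
    chrom2 = character(), start2 = integer(), end2 = integer(),
    strand1 = character(), strand2 = character(),
    total_support = integer(), support = character(),
    fp_start1 = integer(), fp_end1 = integer(),
    fp_start2 = integer(), fp_end2 = integer()
  )
}
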