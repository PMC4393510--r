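#' Tumor-normal pairing of a cohort
#'
#' Builds the pairing structure from a sample sheet: matched tumor-normal
#' pairs share a non-blank `pair_id`; everything else is unpaired.
#'
#' @param sample_sheet Path or data.frame (see [read_sample_sheet()]).
#' @return List with `pairs` (data.table: `pair_id`, `tumor`, `normal`),
#'   `tumors`, `normals`, `unpaired` (character vectors).
#' @export
sample_pairing <- function(sample_sheet) {
  sheet <- read_sample_sheet(sample_sheet)
  tumors <- sheet$sample_id[sheet$role == "tumor"]
  normals <- sheet$sample_id[sheet$role == "normal"]
  paired <- sheet[!is.na(sheet$pair_id) & sheet$pair_id != "", ]
  pairs <- list()
  for (pid in unique(paired$pair_id)) {
    grp <- paired[paired$pair_id == pid, ]
    t <- grp$sample_id[grp$role == "tumor"]
    n <- grp$sample_id[grp$role == "normal"]
    if (length(t) != 1 || length(n) != 1)
      .stopf("pair %s must contain exactly one tumor and one normal", pid)
    pairs[[length(pairs) + 1L]] <-
      data.table::data.table(pair_id = pid, tumor = t, normal = n)
  }
  pairs <- if (length(pairs) > 0) data.table::rbindlist(pairs) else
    data.table::data.table(pair_id = character(), tumor = character(),
                           normal = character())
  list(pairs = pairs, tumors = tumors, normals = normals,
       unpaired = setdiff(sheet$sample_id, c(pairs$tumor, pairs$normal)))
}

#' Breakpoint presence/absence matrix
#'
#' A call is present in a sample if that sample contributed at least
#' `min_pairs` supporting read pairs.
#'
#' @param calls Call table with `call_id` and `support` columns.
#' @param sample_ids Column order (cohort sample ids).
#' @param min_pairs Presence threshold in read pairs (default 1).
#' @return Logical matrix, rows = call ids, columns = sample ids.
#' @export
presence_matrix <- function(calls, sample_ids, min_pairs = 1L) {
  sup <- parse_support(calls$support)
  m <- matrix(FALSE, nrow = nrow(calls), ncol = length(sample_ids),
              dimnames = list(calls$call_id, sample_ids))
  for (i in seq_along(sup)) {
    s <- sup[[i]][names(sup[[i]]) %in% sample_ids]
    m[i, names(s)[s >= min_pairs]] <- TRUE
  }
  m
}

#' Classify breakpoints as germline / private / tumor- or normal-private
#'
#' Labels are sets, not exclusive: a breakpoint is *germline* if present in
#' at least one normal sample, *private* if present in exactly one sample
#' of the cohort, *tumor_private* / *normal_private* if private to a tumor
#' or normal respectively. A normal-private breakpoint is therefore also
#' germline under the at-least-one-normal rule.
#'
#' @param presence Logical presence matrix ([presence_matrix()]).
#' @param pairing Pairing structure ([sample_pairing()]).
#' @return `data.table` with one row per call: `call_id`, `n_present`,
#'   logical columns `germline`, `private`, `tumor_private`,
#'   `normal_private`, and `private_sample` (NA unless private).
#' @export
classify_breakpoints <- function(presence, pairing) {
  missing <- setdiff(c(pairing$tumors, pairing$normals), colnames(presence))
  if (length(missing) > 0)
    .stopf("presence matrix lacks columns for samples: %s",
           paste(missing, collapse = ", "))
  n_present <- rowSums(presence)
  if (any(n_present == 0))
    .stopf("call(s) present in no sample: %s",
           paste(utils::head(rownames(presence)[n_present == 0]),
                 collapse = ", "))
  normals <- intersect(colnames(presence), pairing$normals)
  tumors <- intersect(colnames(presence), pairing$tumors)
  germline <- rowSums(presence[, normals, drop = FALSE]) >= 1
  private <- n_present == 1
  which_sample <- colnames(presence)[max.col(presence, ties.method = "first")]
  private_sample <- ifelse(private, which_sample, NA_character_)
  data.table::data.table(
    call_id = rownames(presence),
    n_present = as.integer(n_present),
    germline = germline,
    private = private,
    tumor_private = private & private_sample %in% tumors,
    normal_private = private & private_sample %in% normals,
    private_sample = private_sample
  )
}

#' Somatic false discovery rate from a cohort classification
#'
#' Assumes every variant private to a normal genome is false and that false
#' positives arise at similar absolute rates in tumor and normal datasets;
#' the somatic FDR is then `100 * n_normal_private / n_tumor_private` (a
#' percentage).
#'
#' @param labels Classification table ([classify_breakpoints()]).
#' @return Numeric percentage.
#' @export
somatic_fdr <- function(labels) {
  nt <- sum(labels$tumor_private)
  if (nt == 0) .stopf("somatic FDR undefined: no tumor-private breakpoints")
  100 * sum(labels$normal_private) / nt
}

#' Somatic FDR as a function of additional tumor-normal pairs
#'
#' Estimates how the somatic FDR shrinks as more pairs join the analysis.
#' For each focal pair and each N, N additional pairs are drawn uniformly
#' without replacement; a candidate present in the focal normal counts as a
#' false somatic call iff it is absent from the focal tumor and from every
#' sample of the N additional pairs, and the denominator is the analogous
#' tumor-side count. At N = 0 this reduces to the classical
#' tumor-versus-matched-normal estimator. Counts are pooled over focal
#' pairs within a replicate and the mean over replicates is reported.
#'
#' @param presence Logical presence matrix.
#' @param pairing Pairing structure with at least `max(n_values) + 1` pairs.
#' @param n_values Integer vector of N (additional pairs).
#' @param replicates Monte-Carlo replicates (default 50).
#' @param seed Integer seed.
#' @return `data.table` with columns `n_additional`, `mean_fdr`.
#' @export
fdr_vs_n <- function(presence, pairing, n_values, replicates = 50L, seed) {
  pr <- pairing$pairs
  np <- nrow(pr)
  if (any(n_values >= np))
    .stopf("N must be smaller than the number of pairs (%d)", np)
  if (replicates < 1) .stopf("replicates must be >= 1")
  set.seed(seed)
  out <- data.table::data.table(n_additional = as.integer(n_values),
                                mean_fdr = NA_real_)
  for (vi in seq_along(n_values)) {
    N <- n_values[vi]
    fdrs <- numeric(replicates)
    for (r in seq_len(replicates)) {
      num <- 0L; den <- 0L
      for (f in seq_len(np)) {
        others <- setdiff(seq_len(np), f)
        extra <- if (N > 0) sample(others, N) else integer(0)
        screen <- c(pr$tumor[extra], pr$normal[extra])
        scr_present <- if (length(screen) > 0)
          rowSums(presence[, screen, drop = FALSE]) > 0 else
          rep(FALSE, nrow(presence))
        in_n <- presence[, pr$normal[f]]
        in_t <- presence[, pr$tumor[f]]
        num <- num + sum(in_n & !in_t & !scr_present)
        den <- den + sum(in_t & !in_n & !scr_present)
      }
      fdrs[r] <- if (den > 0) 100 * num / den else NA_real_
    }
    out$mean_fdr[vi] <- mean(fdrs, na.rm = TRUE)
  }
  out
}

#' Hierarchical clustering of samples by shared breakpoints
#'
#' Computes pairwise Jaccard distances between the presence columns of the
#' samples and agglomerates with average linkage. Intended for germline
#' deletion/duplication breakpoints (see
#' [germline_deldup_presence()]); with matched tumor-normal pairs, each
#' tumor should cluster with its own normal.
#'
#' @param presence Logical presence matrix (calls x samples).
#' @return List with `dist` (a `dist`), `hclust`, `phylo` (an
#'   [ape::as.phylo()] tree) and `newick` (serialized tree string).
#' @export
sample_clustering <- function(presence) {
  if (ncol(presence) < 2) .stopf("need at least 2 samples")
  if (nrow(presence) < 1) .stopf("need at least 1 call")
  empty <- colSums(presence) == 0
  if (any(empty))
    warning(sprintf("sample(s) with no present call (distance 1 to all): %s",
                    paste(colnames(presence)[empty], collapse = ", ")))
  d <- vegan::vegdist(t(presence) * 1, method = "jaccard", binary = TRUE)
  dm <- as.matrix(d)
  dm[is.na(dm)] <- 1
  diag(dm) <- 0
  d <- stats::as.dist(dm)
  hc <- stats::hclust(d, method = "average")
  ph <- ape::as.phylo(hc)
  list(dist = d, hclust = hc, phylo = ph,
       newick = ape::write.tree(ph))
}

#' Presence matrix restricted to germline deletion/duplication breakpoints
#'
#' Keeps same-chromosome deletion and tandem-duplication calls whose inner
#' span (`start2 - end1`) is at most `max_span`, and whose classification is
#' germline; intended as input to [sample_clustering()].
#'
#' @param calls Call table.
#' @param presence Presence matrix over the same calls.
#' @param labels Classification ([classify_breakpoints()]).
#' @param max_span Maximum inner span in bp (default 1e6).
#' @return Row-subset of `presence`.
#' @export
germline_deldup_presence <- function(calls, presence, labels, max_span = 1e6) {
  stopifnot(identical(calls$call_id, rownames(presence)),
            identical(calls$call_id, labels$call_id))
  span <- calls$start2 - calls$end1
  keep <- calls$svclass %in% c("deletion", "tandem_duplication") &
    calls$chrom1 == calls$chrom2 & span <= max_span & labels$germline
  presence[keep, , drop = FALSE]
}
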