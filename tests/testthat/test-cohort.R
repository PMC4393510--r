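two_pair_presence <- function(rows) {
  sheet <- data.table::data.table(
    sample_id = c("T1", "N1", "T2", "N2"),
    role = c("tumor", "normal", "tumor", "normal"),
    pair_id = c("P1", "P1", "P2", "P2"), path = "")
  m <- do.call(rbind, rows)
  rownames(m) <- sprintf("c%d", seq_len(nrow(m)))
  colnames(m) <- sheet$sample_id
  list(presence = m, pairing = sample_pairing(sheet))
}

test_that("breakpoint labels compose as overlapping sets", {
  x <- two_pair_presence(list(
    c(FALSE, TRUE, FALSE, FALSE),   # private to a normal
    c(TRUE, FALSE, FALSE, FALSE),   # private to a tumor
    c(TRUE, TRUE, FALSE, FALSE)))   # matched tumor + normal
  lab <- classify_breakpoints(x$presence, x$pairing)
  expect_equal(lab$germline, c(TRUE, FALSE, TRUE))
  expect_equal(lab$private, c(TRUE, TRUE, FALSE))
  expect_equal(lab$normal_private, c(TRUE, FALSE, FALSE))
  expect_equal(lab$tumor_private, c(FALSE, TRUE, FALSE))
  # a normal-private breakpoint is also germline under the >=1-normal rule
  expect_true(lab$germline[1] && lab$normal_private[1])

  bad <- two_pair_presence(list(c(FALSE, FALSE, FALSE, FALSE)))
  expect_error(classify_breakpoints(bad$presence, bad$pairing), "no sample")
})

test_that("presence respects the min_pairs threshold", {
  calls <- data.table::data.table(
    call_id = c("a", "b"), support = c("T1:3;N1:1", "T1:1"))
  m <- presence_matrix(calls, c("T1", "N1"), min_pairs = 1)
  expect_equal(m, matrix(c(TRUE, TRUE, TRUE, FALSE), 2, byrow = TRUE,
                         dimnames = list(c("a", "b"), c("T1", "N1"))))
  m2 <- presence_matrix(calls, c("T1", "N1"), min_pairs = 2)
  expect_equal(unname(m2[, "N1"]), c(FALSE, FALSE))
})

test_that("somatic FDR is the normal- to tumor-private ratio, in percent", {
  mk <- function(n_norm, n_tum) data.table::data.table(
    tumor_private = rep(c(FALSE, TRUE), c(n_norm, n_tum)),
    normal_private = rep(c(TRUE, FALSE), c(n_norm, n_tum)))
  expect_equal(round(somatic_fdr(mk(323, 6179)), 1), 5.2)
  expect_equal(somatic_fdr(mk(0, 10)), 0)
  expect_equal(somatic_fdr(mk(10, 100)), 10.0)
  # scale invariance
  expect_equal(somatic_fdr(mk(30, 300)), somatic_fdr(mk(10, 100)))
  expect_error(somatic_fdr(mk(5, 0)), "undefined")
})

test_that("germline plus tumor-private labels cover a cohort call set", {
  x <- synthetic_cohort_presence(n_tumor_private = 40, n_normal_private = 7,
                                 n_shared_germline = 120, n_pairs = 10)
  lab <- classify_breakpoints(x$presence, x$pairing)
  expect_equal(sum(lab$germline) + sum(lab$tumor_private), nrow(x$presence))
  expect_equal(sum(lab$tumor_private), 40)
  expect_equal(sum(lab$normal_private), 7)
})

test_that("the FDR-vs-N curve starts at the pairwise estimator and declines", {
  sim <- simulate_cohort_calls(n_pairs = 20, n_germline = 150, n_somatic = 25,
                               n_false = 20, seed = 123)
  presence <- presence_matrix(sim$calls, sim$sheet$sample_id)
  pairing <- sample_pairing(sim$sheet)
  curve <- fdr_vs_n(presence, pairing, n_values = c(0, 5, 10, 19),
                    replicates = 25, seed = 7)

  # N = 0 reduces to the deterministic pairwise-only estimator
  num <- 0L; den <- 0L
  for (f in seq_len(nrow(pairing$pairs))) {
    in_n <- presence[, pairing$pairs$normal[f]]
    in_t <- presence[, pairing$pairs$tumor[f]]
    num <- num + sum(in_n & !in_t)
    den <- den + sum(in_t & !in_n)
  }
  expect_equal(curve$mean_fdr[1], 100 * num / den)

  # non-increasing in expectation (Monte-Carlo tolerance: allow tiny bumps)
  expect_true(all(diff(curve$mean_fdr) <= 1e-8 + 0.02 * curve$mean_fdr[1]))
  expect_lt(curve$mean_fdr[4], curve$mean_fdr[1])

  expect_error(fdr_vs_n(presence, pairing, n_values = 20, seed = 1),
               "smaller than")
})

test_that("sample clustering pairs each tumor with its matched normal", {
  sim <- simulate_cohort_calls(n_pairs = 10, n_germline = 250, n_somatic = 10,
                               n_false = 10, seed = 42)
  presence <- presence_matrix(sim$calls, sim$sheet$sample_id)
  pairing <- sample_pairing(sim$sheet)
  lab <- classify_breakpoints(presence, pairing)
  germ <- presence[lab$germline, , drop = FALSE]
  cl <- sample_clustering(germ)
  dm <- as.matrix(cl$dist)
  for (f in seq_len(nrow(pairing$pairs))) {
    t <- pairing$pairs$tumor[f]; n <- pairing$pairs$normal[f]
    others <- setdiff(colnames(dm), c(t, n))
    expect_lt(dm[t, n], min(dm[t, others]))
  }
  # the tree serializes to parseable Newick
  tree <- ape::read.tree(text = cl$newick)
  expect_setequal(tree$tip.label, colnames(germ))
})

test_that("Jaccard distances hit their bounds for identical and disjoint samples", {
  m <- matrix(c(TRUE, TRUE, FALSE,
                TRUE, TRUE, FALSE,
                FALSE, FALSE, TRUE), nrow = 3,
              dimnames = list(c("c1", "c2", "c3"), c("s1", "s2", "s3")))
  cl <- sample_clustering(m)
  dm <- as.matrix(cl$dist)
  expect_equal(dm["s1", "s2"], 0)
  expect_equal(dm["s1", "s3"], 1)
})

test_that("germline deletion/duplication presence filter applies class, span and label", {
  calls <- data.table::data.table(
    call_id = c("a", "b", "c", "d"),
    svclass = c("deletion", "deletion", "inversion", "tandem_duplication"),
    chrom1 = "chr1", start1 = 0L, end1 = c(10L, 10L, 10L, 10L),
    chrom2 = "chr1", start2 = c(500L, 2000010L, 500L, 500L),
    end2 = c(700L, 2000210L, 700L, 700L),
    strand1 = "+", strand2 = "-",
    total_support = 5L,
    support = c("N1:5", "N1:5", "N1:5", "T1:5"))
  sheet <- data.table::data.table(sample_id = c("T1", "N1"),
                                  role = c("tumor", "normal"),
                                  pair_id = "P1", path = "")
  presence <- presence_matrix(calls, sheet$sample_id)
  lab <- classify_breakpoints(presence, sample_pairing(sheet))
  germ <- germline_deldup_presence(calls, presence, lab, max_span = 1e6)
  # "b" exceeds 1 Mb, "c" is an inversion, "d" is tumor-private
  expect_equal(rownames(germ), "a")
})
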