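test_that("breakpoint rectangles point away from the mapped bases", {
  prof <- make_profiles(max_concordant_span = 325L)
  p <- make_pairs(start1 = 100L, end1 = 150L, strand1 = "+",
                  start2 = 500L, end2 = 550L, strand2 = "-")
  r <- breakpoint_rectangles(p, prof)
  expect_equal(unlist(r[1, c("lo1", "hi1")]), c(lo1 = 150L, hi1 = 425L))
  expect_equal(unlist(r[1, c("lo2", "hi2")]), c(lo2 = 225L, hi2 = 500L))
  # a cutoff no larger than the mapped length leaves an empty interval
  degenerate <- make_profiles(max_concordant_span = 50L)
  expect_error(breakpoint_rectangles(p, degenerate), "degenerate")
})

test_that("rectangle compatibility needs overlap on both sides", {
  a <- list(lo1 = 150L, hi1 = 425L, lo2 = 600L, hi2 = 875L)
  b <- list(lo1 = 200L, hi1 = 480L, lo2 = 650L, hi2 = 900L)
  expect_true(rectangles_compatible(a, b))
  expect_true(rectangles_compatible(a, a))
  disjoint1 <- list(lo1 = 500L, hi1 = 600L, lo2 = 650L, hi2 = 900L)
  expect_false(rectangles_compatible(a, disjoint1))
})

test_that("the sweep clusters compatible pairs and closes passed clusters", {
  prof <- make_profiles(max_concordant_span = 325L)
  # four mutually compatible pairs around one junction
  p <- random_separated_partition(5, n_clusters = 1, members_range = 4:4)
  res <- sweep_cluster(p$pairs, p$profiles)
  expect_length(res$clusters, 1L)
  expect_length(res$clusters[[1]]$members, 4L)

  # a pair far to the right terminates the first cluster and seeds another
  p2 <- random_separated_partition(6, n_clusters = 2, members_range = 3:3)
  res2 <- sweep_cluster(p2$pairs, p2$profiles)
  expect_length(res2$clusters, 2L)
  expect_equal(member_sets(res2$clusters),
               unname(split(seq_along(p2$group), p2$group)))

  # depth cap: 5 compatible pairs with cap 3 -> one dropped cluster, no call
  p3 <- random_separated_partition(7, n_clusters = 1, members_range = 5:5)
  res3 <- sweep_cluster(p3$pairs, p3$profiles, cluster_cap = 3)
  expect_length(res3$dropped, 1L)
  expect_equal(res3$dropped[[1]]$state, "dropped_depth")
  expect_error(finalize_call(res3$dropped[[1]], p3$pairs), "dropped_depth")
})

test_that("finalized calls intersect member rectangles and tally support", {
  prof <- make_profiles(sample_id = c("A", "B"), max_concordant_span = 400L)
  p <- make_pairs(n = 3,
                  start1 = c(100L, 80L, 120L), end1 = c(150L, 130L, 170L),
                  start2 = c(900L, 880L, 920L), end2 = c(950L, 930L, 970L),
                  sample_id = c("A", "A", "B"),
                  read_id = c("r1", "r2", "r3"))
  p <- p[order(p$start1), ]
  res <- sweep_cluster(p, prof)
  expect_length(res$clusters, 1L)
  call <- finalize_call(res$clusters[[1]], p, "c1")
  r <- breakpoint_rectangles(p, prof)
  expect_equal(call$start1, max(r$lo1))
  expect_equal(call$end1, min(r$hi1))
  expect_equal(call$total_support, 3L)
  expect_equal(call$support, "A:2;B:1")

  single <- sweep_cluster(p[1, ], prof)
  c1 <- finalize_call(single$clusters[[1]], p[1, ], "c2")
  r1 <- breakpoint_rectangles(p[1, ], prof)
  expect_equal(c(c1$start1, c1$end1, c1$start2, c1$end2),
               c(r1$lo1, r1$hi1, r1$lo2, r1$hi2))
})

test_that("every emitted call has pairwise-compatible members and members are conserved", {
  for (seed in 1:10) {
    p <- random_separated_partition(seed, n_clusters = sample(1:4, 1))
    res <- sweep_cluster(p$pairs, p$profiles, cluster_cap = 6)
    rect <- breakpoint_rectangles(p$pairs, p$profiles)
    for (cl in res$clusters) {
      mm <- cl$members
      for (i in mm) for (j in mm)
        expect_true(rectangles_compatible(rect[i, ], rect[j, ]))
    }
    n_members <- sum(lengths(lapply(res$clusters, `[[`, "members"))) +
      sum(lengths(lapply(res$dropped, `[[`, "members")))
    expect_equal(n_members, nrow(p$pairs))
  }
})

test_that("greedy clustering matches maximal-compatible-set enumeration", {
  skip_if_not_installed("igraph")
  for (seed in 1:25) {
    p <- random_separated_partition(seed, n_clusters = sample(1:5, 1),
                                    members_range = 1:8)
    res <- sweep_cluster(p$pairs, p$profiles, cluster_cap = 1000L)
    rect <- breakpoint_rectangles(p$pairs, p$profiles)
    n <- nrow(rect)
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) for (j in seq_len(n))
      adj[i, j] <- rectangles_compatible(rect[i, ], rect[j, ])
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             diag = FALSE)
    cliques <- lapply(igraph::max_cliques(g), function(x) sort(as.integer(x)))
    cliques <- cliques[order(vapply(cliques, min, integer(1)))]
    expect_equal(member_sets(res$clusters), cliques)
  }
})

test_that("unsorted partitions and mixed routing keys are rejected", {
  prof <- make_profiles(max_concordant_span = 325L)
  bad <- make_pairs(n = 2, start1 = c(500L, 100L), end1 = c(550L, 150L))
  expect_error(sweep_cluster(bad, prof), "not sorted")
  mixed <- make_pairs(n = 2, strand1 = c("+", "-"))
  expect_error(sweep_cluster(mixed, prof), "routing key")
})
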