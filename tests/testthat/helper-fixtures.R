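# Fixture builders shared across the suite. Everything is generated in code;
# no data files.

make_profiles <- function(sample_id = "S1", library_id = "libA",
                          median = 300L, mad = 5L, k_mad = 5,
                          max_concordant_span = NULL, n = 1000L) {
  dt <- data.table::data.table(
    sample_id = sample_id, library_id = library_id,
    median = as.integer(median), mad = as.integer(mad), k_mad = k_mad,
    n = as.integer(n))
  dt$max_concordant_span <- if (is.null(max_concordant_span))
    as.integer(floor(median + k_mad * mad + 0.5)) else
    as.integer(max_concordant_span)
  dt
}

make_pairs <- function(n = 1, chrom1 = "chr1", start1 = 100L, end1 = 150L,
                       strand1 = "+", chrom2 = "chr1", start2 = 600L,
                       end2 = 650L, strand2 = "-", sample_id = "S1",
                       library_id = "libA", read_id = NULL,
                       mapq1 = 60L, mapq2 = 60L) {
  if (is.null(read_id)) read_id <- sprintf("r%03d", seq_len(n))
  data.table::data.table(
    chrom1 = chrom1, start1 = as.integer(start1), end1 = as.integer(end1),
    strand1 = strand1,
    chrom2 = chrom2, start2 = as.integer(start2), end2 = as.integer(end2),
    strand2 = strand2,
    sample_id = sample_id, library_id = library_id, read_id = read_id,
    mapq1 = as.integer(mapq1), mapq2 = as.integer(mapq2))
}

# Minimal SAM writer for extractor tests: records is a data.frame with
# qname, flag, chrom, pos (1-based), mapq, cigar, rnext, pnext, rg.
write_tiny_sam <- function(records, path, chroms = c(chr1 = 100000L,
                                                     chr2 = 100000L)) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chroms), chroms),
           "@RG\tID:libA\tSM:S1\tLB:libA")
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t0\t*\t*\tRG:Z:%s",
                  records$qname, records$flag, records$chrom, records$pos,
                  records$mapq, records$cigar, records$rnext, records$pnext,
                  records$rg)
  writeLines(c(hdr, body), path)
  path
}

# A deletion-signature partition with m well-separated clusters: every
# member's rectangle contains its cluster's junction point, clusters are
# separated by > 2 W on side 1. Returns the (sorted) pair table and the
# planted grouping.
random_separated_partition <- function(seed, n_clusters = 3,
                                       members_range = 2:8, W = 325L,
                                       rl = 50L) {
  set.seed(seed)
  profiles <- make_profiles(max_concordant_span = W)
  pairs <- list()
  group <- integer(0)
  j1 <- 10000L
  for (g in seq_len(n_clusters)) {
    j2 <- j1 + 50000L
    m <- members_range[sample.int(length(members_range), 1L)]
    a <- sample.int(W - rl - 1L, m, replace = TRUE) - 1L
    b <- sample.int(W - rl - 1L, m, replace = TRUE) - 1L
    pairs[[g]] <- make_pairs(
      n = m,
      start1 = j1 - a - rl, end1 = j1 - a, strand1 = "+",
      start2 = j2 + b, end2 = j2 + b + rl, strand2 = "-",
      read_id = sprintf("g%d_r%02d", g, seq_len(m)))
    group <- c(group, rep(g, m))
    j1 <- j1 + 3L * W + 1000L
  }
  pairs <- data.table::rbindlist(pairs)
  o <- order(pairs$start1, pairs$end1, pairs$chrom2, pairs$start2,
             pairs$sample_id, pairs$read_id, method = "radix")
  list(pairs = pairs[o, ], group = group[o], profiles = profiles)
}

# Member index sets of a clustering result, order-insensitive.
member_sets <- function(clusters) {
  s <- lapply(clusters, function(cl) sort(cl$members))
  s[order(vapply(s, min, integer(1)))]
}

# Presence matrix mirroring a large tumor-normal cohort with a given number
# of tumor-private, normal-private and shared germline breakpoints.
synthetic_cohort_presence <- function(n_tumor_private, n_normal_private,
                                      n_shared_germline, n_pairs = 64,
                                      extra_normals = 1) {
  tumors <- sprintf("T%03d", seq_len(n_pairs))
  normals <- sprintf("N%03d", seq_len(n_pairs + extra_normals))
  samples <- c(tumors, normals)
  n_calls <- n_tumor_private + n_normal_private + n_shared_germline
  m <- matrix(FALSE, n_calls, length(samples),
              dimnames = list(sprintf("bp_%05d", seq_len(n_calls)), samples))
  i <- 0L
  for (k in seq_len(n_tumor_private)) {
    i <- i + 1L
    m[i, tumors[1L + (k - 1L) %% n_pairs]] <- TRUE
  }
  for (k in seq_len(n_normal_private)) {
    i <- i + 1L
    m[i, normals[1L + (k - 1L) %% length(normals)]] <- TRUE
  }
  for (k in seq_len(n_shared_germline)) {
    i <- i + 1L
    p <- 1L + (k - 1L) %% n_pairs
    m[i, c(tumors[p], normals[p])] <- TRUE
  }
  sheet <- data.table::data.table(
    sample_id = samples,
    role = c(rep("tumor", n_pairs), rep("normal", n_pairs + extra_normals)),
    pair_id = c(sprintf("P%03d", seq_len(n_pairs)),
                sprintf("P%03d", seq_len(n_pairs)),
                rep("", extra_normals)),
    path = "")
  list(presence = m, pairing = sweepsv::sample_pairing(sheet))
}
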