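base_config <- function(seed = 7, allele_freq = 0.5, somatic_fraction = 0,
                        noise_rate = 0, samples = NULL, sv_counts = NULL) {
  if (is.null(samples))
    samples <- data.frame(sample_id = c("T1", "N1"),
                          role = c("tumor", "normal"),
                          pair_id = "P1", depth = c(6, 6))
  if (is.null(sv_counts))
    sv_counts <- data.frame(class = "deletion", n = 8,
                            min_size = 2000, max_size = 10000)
  sim_config(chrom_lengths = c(chr1 = 600000L, chr2 = 300000L),
             samples = samples,
             libraries = data.frame(library_id = "libA", median = 300,
                                    mad = 15),
             sv_counts = sv_counts, allele_freq = allele_freq,
             somatic_fraction = somatic_fraction, noise_rate = noise_rate,
             seed = seed)
}

test_that("planting is deterministic, non-overlapping and genotype-consistent", {
  cfg <- base_config(seed = 7)
  p1 <- plant_svs(cfg)
  p2 <- plant_svs(cfg)
  expect_identical(p1$svs, p2$svs)
  expect_identical(p1$genotypes, p2$genotypes)

  same_chrom <- p1$svs[!is.na(p1$svs$start), ]
  for (chrom in unique(same_chrom$chrom1)) {
    s <- same_chrom[same_chrom$chrom1 == chrom, ]
    s <- s[order(s$start), ]
    if (nrow(s) > 1) expect_true(all(s$start[-1] >= s$end[-nrow(s)]))
  }

  # allele frequency 1 -> every sample carries every germline SV, homozygous
  all_cfg <- base_config(seed = 8, allele_freq = 1)
  pa <- plant_svs(all_cfg)
  expect_equal(nrow(pa$genotypes), nrow(pa$svs) * 2L)
  expect_true(all(pa$genotypes$genotype == "hom"))

  # somatic fraction 0 -> every SV is carried by at least one normal
  expect_true(all(p1$svs$origin == "germline"))

  som_cfg <- base_config(seed = 9, somatic_fraction = 1)
  ps <- plant_svs(som_cfg)
  expect_true(all(startsWith(ps$svs$origin, "somatic:")))
  expect_true(all(ps$genotypes$sample_id == "T1"))
})

test_that("fragments crossing a deletion inflate the span by the deleted length", {
  cfg <- base_config(seed = 11, allele_freq = 1,
                     sv_counts = data.frame(class = "deletion", n = 2,
                                            min_size = 5000, max_size = 5000))
  planted <- plant_svs(cfg)
  sims <- simulate_pairs(planted, cfg)
  pairs <- sims[["T1"]]
  disc <- pairs[pairs$strand1 == "+" & pairs$strand2 == "-" &
                  (pairs$end2 - pairs$start1) > 1000, ]
  expect_gt(nrow(disc), 0)
  spans <- disc$end2 - disc$start1
  # span = fragment length + deleted length; fragment ~ N(300, 1.4826*15)
  expect_true(all(abs(spans - 5300) < 300))
  # each such pair straddles a planted junction
  dels <- planted$svs
  ok <- vapply(seq_len(nrow(disc)), function(i) {
    any(disc$end1[i] <= dels$start & disc$start2[i] >= dels$end &
          disc$chrom1[i] == dels$chrom1)
  }, logical(1))
  expect_true(all(ok))
})

test_that("a non-carrier emits no discordant pairs at a locus when noise is zero", {
  cfg <- base_config(seed = 13, somatic_fraction = 1,
                     sv_counts = data.frame(class = "deletion", n = 3,
                                            min_size = 5000, max_size = 9000))
  planted <- plant_svs(cfg)
  sims <- simulate_pairs(planted, cfg)
  normal <- sims[["N1"]]
  spans <- normal$end2 - normal$start1
  expect_true(all(normal$strand1 == "+" & normal$strand2 == "-"))
  expect_lt(mean(spans > 300 + 8 * 1.4826 * 15), 0.01)
})

test_that("without SVs or noise, extraction finds almost nothing discordant", {
  cfg <- base_config(seed = 17,
                     sv_counts = data.frame(class = character(),
                                            n = integer(),
                                            min_size = integer(),
                                            max_size = integer()))
  out <- simulate_cohort(cfg, tempfile("clean"))
  profiles <- profile_libraries(out$sample_sheet, k_mad = 8,
                                min_observations = 100)
  ex <- extract_discordants(out$sample_sheet, profiles,
                            workdir = tempfile("wd"))
  r <- ex$reports
  expect_lt(sum(r$discordant) / sum(r$pairs), 0.01)
})

test_that("estimated profiles recover the configured library parameters", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 2000000L),
                    samples = data.frame(sample_id = "S1", role = "none",
                                         pair_id = "", depth = 3),
                    libraries = data.frame(
                      library_id = c("lib300", "lib400", "lib500"),
                      median = c(300, 400, 500), mad = c(15, 30, 50)),
                    sv_counts = data.frame(class = character(), n = integer(),
                                           min_size = integer(),
                                           max_size = integer()),
                    seed = 19)
  out <- simulate_cohort(cfg, tempfile("prof"))
  profiles <- profile_libraries(out$sample_sheet, k_mad = 8,
                                min_observations = 1000)
  profiles <- profiles[order(profiles$library_id), ]
  expect_true(all(profiles$n >= 1000))
  expect_true(all(abs(profiles$median - c(300, 400, 500)) /
                    c(300, 400, 500) <= 0.02))
  expect_true(all(abs(profiles$mad - c(15, 30, 50)) / c(15, 30, 50) <= 0.10))
})

test_that("truth files round-trip the planted variants", {
  cfg <- base_config(seed = 23)
  planted <- plant_svs(cfg)
  dir <- tempfile("truth")
  paths <- write_truth(planted, dir)
  bed <- read_bed(paths$deletions_bed)
  dels <- planted$svs[planted$svs$class == "deletion", ]
  expect_equal(bed$start, dels$start)
  expect_equal(bed$end, dels$end)
  expect_equal(bed$id, dels$sv_id)
  gt <- data.table::fread(paths$genotypes, sep = "\t")
  expect_equal(as.data.frame(gt), as.data.frame(planted$genotypes))
})
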