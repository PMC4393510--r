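# Synthetic multi-sample paired-end cohorts with planted SVs.
#
# Alignments are simulated directly in reference coordinates: the caller
# consumes mappings, not bases, so no sequence or aligner is involved.
# Fragment lengths are Normal(median, 1.4826 * mad) truncated at twice the
# read length, so a library configured with a given MAD realizes that MAD
# under the profiler's unscaled-MAD convention.

#' Build and validate a simulation configuration
#'
#' @param chrom_lengths Named integer vector of chromosome lengths (bp).
#' @param samples `data.frame` with `sample_id`, `role`
#'   (tumor/normal/none), `pair_id` (blank if unpaired), `depth` (mean
#'   sequence coverage of the sample).
#' @param libraries `data.frame` with `library_id`, `median`, `mad`
#'   (fragment-size parameters, bp); each sample's depth is split evenly
#'   across these libraries.
#' @param sv_counts `data.frame` with `class`
#'   (deletion/tandem_duplication/inversion/translocation), `n`,
#'   `min_size`, `max_size` (bp; ignored for translocations).
#' @param allele_freq Population allele frequency of germline SVs; carrier
#'   genotypes are drawn per sample under Hardy-Weinberg.
#' @param somatic_fraction Fraction of planted SVs that are somatic
#'   (private to one tumor, heterozygous).
#' @param noise_rate Fraction of fragments replaced by uniformly random
#'   discordant pairs (default 0).
#' @param read_length Read length in bp (default 100).
#' @param seed Mandatory integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(chrom_lengths, samples, libraries, sv_counts,
                       allele_freq = 0.3, somatic_fraction = 0,
                       noise_rate = 0, read_length = 100L, seed) {
  if (missing(seed)) .stopf("sim_config: seed is mandatory")
  samples <- data.table::as.data.table(samples)
  libraries <- data.table::as.data.table(libraries)
  sv_counts <- data.table::as.data.table(sv_counts)
  if (is.null(names(chrom_lengths)) || any(chrom_lengths <= 0))
    .stopf("chrom_lengths must be a named vector of positive lengths")
  if (any(samples$depth <= 0)) .stopf("depths must be positive")
  if (somatic_fraction > 0 && !any(samples$role == "tumor"))
    .stopf("somatic SVs require at least one tumor sample")
  bad <- setdiff(sv_counts$class, c("deletion", "tandem_duplication",
                                    "inversion", "translocation"))
  if (length(bad) > 0) .stopf("unknown SV class: %s", paste(bad, collapse = ", "))
  structure(list(
    chrom_lengths = chrom_lengths, samples = samples, libraries = libraries,
    sv_counts = sv_counts, allele_freq = allele_freq,
    somatic_fraction = somatic_fraction, noise_rate = noise_rate,
    read_length = as.integer(read_length), seed = as.integer(seed)
  ), class = "sim_config")
}

#' Plant structural variants in the simulated genome
#'
#' Positions are rejection-sampled so that no two SV footprints overlap.
#' Germline SVs are assigned carrier genotypes per sample under
#' Hardy-Weinberg at the configured allele frequency (re-drawn until at
#' least one sample carries each SV); somatic SVs are assigned to a single
#' tumor, heterozygous. Deterministic under the config seed.
#'
#' @param config A [sim_config()].
#' @return List with `svs` (data.table: `sv_id`, `class`, `chrom1`, `pos1`,
#'   `chrom2`, `pos2`, `start`, `end`, `origin`) and `genotypes`
#'   (data.table: `sv_id`, `sample_id`, `genotype` in het/hom).
#' @export
plant_svs <- function(config) {
  set.seed(config$seed)
  chroms <- names(config$chrom_lengths)
  placed <- data.table::data.table(chrom = character(), start = integer(),
                                   end = integer())
  pick_locus <- function(size) {
    for (try in 1:1000) {
      chrom <- sample(chroms, 1,
                      prob = config$chrom_lengths / sum(config$chrom_lengths))
      margin <- 2000L  # keep junction-flanking fragments on-chromosome
      max_start <- config$chrom_lengths[[chrom]] - size - margin
      if (max_start <= margin) next
      start <- margin + sample.int(max_start - margin, 1)
      hit <- placed$chrom == chrom & placed$start < start + size + margin &
        placed$end > start - margin
      if (!any(hit)) {
        placed <<- rbind(placed,
                         data.table::data.table(chrom = chrom, start = start,
                                                end = start + size))
        return(list(chrom = chrom, start = start, end = start + size))
      }
    }
    .stopf("could not place an SV of %d bp after 1000 tries; reduce counts or sizes", size)
  }

  svs <- list()
  for (ci in seq_len(nrow(config$sv_counts))) {
    cls <- config$sv_counts$class[ci]
    for (k in seq_len(config$sv_counts$n[ci])) {
      if (cls == "translocation") {
        if (length(chroms) < 2)
          .stopf("translocations need at least two chromosomes")
        a <- pick_locus(1000L)
        repeat {
          b <- pick_locus(1000L)
          if (b$chrom != a$chrom) break
        }
        svs[[length(svs) + 1L]] <- data.table::data.table(
          class = cls, chrom1 = a$chrom, pos1 = a$start,
          chrom2 = b$chrom, pos2 = b$start,
          start = NA_integer_, end = NA_integer_)
      } else {
        lo <- config$sv_counts$min_size[ci]
        hi <- config$sv_counts$max_size[ci]
        size <- lo + sample.int(hi - lo + 1L, 1) - 1L
        l <- pick_locus(size)
        svs[[length(svs) + 1L]] <- data.table::data.table(
          class = cls, chrom1 = l$chrom, pos1 = l$start,
          chrom2 = l$chrom, pos2 = l$end,
          start = l$start, end = l$end)
      }
    }
  }
  svs <- data.table::rbindlist(svs)
  if (nrow(svs) == 0) {
    return(list(
      svs = data.table::data.table(
        class = character(), chrom1 = character(), pos1 = integer(),
        chrom2 = character(), pos2 = integer(),
        start = integer(), end = integer(),
        sv_id = character(), origin = character()),
      genotypes = data.table::data.table(
        sv_id = character(), sample_id = character(), genotype = character())
    ))
  }
  svs[, sv_id := sprintf("sv_%04d", seq_len(.N))]

  n_somatic <- round_half_up(config$somatic_fraction * nrow(svs))
  somatic_idx <- if (n_somatic > 0) sample(nrow(svs), n_somatic) else integer(0)
  svs[, origin := "germline"]
  tumors <- config$samples$sample_id[config$samples$role == "tumor"]

  genos <- list()
  af <- config$allele_freq
  for (i in seq_len(nrow(svs))) {
    if (i %in% somatic_idx) {
      tid <- sample(tumors, 1)
      svs$origin[i] <- paste0("somatic:", tid)
      genos[[length(genos) + 1L]] <- data.table::data.table(
        sv_id = svs$sv_id[i], sample_id = tid, genotype = "het")
    } else {
      repeat {
        u <- runif(nrow(config$samples))
        gt <- ifelse(u < af^2, "hom",
              ifelse(u < af^2 + 2 * af * (1 - af), "het", NA_character_))
        if (any(!is.na(gt))) break
      }
      carriers <- which(!is.na(gt))
      genos[[length(genos) + 1L]] <- data.table::data.table(
        sv_id = svs$sv_id[i],
        sample_id = config$samples$sample_id[carriers],
        genotype = gt[carriers])
    }
  }
  list(svs = svs, genotypes = data.table::rbindlist(genos))
}

# One truncated-normal fragment length per draw (vectorized).
.frag_lengths <- function(n, median, mad, read_length) {
  if (n == 0) return(integer(0))
  sd <- 1.4826 * mad
  l <- round_half_up(rnorm(n, median, sd))
  pmax(as.integer(l), 2L * read_length)
}

# Junction-crossing discordant pairs for one junction signature.
# Returns data.table(start1,end1,strand1,start2,end2,strand2) in reference
# coordinates for `n` fragments of lengths `L` crossing the junction with
# left clearance a ~ U(0, L - 2rl).
.junction_pairs <- function(n, L, rl, type, j1, j2) {
  if (n == 0) return(NULL)
  a <- floor(runif(n) * (L - 2 * rl + 1))
  b <- L - 2 * rl - a
  switch(type,
    deletion = data.table::data.table(    # (+,-): left read before j1, right read after j2
      start1 = j1 - a - rl, end1 = j1 - a, strand1 = "+",
      start2 = j2 + b, end2 = j2 + b + rl, strand2 = "-"),
    dup = data.table::data.table(         # (-,+): everted across the tandem junction
      start1 = j1 + b, end1 = j1 + b + rl, strand1 = "-",
      start2 = j2 - a - rl, end2 = j2 - a, strand2 = "+"),
    inv_left = data.table::data.table(    # (+,+): read 2 reflected into [j1,j2)
      start1 = j1 - a - rl, end1 = j1 - a, strand1 = "+",
      start2 = j2 - b - rl, end2 = j2 - b, strand2 = "+"),
    inv_right = data.table::data.table(   # (-,-): read 1 reflected, read 2 past j2
      start1 = j1 + a, end1 = j1 + a + rl, strand1 = "-",
      start2 = j2 + b, end2 = j2 + b + rl, strand2 = "-"),
    tra = data.table::data.table(         # interchromosomal
      start1 = j1 - a - rl, end1 = j1 - a, strand1 = "+",
      start2 = j2 + b, end2 = j2 + b + rl, strand2 = "-")
  )
}

#' Simulate per-sample paired-end alignments
#'
#' Emits, per sample, (i) a concordant (+,-) background at the configured
#' depth, (ii) for every SV the sample carries, junction-crossing discordant
#' pairs with the class's orientation signature at the rate implied by the
#' fragment model (heterozygous carriers at half the homozygous rate), and
#' (iii) optional uniformly random noise pairs. The read-depth footprint of
#' the variant alleles (e.g. missing coverage inside a homozygous deletion)
#' is not modelled: the caller uses only pair orientation and span.
#'
#' @param planted Output of [plant_svs()].
#' @param config The same [sim_config()].
#' @return Named list (per sample) of alignment record tables with columns
#'   `read_id`, `chrom`, `start`, `end`, `strand`, `library_id`, `mate`
#'   (0-based half-open coordinates).
#' @export
simulate_pairs <- function(planted, config) {
  set.seed(config$seed + 1L)
  rl <- config$read_length
  chroms <- names(config$chrom_lengths)
  out <- list()
  for (si in seq_len(nrow(config$samples))) {
    sid <- config$samples$sample_id[si]
    depth <- config$samples$depth[si]
    nlib <- nrow(config$libraries)
    frags <- list()
    for (li in seq_len(nlib)) {
      lib <- config$libraries[li, ]
      lib_depth <- depth / nlib
      # concordant background
      for (chrom in chroms) {
        clen <- config$chrom_lengths[[chrom]]
        nfrag <- rpois(1, lib_depth * clen / (2 * rl))
        if (nfrag == 0) next
        L <- .frag_lengths(nfrag, lib$median, lib$mad, rl)
        s <- floor(runif(nfrag) * pmax(1, clen - L))
        frags[[length(frags) + 1L]] <- data.table::data.table(
          chrom1 = chrom, start1 = as.integer(s), end1 = as.integer(s + rl),
          strand1 = "+",
          chrom2 = chrom, start2 = as.integer(s + L - rl),
          end2 = as.integer(s + L), strand2 = "-",
          library_id = lib$library_id)
      }
      # junction-crossing pairs for carried SVs
      if (nrow(planted$svs) > 0) {
        gt <- planted$genotypes[planted$genotypes$sample_id == sid, ]
        for (gi in seq_len(nrow(gt))) {
          sv <- planted$svs[planted$svs$sv_id == gt$sv_id[gi], ]
          hap <- if (gt$genotype[gi] == "hom") 2L else 1L
          lambda <- hap * (lib_depth / 2) / (2 * rl)
          mean_clear <- max(0, lib$median - 2 * rl)
          n <- rpois(1, lambda * mean_clear)
          if (sv$class == "inversion") {
            n2 <- rpois(1, lambda * mean_clear)
          }
          emit <- function(n, type, j1, j2, c1, c2) {
            if (n == 0) return(NULL)
            L <- .frag_lengths(n, lib$median, lib$mad, rl)
            jp <- .junction_pairs(n, L, rl, type, j1, j2)
            if (is.null(jp)) return(NULL)
            jp[, `:=`(chrom1 = c1, chrom2 = c2, library_id = lib$library_id)]
            jp
          }
          frags[[length(frags) + 1L]] <- switch(
            sv$class,
            deletion = emit(n, "deletion", sv$start, sv$end,
                            sv$chrom1, sv$chrom2),
            tandem_duplication = emit(n, "dup", sv$start, sv$end,
                                      sv$chrom1, sv$chrom2),
            inversion = rbind(
              emit(n, "inv_left", sv$start, sv$end, sv$chrom1, sv$chrom2),
              emit(n2, "inv_right", sv$start, sv$end, sv$chrom1, sv$chrom2)),
            translocation = emit(n, "tra", sv$pos1, sv$pos2,
                                 sv$chrom1, sv$chrom2)
          )
        }
      }
      # noise pairs
      if (config$noise_rate > 0) {
        tot <- sum(vapply(frags, nrow, integer(1)))
        nn <- rpois(1, config$noise_rate * tot)
        if (nn > 0) {
          rchrom <- function(k) sample(chroms, k, replace = TRUE,
                                       prob = config$chrom_lengths)
          c1 <- rchrom(nn); c2 <- rchrom(nn)
          s1 <- floor(runif(nn) * (unlist(config$chrom_lengths[c1]) - rl))
          s2 <- floor(runif(nn) * (unlist(config$chrom_lengths[c2]) - rl))
          frags[[length(frags) + 1L]] <- data.table::data.table(
            chrom1 = c1, start1 = as.integer(s1), end1 = as.integer(s1 + rl),
            strand1 = sample(c("+", "-"), nn, replace = TRUE),
            chrom2 = c2, start2 = as.integer(s2), end2 = as.integer(s2 + rl),
            strand2 = sample(c("+", "-"), nn, replace = TRUE),
            library_id = lib$library_id)
        }
      }
    }
    pairs <- data.table::rbindlist(frags, use.names = TRUE)
    # clip anything the junction arithmetic pushed off-chromosome
    len1 <- unlist(config$chrom_lengths[pairs$chrom1])
    len2 <- unlist(config$chrom_lengths[pairs$chrom2])
    pairs <- pairs[pairs$start1 >= 0 & pairs$start2 >= 0 &
                     pairs$end1 <= len1 & pairs$end2 <= len2, ]
    pairs[, read_id := sprintf("%s_rp%07d", sid, seq_len(.N))]
    out[[sid]] <- pairs
  }
  out
}

#' Write simulated alignments as SAM
#'
#' Two primary records per pair, mapping quality 60, CIGAR fully matched,
#' read group = library. Header declares the chromosome order shared by the
#' cohort.
#'
#' @param pairs One sample's pair table from [simulate_pairs()].
#' @param path Output SAM path.
#' @param config The [sim_config()].
#' @param sample_id Sample name for the read groups.
#' @return `path`, invisibly.
#' @export
write_sam <- function(pairs, path, config, sample_id) {
  rl <- config$read_length
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(config$chrom_lengths),
                   as.integer(config$chrom_lengths)),
           sprintf("@RG\tID:%s\tSM:%s\tLB:%s", config$libraries$library_id,
                   sample_id, config$libraries$library_id))
  flag1 <- 0x1L + 0x40L + ifelse(pairs$strand1 == "-", 0x10L, 0L) +
    ifelse(pairs$strand2 == "-", 0x20L, 0L)
  flag2 <- 0x1L + 0x80L + ifelse(pairs$strand2 == "-", 0x10L, 0L) +
    ifelse(pairs$strand1 == "-", 0x20L, 0L)
  cigar <- sprintf("%dM", rl)
  l1 <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t%s\t%d\t0\t*\t*\tRG:Z:%s",
                pairs$read_id, flag1, pairs$chrom1, pairs$start1 + 1L, cigar,
                pairs$chrom2, pairs$start2 + 1L, pairs$library_id)
  l2 <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t%s\t%d\t0\t*\t*\tRG:Z:%s",
                pairs$read_id, flag2, pairs$chrom2, pairs$start2 + 1L, cigar,
                pairs$chrom1, pairs$start1 + 1L, pairs$library_id)
  con <- file(path, open = "w")
  on.exit(close(con))
  writeLines(hdr, con)
  if (nrow(pairs) > 0) writeLines(c(rbind(l1, l2)), con)
  invisible(path)
}

#' Write truth files for a planted cohort
#'
#' Emits a BED of planted deletions (`chrom start end id`), a BEDPE-style
#' TSV of all planted SVs and a per-sample genotype table, in the formats
#' the evaluator and cohort analytics consume.
#'
#' @param planted Output of [plant_svs()].
#' @param dir Output directory.
#' @return Named list of file paths.
#' @export
write_truth <- function(planted, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  svs <- planted$svs
  del <- svs[svs$class == "deletion", ]
  bed <- file.path(dir, "truth_deletions.bed")
  write_bed(data.table::data.table(chrom = del$chrom1, start = del$start,
                                   end = del$end, id = del$sv_id), bed)
  all_path <- file.path(dir, "truth_svs.tsv")
  data.table::fwrite(svs, all_path, sep = "\t")
  gt_path <- file.path(dir, "truth_genotypes.tsv")
  data.table::fwrite(planted$genotypes, gt_path, sep = "\t")
  list(deletions_bed = bed, svs = all_path, genotypes = gt_path)
}

#' Simulate a full cohort to disk
#'
#' Plants the SVs, simulates per-sample alignments, writes one SAM per
#' sample, a sample sheet and the truth files.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory.
#' @return List with `sample_sheet` (path), `planted`, `truth` (paths),
#'   `sam_paths`.
#' @export
simulate_cohort <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  planted <- plant_svs(config)
  sims <- simulate_pairs(planted, config)
  paths <- character(nrow(config$samples))
  for (si in seq_len(nrow(config$samples))) {
    sid <- config$samples$sample_id[si]
    paths[si] <- file.path(outdir, paste0(sid, ".sam"))
    write_sam(sims[[sid]], paths[si], config, sid)
  }
  sheet <- data.table::data.table(
    sample_id = config$samples$sample_id,
    role = config$samples$role,
    pair_id = config$samples$pair_id,
    path = paths,
    depth = config$samples$depth
  )
  sheet_path <- file.path(outdir, "sample_sheet.tsv")
  data.table::fwrite(sheet, sheet_path, sep = "\t")
  truth <- write_truth(planted, outdir)
  list(sample_sheet = sheet_path, planted = planted, truth = truth,
       sam_paths = paths)
}

#' Simulate a cohort at the call level
#'
#' Generates a finished call set plus sample sheet directly, without
#' simulating alignments: germline SVs carried under Hardy-Weinberg with
#' per-sample detection support drawn from a Poisson, somatic SVs present
#' only in their tumor, and spurious private calls present in a single
#' random sample. Useful for exercising the cohort analytics (FDR curves,
#' sample clustering) at scales where full alignment simulation is
#' unnecessary.
#'
#' @param n_pairs Number of tumor-normal pairs.
#' @param n_germline,n_somatic,n_false Numbers of germline SVs, somatic SVs
#'   (assigned to random tumors) and spurious private calls (assigned to
#'   random samples).
#' @param allele_freq Germline allele frequency (default 0.3).
#' @param mean_support Mean supporting pairs where a variant is present
#'   (default 3, the discordant-pair yield of a heterozygous variant in a
#'   shallow, few-fold-coverage genome); per-sample support ~ Poisson, so
#'   real variants are regularly missed in a carrier (support 0), which is
#'   what joint calling rescues.
#' @param seed Integer seed.
#' @return List with `calls` (call table), `sheet` (sample sheet
#'   data.table, paths blank) and `truth_origin` (per call:
#'   germline/somatic/false).
#' @export
simulate_cohort_calls <- function(n_pairs, n_germline = 200, n_somatic = 30,
                                  n_false = 30, allele_freq = 0.3,
                                  mean_support = 3, seed) {
  set.seed(seed)
  tumors <- sprintf("T%02d", seq_len(n_pairs))
  normals <- sprintf("N%02d", seq_len(n_pairs))
  sheet <- data.table::data.table(
    sample_id = c(rbind(tumors, normals)),
    role = rep(c("tumor", "normal"), n_pairs),
    pair_id = rep(sprintf("P%02d", seq_len(n_pairs)), each = 2),
    path = "")
  samples <- sheet$sample_id
  af <- allele_freq

  mk_call <- function(i, origin) {
    present <- switch(origin,
      germline = {
        repeat {
          u <- runif(length(samples))
          carrier <- u < af^2 + 2 * af * (1 - af)
          # tumor and normal of one individual share germline genotypes
          carrier <- rep(carrier[seq(1, length(samples), 2)] |
                           carrier[seq(2, length(samples), 2)], each = 2)
          sup <- ifelse(carrier, rpois(length(samples), mean_support), 0L)
          if (sum(sup > 0) >= 1) break
        }
        sup
      },
      somatic = {
        sup <- integer(length(samples))
        t <- sample(which(sheet$role == "tumor"), 1)
        sup[t] <- 1L + rpois(1, mean_support)
        sup
      },
      false = {
        sup <- integer(length(samples))
        sup[sample(length(samples), 1)] <- 1L + rpois(1, 2)
        sup
      })
    keep <- present > 0
    start1 <- 1000L * i
    data.table::data.table(
      call_id = sprintf("sim_%05d", i), svclass = "deletion",
      chrom1 = "chr1", start1 = start1, end1 = start1 + 200L,
      chrom2 = "chr1", start2 = start1 + 5000L, end2 = start1 + 5200L,
      strand1 = "+", strand2 = "-",
      total_support = sum(present),
      support = paste(sprintf("%s:%d", samples[keep], present[keep]),
                      collapse = ";"))
  }
  origins <- c(rep("germline", n_germline), rep("somatic", n_somatic),
               rep("false", n_false))
  calls <- data.table::rbindlist(
    lapply(seq_along(origins), function(i) mk_call(i, origins[i])))
  list(calls = calls, sheet = sheet, truth_origin = origins)
}
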