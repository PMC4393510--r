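#' Read mated alignment pairs from a SAM/BAM file
#'
#' Loads primary alignments through Rsamtools, applies record-level filters
#' (duplicates, secondary/supplementary, unmapped, sub-threshold mapping
#' quality), mates the survivors by read name and returns canonicalized
#' pairs together with a filter report. The read group (`RG` tag) is used as
#' the library identifier; reads without one fall into library `"default"`.
#'
#' @param path SAM or BAM file. SAM input is converted on the fly.
#' @param sample_id Sample identifier attached to every pair.
#' @param min_mapq Minimum mapping quality per record (default 20).
#' @param drop_duplicates,drop_secondary_supplementary Filter toggles
#'   (default TRUE).
#' @return List with `pairs` (canonicalized pair table), `report` (named
#'   counts of records read and dropped) and `chrom_order` (reference order
#'   declared in the header).
#' @export
read_alignment_pairs <- function(path, sample_id, min_mapq = 20,
                                 drop_duplicates = TRUE,
                                 drop_secondary_supplementary = TRUE) {
  bam <- .as_bam(path)
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]
  chrom_order <- names(hdr$targets)
  if (length(chrom_order) == 0)
    .stopf("%s: header declares no reference sequences", path)

  res <- Rsamtools::scanBam(
    bam,
    param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "mapq", "cigar"),
      tag = "RG"
    )
  )[[1]]
  n_total <- length(res$qname)
  rg <- res$tag$RG
  if (is.null(rg)) rg <- rep(NA_character_, n_total)
  rg[is.na(rg)] <- "default"

  flag <- res$flag
  is_secsup <- bitwAnd(flag, 0x100L) > 0L | bitwAnd(flag, 0x800L) > 0L
  is_dup <- bitwAnd(flag, 0x400L) > 0L
  is_unmapped <- bitwAnd(flag, 0x4L) > 0L | is.na(res$pos)

  keep <- rep(TRUE, n_total)
  report <- c(total_records = n_total, secondary_supplementary_dropped = 0L,
              duplicate_dropped = 0L, unmapped_dropped = 0L,
              mapq_dropped = 0L, unmated_dropped = 0L)
  if (drop_secondary_supplementary) {
    report["secondary_supplementary_dropped"] <- sum(keep & is_secsup)
    keep <- keep & !is_secsup
  }
  if (drop_duplicates) {
    report["duplicate_dropped"] <- sum(keep & is_dup)
    keep <- keep & !is_dup
  }
  report["unmapped_dropped"] <- sum(keep & is_unmapped)
  keep <- keep & !is_unmapped
  low_mapq <- !is.na(res$mapq) & res$mapq < min_mapq
  report["mapq_dropped"] <- sum(keep & low_mapq)
  keep <- keep & !low_mapq

  rec <- data.table::data.table(
    qname = res$qname[keep],
    chrom = as.character(res$rname[keep]),
    start = res$pos[keep] - 1L,  # 0-based half-open on ingestion
    width = GenomicAlignments::cigarWidthAlongReferenceSpace(res$cigar[keep]),
    strand = ifelse(bitwAnd(flag[keep], 0x10L) > 0L, "-", "+"),
    mapq = res$mapq[keep],
    library_id = rg[keep]
  )
  rec[, `:=`(end = start + width, width = NULL)]

  cnt <- rec[, .N, by = "qname"]
  mated <- cnt$qname[cnt$N == 2L]
  report["unmated_dropped"] <- sum(cnt$N[cnt$N != 2L])
  rec <- rec[rec$qname %in% mated, ]
  if (nrow(rec) == 0) {
    return(list(pairs = .empty_pair_table(), report = report,
                chrom_order = chrom_order))
  }
  data.table::setorder(rec, qname)  # radix, C locale
  odd <- seq(1L, nrow(rec), by = 2L)
  even <- odd + 1L
  raw <- data.table::data.table(
    chrom1 = rec$chrom[odd], start1 = rec$start[odd], end1 = rec$end[odd],
    strand1 = rec$strand[odd],
    chrom2 = rec$chrom[even], start2 = rec$start[even], end2 = rec$end[even],
    strand2 = rec$strand[even],
    sample_id = sample_id, library_id = rec$library_id[odd],
    read_id = rec$qname[odd],
    mapq1 = rec$mapq[odd], mapq2 = rec$mapq[even]
  )
  if (nrow(raw) == 0) raw <- .empty_pair_table()
  list(pairs = canonicalize_pairs(raw, chrom_order),
       report = report, chrom_order = chrom_order)
}

.empty_pair_table <- function() {
  data.table::data.table(
    chrom1 = character(), start1 = integer(), end1 = integer(),
    strand1 = character(),
    chrom2 = character(), start2 = integer(), end2 = integer(),
    strand2 = character(),
    sample_id = character(), library_id = character(), read_id = character(),
    mapq1 = integer(), mapq2 = integer()
  )
}

.as_bam <- function(path) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) return(path)
  dest <- tempfile(fileext = "")
  Rsamtools::asBam(path, destination = dest, indexDestination = FALSE,
                   overwrite = TRUE)
}

#' Canonicalize pair end order
#'
#' Reorders the two ends of each pair so that end 1 is the lower end under
#' (chromosome order, start coordinate); strands travel with their ends.
#' Idempotent.
#'
#' @param pairs Pair table.
#' @param chrom_order Character vector giving the reference order of
#'   chromosome names (from the alignment header).
#' @return Canonicalized pair table.
#' @export
canonicalize_pairs <- function(pairs, chrom_order) {
  .assert_pair_table(pairs)
  pairs <- data.table::as.data.table(pairs)
  if (nrow(pairs) == 0) return(pairs)
  c1 <- match(pairs$chrom1, chrom_order)
  c2 <- match(pairs$chrom2, chrom_order)
  if (anyNA(c1) || anyNA(c2))
    .stopf("pair references chromosome absent from the declared order: %s",
           paste(unique(c(pairs$chrom1[is.na(c1)], pairs$chrom2[is.na(c2)])),
                 collapse = ", "))
  swap <- c2 < c1 | (c1 == c2 & pairs$start2 < pairs$start1)
  if (any(swap)) {
    s <- pairs[swap, ]
    pairs[swap, `:=`(
      chrom1 = s$chrom2, start1 = s$start2, end1 = s$end2, strand1 = s$strand2,
      chrom2 = s$chrom1, start2 = s$start1, end2 = s$end1, strand2 = s$strand1
    )]
  }
  pairs
}

#' Routing key and rearrangement class of canonicalized pairs
#'
#' The routing key `(chrom1, chrom2, strand1, strand2)` isolates the set of
#' alignments able to support one rearrangement class on one chromosome (or
#' chromosome pair). For same-chromosome keys in an FR library: oversized
#' (+,-) pairs span deletions, everted (-,+) pairs span tandem-duplication
#' junctions, (+,+) and (-,-) pairs span inversion junctions. Any
#' interchromosomal key is a translocation.
#'
#' @param pairs Canonicalized pair table.
#' @return `data.table` with columns `key` (string) and `svclass`.
#' @export
routing_key <- function(pairs) {
  .assert_pair_table(pairs)
  key <- paste(pairs$chrom1, pairs$chrom2, pairs$strand1, pairs$strand2,
               sep = "\r")
  ori <- paste0(pairs$strand1, pairs$strand2)
  svclass <- ifelse(pairs$chrom1 != pairs$chrom2, "translocation",
             ifelse(ori == "+-", "deletion",
             ifelse(ori == "-+", "tandem_duplication", "inversion")))
  out <- data.table::data.table(.k = key, svclass = svclass)
  data.table::setnames(out, ".k", "key")
  out
}

#' Extract discordant pairs from a cohort and partition them by routing key
#'
#' Runs extraction for every sample of the sheet (each file is independent,
#' so extraction order cannot change the result), classifies pairs against
#' the per-library profiles, and writes every discordant pair to exactly one
#' spill file per routing key under `workdir/spill/`. Spill files use a
#' versioned tab-separated dialect (one pair per line, header row) so the
#' sort and clustering stages can be run and inspected in isolation.
#'
#' @param sample_sheet Path or data.frame (see [read_sample_sheet()]).
#' @param profiles Profile table covering every (sample, library).
#' @param min_mapq Minimum mapping quality (default 20).
#' @param workdir Working directory; `spill/` is created inside it.
#' @return List with `manifest` (data.table: chrom1, chrom2, strand1,
#'   strand2, svclass, n, file), `reports` (per-sample filter and
#'   classification counts) and `chrom_order`.
#' @export
extract_discordants <- function(sample_sheet, profiles, min_mapq = 20,
                                workdir) {
  sheet <- read_sample_sheet(sample_sheet)
  .assert_profile_table(profiles)
  spill_dir <- file.path(workdir, "spill")
  dir.create(spill_dir, recursive = TRUE, showWarnings = FALSE)

  chrom_order <- NULL
  disc <- vector("list", nrow(sheet))
  reports <- vector("list", nrow(sheet))
  for (i in seq_len(nrow(sheet))) {
    rd <- read_alignment_pairs(sheet$path[i], sample_id = sheet$sample_id[i],
                               min_mapq = min_mapq)
    if (is.null(chrom_order)) {
      chrom_order <- rd$chrom_order
    } else if (!identical(chrom_order, rd$chrom_order)) {
      .stopf("sample %s declares a different chromosome order than sample %s",
             sheet$sample_id[i], sheet$sample_id[1])
    }
    lab <- classify_alignment_pairs(rd$pairs, profiles)
    disc[[i]] <- rd$pairs[lab == "discordant", ]
    reports[[i]] <- data.table::data.table(
      sample_id = sheet$sample_id[i],
      t(rd$report),
      pairs = nrow(rd$pairs),
      concordant = sum(lab == "concordant"),
      discordant = sum(lab == "discordant"),
      excluded = sum(lab == "excluded")
    )
  }
  disc <- data.table::rbindlist(disc)
  if (nrow(disc) == 0) disc <- .empty_pair_table()

  rk <- routing_key(disc)
  keys <- unique(data.table::data.table(
    chrom1 = disc$chrom1, chrom2 = disc$chrom2,
    strand1 = disc$strand1, strand2 = disc$strand2, rkey = rk$key,
    svclass = rk$svclass
  ))
  if (nrow(keys) > 0) {
    ko <- order(match(keys$chrom1, chrom_order), match(keys$chrom2, chrom_order),
                keys$strand1, keys$strand2, method = "radix")
    keys <- keys[ko, ]
    keys[, file := file.path(spill_dir,
                             sprintf("partition-%04d.tsv", seq_len(.N)))]
  } else {
    keys[, file := character()]
  }
  n_by_key <- integer(nrow(keys))
  for (j in seq_len(nrow(keys))) {
    part <- disc[rk$key == keys$rkey[j], PAIR_COLS, with = FALSE]
    n_by_key[j] <- nrow(part)
    data.table::fwrite(part, keys$file[j], sep = "\t")
  }
  manifest <- keys[, c("chrom1", "chrom2", "strand1", "strand2", "svclass",
                       "file"), with = FALSE]
  manifest[, n := n_by_key]
  data.table::fwrite(manifest, file.path(workdir, "partitions.tsv"), sep = "\t")
  list(manifest = manifest, reports = data.table::rbindlist(reports),
       chrom_order = chrom_order)
}
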