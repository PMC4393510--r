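#' Parse "sample:count" support strings
#'
#' @param support Character vector like `"A:3;B:1"`.
#' @return List of named integer vectors, one per call.
#' @export
parse_support <- function(support) {
  lapply(support, function(s) {
    if (is.na(s) || s == "") return(setNames(integer(0), character(0)))
    parts <- strsplit(s, ";", fixed = TRUE)[[1]]
    kv <- strsplit(parts, ":", fixed = TRUE)
    bad <- lengths(kv) != 2
    if (any(bad)) .stopf("malformed support field: %s", s)
    setNames(as.integer(vapply(kv, `[`, "", 2)), vapply(kv, `[`, "", 1))
  })
}

#' Filter calls by minimum support
#'
#' Keeps calls with at least `min_support` supporting read pairs in total
#' and, when `require_sample` is given, at least one supporting pair from
#' that sample. The latter mirrors evaluations where the focal sample has
#' to contribute evidence for a call to count as a detection in it.
#'
#' When the call table carries a `"sample_ids"` attribute (pipeline outputs
#' do), `require_sample` must name a sample from that cohort; otherwise any
#' name is accepted and calls lacking its support are simply dropped.
#'
#' @param calls Call table ([finalize_call()] / [read_bedpe()]).
#' @param min_support Minimum total supporting read pairs (>= 1).
#' @param require_sample Optional sample id that must contribute >= 1 pair.
#' @return Filtered call table.
#' @export
filter_calls <- function(calls, min_support, require_sample = NULL) {
  if (min_support < 1) .stopf("min_support must be >= 1")
  if (nrow(calls) == 0) return(calls)
  keep <- calls$total_support >= min_support
  if (!is.null(require_sample)) {
    sup <- parse_support(calls$support)
    universe <- attr(calls, "sample_ids")
    if (!is.null(universe) && !(require_sample %in% universe))
      .stopf("unknown sample: %s", require_sample)
    has <- vapply(sup, function(x) {
      v <- x[require_sample]
      !is.na(v) && v >= 1
    }, logical(1))
    keep <- keep & has
  }
  calls[keep, ]
}

BEDPE_COLS <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
                "name", "score", "strand1", "strand2", "svclass",
                "total_support", "support")

#' Write / read SV calls as BEDPE
#'
#' BEDPE, 0-based half-open, with three extra columns: SV class, total
#' support and the per-sample support string. `score` is the total support
#' and `name` the call id, so files are directly inspectable. Reading back
#' inverts writing on the call data model.
#'
#' @param calls Call table.
#' @param path Output (input) path.
#' @export
write_bedpe <- function(calls, path) {
  con <- file(path, open = "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(BEDPE_COLS, collapse = "\t")), con)
  if (nrow(calls) > 0) {
    lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%d\t%s\t%d\t%s\t%s\t%s\t%d\t%s",
                     calls$chrom1, calls$start1, calls$end1,
                     calls$chrom2, calls$start2, calls$end2,
                     calls$call_id, calls$total_support,
                     calls$strand1, calls$strand2,
                     calls$svclass, calls$total_support, calls$support)
    writeLines(lines, con)
  }
  invisible(path)
}

#' @rdname write_bedpe
#' @export
read_bedpe <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0) {
    out <- .empty_call_table()
    return(out[, setdiff(names(out), c("fp_start1", "fp_end1", "fp_start2",
                                       "fp_end2")), with = FALSE])
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf != length(BEDPE_COLS))) {
    ln <- which(nf != length(BEDPE_COLS))[1]
    .stopf("%s: malformed BEDPE line %d (%d fields, expected %d)",
           path, which(!startsWith(lines, "#"))[ln], nf[ln],
           length(BEDPE_COLS))
  }
  g <- function(i) vapply(f, `[`, "", i)
  gi <- function(i) {
    v <- suppressWarnings(as.integer(g(i)))
    if (anyNA(v)) {
      ln <- which(!startsWith(lines, "#"))[which(is.na(v))[1]]
      .stopf("%s: malformed BEDPE line %d (non-integer coordinate)", path, ln)
    }
    v
  }
  data.table::data.table(
    call_id = g(7), svclass = g(11),
    chrom1 = g(1), start1 = gi(2), end1 = gi(3),
    chrom2 = g(4), start2 = gi(5), end2 = gi(6),
    strand1 = g(9), strand2 = g(10),
    total_support = gi(12), support = g(13)
  )
}
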