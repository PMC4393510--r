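# Internal helpers shared across pipeline stages.

# Deterministic half-up rounding (base round() is round-half-even).
round_half_up <- function(x) floor(x + 0.5)

# Lower-median: for even n the lower of the two central order statistics.
lower_median <- function(v) {
  v <- sort(v)
  v[floor((length(v) + 1) / 2)]
}

#' @importFrom data.table data.table setDT setorder fread fwrite rbindlist
#' @importFrom stats rnorm rpois runif rbinom setNames
NULL

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Columns of the discordant-pair table; also the column order of the
# tab-separated spill/run dialect (version 1).
PAIR_COLS <- c(
  "chrom1", "start1", "end1", "strand1",
  "chrom2", "start2", "end2", "strand2",
  "sample_id", "library_id", "read_id", "mapq1", "mapq2"
)
PAIR_INT_COLS <- c("start1", "end1", "start2", "end2", "mapq1", "mapq2")

.assert_pair_table <- function(pairs) {
  missing <- setdiff(PAIR_COLS, names(pairs))
  if (length(missing) > 0)
    .stopf("pair table is missing columns: %s", paste(missing, collapse = ", "))
  invisible(pairs)
}

# Read a sample sheet (TSV: sample_id, role, pair_id, path, optionally depth).
# Accepts a path or an existing data.frame.
read_sample_sheet <- function(sheet) {
  if (is.character(sheet) && length(sheet) == 1) {
    sheet <- data.table::fread(sheet, sep = "\t", header = TRUE,
                               colClasses = list(character = "pair_id"))
  }
  sheet <- data.table::as.data.table(sheet)
  req <- c("sample_id", "role", "pair_id", "path")
  missing <- setdiff(req, names(sheet))
  if (length(missing) > 0)
    .stopf("sample sheet is missing columns: %s", paste(missing, collapse = ", "))
  if (anyDuplicated(sheet$sample_id))
    .stopf("sample sheet contains duplicated sample_id values")
  bad <- setdiff(unique(sheet$role), c("tumor", "normal", "none"))
  if (length(bad) > 0)
    .stopf("sample sheet role must be tumor/normal/none, found: %s",
           paste(bad, collapse = ", "))
  sheet[]
}
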