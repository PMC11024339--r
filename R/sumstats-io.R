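#' Read GWAS summary statistics from a delimited file
#'
#' Reads a tab- or comma-delimited file with a header row into a validated
#' \code{\link{SumstatsTable}}. Rows violating the per-record invariants
#' (non-positive se, p-value outside (0, 1], non-ACGT or identical alleles,
#' out-of-range eaf, bad position, missing rsid, duplicated rsid) are
#' dropped; the count per rejection reason is reported via \code{message()}
#' and stored in \code{metadata(x)$dropLog}.
#'
#' @param path file to read.
#' @param columnMap named character vector mapping canonical field names
#'   (rsid, chrom, pos, effect_allele, other_allele, eaf, beta, se, pval, n)
#'   to the file's column names; unmapped names default to themselves.
#'   \code{eaf} and \code{n} may be absent from the file.
#' @param traitType \code{"continuous"} or \code{"binary"}.
#' @param traitId trait identifier; defaults to the file name.
#' @param ancestry ancestry label (metadata only).
#' @return a \code{SumstatsTable}.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' df <- data.frame(rsid = c("rs1", "rs2"), chrom = "1", pos = c(100, 200),
#'                  effect_allele = "A", other_allele = "G", eaf = 0.3,
#'                  beta = c(0.1, -0.2), se = 0.02, pval = c(1e-9, 1e-10),
#'                  n = 1000)
#' write.table(df, tf, sep = "\t", quote = FALSE, row.names = FALSE)
#' readSumstats(tf, traitType = "continuous", traitId = "demo")
#' @export
readSumstats <- function(path, columnMap = NULL,
                         traitType = c("continuous", "binary"),
                         traitId = NULL, ancestry = "EUR") {
  traitType <- match.arg(traitType)
  if (!file.exists(path)) mrStop(paste("no such file:", path), "ioError")
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = c("NA", ""))
  map <- setNames(SUMSTATS_COLS, SUMSTATS_COLS)
  if (!is.null(columnMap)) map[names(columnMap)] <- columnMap
  required <- setdiff(SUMSTATS_COLS, c("eaf", "n"))
  absent <- required[!map[required] %in% names(raw)]
  if (length(absent))
    mrStop(paste("mapped columns not found in file:",
                 paste(map[absent], collapse = ", ")), "configError")
  df <- data.frame(row.names = seq_len(nrow(raw)))
  for (col in SUMSTATS_COLS) {
    df[[col]] <- if (map[[col]] %in% names(raw)) raw[[map[[col]]]] else NA
  }
  df <- canonicalizeSnps(df)

  reason <- rowInvalidReason(df)
  dup <- duplicated(df$rsid) & is.na(reason)
  reason[dup] <- "duplicate_rsid"
  dropLog <- table(reason[!is.na(reason)])
  df <- df[is.na(reason), , drop = FALSE]
  rownames(df) <- NULL
  if (length(dropLog))
    message(sprintf("readSumstats: dropped %d row(s): %s", sum(dropLog),
                    paste(sprintf("%s=%d", names(dropLog), dropLog),
                          collapse = ", ")))
  if (!nrow(df))
    mrStop(paste("no valid summary-statistic rows in", path), "emptyInput")
  if (is.null(traitId)) traitId <- basename(path)
  SumstatsTable(df, traitId = traitId, traitType = traitType,
                ancestry = ancestry,
                metadata = list(dropLog = as.list(dropLog), source = path))
}

#' Write a SumstatsTable to tab-delimited text
#'
#' Columns are written in the fixed order rsid, chrom, pos, effect_allele,
#' other_allele, eaf, beta, se, pval, n; floating-point values carry 15
#' significant digits so that \code{readSumstats(writeSumstats(x))} returns
#' the table unchanged; missing values are written as the literal
#' \code{NA}. An empty table yields a header-only file.
#'
#' @param x a \code{\link{SumstatsTable}}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeSumstats <- function(x, path) {
  stopifnot(is(x, "SumstatsTable"))
  df <- x@snps[SUMSTATS_COLS]
  for (col in c("eaf", "beta", "se", "pval"))
    df[[col]] <- formatFloat(df[[col]])
  df$n <- formatFloat(df$n)
  ok <- tryCatch({
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "NA")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) mrStop(paste("cannot write to", path), "ioError")
  invisible(path)
}

formatFloat <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.15g", v)
  }, character(1))
  out
}

#' Read a confounder-annotation table
#'
#' Tab- or comma-delimited file with columns \code{rsid}, \code{trait},
#' \code{pval}: known SNP-trait associations (e.g. a PhenoScanner export)
#' used by \code{\link{screenConfounders}} to enforce the MR independence
#' assumption. Rows with p-values outside (0, 1] are dropped with a message.
#'
#' @param path file to read.
#' @return data.frame with columns rsid, trait, pval.
#' @export
readConfounderAnnotations <- function(path) {
  if (!file.exists(path)) mrStop(paste("no such file:", path), "ioError")
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("rsid", "trait", "pval")
  if (!all(need %in% names(df)))
    mrStop("annotation file needs columns rsid, trait, pval", "configError")
  df <- df[need]
  df$pval <- as.numeric(df$pval)
  bad <- is.na(df$pval) | df$pval <= 0 | df$pval > 1
  if (any(bad))
    message(sprintf("readConfounderAnnotations: dropped %d row(s) with bad p-values",
                    sum(bad)))
  df <- df[!bad, , drop = FALSE]
  rownames(df) <- NULL
  df
}

setMethod("metadata", "SumstatsTable", function(x, ...) x@metadata)
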