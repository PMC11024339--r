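#' Is an allele pair palindromic?
#'
#' A variant is palindromic when its two alleles are complementary
#' (\{A, T\} or \{C, G\}), so the strand cannot be resolved from the allele
#' letters alone. Palindromic instruments are eliminated during
#' harmonization.
#'
#' @param a1,a2 allele letters (vectorized).
#' @return logical vector.
#' @examples
#' isPalindromic("A", "T")  # TRUE
#' isPalindromic("A", "G")  # FALSE
#' @export
isPalindromic <- function(a1, a2) {
  a1 <- toupper(a1); a2 <- toupper(a2)
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize one exposure/outcome record pair
#'
#' Aligns an outcome record onto the exposure's effect-allele frame. The
#' decision sequence is: (1) palindromic exposure alleles are dropped
#' outright; (2) if the outcome alleles equal the exposure's in the same
#' order the record is kept as is, and if in swapped order the outcome beta
#' is negated and its frequency reflected (eaf to 1 - eaf); (3) otherwise
#' the outcome alleles are strand-complemented (A/T, C/G) and step 2 is
#' retried; (4) records that still fail to match are dropped as
#' incompatible; (5) after alignment a record is dropped when the minor
#' allele frequency on either side is not strictly above \code{mafMin}, or
#' when a frequency is missing. The exposure record is never modified.
#'
#' @param exp,out single-row data.frames (or one-row lists) with the
#'   \code{SumstatsTable} columns, sharing one rsid.
#' @param mafMin minor-allele-frequency floor (default 0.01).
#' @return a one-row data.frame with columns rsid, beta_exp, se_exp,
#'   beta_out, se_out, eaf_exp, eaf_out, action — or a character scalar
#'   naming the drop reason (\code{palindromic},
#'   \code{incompatible_alleles}, \code{low_maf}).
#' @export
harmonizePair <- function(exp, out, mafMin = 0.01) {
  if (exp$rsid != out$rsid)
    mrStop("harmonizePair requires matching rsids", "contractViolation")
  if (isPalindromic(exp$effect_allele, exp$other_allele))
    return("palindromic")
  beta_out <- out$beta
  eaf_out <- out$eaf
  oe <- toupper(out$effect_allele); oo <- toupper(out$other_allele)
  ee <- toupper(exp$effect_allele); eo <- toupper(exp$other_allele)
  action <- NULL
  if (oe == ee && oo == eo) {
    action <- "kept_as_is"
  } else if (oe == eo && oo == ee) {
    action <- "flipped"
  } else {
    oe <- unname(COMPLEMENT[oe]); oo <- unname(COMPLEMENT[oo])
    if (oe == ee && oo == eo) {
      action <- "strand_complemented"
    } else if (oe == eo && oo == ee) {
      action <- "strand_complemented_and_flipped"
    }
  }
  if (is.null(action)) return("incompatible_alleles")
  if (action %in% c("flipped", "strand_complemented_and_flipped")) {
    beta_out <- -beta_out
    eaf_out <- if (is.na(eaf_out)) NA_real_ else 1 - eaf_out
  }
  maf <- function(f) pmin(f, 1 - f)
  if (is.na(exp$eaf) || is.na(eaf_out) ||
      maf(exp$eaf) <= mafMin || maf(eaf_out) <= mafMin)
    return("low_maf")
  data.frame(rsid = exp$rsid, beta_exp = exp$beta, se_exp = exp$se,
             beta_out = beta_out, se_out = out$se, eaf_exp = exp$eaf,
             eaf_out = eaf_out, action = action, stringsAsFactors = FALSE)
}

#' Harmonize an instrument set against an outcome trait
#'
#' Joins each instrument to the outcome table by rsid and applies
#' \code{\link{harmonizePair}}. Instruments absent from the outcome table
#' are logged as \code{not_in_outcome}. Every input instrument is accounted
#' for exactly once, either among the aligned pairs or in the drop log.
#'
#' @param instr an \code{\link{InstrumentSet}}.
#' @param outcome outcome \code{\link{SumstatsTable}}.
#' @param mafMin minor-allele-frequency floor (default 0.01).
#' @return a \code{\link{HarmonizedSet}}.
#' @export
harmonize <- function(instr, outcome, mafMin = 0.01) {
  stopifnot(is(instr, "InstrumentSet"), is(outcome, "SumstatsTable"))
  idf <- instr@instruments
  odf <- outcome@snps
  idx <- match(idf$rsid, odf$rsid)
  pairs <- list()
  drops <- list()
  for (i in seq_len(nrow(idf))) {
    if (is.na(idx[i])) {
      drops[[length(drops) + 1L]] <-
        data.frame(rsid = idf$rsid[i], reason = "not_in_outcome")
      next
    }
    res <- harmonizePair(idf[i, ], odf[idx[i], ], mafMin = mafMin)
    if (is.character(res)) {
      drops[[length(drops) + 1L]] <-
        data.frame(rsid = idf$rsid[i], reason = res)
    } else {
      pairs[[length(pairs) + 1L]] <- res
    }
  }
  emptyPairs <- data.frame(rsid = character(), beta_exp = numeric(),
                           se_exp = numeric(), beta_out = numeric(),
                           se_out = numeric(), eaf_exp = numeric(),
                           eaf_out = numeric(), action = character(),
                           stringsAsFactors = FALSE)
  pairDf <- if (length(pairs)) do.call(rbind, pairs) else emptyPairs
  dropDf <- if (length(drops)) do.call(rbind, drops) else
    data.frame(rsid = character(), reason = character())
  new("HarmonizedSet", exposureId = instr@exposureId,
      outcomeId = traitId(outcome), outcomeType = traitType(outcome),
      pairs = resetRows(pairDf), dropLog = resetRows(dropDf))
}

#' Serialize a HarmonizedSet
#'
#' Writes the aligned pairs to \code{path} (TSV with columns rsid, beta_exp,
#' se_exp, beta_out, se_out, eaf_exp, eaf_out, action) and the drop log to
#' \code{<path>.drops.tsv}.
#'
#' @param h a \code{\link{HarmonizedSet}}.
#' @param path output file for the aligned pairs.
#' @return invisibly, \code{path}.
#' @export
writeHarmonizedSet <- function(h, path) {
  stopifnot(is(h, "HarmonizedSet"))
  write.table(h@pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(h@dropLog, paste0(path, ".drops.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
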