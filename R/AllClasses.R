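#' @import methods
#' @importFrom stats pchisq pnorm pt qnorm rnorm runif sd setNames cor
#'   optimize lm coef
#' @importFrom utils read.delim write.table
NULL

SUMSTATS_COLS <- c("rsid", "chrom", "pos", "effect_allele", "other_allele",
                   "eaf", "beta", "se", "pval", "n")

#' SumstatsTable: per-SNP GWAS summary statistics for one trait
#'
#' Holds the per-variant association record of a single GWAS trait: rsid,
#' chromosome, 1-based position, effect and other allele (single A/C/G/T
#' letters), effect-allele frequency (may be \code{NA}), additive effect
#' \code{beta} (log-odds for binary traits), its standard error, two-sided
#' p-value and optional sample size. Validity enforces \code{se > 0},
#' \code{pval} in (0, 1], distinct single-letter alleles and unique rsids.
#'
#' @slot traitId single string identifying the trait.
#' @slot traitType \code{"binary"} or \code{"continuous"}; decides whether
#'   causal estimates with this trait as outcome are reported as odds ratios.
#' @slot ancestry free-text ancestry label (metadata only).
#' @slot snps \code{data.frame} with columns rsid, chrom, pos, effect_allele,
#'   other_allele, eaf, beta, se, pval, n.
#' @slot metadata list of run metadata, e.g. the per-reason drop counts
#'   recorded by \code{\link{readSumstats}}.
#' @exportClass SumstatsTable
setClass("SumstatsTable",
  representation(traitId = "character", traitType = "character",
                 ancestry = "character", snps = "data.frame",
                 metadata = "list"),
  prototype(traitId = NA_character_, traitType = "continuous",
            ancestry = "EUR", metadata = list()))

setValidity("SumstatsTable", function(object) {
  df <- object@snps
  msg <- character()
  if (length(object@traitId) != 1L) msg <- c(msg, "traitId must be length 1")
  if (!object@traitType %in% c("binary", "continuous"))
    msg <- c(msg, "traitType must be 'binary' or 'continuous'")
  if (!all(SUMSTATS_COLS %in% names(df)))
    msg <- c(msg, paste("snps must have columns:",
                        paste(SUMSTATS_COLS, collapse = ", ")))
  if (length(msg)) return(msg)
  if (nrow(df)) {
    bad <- rowInvalidReason(df)
    if (any(!is.na(bad)))
      msg <- c(msg, paste0("invalid rows: ",
                           paste(unique(bad[!is.na(bad)]), collapse = ", ")))
    if (anyDuplicated(df$rsid)) msg <- c(msg, "rsid values must be unique")
  }
  if (length(msg)) msg else TRUE
})

## one rejection reason per row (first failed check wins); NA = valid
rowInvalidReason <- function(df) {
  reason <- rep(NA_character_, nrow(df))
  take <- function(cond, why) {
    cond[is.na(cond)] <- TRUE
    ifelse(is.na(reason) & cond, why, reason)
  }
  alpha <- c("A", "C", "G", "T")
  reason <- take(!(df$effect_allele %in% alpha), "bad_effect_allele")
  reason <- take(!(df$other_allele %in% alpha), "bad_other_allele")
  reason <- take(df$effect_allele == df$other_allele, "identical_alleles")
  reason <- take(!(df$se > 0), "nonpositive_se")
  reason <- take(!(df$pval > 0 & df$pval <= 1), "pval_out_of_range")
  reason <- take(!is.na(df$eaf) & !(df$eaf >= 0 & df$eaf <= 1),
                 "eaf_out_of_range")
  reason <- take(!(df$pos >= 1), "bad_position")
  reason <- take(is.na(df$rsid) | df$rsid == "", "missing_rsid")
  reason
}

#' Construct a SumstatsTable
#'
#' Allele letters are upper-cased; columns are coerced to their canonical
#' types. Rows violating the record invariants raise an error (use
#' \code{\link{readSumstats}} for tolerant row-dropping ingestion).
#'
#' @param snps data.frame of per-SNP records (see class docs for columns;
#'   \code{eaf} and \code{n} may be missing and default to \code{NA}).
#' @param traitId trait identifier.
#' @param traitType \code{"binary"} or \code{"continuous"}.
#' @param ancestry ancestry label, metadata only.
#' @param metadata optional list of metadata.
#' @return a validated \code{SumstatsTable}.
#' @export
SumstatsTable <- function(snps, traitId, traitType = c("continuous", "binary"),
                          ancestry = "EUR", metadata = list()) {
  traitType <- match.arg(traitType)
  snps <- canonicalizeSnps(snps)
  new("SumstatsTable", traitId = as.character(traitId), traitType = traitType,
      ancestry = ancestry, snps = snps, metadata = metadata)
}

canonicalizeSnps <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"eaf" %in% names(df)) df$eaf <- NA_real_
  if (!"n" %in% names(df)) df$n <- NA_real_
  missing <- setdiff(SUMSTATS_COLS, names(df))
  if (length(missing))
    mrStop(paste("missing summary-statistic columns:",
                 paste(missing, collapse = ", ")), "configError")
  df <- df[SUMSTATS_COLS]
  df$rsid <- as.character(df$rsid)
  df$chrom <- as.character(df$chrom)
  df$pos <- as.numeric(df$pos)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (col in c("eaf", "beta", "se", "pval", "n"))
    df[[col]] <- as.numeric(df[[col]])
  rownames(df) <- NULL
  df
}

#' LdReference: pairwise linkage-disequilibrium lookup
#'
#' Backs LD clumping with pairwise r-squared values, either computed on the
#' fly from a per-sample allele-dosage panel (values in [0, 2]) or looked up
#' in a precomputed symmetric map. \code{r2(ld, a, b)} returns \code{NA} for
#' pairs absent from a precomputed map.
#'
#' @slot dosages numeric matrix (samples x rsids) of allele dosages; empty
#'   when a precomputed map is used.
#' @slot r2map named numeric vector of precomputed r-squared values keyed by
#'   the sorted rsid pair; empty when a dosage panel is used.
#' @slot rsids character vector of variants known to the reference.
#' @exportClass LdReference
setClass("LdReference",
  representation(dosages = "matrix", r2map = "numeric", rsids = "character"))

setValidity("LdReference", function(object) {
  if (length(object@dosages) && length(object@r2map))
    return("supply a dosage panel or an r2 map, not both")
  if (length(object@dosages)) {
    if (is.null(colnames(object@dosages)))
      return("dosage panel must have rsid column names")
    if (any(object@dosages < 0 | object@dosages > 2))
      return("dosages must lie in [0, 2]")
  }
  if (length(object@r2map) &&
      any(object@r2map < 0 | object@r2map > 1 + 1e-12))
    return("r2 values must lie in [0, 1]")
  TRUE
})

#' Construct an LdReference
#'
#' @param dosages samples x rsids matrix of allele dosages in [0, 2], with
#'   rsid column names. Mutually exclusive with \code{r2map}.
#' @param r2map data.frame with columns \code{rsid_i}, \code{rsid_j},
#'   \code{r2}; stored symmetrically.
#' @return an \code{LdReference}.
#' @export
LdReference <- function(dosages = NULL, r2map = NULL) {
  if (!is.null(dosages)) {
    dosages <- as.matrix(dosages)
    return(new("LdReference", dosages = dosages, r2map = numeric(),
               rsids = colnames(dosages)))
  }
  if (is.null(r2map))
    mrStop("supply either a dosage panel or an r2 map", "configError")
  r2map <- as.data.frame(r2map)
  stopifnot(all(c("rsid_i", "rsid_j", "r2") %in% names(r2map)))
  key <- pairKey(r2map$rsid_i, r2map$rsid_j)
  vals <- setNames(as.numeric(r2map$r2), key)
  vals <- vals[!duplicated(names(vals))]
  new("LdReference", dosages = matrix(numeric(), 0, 0), r2map = vals,
      rsids = unique(c(r2map$rsid_i, r2map$rsid_j)))
}

pairKey <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' InstrumentSet: selected genetic instruments for one exposure
#'
#' @slot exposureId exposure trait id.
#' @slot instruments data.frame of surviving exposure-side records plus an
#'   \code{f_stat} column, \code{(beta/se)^2}.
#' @slot selectionLog named integer vector of per-stage counts
#'   (input, eaf_present, p_filter, f_filter, clump, confounder_screen).
#' @exportClass InstrumentSet
setClass("InstrumentSet",
  representation(exposureId = "character", instruments = "data.frame",
                 selectionLog = "integer"))

setValidity("InstrumentSet", function(object) {
  df <- object@instruments
  if (nrow(df)) {
    if (anyDuplicated(df$rsid)) return("instrument rsids must be unique")
    if (!"f_stat" %in% names(df)) return("instruments need an f_stat column")
    rel <- abs(df$f_stat - (df$beta / df$se)^2) /
      pmax(1e-300, (df$beta / df$se)^2)
    if (any(df$f_stat > 0 & rel > 1e-12))
      return("f_stat must equal (beta/se)^2")
  }
  if (any(diff(object@selectionLog) > 0L))
    return("selection-stage counts must be non-increasing")
  TRUE
})

#' HarmonizedSet: exposure/outcome effects aligned on one effect allele
#'
#' @slot exposureId,outcomeId trait ids of the aligned pair.
#' @slot outcomeType outcome trait type, drives odds-ratio reporting.
#' @slot pairs data.frame with columns rsid, beta_exp, se_exp, beta_out,
#'   se_out, eaf_exp, eaf_out, action (kept_as_is / flipped /
#'   strand_complemented / strand_complemented_and_flipped).
#' @slot dropLog data.frame (rsid, reason) for instruments not carried
#'   forward: not_in_outcome, palindromic, incompatible_alleles, low_maf,
#'   presso_outlier.
#' @exportClass HarmonizedSet
setClass("HarmonizedSet",
  representation(exposureId = "character", outcomeId = "character",
                 outcomeType = "character", pairs = "data.frame",
                 dropLog = "data.frame"))

setValidity("HarmonizedSet", function(object) {
  p <- object@pairs
  msg <- character()
  need <- c("rsid", "beta_exp", "se_exp", "beta_out", "se_out",
            "eaf_exp", "eaf_out", "action")
  if (!all(need %in% names(p))) return("pairs is missing required columns")
  if (nrow(p) && any(p$se_exp <= 0 | p$se_out <= 0))
    msg <- c(msg, "standard errors must be positive")
  if (length(intersect(p$rsid, object@dropLog$rsid)))
    msg <- c(msg, "a variant cannot be both kept and dropped")
  if (length(msg)) msg else TRUE
})

#' MrResult: a single causal estimate
#'
#' @slot method one of ivw, egger, weighted_median, penalized_weighted_median,
#'   max_likelihood.
#' @slot nSnp number of variants used.
#' @slot beta point estimate on the current scale (log-odds/beta, or OR after
#'   \code{\link{toOddsRatio}}).
#' @slot se standard error, always on the beta (log) scale.
#' @slot ciLow,ciHigh 95 percent confidence bounds on the current scale.
#' @slot pval two-sided p-value.
#' @slot effectScale \code{"beta"} or \code{"or"}.
#' @slot ivwModel \code{"fixed"} or \code{"random"} for IVW, otherwise
#'   \code{NA}.
#' @exportClass MrResult
setClass("MrResult",
  representation(method = "character", nSnp = "integer", beta = "numeric",
                 se = "numeric", ciLow = "numeric", ciHigh = "numeric",
                 pval = "numeric", effectScale = "character",
                 ivwModel = "character"),
  prototype(effectScale = "beta", ivwModel = NA_character_))

setValidity("MrResult", function(object) {
  msg <- character()
  if (!(object@ciLow <= object@beta && object@beta <= object@ciHigh))
    msg <- c(msg, "confidence interval must bracket the estimate")
  if (!(object@se > 0)) msg <- c(msg, "se must be positive")
  if (!(object@pval > 0 && object@pval <= 1))
    msg <- c(msg, "pval must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Diagnostics: heterogeneity and directional-pleiotropy checks
#'
#' Cochran's Q from the IVW fit (with df and chi-square p) and the MR-Egger
#' intercept with its standard error and t-test p-value. Fields not yet
#' computed are \code{NA}.
#'
#' @exportClass Diagnostics
setClass("Diagnostics",
  representation(cochranQ = "numeric", qDf = "numeric", qPval = "numeric",
                 eggerIntercept = "numeric", interceptSe = "numeric",
                 interceptPval = "numeric"),
  prototype(cochranQ = NA_real_, qDf = NA_real_, qPval = NA_real_,
            eggerIntercept = NA_real_, interceptSe = NA_real_,
            interceptPval = NA_real_))

setValidity("Diagnostics", function(object) {
  if (!is.na(object@cochranQ) && object@cochranQ < 0)
    return("Cochran's Q cannot be negative")
  if (!is.na(object@qDf) && object@qDf < 1)
    return("Q degrees of freedom must be >= 1")
  TRUE
})

#' PressoResult: MR-PRESSO global test and per-SNP outlier calls
#'
#' @slot rssObs observed leave-one-out weighted residual sum of squares.
#' @slot globalPval Monte-Carlo global heterogeneity p (+1 corrected, so
#'   never below 1/(nSim+1)).
#' @slot outlierPvals named per-SNP Bonferroni-adjusted Monte-Carlo p-values.
#' @slot outliers rsids flagged at the configured significance level.
#' @slot nSim simulation count; @slot seed RNG seed used.
#' @exportClass PressoResult
setClass("PressoResult",
  representation(rssObs = "numeric", globalPval = "numeric",
                 outlierPvals = "numeric", outliers = "character",
                 nSim = "integer", seed = "integer"))

setValidity("PressoResult", function(object) {
  if (object@globalPval < 1 / (object@nSim + 1) - 1e-12 ||
      object@globalPval > 1)
    return("globalPval must lie in [1/(nSim+1), 1]")
  if (!all(object@outliers %in% names(object@outlierPvals)))
    return("outliers must be a subset of tested rsids")
  TRUE
})

#' PairAnalysis: one exposure-to-outcome record of the bi-directional grid
#'
#' @slot exposureId,outcomeId,direction identity of the pair
#'   (\code{"forward"} or \code{"reverse"}).
#' @slot stageCounts named integer vector of instrument counts through
#'   selection, harmonization and outlier removal.
#' @slot diagnostics a \code{Diagnostics}.
#' @slot presso a \code{PressoResult}, or \code{NULL} when skipped.
#' @slot results named list of \code{MrResult}, one per estimable method.
#' @slot significant IVW p-value below the direction's Bonferroni threshold.
#' @slot threshold the Bonferroni threshold applied.
#' @slot status \code{"ok"} or \code{"not_estimable(<stage>)"}.
#' @exportClass PairAnalysis
setClass("PairAnalysis",
  representation(exposureId = "character", outcomeId = "character",
                 direction = "character", stageCounts = "integer",
                 diagnostics = "Diagnostics", presso = "ANY",
                 results = "list", significant = "logical",
                 threshold = "numeric", status = "character"))

setValidity("PairAnalysis", function(object) {
  if (!object@direction %in% c("forward", "reverse"))
    return("direction must be 'forward' or 'reverse'")
  ivw <- object@results[["ivw"]]
  if (!is.null(ivw)) {
    flag <- mrPval(ivw) < object@threshold
    if (!identical(flag, object@significant))
      return("significant flag must derive from the IVW p and threshold")
  } else if (isTRUE(object@significant)) {
    return("a pair without an IVW estimate cannot be significant")
  }
  TRUE
})
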