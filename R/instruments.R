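#' Instrument-strength F statistic
#'
#' For a single-SNP association the F statistic is the squared Wald
#' statistic, F = (beta/se)^2; values above 10 are conventionally taken as
#' protection against weak-instrument bias.
#'
#' @param beta effect size(s).
#' @param se standard error(s), strictly positive.
#' @return numeric vector of F statistics.
#' @examples
#' computeFStatistic(0.03, 0.005)   # 36
#' @export
computeFStatistic <- function(beta, se) {
  if (any(is.na(se)) || any(se <= 0))
    mrStop("se must be strictly positive", "domainError")
  (beta / se)^2
}

#' Keep genome-wide-significant, strong instruments
#'
#' Retains exactly the records with \code{pval < pThreshold} and
#' F = (beta/se)^2 \code{> fThreshold} (both strict, so a record at
#' p = 5e-8 exactly is dropped). Row order is preserved.
#'
#' @param x a \code{\link{SumstatsTable}}.
#' @param pThreshold genome-wide significance ceiling (default 5e-8).
#' @param fThreshold F-statistic floor (default 10).
#' @return a filtered \code{SumstatsTable} (possibly empty).
#' @export
filterSignificant <- function(x, pThreshold = 5e-8, fThreshold = 10) {
  stopifnot(is(x, "SumstatsTable"))
  df <- x@snps
  keep <- df$pval < pThreshold & computeFStatistic(df$beta, df$se) > fThreshold
  initialize(x, snps = df[keep, , drop = FALSE] |> resetRows())
}

#' Greedy LD clumping
#'
#' Screens LD-independent variants with the standard greedy algorithm: sort
#' by ascending p-value (ties broken by chromosome then position), take the
#' most significant unassigned variant as an index, and discard every
#' unassigned variant on the same chromosome within \code{windowKb}
#' kilobases whose r-squared with the index is at least \code{r2Threshold}.
#' Index variants are returned in their original table order. Variants
#' absent from the LD reference are dropped first with a message; pairs
#' missing from a precomputed r-squared map are kept with a warning
#' (unknown LD is not grounds for discarding an instrument).
#'
#' @param x a \code{\link{SumstatsTable}}.
#' @param ld an \code{\link{LdReference}} covering the table's rsids.
#' @param r2Threshold clumping r-squared ceiling (default 0.001).
#' @param windowKb window half-width in kilobases around the index variant
#'   (default 1000, i.e. a 1 Mb window on either side).
#' @return a \code{SumstatsTable} of index variants.
#' @export
ldClump <- function(x, ld, r2Threshold = 0.001, windowKb = 1000) {
  stopifnot(is(x, "SumstatsTable"), is(ld, "LdReference"))
  if (r2Threshold <= 0 || r2Threshold > 1)
    mrStop("r2Threshold must lie in (0, 1]", "configError")
  if (windowKb <= 0) mrStop("windowKb must be positive", "configError")
  df <- x@snps
  known <- hasRsid(ld, df$rsid)
  if (any(!known)) {
    message(sprintf("ldClump: %d variant(s) absent from the LD reference dropped",
                    sum(!known)))
    df <- df[known, , drop = FALSE]
  }
  if (!nrow(df))
    return(initialize(x, snps = df |> resetRows()))
  ord <- order(df$pval, df$chrom, df$pos)
  state <- rep("unassigned", nrow(df))  # -> index | discarded
  for (i in ord) {
    if (state[i] != "unassigned") next
    state[i] <- "index"
    near <- which(state == "unassigned" & df$chrom == df$chrom[i] &
                    abs(df$pos - df$pos[i]) <= windowKb * 1000)
    if (!length(near)) next
    r2 <- ldR2(ld, df$rsid[i], df$rsid[near])
    if (anyNA(r2)) {
      warning(sprintf("ldClump: unknown r2 for %d pair(s) near %s; keeping them",
                      sum(is.na(r2)), df$rsid[i]))
      r2[is.na(r2)] <- 0
    }
    state[near[r2 >= r2Threshold]] <- "discarded"
  }
  initialize(x, snps = df[state == "index", , drop = FALSE] |> resetRows())
}

#' Remove variants associated with known confounders
#'
#' Enforces the MR independence assumption: a variant is dropped when it has
#' at least one annotation to a trait in \code{confounders}
#' (case-insensitive exact match) with \code{pval < pThreshold}. Dropped
#' rsids and the matched traits are reported via \code{message()}.
#'
#' @param x a \code{\link{SumstatsTable}}.
#' @param annotations data.frame with columns rsid, trait, pval (see
#'   \code{\link{readConfounderAnnotations}}).
#' @param confounders trait names to screen; defaults to
#'   \code{\link{confounderTraits}()}.
#' @param pThreshold association p-value below which an annotation
#'   disqualifies the variant (default 5e-8).
#' @return a filtered \code{SumstatsTable}.
#' @export
screenConfounders <- function(x, annotations, confounders = confounderTraits(),
                              pThreshold = 5e-8) {
  stopifnot(is(x, "SumstatsTable"))
  if (is.null(annotations) || !nrow(annotations)) return(x)
  hits <- annotations[tolower(annotations$trait) %in% tolower(confounders) &
                        annotations$pval < pThreshold, , drop = FALSE]
  drop <- x@snps$rsid %in% hits$rsid
  if (any(drop)) {
    dropped <- hits[hits$rsid %in% x@snps$rsid, , drop = FALSE]
    message(sprintf("screenConfounders: dropped %s",
                    paste(sprintf("%s (%s)", dropped$rsid, dropped$trait),
                          collapse = ", ")))
  }
  initialize(x, snps = x@snps[!drop, , drop = FALSE] |> resetRows())
}

#' Select genetic instruments for an exposure
#'
#' Applies the full selection cascade: records with a usable effect-allele
#' frequency, then the genome-wide significance and F-statistic filters,
#' greedy LD clumping, and confounder screening; per-SNP F statistics are
#' attached to the survivors. The per-stage counts (input, eaf_present,
#' p_filter, f_filter, clump, confounder_screen) are recorded in the
#' selection log. Records without an effect-allele frequency are ineligible
#' because the downstream minor-allele-frequency rule could not be applied
#' to them.
#'
#' @param x exposure \code{\link{SumstatsTable}}.
#' @param ld an \code{\link{LdReference}}.
#' @param annotations confounder annotations (data.frame or \code{NULL}).
#' @param config an \code{\link{mrConfig}} list.
#' @return an \code{\link{InstrumentSet}}.
#' @export
selectInstruments <- function(x, ld, annotations = NULL, config = mrConfig()) {
  stopifnot(is(x, "SumstatsTable"))
  nInput <- nSnps(x)
  withEaf <- initialize(x, snps = x@snps[!is.na(x@snps$eaf), , drop = FALSE] |> resetRows())
  pOnly <- initialize(withEaf,
                      snps = withEaf@snps[withEaf@snps$pval < config$pThreshold, ,
                                          drop = FALSE] |> resetRows())
  sig <- filterSignificant(withEaf, config$pThreshold, config$fThreshold)
  clumped <- ldClump(sig, ld, config$clumpR2, config$clumpWindowKb)
  screened <- screenConfounders(clumped, annotations,
                                config$confounderTraits, config$confounderP)
  df <- screened@snps
  df$f_stat <- if (nrow(df)) computeFStatistic(df$beta, df$se) else numeric()
  log <- c(input = nInput, eaf_present = nSnps(withEaf), p_filter = nSnps(pOnly),
           f_filter = nSnps(sig), clump = nSnps(clumped),
           confounder_screen = nrow(df))
  new("InstrumentSet", exposureId = traitId(x), instruments = df,
      selectionLog = as.integer(setNames(log, names(log))) |>
        setNames(names(log)))
}
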