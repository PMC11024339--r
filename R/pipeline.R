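#' Bonferroni-corrected significance threshold
#'
#' The family-wise threshold is alpha divided by the number of exposure
#' factors tested in a direction: 0.05/6 (printed as 0.008) when six
#' exposures are tested forward, 0.05/8 (printed as 0.006) in the reverse
#' direction with eight exposures. Gating uses the exact value; reports
#' print both.
#'
#' @param nExposures number of exposure factors in the direction.
#' @param alpha family-wise significance level (default 0.05).
#' @return the exact threshold alpha / nExposures.
#' @examples
#' bonferroniThreshold(6)   # 0.008333...
#' bonferroniThreshold(8)   # 0.00625
#' @export
bonferroniThreshold <- function(nExposures, alpha = 0.05) {
  if (length(nExposures) != 1L || is.na(nExposures) || nExposures < 1)
    mrStop("nExposures must be a positive count", "domainError")
  alpha / nExposures
}

estimateAll <- function(h, config, pairSeed) {
  res <- list()
  diag <- mrDiagnostics(h)
  ivw <- tryCatch(mrIvw(h, model = "auto"),
                  bidirMRError = function(e) NULL)
  if (is.null(ivw)) return(list(results = res, diagnostics = diag))
  res$ivw <- ivw$result
  eg <- tryCatch(mrEgger(h)$result, bidirMRError = function(e) NULL)
  if (!is.null(eg)) res$egger <- eg
  wm <- tryCatch(mrWeightedMedian(h, nBoot = config$nBoot,
                                  seed = deriveSeed(pairSeed, 1L)),
                 bidirMRError = function(e) NULL)
  if (!is.null(wm)) res$weighted_median <- wm
  pwm <- tryCatch(mrPenalizedWeightedMedian(h, nBoot = config$nBoot,
                                            seed = deriveSeed(pairSeed, 2L)),
                  bidirMRError = function(e) NULL)
  if (!is.null(pwm)) res$penalized_weighted_median <- pwm
  ml <- tryCatch(mrMaxLikelihood(h), bidirMRError = function(e) NULL)
  if (!is.null(ml)) res$max_likelihood <- ml
  list(results = res, diagnostics = diag)
}

#' Analyse one exposure-to-outcome pair
#'
#' Runs the full per-pair cascade: instrument selection, harmonization,
#' iterative MR-PRESSO outlier removal (skipped below four instruments),
#' all five estimators with the Q-driven fixed/random IVW switch,
#' diagnostics, odds-ratio reporting for binary outcomes, and the
#' Bonferroni significance flag. A stage with no surviving instruments
#' marks the pair \code{not_estimable(<stage>)} instead of failing.
#'
#' @param exposure,outcome \code{\link{SumstatsTable}}s.
#' @param ld an \code{\link{LdReference}}.
#' @param annotations confounder annotations (or \code{NULL}).
#' @param config an \code{\link{mrConfig}}.
#' @param direction \code{"forward"} or \code{"reverse"} (labelling only).
#' @param threshold Bonferroni threshold for the significance flag;
#'   defaults to \code{config$alpha} (no correction).
#' @param pairSeed seed for this pair's stochastic steps (PRESSO, median
#'   bootstraps); defaults to \code{config$seed}.
#' @return a \code{\link{PairAnalysis}}.
#' @export
runPair <- function(exposure, outcome, ld, annotations = NULL,
                    config = mrConfig(), direction = "forward",
                    threshold = config$alpha, pairSeed = config$seed) {
  counts <- c(input = nSnps(exposure))
  finish <- function(status, counts, results = list(),
                     diagnostics = new("Diagnostics"), presso = NULL,
                     significant = FALSE) {
    new("PairAnalysis", exposureId = traitId(exposure),
        outcomeId = traitId(outcome), direction = direction,
        stageCounts = setNames(as.integer(counts), names(counts)),
        diagnostics = diagnostics, presso = presso, results = results,
        significant = significant, threshold = threshold, status = status)
  }
  sel <- selectInstruments(exposure, ld, annotations, config)
  counts <- c(counts, selectionLog(sel)[-1])
  if (!nSnps(sel)) return(finish("not_estimable(selection)", counts))
  h <- harmonize(sel, outcome, config$mafMin)
  counts <- c(counts, harmonized = nSnps(h))
  if (!nSnps(h)) return(finish("not_estimable(harmonization)", counts))
  presso <- NULL
  if (nSnps(h) >= 4L) {
    pf <- pressoFilter(h, nSim = config$pressoNSim,
                       significance = config$pressoSig,
                       seed = deriveSeed(pairSeed, 17L),
                       maxRounds = config$pressoMaxRounds)
    h <- pf$h
    presso <- pf$presso
  } else {
    message(sprintf("runPair %s -> %s: MR-PRESSO skipped (fewer than 4 instruments)",
                    traitId(exposure), traitId(outcome)))
  }
  counts <- c(counts, presso_kept = nSnps(h))
  est <- estimateAll(h, config, pairSeed)
  if (is.null(est$results$ivw))
    return(finish("not_estimable(estimation)", counts, presso = presso,
                  diagnostics = est$diagnostics))
  significant <- mrPval(est$results$ivw) < threshold
  results <- est$results
  if (traitType(outcome) == "binary")
    results <- lapply(results, toOddsRatio, outcomeType = "binary")
  finish("ok", counts, results = results, diagnostics = est$diagnostics,
         presso = presso, significant = significant)
}

#' Run the full bi-directional analysis grid
#'
#' Forward direction analyses every exposure-outcome product; the reverse
#' direction swaps the roles. Each direction applies its own Bonferroni
#' threshold, alpha divided by that direction's exposure count. Pairs are
#' processed in sorted (direction, exposure, outcome) order and every
#' pair's randomness derives deterministically from the master seed, so a
#' rerun with the same inputs is bit-identical.
#'
#' @param exposures,outcomes lists of \code{\link{SumstatsTable}}s.
#' @param ld an \code{\link{LdReference}} covering all tables.
#' @param annotations confounder annotations (or \code{NULL}).
#' @param config an \code{\link{mrConfig}}; \code{config$seed} is the
#'   master seed.
#' @param outDir optional directory; when given, writes
#'   \code{results.tsv} (the long-format table) and \code{manifest.json}.
#' @return list with \code{pairs} (list of \code{\link{PairAnalysis}}),
#'   \code{table} (long-format results, see
#'   \code{\link{pairResultsTable}}) and \code{manifest}.
#' @export
runBidirectional <- function(exposures, outcomes, ld, annotations = NULL,
                             config = mrConfig(), outDir = NULL) {
  ids <- function(lst) vapply(lst, traitId, "")
  exposures <- exposures[order(ids(exposures))]
  outcomes <- outcomes[order(ids(outcomes))]
  thrFwd <- bonferroniThreshold(length(exposures), config$alpha)
  thrRev <- bonferroniThreshold(length(outcomes), config$alpha)
  pairs <- list()
  idx <- 0L
  for (e in exposures) for (o in outcomes) {
    idx <- idx + 1L
    pairs[[idx]] <- runPair(e, o, ld, annotations, config,
                            direction = "forward", threshold = thrFwd,
                            pairSeed = deriveSeed(config$seed, idx))
  }
  for (e in outcomes) for (o in exposures) {
    idx <- idx + 1L
    pairs[[idx]] <- runPair(e, o, ld, annotations, config,
                            direction = "reverse", threshold = thrRev,
                            pairSeed = deriveSeed(config$seed, idx))
  }
  table <- pairResultsTable(pairs)
  manifest <- list(
    package = "bidirMR",
    version = as.character(utils::packageVersion("bidirMR")),
    seed = config$seed,
    n_exposures = length(exposures), n_outcomes = length(outcomes),
    forward_threshold = thrFwd, reverse_threshold = thrRev,
    forward_threshold_printed = round(thrFwd, 3),
    reverse_threshold_printed = round(thrRev, 3),
    config = unclass(config)[setdiff(names(config), "confounderTraits")],
    presso_distortion_test = "omitted: detection/removal only")
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    write.table(table, file.path(outDir, "results.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(pairs = pairs, table = table, manifest = manifest)
}

#' Long-format results table
#'
#' One row per pair and method, mirroring the usual MR report layout:
#' direction, exposure, outcome, number of instruments, Cochran's Q and its
#' p, the Egger intercept p, method, IVW model, effect scale, estimate with
#' 95 percent CI, p-value, the pair's Bonferroni threshold (exact and at
#' printed precision), significance flag and status. Pairs that were not
#' estimable contribute a single row with their status.
#'
#' @param pairs list of \code{\link{PairAnalysis}} objects.
#' @return a data.frame.
#' @export
pairResultsTable <- function(pairs) {
  rows <- lapply(pairs, function(p) {
    base <- data.frame(direction = p@direction, exposure = p@exposureId,
                       outcome = p@outcomeId,
                       n_ivs = if ("presso_kept" %in% names(p@stageCounts))
                         p@stageCounts[["presso_kept"]] else 0L,
                       cochran_q = p@diagnostics@cochranQ,
                       q_pval = p@diagnostics@qPval,
                       egger_intercept = p@diagnostics@eggerIntercept,
                       egger_intercept_pval = p@diagnostics@interceptPval,
                       threshold = p@threshold,
                       threshold_printed = round(p@threshold, 3),
                       significant = p@significant, status = p@status,
                       stringsAsFactors = FALSE)
    if (!length(p@results)) {
      base$method <- NA_character_; base$ivw_model <- NA_character_
      base$effect_scale <- NA_character_; base$estimate <- NA_real_
      base$ci_low <- NA_real_; base$ci_high <- NA_real_
      base$pval <- NA_real_
      return(base)
    }
    do.call(rbind, lapply(p@results, function(r) {
      out <- base
      out$method <- r@method
      out$ivw_model <- r@ivwModel
      out$effect_scale <- r@effectScale
      out$estimate <- r@beta
      out$ci_low <- r@ciLow
      out$ci_high <- r@ciHigh
      out$pval <- r@pval
      out
    }))
  })
  resetRows(do.call(rbind, rows))
}
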