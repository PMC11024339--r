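## classed conditions so callers and the pipeline can branch on failure kind
mrStop <- function(msg, class) {
  stop(structure(class = c(class, "bidirMRError", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

## run expr under a local RNG seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## deterministic per-task seed derived from a master seed, kept < 2^31
deriveSeed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 104729) %%
               2147483647)
}

## two-sided normal p, floored away from 0 to respect the (0, 1] contract
twoSidedNormalP <- function(z) {
  pmax(2 * pnorm(-abs(z)), .Machine$double.xmin)
}

Z95 <- 1.959964

resetRows <- function(df) {
  rownames(df) <- NULL
  df
}

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

#' Confounder traits screened during instrument selection
#'
#' The default trait names treated as potential confounders of the
#' autoimmune-disease / sarcopenia relationship: smoking, body mass index,
#' physical inactivity, malnutrition and extreme sleep duration. Matching in
#' \code{\link{screenConfounders}} is case-insensitive.
#'
#' @return character vector of trait names.
#' @export
confounderTraits <- function() {
  c("smoking", "body mass index", "physical inactivity", "malnutrition",
    "extreme sleep duration")
}

#' Analysis configuration
#'
#' Bundles every tunable threshold of the pipeline with the defaults used
#' throughout: genome-wide significance 5e-8, instrument-strength F > 10,
#' clumping at r-squared < 0.001 within a 1000 kb window, confounder
#' screening at 5e-8, minor-allele-frequency floor 0.01, 1000 bootstrap
#' draws for median-based standard errors, MR-PRESSO with 1000 simulations
#' at significance 0.05 and at most 10 removal rounds, and family-wise
#' alpha 0.05 for the Bonferroni gate.
#'
#' @param pThreshold exposure-association p-value ceiling for instruments.
#' @param fThreshold minimum F statistic (strict).
#' @param clumpR2 r-squared ceiling for LD clumping (strict >= discards).
#' @param clumpWindowKb clump window half-width in kilobases.
#' @param confounderTraits trait names screened as confounders.
#' @param confounderP p-value below which a confounder annotation disqualifies
#'   a variant.
#' @param mafMin minor-allele-frequency floor (strict: maf must exceed it).
#' @param nBoot parametric-bootstrap draws for median estimators.
#' @param pressoNSim MR-PRESSO Monte-Carlo simulation count.
#' @param pressoSig MR-PRESSO outlier significance level.
#' @param pressoMaxRounds cap on iterative outlier-removal rounds.
#' @param alpha family-wise significance level before Bonferroni division.
#' @param seed master seed; all per-pair randomness derives from it.
#' @return a list with class \code{MrConfig}.
#' @export
mrConfig <- function(pThreshold = 5e-8, fThreshold = 10, clumpR2 = 0.001,
                     clumpWindowKb = 1000,
                     confounderTraits = NULL,
                     confounderP = 5e-8, mafMin = 0.01, nBoot = 1000,
                     pressoNSim = 1000, pressoSig = 0.05,
                     pressoMaxRounds = 10, alpha = 0.05, seed = 1) {
  stopifnot(pThreshold > 0, pThreshold <= 1, fThreshold >= 0, mafMin >= 0,
            nBoot >= 1, pressoNSim >= 1, alpha > 0, alpha <= 1)
  if (clumpR2 <= 0 || clumpR2 > 1)
    mrStop("clumpR2 must lie in (0, 1]", "configError")
  if (clumpWindowKb <= 0)
    mrStop("clumpWindowKb must be positive", "configError")
  if (is.null(confounderTraits))
    confounderTraits <- confounderTraits()
  structure(list(pThreshold = pThreshold, fThreshold = fThreshold,
                 clumpR2 = clumpR2, clumpWindowKb = clumpWindowKb,
                 confounderTraits = confounderTraits,
                 confounderP = confounderP, mafMin = mafMin, nBoot = nBoot,
                 pressoNSim = pressoNSim, pressoSig = pressoSig,
                 pressoMaxRounds = pressoMaxRounds, alpha = alpha,
                 seed = as.integer(seed)),
            class = "MrConfig")
}
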