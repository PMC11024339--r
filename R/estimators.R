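## ---- per-SNP ratio estimates ------------------------------------------

#' Per-SNP Wald ratios
#'
#' For each aligned variant the single-SNP causal estimate is
#' ratio_j = beta_out_j / beta_exp_j with first-order standard error
#' se_j = se_out_j / |beta_exp_j|; the inverse-variance weight is
#' w_j = 1 / se_j^2 = beta_exp_j^2 / se_out_j^2. Variants with
#' beta_exp = 0 are dropped with a warning (their ratio is undefined).
#'
#' @param h a \code{\link{HarmonizedSet}} with at least one pair.
#' @return data.frame with columns rsid, ratio, se, w.
#' @export
waldRatios <- function(h) {
  stopifnot(is(h, "HarmonizedSet"))
  p <- h@pairs
  if (!nrow(p)) mrStop("no harmonized pairs", "insufficientInstruments")
  zero <- p$beta_exp == 0
  if (any(zero)) {
    warning(sprintf("waldRatios: dropping %d variant(s) with beta_exp = 0",
                    sum(zero)))
    p <- p[!zero, , drop = FALSE]
  }
  data.frame(rsid = p$rsid, ratio = p$beta_out / p$beta_exp,
             se = p$se_out / abs(p$beta_exp),
             w = p$beta_exp^2 / p$se_out^2, stringsAsFactors = FALSE)
}

makeResult <- function(method, k, beta, se, pval = NULL,
                       ivwModel = NA_character_) {
  if (is.null(pval)) pval <- twoSidedNormalP(beta / se)
  new("MrResult", method = method, nSnp = as.integer(k), beta = beta,
      se = se, ciLow = beta - Z95 * se, ciHigh = beta + Z95 * se,
      pval = pval, effectScale = "beta", ivwModel = ivwModel)
}

ratioFrame <- function(h, min_k, method) {
  r <- waldRatios(h)
  if (nrow(r) < min_k)
    mrStop(sprintf("%s requires at least %d instruments, have %d",
                   method, min_k, nrow(r)), "insufficientInstruments")
  r
}

## ---- inverse-variance weighted ----------------------------------------

#' Inverse-variance-weighted causal estimate
#'
#' The primary estimator: the IVW estimate is the inverse-variance-weighted
#' mean of the per-SNP Wald ratios, equivalently the weighted regression of
#' beta_out on beta_exp through the origin with weights 1/se_out^2.
#' Heterogeneity is measured by Cochran's Q = sum w_j (ratio_j - beta)^2 on
#' k - 1 degrees of freedom. Under \code{model = "auto"} the fixed-effect
#' standard error sqrt(1 / sum w_j) is used when the Q p-value is at least
#' 0.05; otherwise the multiplicative random-effects standard error
#' (fixed SE scaled by max(1, sqrt(Q / (k - 1)))) is used. Inference is
#' two-sided normal with a 95 percent interval at z = 1.959964.
#'
#' @param h a \code{\link{HarmonizedSet}} with at least two pairs.
#' @param model \code{"auto"} (Q-driven switch), \code{"fixed"} or
#'   \code{"random"}.
#' @return list with elements \code{result} (an \code{\link{MrResult}},
#'   with \code{ivwModel} recording the model used) and \code{diagnostics}
#'   (a \code{\link{Diagnostics}} carrying the Cochran's Q fields).
#' @export
mrIvw <- function(h, model = c("auto", "fixed", "random")) {
  model <- match.arg(model)
  r <- ratioFrame(h, 2L, "ivw")
  k <- nrow(r)
  beta <- sum(r$w * r$ratio) / sum(r$w)
  seFixed <- sqrt(1 / sum(r$w))
  q <- sum(r$w * (r$ratio - beta)^2)
  qDf <- k - 1
  qPval <- pchisq(q, df = qDf, lower.tail = FALSE)
  used <- switch(model,
                 fixed = "fixed",
                 random = "random",
                 auto = if (qPval < 0.05) "random" else "fixed")
  se <- if (used == "random") seFixed * max(1, sqrt(q / qDf)) else seFixed
  list(result = makeResult("ivw", k, beta, se, ivwModel = used),
       diagnostics = new("Diagnostics", cochranQ = q, qDf = as.numeric(qDf),
                         qPval = qPval))
}

## ---- MR-Egger ----------------------------------------------------------

#' MR-Egger regression
#'
#' Weighted linear regression of beta_out on beta_exp with a free intercept
#' and weights 1/se_out^2, after orienting every variant so beta_exp >= 0
#' (both betas are negated where needed; the fit is invariant to allele
#' coding only in this orientation). The slope is the causal estimate; a
#' non-zero intercept indicates directional horizontal pleiotropy. Standard
#' errors use the multiplicative residual scale max(1, sqrt(RSS_w/(k-2)))
#' and p-values come from a t distribution on k - 2 degrees of freedom.
#'
#' @param h a \code{\link{HarmonizedSet}} with at least three pairs.
#' @return list with \code{result} (slope as an \code{\link{MrResult}}) and
#'   \code{diagnostics} (a \code{\link{Diagnostics}} carrying the intercept
#'   fields).
#' @export
mrEgger <- function(h) {
  p <- h@pairs[h@pairs$beta_exp != 0, , drop = FALSE]
  if (nrow(p) < 3L)
    mrStop("MR-Egger requires at least 3 instruments",
           "insufficientInstruments")
  k <- nrow(p)
  flip <- sign(p$beta_exp)
  x <- p$beta_exp * flip
  y <- p$beta_out * flip
  w <- 1 / p$se_out^2
  fit <- lm(y ~ x, weights = w)
  sm <- summary(fit)
  phi <- max(1, sm$sigma)
  seU <- sqrt(diag(sm$cov.unscaled))  # (X' W X)^{-1}, unscaled
  est <- coef(fit)
  se <- seU * phi
  pv <- pmax(2 * pt(-abs(est / se), df = k - 2), .Machine$double.xmin)
  list(result = makeResult("egger", k, unname(est[2]), unname(se[2]),
                           pval = unname(pv[2])),
       diagnostics = new("Diagnostics", eggerIntercept = unname(est[1]),
                         interceptSe = unname(se[1]),
                         interceptPval = unname(pv[1])))
}

## ---- weighted median ---------------------------------------------------

## weighted median by linear interpolation of the cumulative-midpoint grid
weightedMedianEstimate <- function(ratio, w) {
  if (all(w == 0)) mrStop("all weights are zero", "degenerateWeights")
  ord <- order(ratio)
  ratio <- ratio[ord]
  wn <- w[ord] / sum(w)
  p <- cumsum(wn) - wn / 2
  hit <- which(abs(p - 0.5) < 1e-12)
  if (length(hit)) return(mean(ratio[hit]))
  if (p[1] > 0.5) return(ratio[1])
  j <- max(which(p < 0.5))
  if (j == length(ratio)) return(ratio[j])
  ratio[j] + (ratio[j + 1] - ratio[j]) * (0.5 - p[j]) / (p[j + 1] - p[j])
}

## parametric bootstrap over the observed effect sizes; estimator is a
## function(ratio, w) applied to each resampled draw
bootstrapSe <- function(h, estimator, nBoot, seed) {
  p <- h@pairs[h@pairs$beta_exp != 0, , drop = FALSE]
  k <- nrow(p)
  withSeed(seed, {
    be <- p$beta_exp + p$se_exp * matrix(rnorm(k * nBoot), k)
    bo <- p$beta_out + p$se_out * matrix(rnorm(k * nBoot), k)
    est <- numeric(nBoot)
    for (b in seq_len(nBoot)) {
      ratio <- bo[, b] / be[, b]
      w <- be[, b]^2 / p$se_out^2
      est[b] <- estimator(ratio, w)
    }
    sd(est)
  })
}

#' Weighted-median causal estimate
#'
#' The weighted median of the per-SNP Wald ratios: consistent as long as
#' valid instruments carry at least half of the total weight. Ratios are
#' sorted and the estimate interpolated where the cumulative weight
#' midpoint crosses one half. The standard error is a parametric bootstrap:
#' exposure and outcome effects are resampled from normal distributions
#' centred on the observed values with their reported standard errors, the
#' weighted median recomputed each draw, and the standard deviation over
#' draws taken. Inference is two-sided normal.
#'
#' @param h a \code{\link{HarmonizedSet}} with at least three pairs.
#' @param nBoot bootstrap draws (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return an \code{\link{MrResult}}.
#' @export
mrWeightedMedian <- function(h, nBoot = 1000, seed = 1) {
  r <- ratioFrame(h, 3L, "weighted_median")
  beta <- weightedMedianEstimate(r$ratio, r$w)
  se <- bootstrapSe(h, weightedMedianEstimate, nBoot, seed)
  makeResult("weighted_median", nrow(r), beta, se)
}

penalizedEstimate <- function(penaltyK) {
  function(ratio, w) {
    theta0 <- weightedMedianEstimate(ratio, w)
    q <- w * (ratio - theta0)^2
    pj <- pchisq(q, df = 1, lower.tail = FALSE)
    wStar <- w * pmin(1, penaltyK * pj)
    if (all(wStar == 0))
      mrStop("penalization removed all weight", "degenerateWeights")
    weightedMedianEstimate(ratio, wStar)
  }
}

#' Penalized weighted-median causal estimate
#'
#' Downweights heterogeneous variants before taking the weighted median:
#' from an initial weighted-median estimate, each variant's contribution to
#' heterogeneity q_j = w_j (ratio_j - theta)^2 is converted to an upper
#' chi-square(1) tail probability p_j, the weight multiplied by
#' min(1, penaltyK * p_j), and the weighted median recomputed. The
#' bootstrap standard error applies the whole penalized procedure to each
#' resampled draw.
#'
#' @inheritParams mrWeightedMedian
#' @param penaltyK penalization constant (default 20); 0 removes all
#'   weight and raises a degenerate-weights error.
#' @return an \code{\link{MrResult}}.
#' @export
mrPenalizedWeightedMedian <- function(h, penaltyK = 20, nBoot = 1000,
                                      seed = 1) {
  r <- ratioFrame(h, 3L, "penalized_weighted_median")
  est <- penalizedEstimate(penaltyK)
  beta <- est(r$ratio, r$w)
  se <- bootstrapSe(h, est, nBoot, seed)
  makeResult("penalized_weighted_median", nrow(r), beta, se)
}

## ---- profile maximum likelihood ----------------------------------------

#' Profile maximum-likelihood causal estimate
#'
#' Models measurement error on both sides: the causal effect minimizes
#' L(theta) = sum_j (beta_out_j - theta * beta_exp_j)^2 /
#' (se_out_j^2 + theta^2 * se_exp_j^2), the profile objective of the
#' bivariate normal likelihood after profiling out the true exposure
#' effects. Solved by bounded one-dimensional minimization bracketed
#' around the IVW estimate; the standard error comes from the curvature of
#' L/2 at the optimum, evaluated by central differences. In the limit of
#' vanishing exposure-side standard errors the estimate coincides with the
#' fixed-effect IVW estimate.
#'
#' @param h a \code{\link{HarmonizedSet}} with at least two pairs.
#' @return an \code{\link{MrResult}}.
#' @export
mrMaxLikelihood <- function(h) {
  r <- ratioFrame(h, 2L, "max_likelihood")
  p <- h@pairs[h@pairs$beta_exp != 0, , drop = FALSE]
  k <- nrow(p)
  objective <- function(theta) {
    sum((p$beta_out - theta * p$beta_exp)^2 /
          (p$se_out^2 + theta^2 * p$se_exp^2))
  }
  ivw0 <- sum(r$w * r$ratio) / sum(r$w)
  half <- 10 * max(abs(ivw0), 0.1)
  opt <- optimize(objective, interval = c(ivw0 - half, ivw0 + half),
                  tol = 1e-10)
  theta <- opt$minimum
  if (min(theta - (ivw0 - half), (ivw0 + half) - theta) < 1e-6 * half)
    mrStop("profile-likelihood optimum hit the search bracket",
           "estimationFailure")
  step <- 1e-5 * max(1, abs(theta))
  curv <- (objective(theta + step) - 2 * objective(theta) +
             objective(theta - step)) / (2 * step^2)  # d2 (L/2) / dtheta2
  if (!is.finite(curv) || curv <= 0)
    mrStop("non-positive curvature at the profile-likelihood optimum",
           "estimationFailure")
  makeResult("max_likelihood", k, theta, sqrt(1 / curv))
}

## ---- reporting helpers -------------------------------------------------

#' Report an estimate as an odds ratio
#'
#' For binary outcomes the causal estimate is a log odds ratio; this
#' exponentiates the estimate and its confidence bounds (the p-value and
#' the log-scale standard error are unchanged) and marks the effect scale
#' as \code{"or"}.
#'
#' @param r an \code{\link{MrResult}} on the beta scale.
#' @param outcomeType trait type of the outcome; applying the transform to
#'   a continuous outcome is a contract violation.
#' @return an \code{\link{MrResult}} on the odds-ratio scale.
#' @export
toOddsRatio <- function(r, outcomeType = "binary") {
  stopifnot(is(r, "MrResult"))
  if (!identical(outcomeType, "binary"))
    mrStop("odds ratios are only defined for binary outcomes",
           "contractViolation")
  if (r@effectScale == "or") return(r)
  initialize(r, beta = exp(r@beta), ciLow = exp(r@ciLow),
             ciHigh = exp(r@ciHigh), effectScale = "or")
}

#' Heterogeneity and pleiotropy diagnostics
#'
#' Convenience wrapper combining the Cochran's Q fields from the IVW fit
#' with the MR-Egger intercept fields into a single
#' \code{\link{Diagnostics}} object. Fields whose estimator is not
#' estimable (too few instruments) are left \code{NA}.
#'
#' @param h a \code{\link{HarmonizedSet}}.
#' @return a \code{\link{Diagnostics}}.
#' @export
mrDiagnostics <- function(h) {
  qd <- tryCatch(mrIvw(h)$diagnostics, bidirMRError = function(e) NULL)
  ed <- tryCatch(mrEgger(h)$diagnostics, bidirMRError = function(e) NULL)
  new("Diagnostics",
      cochranQ = if (is.null(qd)) NA_real_ else qd@cochranQ,
      qDf = if (is.null(qd)) NA_real_ else qd@qDf,
      qPval = if (is.null(qd)) NA_real_ else qd@qPval,
      eggerIntercept = if (is.null(ed)) NA_real_ else ed@eggerIntercept,
      interceptSe = if (is.null(ed)) NA_real_ else ed@interceptSe,
      interceptPval = if (is.null(ed)) NA_real_ else ed@interceptPval)
}
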