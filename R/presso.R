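## leave-one-out IVW slopes (origin regression, weights 1/se_out^2),
## computed for every j in O(k) from the full sums
looSlopes <- function(x, y, w) {
  sxy <- sum(w * x * y)
  sxx <- sum(w * x^2)
  (sxy - w * x * y) / (sxx - w * x^2)
}

#' MR-PRESSO global heterogeneity and outlier test
#'
#' Monte-Carlo residual-sum-of-squares test for horizontal pleiotropy. For
#' each variant j the IVW slope is refitted leaving j out, and the observed
#' weighted residual r_j = (beta_out_j - slope_(-j) * beta_exp_j)^2 /
#' se_out_j^2 computed; RSS_obs is their sum. In each of \code{nSim}
#' simulations all exposure effects are redrawn from
#' Normal(beta_exp_j, se_exp_j) and outcome effects from the no-pleiotropy
#' expectation Normal(slope_(-j) * beta_exp_j, se_out_j), and the RSS
#' recomputed with fresh leave-one-out slopes. The global p-value is the
#' +1-corrected exceedance fraction (so it is never below 1/(nSim+1));
#' per-variant Monte-Carlo p-values are Bonferroni-multiplied by k, capped
#' at 1, and variants below \code{significance} are flagged as outliers.
#' The same seed always yields a bit-identical result.
#'
#' @param h a \code{\link{HarmonizedSet}} with at least four pairs (fewer
#'   leaves too little support for stable leave-one-out slopes).
#' @param nSim Monte-Carlo simulation count (default 1000).
#' @param significance adjusted-p threshold for flagging (default 0.05).
#' @param seed RNG seed.
#' @return a \code{\link{PressoResult}}.
#' @export
pressoTest <- function(h, nSim = 1000, significance = 0.05, seed = 1) {
  stopifnot(is(h, "HarmonizedSet"))
  p <- h@pairs[h@pairs$beta_exp != 0, , drop = FALSE]
  k <- nrow(p)
  if (k < 4L)
    mrStop("MR-PRESSO requires at least 4 instruments",
           "insufficientInstruments")
  w <- 1 / p$se_out^2
  loo <- looSlopes(p$beta_exp, p$beta_out, w)
  rObs <- w * (p$beta_out - loo * p$beta_exp)^2
  rssObs <- sum(rObs)
  withSeed(seed, {
    be <- p$beta_exp + p$se_exp * matrix(rnorm(k * nSim), k)
    bo <- loo * p$beta_exp + p$se_out * matrix(rnorm(k * nSim), k)
    sxy <- colSums(w * be * bo)
    sxx <- colSums(w * be^2)
    looSim <- (rep(sxy, each = k) - w * be * bo) /
      (rep(sxx, each = k) - w * be^2)
    rSim <- w * (bo - looSim * be)^2
    rssSim <- colSums(rSim)
    globalP <- (1 + sum(rssSim >= rssObs)) / (nSim + 1)
    perSnpP <- (1 + rowSums(rSim >= rObs)) / (nSim + 1)
    adj <- pmin(1, perSnpP * k)
    names(adj) <- p$rsid
    new("PressoResult", rssObs = rssObs, globalPval = globalP,
        outlierPvals = adj, outliers = p$rsid[adj < significance],
        nSim = as.integer(nSim), seed = as.integer(seed))
  })
}

#' Remove MR-PRESSO outliers from a harmonized set
#'
#' Drops the variants flagged by \code{\link{pressoTest}} and extends the
#' drop log with reason \code{presso_outlier}. With no flagged outliers the
#' set is returned unchanged.
#'
#' @param h the \code{\link{HarmonizedSet}} the test was computed on.
#' @param p a \code{\link{PressoResult}}.
#' @return a \code{\link{HarmonizedSet}}.
#' @export
removeOutliers <- function(h, p) {
  stopifnot(is(h, "HarmonizedSet"), is(p, "PressoResult"))
  if (!length(p@outliers)) return(h)
  drop <- h@pairs$rsid %in% p@outliers
  newLog <- rbind(h@dropLog,
                  data.frame(rsid = h@pairs$rsid[drop],
                             reason = "presso_outlier"))
  initialize(h, pairs = resetRows(h@pairs[!drop, , drop = FALSE]),
             dropLog = resetRows(newLog))
}

#' Iterative MR-PRESSO outlier removal
#'
#' Re-runs the outlier test on the reduced set until no variant is flagged,
#' fewer than four variants remain, or \code{maxRounds} rounds have run.
#' Each round derives its own seed from \code{seed} so the whole procedure
#' is deterministic.
#'
#' @inheritParams pressoTest
#' @param maxRounds hard cap on removal rounds (default 10).
#' @return list with \code{h} (the reduced \code{\link{HarmonizedSet}}),
#'   \code{presso} (the final \code{\link{PressoResult}}, or \code{NULL}
#'   when the test was never runnable), \code{removed} (rsids dropped) and
#'   \code{rounds} (tests run).
#' @export
pressoFilter <- function(h, nSim = 1000, significance = 0.05, seed = 1,
                         maxRounds = 10) {
  removed <- character()
  last <- NULL
  rounds <- 0L
  repeat {
    if (nrow(h@pairs) < 4L || rounds >= maxRounds) break
    res <- pressoTest(h, nSim = nSim, significance = significance,
                      seed = deriveSeed(seed, rounds))
    rounds <- rounds + 1L
    last <- res
    if (!length(res@outliers)) break
    removed <- c(removed, res@outliers)
    h <- removeOutliers(h, res)
  }
  list(h = h, presso = last, removed = removed, rounds = rounds)
}
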