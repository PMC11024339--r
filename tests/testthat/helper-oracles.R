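## Independent brute-force oracles used to check the estimators and the
## clumping algorithm; deliberately different code paths from the package.

## weighted regression through the origin (IVW equivalent form)
oracleWlsOrigin <- function(x, y, w) {
  beta <- sum(w * x * y) / sum(w * x^2)
  list(beta = beta, se = sqrt(1 / sum(w * x^2)),
       q = sum(w * (y - beta * x)^2))
}

## weighted normal equations with intercept, MR-Egger orientation applied
oracleEgger <- function(x, y, w) {
  s <- sign(x); s[s == 0] <- 1
  x <- x * s; y <- y * s
  X <- cbind(1, x)
  A <- t(X) %*% (w * X)
  est <- solve(A, t(X) %*% (w * y))
  fit <- X %*% est
  rss <- sum(w * (y - fit)^2)
  k <- length(x)
  phi <- max(1, sqrt(rss / (k - 2)))
  se <- sqrt(diag(solve(A))) * phi
  list(intercept = unname(est[1]), slope = unname(est[2]),
       seIntercept = unname(se[1]), seSlope = unname(se[2]))
}

## weighted median via stats::approx on the cumulative-midpoint grid
oracleWeightedMedian <- function(ratio, w) {
  ord <- order(ratio)
  ratio <- ratio[ord]
  wn <- w[ord] / sum(w)
  p <- cumsum(wn) - wn / 2
  if (0.5 <= p[1]) return(ratio[1])
  if (0.5 >= p[length(p)]) return(ratio[length(p)])
  stats::approx(p, ratio, xout = 0.5, ties = "ordered")$y
}

## brute-force greedy clump enumerating every discard decision
oracleClump <- function(df, r2fun, r2Threshold, windowKb) {
  remaining <- df
  kept <- character()
  while (nrow(remaining)) {
    ord <- order(remaining$pval, remaining$chrom, remaining$pos)
    idx <- remaining[ord[1], ]
    kept <- c(kept, idx$rsid)
    drop <- vapply(seq_len(nrow(remaining)), function(i) {
      r <- remaining[i, ]
      if (r$rsid == idx$rsid) return(TRUE)
      if (r$chrom != idx$chrom) return(FALSE)
      if (abs(r$pos - idx$pos) > windowKb * 1000) return(FALSE)
      r2fun(idx$rsid, r$rsid) >= r2Threshold
    }, TRUE)
    remaining <- remaining[!drop, , drop = FALSE]
  }
  kept
}

## random valid summary-statistic data.frame (not via the simulator)
randomSnpFrame <- function(n, seed) {
  set.seed(seed)
  alleles <- c("A", "C", "G", "T")
  ea <- sample(alleles, n, replace = TRUE)
  oa <- vapply(ea, function(a) sample(setdiff(alleles, a), 1), "")
  data.frame(rsid = sprintf("rs%d", seq_len(n)),
             chrom = as.character(sample(1:22, n, replace = TRUE)),
             pos = sample.int(5e7, n), effect_allele = ea,
             other_allele = unname(oa), eaf = runif(n, 0.01, 0.99),
             beta = rnorm(n, 0, 0.1), se = runif(n, 0.001, 0.05),
             pval = runif(n), n = 10000, stringsAsFactors = FALSE)
}

## random harmonized set for estimator checks
randomHarmonized <- function(k, seed, theta = 0.2) {
  set.seed(seed)
  se_exp <- runif(k, 0.005, 0.03)
  se_out <- runif(k, 0.005, 0.03)
  gamma <- rnorm(k, 0, 0.15)
  gamma <- gamma + sign(gamma) * 0.05   # keep beta_exp away from 0
  pairs <- data.frame(rsid = sprintf("rs%d", seq_len(k)),
                      beta_exp = gamma + rnorm(k, 0, se_exp),
                      se_exp = se_exp,
                      beta_out = theta * gamma + rnorm(k, 0, se_out),
                      se_out = se_out, eaf_exp = runif(k, 0.1, 0.9),
                      eaf_out = runif(k, 0.1, 0.9), action = "kept_as_is",
                      stringsAsFactors = FALSE)
  new("HarmonizedSet", exposureId = "E", outcomeId = "O",
      outcomeType = "continuous", pairs = pairs,
      dropLog = data.frame(rsid = character(), reason = character()))
}

## harmonized set with explicit per-SNP ratios and ratio-scale SEs
harmonizedFromRatios <- function(ratio, ratioSe, beta_exp = NULL) {
  k <- length(ratio)
  if (is.null(beta_exp)) beta_exp <- rep(1, k)
  pairs <- data.frame(rsid = sprintf("rs%d", seq_len(k)),
                      beta_exp = beta_exp, se_exp = rep(1e-8, k),
                      beta_out = ratio * beta_exp,
                      se_out = ratioSe * abs(beta_exp),
                      eaf_exp = 0.5, eaf_out = 0.5, action = "kept_as_is",
                      stringsAsFactors = FALSE)
  new("HarmonizedSet", exposureId = "E", outcomeId = "O",
      outcomeType = "continuous", pairs = pairs,
      dropLog = data.frame(rsid = character(), reason = character()))
}

## treat every record of a simulated exposure table as an instrument
makeInstruments <- function(tab) {
  df <- snps(tab)
  df$f_stat <- (df$beta / df$se)^2
  n <- nrow(df)
  log <- setNames(rep(n, 6L),
                  c("input", "eaf_present", "p_filter", "f_filter",
                    "clump", "confounder_screen"))
  new("InstrumentSet", exposureId = traitId(tab), instruments = df,
      selectionLog = setNames(as.integer(log), names(log)))
}

harmonizeSim <- function(sim, mafMin = 0.01) {
  harmonize(makeInstruments(sim$exposure), sim$outcome, mafMin = mafMin)
}
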