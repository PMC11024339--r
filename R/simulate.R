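#' Configuration for the synthetic GWAS summary-statistic generator
#'
#' Describes one exposure/outcome pair of GWAS summary-statistic tables
#' with known ground truth. Instruments carry true exposure effects
#' gamma_j ~ Normal(0, \code{gammaSd}); the observed exposure effect is
#' gamma_j plus sampling noise at the per-SNP standard error, redrawn until
#' the observed association passes genome-wide significance so that every
#' labelled instrument passes the selection filter by construction. Outcome
#' effects are theta * gamma_j plus a direct (pleiotropic) effect alpha_j
#' plus sampling noise.
#'
#' Pleiotropy models (\code{pleiotropy$type}):
#' \describe{
#'   \item{none}{alpha_j = 0.}
#'   \item{balanced}{alpha_j ~ Normal(0, \code{sd}) on a fraction
#'     \code{frac} of instruments.}
#'   \item{directional}{alpha_j = sign(gamma_j) * Normal(\code{mean},
#'     \code{sd}) on a fraction \code{frac}: the direct effects share a
#'     direction relative to the exposure-increasing allele, the scenario
#'     that biases IVW.}
#'   \item{outlier}{\code{count} designated instruments get a direct effect
#'     of magnitude \code{effect}, sign-aligned with gamma_j.}
#' }
#'
#' @param nSnp total variants in each table.
#' @param nInstrument variants with true exposure effects.
#' @param theta true causal effect of exposure on outcome.
#' @param gammaSd standard deviation of true instrument effects.
#' @param seExpRange,seOutRange uniform sampling intervals for per-SNP
#'   standard errors on the exposure and outcome side.
#' @param pleiotropy list describing the direct-effect model (see above).
#' @param mafRange uniform sampling interval for minor-allele frequencies,
#'   within (0, 0.5].
#' @param fracPalindromic fraction of variants given A/T or C/G alleles.
#' @param fracStrandFlipped fraction of outcome records reported on the
#'   opposite strand (alleles complemented).
#' @param ldBlocks list of length-2 vectors \code{c(size, r)}: consecutive
#'   variants grouped into LD blocks with within-block latent correlation
#'   \code{r}; variants not covered are independent singletons.
#' @param nConfounderSnps variants that are genome-wide significant for the
#'   exposure but act through a confounder; they receive a confounder
#'   annotation and a direct outcome effect.
#' @param seed integer seed; all generator output is bit-reproducible given
#'   the configuration.
#' @return a list with class \code{SimulationConfig}.
#' @export
simulationConfig <- function(nSnp = 200, nInstrument = 30, theta = 0,
                             gammaSd = 0.1, seExpRange = c(0.005, 0.015),
                             seOutRange = c(0.01, 0.02),
                             pleiotropy = list(type = "none"),
                             mafRange = c(0.05, 0.5),
                             fracPalindromic = 0.1,
                             fracStrandFlipped = 0.05, ldBlocks = NULL,
                             nConfounderSnps = 0, seed = 1) {
  stopifnot(nInstrument >= 0, nSnp >= nInstrument + nConfounderSnps,
            fracPalindromic >= 0, fracPalindromic <= 1,
            fracStrandFlipped >= 0, fracStrandFlipped <= 1,
            mafRange[1] > 0, mafRange[2] <= 0.5,
            pleiotropy$type %in% c("none", "balanced", "directional",
                                   "outlier"))
  if (!is.null(ldBlocks) && sum(vapply(ldBlocks, `[`, 0, 1)) > nSnp)
    mrStop("ldBlocks cover more variants than nSnp", "configError")
  structure(list(nSnp = nSnp, nInstrument = nInstrument, theta = theta,
                 gammaSd = gammaSd, seExpRange = seExpRange,
                 seOutRange = seOutRange, pleiotropy = pleiotropy,
                 mafRange = mafRange, fracPalindromic = fracPalindromic,
                 fracStrandFlipped = fracStrandFlipped, ldBlocks = ldBlocks,
                 nConfounderSnps = nConfounderSnps,
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

## deterministic genomic layout: LD blocks sit on consecutive positions
## (10 kb apart, well inside the clump window); distinct blocks are 2 Mb
## apart so the 1 Mb clump window never spans them
simLayout <- function(config) {
  n <- config$nSnp
  sizes <- if (is.null(config$ldBlocks)) integer() else
    vapply(config$ldBlocks, function(b) as.integer(b[1]), 0L)
  rs <- if (is.null(config$ldBlocks)) numeric() else
    vapply(config$ldBlocks, function(b) as.numeric(b[2]), 0)
  block <- integer(n)
  blockR <- numeric(n)
  i <- 1L; b <- 0L
  for (s in seq_along(sizes)) {
    b <- b + 1L
    block[i:(i + sizes[s] - 1L)] <- b
    blockR[i:(i + sizes[s] - 1L)] <- rs[s]
    i <- i + sizes[s]
  }
  while (i <= n) {
    b <- b + 1L
    block[i] <- b
    i <- i + 1L
  }
  nBlocks <- b
  blockChrom <- as.character(rep_len(1:22, nBlocks))
  blockSlot <- (seq_len(nBlocks) - 1L) %/% 22L
  chrom <- blockChrom[block]
  within <- stats::ave(rep(1, n), block, FUN = seq_along) - 1
  pos <- 1e6 + blockSlot[block] * 2e6 + within * 1e4
  list(rsid = sprintf("rs%05d", seq_len(n)), chrom = chrom, pos = pos,
       block = block, blockR = blockR)
}

simAlleles <- function(n, fracPalindromic) {
  nonpal <- rbind(c("A", "G"), c("A", "C"), c("G", "A"), c("C", "A"),
                  c("T", "G"), c("T", "C"), c("G", "T"), c("C", "T"))
  pal <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
  isPal <- runif(n) < fracPalindromic
  ea <- oa <- character(n)
  pick <- ifelse(isPal, sample.int(4, n, replace = TRUE),
                 sample.int(8, n, replace = TRUE))
  ea[isPal] <- pal[pick[isPal], 1]; oa[isPal] <- pal[pick[isPal], 2]
  ea[!isPal] <- nonpal[pick[!isPal], 1]; oa[!isPal] <- nonpal[pick[!isPal], 2]
  list(ea = ea, oa = oa, palindromic = isPal)
}

## redraw (gamma, observed beta) until the observed association passes
## genome-wide significance; guarantees labelled instruments survive the
## p < 5e-8 filter (which at that threshold also implies F > 29 > 10)
drawSignificant <- function(m, gammaSd, se, pCeiling = 5e-8,
                            maxTries = 200L) {
  gamma <- numeric(m); beta <- numeric(m)
  todo <- seq_len(m)
  for (try in seq_len(maxTries)) {
    g <- rnorm(length(todo), 0, gammaSd)
    b <- rnorm(length(todo), g, se[todo])
    ok <- 2 * pnorm(-abs(b) / se[todo]) < pCeiling
    gamma[todo[ok]] <- g[ok]
    beta[todo[ok]] <- b[ok]
    todo <- todo[!ok]
    if (!length(todo)) return(list(gamma = gamma, beta = beta))
  }
  mrStop("could not generate genome-wide-significant instruments under this configuration",
         "generationError")
}

directAlphas <- function(config, gamma, nInst, nConf) {
  n <- config$nSnp
  alpha <- numeric(n)
  outlier <- logical(n)
  pl <- config$pleiotropy
  instIdx <- seq_len(nInst)
  if (pl$type == "balanced" || pl$type == "directional") {
    frac <- if (is.null(pl$frac)) 1 else pl$frac
    m <- round(frac * nInst)
    hit <- if (m) sample(instIdx, m) else integer()
    if (pl$type == "balanced") {
      alpha[hit] <- rnorm(length(hit), 0, pl$sd)
    } else {
      alpha[hit] <- sign(gamma[hit]) * rnorm(length(hit), pl$mean, pl$sd)
    }
  } else if (pl$type == "outlier") {
    hit <- sample(instIdx, min(pl$count, nInst))
    alpha[hit] <- sign(gamma[hit]) * pl$effect
    outlier[hit] <- TRUE
  }
  if (nConf) {
    confIdx <- nInst + seq_len(nConf)
    alpha[confIdx] <- sign(gamma[confIdx]) * 0.05  # confounder path
  }
  list(alpha = alpha, outlier = outlier)
}

#' Simulate one exposure/outcome pair of summary-statistic tables
#'
#' Variants are laid out as instruments first, then confounder-associated
#' variants (also genome-wide significant for the exposure), then null
#' variants; positions follow the configured LD-block layout. The outcome
#' table covers the same variants with effects theta * gamma_j + alpha_j
#' plus noise, and presents a fraction of records strand-complemented and a
#' random half with the allele order swapped (beta negated, eaf reflected),
#' which harmonization must undo. P-values are floored at the smallest
#' positive double so they stay in (0, 1].
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param exposureId,outcomeId trait ids for the two tables.
#' @param exposureType,outcomeType trait types.
#' @return list with elements \code{exposure} and \code{outcome}
#'   (\code{\link{SumstatsTable}}s) and \code{truth}, a data.frame with the
#'   per-variant labels (category, gamma, alpha, is_outlier,
#'   is_palindromic, strand_flipped, swapped, block).
#' @export
simulatePair <- function(config, exposureId = "exposure",
                         outcomeId = "outcome", exposureType = "binary",
                         outcomeType = "continuous") {
  stopifnot(inherits(config, "SimulationConfig"))
  layout <- simLayout(config)
  n <- config$nSnp
  nInst <- config$nInstrument
  nConf <- config$nConfounderSnps
  withSeed(config$seed, {
    al <- simAlleles(n, config$fracPalindromic)
    maf <- runif(n, config$mafRange[1], config$mafRange[2])
    eaf <- ifelse(runif(n) < 0.5, maf, 1 - maf)
    seExp <- runif(n, config$seExpRange[1], config$seExpRange[2])
    seOut <- runif(n, config$seOutRange[1], config$seOutRange[2])

    gamma <- numeric(n)
    betaExp <- rnorm(n, 0, seExp)
    nSig <- nInst + nConf
    if (nSig) {
      sig <- drawSignificant(nSig, config$gammaSd, seExp[seq_len(nSig)])
      gamma[seq_len(nSig)] <- sig$gamma
      betaExp[seq_len(nSig)] <- sig$beta
    }
    da <- directAlphas(config, gamma, nInst, nConf)
    betaOut <- rnorm(n, config$theta * gamma + da$alpha, seOut)

    flip <- runif(n) < config$fracStrandFlipped
    swap <- runif(n) < 0.5

    expDf <- data.frame(rsid = layout$rsid, chrom = layout$chrom,
                        pos = layout$pos, effect_allele = al$ea,
                        other_allele = al$oa, eaf = eaf, beta = betaExp,
                        se = seExp,
                        pval = twoSidedNormalP(betaExp / seExp), n = 50000)
    outEa <- ifelse(swap, al$oa, al$ea)
    outOa <- ifelse(swap, al$ea, al$oa)
    outDf <- data.frame(rsid = layout$rsid, chrom = layout$chrom,
                        pos = layout$pos,
                        effect_allele = ifelse(flip, COMPLEMENT[outEa], outEa),
                        other_allele = ifelse(flip, COMPLEMENT[outOa], outOa),
                        eaf = ifelse(swap, 1 - eaf, eaf),
                        beta = ifelse(swap, -betaOut, betaOut), se = seOut,
                        pval = twoSidedNormalP(betaOut / seOut), n = 450000)
    truth <- data.frame(rsid = layout$rsid,
                        category = rep(c("instrument", "confounder", "null"),
                                       c(nInst, nConf, n - nInst - nConf)),
                        gamma = gamma, alpha = da$alpha,
                        is_outlier = da$outlier,
                        is_palindromic = al$palindromic,
                        strand_flipped = flip, swapped = swap,
                        block = layout$block, stringsAsFactors = FALSE)
    list(exposure = SumstatsTable(expDf, exposureId, exposureType),
         outcome = SumstatsTable(outDf, outcomeId, outcomeType),
         truth = truth)
  })
}

#' Simulate an allele-dosage LD panel
#'
#' Generates per-sample dosages for every variant of the configured layout.
#' Variants sharing an LD block are built from a shared latent normal
#' variable with loading sqrt(r), so expected pairwise correlation within a
#' block is about r and about 0 across blocks; dosages are an affine map of
#' the latent score clipped into [0, 2]. The realized r-squared computed
#' from these dosages is what \code{\link{ldClump}} consumes.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param nSamples panel size (default 500).
#' @return an \code{\link{LdReference}} dosage panel.
#' @export
simulateLdPanel <- function(config, nSamples = 500) {
  stopifnot(inherits(config, "SimulationConfig"))
  layout <- simLayout(config)
  n <- config$nSnp
  withSeed(deriveSeed(config$seed, 7L), {
    z <- matrix(rnorm(nSamples * max(layout$block)), nSamples)
    d <- matrix(0, nSamples, n, dimnames = list(NULL, layout$rsid))
    for (j in seq_len(n)) {
      r <- layout$blockR[j]
      lat <- if (r > 0) {
        sqrt(r) * z[, layout$block[j]] + sqrt(1 - r) * rnorm(nSamples)
      } else {
        rnorm(nSamples)
      }
      d[, j] <- pmin(2, pmax(0, 1 + 0.7 * lat))
    }
    LdReference(dosages = d)
  })
}

#' Simulate confounder annotations
#'
#' Builds a PhenoScanner-style annotation table from the generator's truth
#' labels: every confounder-labelled variant is annotated to one of the
#' five screened confounder traits at p well below genome-wide
#' significance; a sprinkling of other variants receive neutral-trait
#' annotations ("height", "education") or confounder-trait annotations
#' above the screening threshold, neither of which must cause a drop.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param truth the truth data.frame from \code{\link{simulatePair}}.
#' @return data.frame with columns rsid, trait, pval.
#' @export
simulateConfounderAnnotations <- function(config, truth) {
  stopifnot(inherits(config, "SimulationConfig"))
  withSeed(deriveSeed(config$seed, 13L), {
    conf <- truth$rsid[truth$category == "confounder"]
    rows <- list()
    if (length(conf)) {
      rows[[1]] <- data.frame(
        rsid = conf,
        trait = sample(confounderTraits(), length(conf), replace = TRUE),
        pval = 10^runif(length(conf), -30, -10))
    }
    others <- truth$rsid[truth$category != "confounder"]
    nNeutral <- min(length(others), max(1L, round(0.1 * length(others))))
    if (nNeutral) {
      pick <- sample(others, nNeutral)
      rows[[length(rows) + 1L]] <- data.frame(
        rsid = pick,
        trait = sample(c("height", "education"), nNeutral, replace = TRUE),
        pval = 10^runif(nNeutral, -30, -3))
      weak <- sample(others, min(length(others), 5L))
      rows[[length(rows) + 1L]] <- data.frame(
        rsid = weak,
        trait = sample(confounderTraits(), length(weak), replace = TRUE),
        pval = 10^runif(length(weak), -6, -3))
    }
    resetRows(do.call(rbind, rows))
  })
}
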