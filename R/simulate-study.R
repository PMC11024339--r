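#' Simulate a full bi-directional study
#'
#' Builds a complete synthetic study over a shared variant universe: a grid
#' of binary exposure traits (autoimmune-disease style) and continuous
#' outcome traits (sarcopenia style), each with its own genome-wide
#' significant instruments, a dosage LD panel, and confounder annotations.
#' Every trait's table covers the whole universe, so any trait can serve as
#' exposure or outcome.
#'
#' Structure: each trait owns \code{nInstrumentPerTrait} consecutive
#' variants; the first two form a 2-variant LD block (latent r = 0.9) that
#' clumping must reduce to one. \code{nConfounderSnps} further variants are
#' genome-wide significant for one trait (cycling over traits) but act
#' through a screened confounder: they carry a direct effect on every trait
#' of the opposite direction and an annotation below the screening
#' threshold. The remaining variants are nulls. True causal effects run
#' only from exposures to outcomes (\code{theta} matrix); all reverse
#' effects are zero, so reverse-direction analyses probe the null. About
#' 10 percent of variants are palindromic and each non-owner table presents
#' a record strand-complemented with probability 0.05 and with swapped
#' allele order (beta negated, frequency reflected) with probability 0.5.
#'
#' @param nExposures,nOutcomes grid dimensions (defaults 6 and 8).
#' @param nInstrumentPerTrait instruments owned by each trait (default 12).
#' @param nConfounderSnps confounder-acting variants (default 10).
#' @param nNullSnps null variants (default 22; the default universe is
#'   (6+8)*12 + 10 + 22 = 200 variants).
#' @param theta true causal-effect matrix (nExposures x nOutcomes); by
#'   default -0.25 where (i + j) is divisible by 3, else 0.
#' @param gammaSd standard deviation of true instrument effects.
#' @param seed master seed; the study is bit-reproducible given it.
#' @return list with \code{exposures} (list of binary
#'   \code{\link{SumstatsTable}}s), \code{outcomes} (continuous tables),
#'   \code{ld} (\code{\link{LdReference}} dosage panel),
#'   \code{annotations} (confounder table) and \code{truth} (list with the
#'   \code{theta} matrix and per-variant labels).
#' @export
simulateStudy <- function(nExposures = 6, nOutcomes = 8,
                          nInstrumentPerTrait = 12, nConfounderSnps = 10,
                          nNullSnps = 22, theta = NULL, gammaSd = 0.1,
                          seed = 1) {
  nTraits <- nExposures + nOutcomes
  nInstTotal <- nTraits * nInstrumentPerTrait
  nSnp <- nInstTotal + nConfounderSnps + nNullSnps
  traitIds <- c(sprintf("AD%d", seq_len(nExposures)),
                sprintf("SARC%d", seq_len(nOutcomes)))
  traitTypes <- rep(c("binary", "continuous"), c(nExposures, nOutcomes))
  if (is.null(theta)) {
    theta <- matrix(0, nExposures, nOutcomes,
                    dimnames = list(traitIds[seq_len(nExposures)],
                                    traitIds[nExposures + seq_len(nOutcomes)]))
    for (i in seq_len(nExposures)) for (j in seq_len(nOutcomes))
      if ((i + j) %% 3 == 0) theta[i, j] <- -0.25
  }
  ## one 2-variant LD block at the head of each trait's instrument run
  blocks <- list()
  for (t in seq_len(nTraits)) {
    blocks[[length(blocks) + 1L]] <- c(2, 0.9)
    for (s in seq_len(nInstrumentPerTrait - 2L))
      blocks[[length(blocks) + 1L]] <- c(1, 0)
  }
  layoutCfg <- simulationConfig(nSnp = nSnp, nInstrument = 0,
                                ldBlocks = blocks, seed = deriveSeed(seed, 3L))
  layout <- simLayout(layoutCfg)
  owner <- rep(NA_integer_, nSnp)           # trait index owning the variant
  for (t in seq_len(nTraits))
    owner[(t - 1L) * nInstrumentPerTrait + seq_len(nInstrumentPerTrait)] <- t
  confIdx <- nInstTotal + seq_len(nConfounderSnps)
  confOwner <- if (nConfounderSnps) rep_len(seq_len(nTraits), nConfounderSnps)
  else integer()

  withSeed(seed, {
    al <- simAlleles(nSnp, 0.1)
    maf <- runif(nSnp, 0.05, 0.5)
    eaf <- ifelse(runif(nSnp) < 0.5, maf, 1 - maf)

    ## true instrument effects per owner trait (confounders included)
    gamma <- numeric(nSnp)
    ownerAll <- owner
    ownerAll[confIdx] <- confOwner
    seByTrait <- function(t) {
      if (traitTypes[t] == "binary") runif(nSnp, 0.01, 0.02)
      else runif(nSnp, 0.005, 0.01)
    }
    se <- vapply(seq_len(nTraits), seByTrait, numeric(nSnp))

    tables <- vector("list", nTraits)
    betaObs <- matrix(NA_real_, nSnp, nTraits)
    for (t in seq_len(nTraits)) {
      own <- which(ownerAll == t)
      sig <- drawSignificant(length(own), gammaSd, se[own, t])
      gamma[own] <- sig$gamma
      betaObs[own, t] <- sig$beta
    }
    ## means for non-owner cells: causal paths + confounder direct effects
    for (t in seq_len(nTraits)) {
      rest <- setdiff(seq_len(nSnp), which(ownerAll == t))
      mu <- numeric(length(rest))
      for (r in seq_along(rest)) {
        j <- rest[r]
        src <- ownerAll[j]
        if (is.na(src)) next
        if (j %in% confIdx) {
          ## confounder path touches every trait on the opposite side
          sameSide <- (src <= nExposures) == (t <= nExposures)
          if (!sameSide) mu[r] <- 0.05 * sign(gamma[j])
        } else if (src <= nExposures && t > nExposures) {
          mu[r] <- theta[src, t - nExposures] * gamma[j]
        }
      }
      betaObs[rest, t] <- rnorm(length(rest), mu, se[rest, t])
    }

    flip <- matrix(runif(nSnp * nTraits) < 0.05, nSnp)
    swap <- matrix(runif(nSnp * nTraits) < 0.5, nSnp)
    for (t in seq_len(nTraits)) {
      ## each trait reports variants it owns in the reference frame
      flip[which(ownerAll == t), t] <- FALSE
      swap[which(ownerAll == t), t] <- FALSE
      ea <- ifelse(swap[, t], al$oa, al$ea)
      oa <- ifelse(swap[, t], al$ea, al$oa)
      df <- data.frame(rsid = layout$rsid, chrom = layout$chrom,
                       pos = layout$pos,
                       effect_allele = ifelse(flip[, t], COMPLEMENT[ea], ea),
                       other_allele = ifelse(flip[, t], COMPLEMENT[oa], oa),
                       eaf = ifelse(swap[, t], 1 - eaf, eaf),
                       beta = ifelse(swap[, t], -betaObs[, t], betaObs[, t]),
                       se = se[, t],
                       pval = twoSidedNormalP(betaObs[, t] / se[, t]),
                       n = if (traitTypes[t] == "binary") 50000 else 450000)
      tables[[t]] <- SumstatsTable(df, traitIds[t], traitTypes[t])
    }

    perSnp <- data.frame(rsid = layout$rsid,
                         owner = ifelse(is.na(ownerAll), NA_character_,
                                        traitIds[ownerAll]),
                         category = ifelse(seq_len(nSnp) %in% confIdx,
                                           "confounder",
                                           ifelse(is.na(owner), "null",
                                                  "instrument")),
                         gamma = gamma, is_palindromic = al$palindromic,
                         block = layout$block, stringsAsFactors = FALSE)
    truth <- list(theta = theta, perSnp = perSnp)

    annotations <- local({
      conf <- layout$rsid[confIdx]
      rows <- list()
      if (length(conf)) {
        rows[[1]] <- data.frame(
          rsid = conf,
          trait = sample(confounderTraits(), length(conf), replace = TRUE),
          pval = 10^runif(length(conf), -30, -10))
      }
      pool <- if (length(confIdx)) layout$rsid[-confIdx] else layout$rsid
      neutral <- sample(pool, min(10L, length(pool)))
      rows[[length(rows) + 1L]] <- data.frame(
        rsid = neutral, trait = "height",
        pval = 10^runif(length(neutral), -30, -3))
      resetRows(do.call(rbind, rows))
    })

    ld <- simulateLdPanel(layoutCfg)
    list(exposures = tables[seq_len(nExposures)],
         outcomes = tables[nExposures + seq_len(nOutcomes)],
         ld = ld, annotations = annotations, truth = truth)
  })
}
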