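test_that("palindrome detection covers exactly the complement pairs", {
  expect_true(isPalindromic("A", "T"))
  expect_true(isPalindromic("C", "G"))
  expect_true(isPalindromic("G", "C"))
  expect_false(isPalindromic("A", "G"))
  expect_false(isPalindromic("a", "c"))
})

snpRow <- function(rsid = "rs1", ea, oa, beta = 0.1, se = 0.02, eaf = 0.3) {
  data.frame(rsid = rsid, chrom = "1", pos = 1000, effect_allele = ea,
             other_allele = oa, eaf = eaf, beta = beta, se = se,
             pval = 1e-9, n = 1000, stringsAsFactors = FALSE)
}

test_that("allele swap negates the outcome beta and reflects its frequency", {
  res <- harmonizePair(snpRow(ea = "A", oa = "G", beta = 0.1),
                       snpRow(ea = "G", oa = "A", beta = 0.05, eaf = 0.3))
  expect_s3_class(res, "data.frame")
  expect_equal(res$beta_out, -0.05)
  expect_equal(res$eaf_out, 0.7)
  expect_identical(res$action, "flipped")
})

test_that("palindromic exposures are dropped unconditionally", {
  expect_identical(harmonizePair(snpRow(ea = "A", oa = "T"),
                                 snpRow(ea = "A", oa = "T")), "palindromic")
  ## even at very informative frequencies
  expect_identical(harmonizePair(snpRow(ea = "C", oa = "G", eaf = 0.05),
                                 snpRow(ea = "C", oa = "G", eaf = 0.05)),
                   "palindromic")
})

test_that("strand-complemented outcomes are recovered with the right sign", {
  res <- harmonizePair(snpRow(ea = "A", oa = "G"),
                       snpRow(ea = "T", oa = "C", beta = 0.05))
  expect_identical(res$action, "strand_complemented")
  expect_equal(res$beta_out, 0.05)
  res2 <- harmonizePair(snpRow(ea = "A", oa = "G"),
                        snpRow(ea = "C", oa = "T", beta = 0.05, eaf = 0.2))
  expect_identical(res2$action, "strand_complemented_and_flipped")
  expect_equal(res2$beta_out, -0.05)
  expect_equal(res2$eaf_out, 0.8)
})

test_that("pair harmonization matches an exhaustive allele-case oracle", {
  alleles <- c("A", "C", "G", "T")
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  oracle <- function(ea, eo, oa, oo) {
    if (comp[ea] == eo) return("palindromic")
    if (oa == ea && oo == eo) return("kept_as_is")
    if (oa == eo && oo == ea) return("flipped")
    ca <- comp[[oa]]; co <- comp[[oo]]
    if (ca == ea && co == eo) return("strand_complemented")
    if (ca == eo && co == ea) return("strand_complemented_and_flipped")
    "incompatible_alleles"
  }
  for (ea in alleles) for (eo in setdiff(alleles, ea))
    for (oa in alleles) for (oo in setdiff(alleles, oa)) {
      got <- harmonizePair(snpRow(ea = ea, oa = eo),
                           snpRow(ea = oa, oa = oo, beta = 0.05))
      want <- oracle(ea, eo, oa, oo)
      if (is.character(got)) {
        expect_identical(got, unname(want))
      } else {
        expect_identical(got$action, unname(want))
        negated <- want %in% c("flipped", "strand_complemented_and_flipped")
        expect_equal(got$beta_out, if (negated) -0.05 else 0.05)
      }
    }
})

test_that("the MAF rule drops rare or frequency-less records on either side", {
  expect_identical(harmonizePair(snpRow(ea = "A", oa = "G", eaf = 0.005),
                                 snpRow(ea = "A", oa = "G")), "low_maf")
  expect_identical(harmonizePair(snpRow(ea = "A", oa = "G"),
                                 snpRow(ea = "A", oa = "G", eaf = 0.995)),
                   "low_maf")
  expect_identical(harmonizePair(snpRow(ea = "A", oa = "G"),
                                 snpRow(ea = "A", oa = "G", eaf = NA)),
                   "low_maf")
  ## boundary is strict: maf must exceed 0.01
  expect_identical(harmonizePair(snpRow(ea = "A", oa = "G", eaf = 0.01),
                                 snpRow(ea = "A", oa = "G")), "low_maf")
})

test_that("harmonizing a table against itself is the identity", {
  cfg <- simulationConfig(nSnp = 25, nInstrument = 10, fracPalindromic = 0,
                          seed = 31)
  tab <- simulatePair(cfg)$exposure
  h <- harmonize(makeInstruments(tab), tab)
  expect_identical(nSnps(h), 25L)
  expect_true(all(harmonizedPairs(h)$action == "kept_as_is"))
  expect_equal(harmonizedPairs(h)$beta_out, harmonizedPairs(h)$beta_exp)
})

test_that("exactly the truth-labelled palindromic instruments are dropped", {
  cfg <- simulationConfig(nSnp = 200, nInstrument = 60,
                          fracPalindromic = 0.1, seed = 32)
  sim <- simulatePair(cfg)
  h <- harmonizeSim(sim)
  dropped <- dropLog(h)
  pal <- dropped$rsid[dropped$reason == "palindromic"]
  expect_setequal(pal, sim$truth$rsid[sim$truth$is_palindromic])
})

test_that("every instrument lands exactly once in pairs or the drop log", {
  cfg <- simulationConfig(nSnp = 80, nInstrument = 30, seed = 33)
  sim <- simulatePair(cfg)
  instr <- makeInstruments(sim$exposure)
  ## knock some variants out of the outcome to exercise not_in_outcome
  odf <- snps(sim$outcome)
  outcome <- SumstatsTable(odf[-(1:5), ], traitId(sim$outcome), "continuous")
  h <- harmonize(instr, outcome)
  seen <- c(harmonizedPairs(h)$rsid, dropLog(h)$rsid)
  expect_setequal(seen, instruments(instr)$rsid)
  expect_identical(anyDuplicated(seen), 0L)
  expect_identical(sum(dropLog(h)$reason == "not_in_outcome"), 5L)
})

test_that("outcome row order does not change the harmonized set", {
  cfg <- simulationConfig(nSnp = 40, nInstrument = 15, seed = 34)
  sim <- simulatePair(cfg)
  instr <- makeInstruments(sim$exposure)
  h1 <- harmonize(instr, sim$outcome)
  odf <- snps(sim$outcome)
  perm <- SumstatsTable(withr::with_seed(9, odf[sample.int(nrow(odf)), ]),
                        traitId(sim$outcome), "continuous")
  h2 <- harmonize(instr, perm)
  expect_identical(harmonizedPairs(h1), harmonizedPairs(h2))
})

test_that("an allele-swapped outcome leaves the aligned effects unchanged", {
  cfg <- simulationConfig(nSnp = 40, nInstrument = 20, fracPalindromic = 0,
                          seed = 35)
  sim <- simulatePair(cfg)
  instr <- makeInstruments(sim$exposure)
  h1 <- harmonize(instr, sim$outcome)
  odf <- snps(sim$outcome)
  swapped <- odf
  swapped$effect_allele <- odf$other_allele
  swapped$other_allele <- odf$effect_allele
  swapped$beta <- -odf$beta
  swapped$eaf <- 1 - odf$eaf
  h2 <- harmonize(instr, SumstatsTable(swapped, "out", "continuous"))
  expect_equal(harmonizedPairs(h2)$beta_out, harmonizedPairs(h1)$beta_out,
               tolerance = 1e-12)
  expect_equal(mrBeta(mrIvw(h2)$result), mrBeta(mrIvw(h1)$result),
               tolerance = 1e-12)
})
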