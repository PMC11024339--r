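test_that("F statistic is the squared Wald ratio", {
  expect_equal(computeFStatistic(0.03, 0.005), 36)
  expect_equal(computeFStatistic(-0.02, 0.004), 25)
  expect_equal(computeFStatistic(0, 0.1), 0)
  expect_error(computeFStatistic(0.1, 0), class = "domainError")
})

test_that("significance filter applies both strict thresholds", {
  df <- randomSnpFrame(3, seed = 10)
  df$pval <- c(4e-8, 5e-8, 1e-9)
  df$beta <- c(0.1, 0.1, 0.1)
  df$se <- c(0.005, 0.005, 0.04)   # F = 400, 400, 6.25
  tab <- SumstatsTable(df, "t")
  kept <- filterSignificant(tab)
  expect_identical(snps(kept)$rsid, df$rsid[1])
})

test_that("significance filter matches a brute-force scan on 1000 SNPs", {
  df <- randomSnpFrame(1000, seed = 11)
  df$pval <- 10^runif(1000, -12, 0)
  tab <- SumstatsTable(df, "t")
  kept <- filterSignificant(tab)
  manual <- df$rsid[df$pval < 5e-8 & (df$beta / df$se)^2 > 10]
  expect_identical(snps(kept)$rsid, manual)
})

test_that("greedy clump keeps the index SNP and distant low-LD SNPs", {
  df <- randomSnpFrame(3, seed = 12)
  df$rsid <- c("A", "B", "C")
  df$chrom <- "1"
  df$pos <- c(100000, 200000, 2500000)
  df$pval <- c(1e-10, 1e-9, 4e-8)
  tab <- SumstatsTable(df, "t")
  ld <- LdReference(r2map = data.frame(
    rsid_i = c("A", "A", "B"), rsid_j = c("B", "C", "C"),
    r2 = c(0.5, 0.0005, 0.0005)))
  out <- ldClump(tab, ld)
  expect_setequal(snps(out)$rsid, c("A", "C"))
})

test_that("the clump window never spans chromosomes; singletons survive", {
  df <- randomSnpFrame(2, seed = 13)
  df$chrom <- c("1", "2"); df$pos <- c(100, 200)
  tab <- SumstatsTable(df, "t")
  ld <- LdReference(r2map = data.frame(rsid_i = df$rsid[1],
                                       rsid_j = df$rsid[2], r2 = 1))
  expect_setequal(snps(ldClump(tab, ld))$rsid, df$rsid)
  one <- SumstatsTable(df[1, ], "t")
  expect_identical(snps(ldClump(one, ld))$rsid, df$rsid[1])
})

test_that("clumping equals the brute-force greedy oracle on random instances", {
  for (s in 1:20) {
    set.seed(100 + s)
    n <- sample(10:50, 1)
    df <- randomSnpFrame(n, seed = 200 + s)
    df$chrom <- as.character(sample(1:3, n, replace = TRUE))
    df$pos <- sample.int(3e6, n)
    df$pval <- 10^runif(n, -12, -2)
    r2 <- matrix(runif(n * n)^3, n, dimnames = list(df$rsid, df$rsid))
    r2 <- (r2 + t(r2)) / 2; diag(r2) <- 1
    pairs <- which(upper.tri(r2), arr.ind = TRUE)
    ld <- LdReference(r2map = data.frame(rsid_i = df$rsid[pairs[, 1]],
                                         rsid_j = df$rsid[pairs[, 2]],
                                         r2 = r2[pairs]))
    tab <- SumstatsTable(df, "t")
    got <- snps(ldClump(tab, ld, r2Threshold = 0.1, windowKb = 500))$rsid
    want <- oracleClump(df, function(a, b) r2[a, b], 0.1, 500)
    expect_setequal(got, want)
    ## maximality: no two kept SNPs are simultaneously close and in LD
    kept <- df[df$rsid %in% got, ]
    for (i in seq_len(nrow(kept))) for (j in seq_len(nrow(kept))) {
      if (i >= j) next
      close <- kept$chrom[i] == kept$chrom[j] &&
        abs(kept$pos[i] - kept$pos[j]) <= 5e5
      expect_false(close && r2[kept$rsid[i], kept$rsid[j]] >= 0.1)
    }
  }
})

test_that("clump rejects bad thresholds and drops unknown variants", {
  df <- randomSnpFrame(2, seed = 14)
  tab <- SumstatsTable(df, "t")
  ld <- LdReference(r2map = data.frame(rsid_i = df$rsid[1],
                                       rsid_j = df$rsid[1], r2 = 1))
  expect_error(ldClump(tab, ld, r2Threshold = 0), class = "configError")
  expect_error(ldClump(tab, ld, windowKb = -1), class = "configError")
  expect_message(out <- ldClump(tab, ld), "absent from the LD reference")
  expect_identical(snps(out)$rsid, df$rsid[1])
})

test_that("confounder screen drops only sub-threshold confounder hits", {
  df <- randomSnpFrame(3, seed = 15)
  tab <- SumstatsTable(df, "t")
  ann <- data.frame(rsid = df$rsid,
                    trait = c("Body Mass Index", "height", "smoking"),
                    pval = c(1e-12, 1e-20, 1e-6))
  out <- suppressMessages(screenConfounders(tab, ann))
  expect_setequal(snps(out)$rsid, df$rsid[2:3])
})

test_that("full selection recovers exactly the labelled instruments", {
  cfg <- simulationConfig(nSnp = 55, nInstrument = 20, nConfounderSnps = 5,
                          fracPalindromic = 0, seed = 21)
  sim <- simulatePair(cfg)
  ld <- simulateLdPanel(cfg)
  ann <- simulateConfounderAnnotations(cfg, sim$truth)
  sel <- suppressMessages(selectInstruments(sim$exposure, ld, ann))
  want <- sim$truth$rsid[sim$truth$category == "instrument"]
  expect_setequal(instruments(sel)$rsid, want)
  expect_true(all(diff(selectionLog(sel)) <= 0))
  expect_true(all(instruments(sel)$f_stat > 10))
})

test_that("selection is idempotent and order-invariant", {
  cfg <- simulationConfig(nSnp = 40, nInstrument = 15, seed = 22)
  sim <- simulatePair(cfg)
  ld <- simulateLdPanel(cfg)
  sel <- selectInstruments(sim$exposure, ld)
  again <- selectInstruments(
    SumstatsTable(instruments(sel)[names(snps(sim$exposure))],
                  traitId(sim$exposure), "binary"), ld)
  expect_setequal(instruments(again)$rsid, instruments(sel)$rsid)
  shuffled <- withr::with_seed(1, {
    df <- snps(sim$exposure)
    SumstatsTable(df[sample.int(nrow(df)), ], traitId(sim$exposure),
                  "binary")
  })
  selShuf <- selectInstruments(shuffled, ld)
  expect_setequal(instruments(selShuf)$rsid, instruments(sel)$rsid)
})

test_that("an all-null table yields an empty set with stage-1 attrition", {
  cfg <- simulationConfig(nSnp = 30, nInstrument = 0, seed = 23)
  sim <- simulatePair(cfg)
  ld <- simulateLdPanel(cfg)
  sel <- selectInstruments(sim$exposure, ld)
  expect_identical(nSnps(sel), 0L)
  expect_identical(selectionLog(sel)[["p_filter"]], 0L)
})
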