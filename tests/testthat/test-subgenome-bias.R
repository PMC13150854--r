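fourChromLayout <- function(lengths = c(100, 100, 100, 100)) {
  GenomeLayout(chrom = paste0("chr1", LETTERS[1:4]), length = lengths,
               subgenome = c("A", "B", "C", "D"), group = rep(1L, 4))
}

test_that("peak counts tally exhaustively per group and subgenome", {
  layout <- fourChromLayout()
  expect_true(all(countPeaksByChromosome(GRanges(), layout) == 0))
  one <- GRanges(rep("chr1B", 5), IRanges(1:5 * 10, width = 3))
  m <- countPeaksByChromosome(one, layout)
  expect_equal(m["1", "B"], 5L)
  expect_equal(sum(m), 5L)
  bad <- GRanges("chrZZ", IRanges(1, 10))
  expect_error(countPeaksByChromosome(bad, layout), "chrZZ")
})

test_that("random peak placement matches a direct tally", {
  cfg <- simulationConfig(seed = 41, nGroups = 4L, genesPerChrom = 5L)
  layout <- simulateGenome(cfg)$layout
  tab <- layoutTable(layout)
  set.seed(5)
  ci <- sample(nrow(tab), 500, replace = TRUE)
  peaks <- GRanges(tab$chrom[ci], IRanges(100, width = 50))
  m <- countPeaksByChromosome(peaks, layout)
  for (k in seq_len(nrow(tab)))
    expect_equal(m[as.character(tab$group[k]), tab$subgenome[k]],
                 sum(ci == k))
})

test_that("expected counts apportion the group total by chromosome length", {
  layout <- fourChromLayout()
  obs <- c(A = 40, B = 30, C = 20, D = 10)
  expect_equal(unname(expectedCounts(obs, layout, 1L)), rep(25, 4))
  layout2 <- fourChromLayout(c(200, 100, 100, 100))
  expect_equal(unname(expectedCounts(obs, layout2, 1L)), c(40, 20, 20, 20))
  ## conservation on random inputs
  set.seed(6)
  for (i in 1:20) {
    layoutR <- fourChromLayout(runif(4, 50, 500))
    obsR <- c(A = rpois(1, 50), B = rpois(1, 50), C = rpois(1, 50),
              D = rpois(1, 50))
    expect_equal(sum(expectedCounts(obsR, layoutR, 1L)), sum(obsR),
                 tolerance = 1e-9)
  }
})

test_that("the chi-square statistic and p-value are exact", {
  res0 <- chiSquareBias(c(25, 25, 25, 25), c(25, 25, 25, 25))
  expect_equal(res0$chi2, 0)
  expect_equal(res0$p_value, 1)
  res <- chiSquareBias(c(40, 20, 20, 20), c(25, 25, 25, 25))
  expect_equal(res$chi2, 12)
  expect_equal(res$df, 3L)
  ## closed form for df = 3: P(X > x) = 2(1 - Phi(sqrt(x))) +
  ## sqrt(2x/pi) exp(-x/2)
  closedForm <- 2 * (1 - pnorm(sqrt(12))) + sqrt(2 * 12 / pi) * exp(-6)
  expect_equal(res$p_value, closedForm, tolerance = 1e-12)
  expect_equal(res$p_value, 0.0073831605, tolerance = 1e-6)
  expect_true(res$significant)
  expect_error(chiSquareBias(c(1, 2), c(0, 3)), "pool")
})

test_that("the chi-square statistic is invariant under subgenome permutation", {
  set.seed(7)
  obs <- rpois(4, 40); exp_ <- obs + rnorm(4)
  exp_ <- exp_ * sum(obs) / sum(exp_)
  base <- chiSquareBias(obs, exp_)$chi2
  for (i in 1:5) {
    o <- sample(4)
    expect_equal(chiSquareBias(obs[o], exp_[o])$chi2, base)
  }
})

test_that("type-I error is calibrated under the size-proportional null", {
  layout <- fourChromLayout(c(120, 80, 150, 90))
  lens <- layoutTable(layout)$length
  set.seed(123)
  nrep <- 1000
  rejected <- logical(nrep)
  for (r in seq_len(nrep)) {
    obs <- as.vector(rmultinom(1, 200, lens / sum(lens)))
    names(obs) <- c("A", "B", "C", "D")
    expd <- expectedCounts(obs, layout, 1L)
    rejected[r] <- chiSquareBias(obs, expd)$p_value <= 0.05
  }
  expect_gte(mean(rejected), 0.03)
  expect_lte(mean(rejected), 0.07)
})

test_that("the per-group bias report covers all groups and supports correction", {
  cfg <- simulationConfig(seed = 42, nGroups = 7L, genesPerChrom = 6L,
                          nPlantedPeaks = 400L)
  genome <- simulateGenome(cfg)
  chip <- simulateChipReplicates(cfg, genome)
  res <- subgenomeBiasTest(chip$rep1, genome$layout)
  expect_equal(sort(unique(res$group)), 1:7)
  expect_equal(nrow(res), 28L)
  ## per group, expected sums to observed
  for (g in 1:7) {
    sub <- res[res$group == g, ]
    expect_equal(sum(sub$expected), sum(sub$observed), tolerance = 1e-9)
    expect_equal(sub$df[1], 3L)
  }
  resB <- subgenomeBiasTest(chip$rep1, genome$layout, correct = "bonferroni")
  expect_true(all(resB$p_bonferroni >= res$p_value - 1e-12))
  ## restricting to promoter-region peaks reuses the same machinery
  maps <- assignTargetGenes(makePairs(as.character(seqnames(chip$rep1)),
                                      start(chip$rep1), end(chip$rep1),
                                      summitDistance = 0L,
                                      summit = chip$rep1$summit,
                                      name = chip$rep1$name),
                            genome$annotation)
  promPeaks <- chip$rep1[chip$rep1$name %in% maps$peak_name]
  resP <- subgenomeBiasTest(promPeaks, genome$layout)
  expect_equal(nrow(resP), 28L)
})
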