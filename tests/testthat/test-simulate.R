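test_that("simulation is byte-stable under a fixed seed", {
  cfg <- simulationConfig(seed = 61, nGroups = 2L, genesPerChrom = 6L,
                          nPlantedPeaks = 40L)
  d1 <- tempfile(); d2 <- tempfile()
  g1 <- simulateGenome(cfg, dir = d1)
  g2 <- simulateGenome(cfg, dir = d2)
  for (f in c("genome_layout.tsv", "genes.gff3", "homoeolog_map.tsv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  c1 <- simulateChipReplicates(cfg, g1, dir = d1)
  c2 <- simulateChipReplicates(cfg, g2, dir = d2)
  expect_identical(readLines(c1$paths$rep1), readLines(c2$paths$rep1))
  expect_identical(readLines(c1$paths$rep2), readLines(c2$paths$rep2))
  t1 <- simulateDegTable(cfg, g1, c1$targetGenes, dir = d1)
  t2 <- simulateDegTable(cfg, g2, c2$targetGenes, dir = d2)
  expect_identical(readLines(t1$path), readLines(t2$path))
})

test_that("the simulated genome has the configured shape", {
  cfg <- simulationConfig(seed = 62, nGroups = 7L, genesPerChrom = 10L)
  genome <- simulateGenome(cfg)
  tab <- layoutTable(genome$layout)
  expect_equal(nrow(tab), 28L)
  expect_equal(sort(unique(tab$group)), 1:7)
  expect_equal(sort(unique(tab$subgenome)), sort(cfg$subgenomes))
  expect_equal(length(genes(genome$annotation)), 7L * 4L * 10L)
  ## homoeolog quartets complete
  expect_true(all(table(genome$map) == 4))
})

test_that("zero jitter makes replicate summits identical", {
  cfg <- simulationConfig(seed = 63, nPlantedPeaks = 60L, summitJitterSd = 0,
                          irreproduciblePeakRate = 0, weakPeakRate = 0)
  genome <- simulateGenome(cfg)
  chip <- simulateChipReplicates(cfg, genome)
  expect_equal(chip$rep1$summit, chip$rep2$summit)
  pairs <- overlapReplicates(chip$rep1, chip$rep2)
  expect_true(all(pairs$summitDistance == 0))
})

test_that("without noise peaks the matched set is exactly the planted set", {
  cfg <- simulationConfig(seed = 64, nPlantedPeaks = 80L,
                          irreproduciblePeakRate = 0, weakPeakRate = 0)
  genome <- simulateGenome(cfg)
  chip <- simulateChipReplicates(cfg, genome)
  pairs <- overlapReplicates(filterPeaks(chip$rep1), filterPeaks(chip$rep2))
  expect_equal(length(pairs), nrow(chip$truth))
  expect_setequal(sub("^r1_", "", pairs$name1), chip$truth$peak)
})

test_that("planted peaks always survive the VL1 fold/q filter", {
  cfg <- simulationConfig(seed = 65, nPlantedPeaks = 100L)
  genome <- simulateGenome(cfg)
  chip <- simulateChipReplicates(cfg, genome)
  planted <- grepl("planted", chip$rep1$name)
  kept <- filterPeaks(chip$rep1)
  expect_true(all(chip$rep1$name[planted] %in% kept$name))
  ## weak peaks never survive
  expect_false(any(grepl("weak", kept$name)))
})

test_that("planted DEGs are all selected and nulls are almost never selected", {
  cfg <- simulationConfig(seed = 66, nGroups = 3L, genesPerChrom = 20L,
                          nPlantedDegs = 60L)
  genome <- simulateGenome(cfg)
  bound <- genes(genome$annotation)$gene_id[1:100]
  sim <- simulateDegTable(cfg, genome, bound)
  sel <- selectConsistentDegs(sim$table)
  planted <- c(sim$direct, sim$indirect)
  expect_true(all(planted %in% sel$gene_id))
  ## false selections among nulls stay below 1%
  nulls <- setdiff(unique(sim$table$gene_id), planted)
  expect_lt(mean(nulls %in% sel$gene_id), 0.01)
})

test_that("the null effect model keeps the false-selection rate below 1%", {
  ## 10^4 null genes drawn from the generator's null model
  set.seed(67)
  n <- 1e4
  grid <- expand.grid(gene_id = sprintf("n%05d", 1:n),
                      line = c("RNAi_3", "RNAi_11"),
                      stage = c("white", "red"), stringsAsFactors = FALSE)
  grid$log2fc <- rnorm(nrow(grid), 0, 0.2)
  grid$fdr <- runif(nrow(grid))
  sel <- selectConsistentDegs(grid)
  expect_lt(nrow(sel) / n, 0.01)
})

test_that("VL3 recall degrades monotonically with summit jitter", {
  recalls <- vapply(c(0, 60, 200), function(js) {
    cfg <- simulationConfig(seed = 68, nPlantedPeaks = 150L,
                            summitJitterSd = js, irreproduciblePeakRate = 0,
                            weakPeakRate = 0)
    genome <- simulateGenome(cfg)
    chip <- simulateChipReplicates(cfg, genome)
    pairs <- overlapReplicates(filterPeaks(chip$rep1), filterPeaks(chip$rep2))
    lv <- assignValidationLevels(pairs, estimateIdr(pairs))
    unname(levelCounts(lv)["VL3"]) / nrow(chip$truth)
  }, numeric(1))
  expect_true(all(diff(recalls) <= 0))
  expect_gt(recalls[1], recalls[3])
})

test_that("zero-noise end-to-end recovery reproduces the planted fractions", {
  cfg <- simulationConfig(seed = 69, nGroups = 3L, genesPerChrom = 15L,
                          nPlantedPeaks = 100L, summitJitterSd = 0,
                          irreproduciblePeakRate = 0, weakPeakRate = 0,
                          nPlantedDegs = 80L, directFraction = 0.25)
  genome <- simulateGenome(cfg)
  chip <- simulateChipReplicates(cfg, genome)
  deg <- simulateDegTable(cfg, genome, chip$targetGenes)
  pairs <- overlapReplicates(filterPeaks(chip$rep1), filterPeaks(chip$rep2))
  pairs <- assignValidationLevels(pairs, estimateIdr(pairs))
  maps <- targetMapsByLevel(pairs, genome$annotation)
  sel <- selectConsistentDegs(deg$table)
  calls <- classifyDirectIndirect(sel, maps,
                                  universe = genes(genome$annotation)$gene_id)
  s <- summarizeClassification(calls)
  expect_equal(s$n_selected, length(deg$direct) + length(deg$indirect))
  expect_equal(unname(s$n_direct[["VL1"]]), length(deg$direct))
  expect_equal(unname(s$pct_direct[["VL1"]]),
               polyChIP:::roundHalfUp(100 * length(deg$direct) /
                                        s$n_selected, 1))
  ## planted direct targets recovered exactly
  direct <- calls$gene_id[calls$class == "direct"]
  expect_setequal(direct, deg$direct)
})
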