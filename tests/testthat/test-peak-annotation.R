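test_that("summits upstream of a TSS are classified into promoter tiers", {
  ann <- toyAnnotation()
  ## gPlus TSS at 10000 (+): 500 bp upstream = 9500; gMinus TSS 32000 (-):
  ## 500 bp upstream = 32500
  pairs <- makePairs("chr1", c(9400L, 32400L), c(9700L, 32700L),
                     summitDistance = 0L, summit = c(9500L, 32500L))
  feat <- classifyFeature(pairs, ann)
  expect_equal(as.character(feat$category),
               c("promoter_0_1kb", "promoter_0_1kb"))
  expect_equal(feat$gene_id, c("gPlus", "gMinus"))
  expect_equal(feat$signed_tss_distance, c(-500, -500))
})

test_that("a summit inside an exon with no promoter overlap is exonic", {
  ann <- toyAnnotation()
  pairs <- makePairs("chr1", 11400L, 11700L, summitDistance = 0L,
                     summit = 11500L)
  feat <- classifyFeature(pairs, ann)
  expect_equal(as.character(feat$category), "exon")
  expect_equal(feat$gene_id, "gPlus")
  ## and between exons -> intron
  pairs2 <- makePairs("chr1", 10700L, 10900L, summitDistance = 0L,
                      summit = 10800L)
  expect_equal(as.character(classifyFeature(pairs2, ann)$category), "intron")
})

test_that("feature classification matches the exhaustive oracle on random peaks", {
  cfg <- simulationConfig(seed = 21, nGroups = 2L, genesPerChrom = 8L)
  genome <- simulateGenome(cfg)
  set.seed(99)
  tab <- layoutTable(genome$layout)
  n <- 200
  ci <- sample(nrow(tab), n, replace = TRUE)
  pos <- as.integer(runif(n, 1000, tab$length[ci] - 1000))
  pairs <- makePairs(tab$chrom[ci], pos - 150L, pos + 150L,
                     summitDistance = 0L, summit = pos)
  got <- classifyFeature(pairs, genome$annotation)
  want <- oracleClassify(pos, tab$chrom[ci], genome$annotation)
  expect_equal(as.character(got$category), want$category)
  expect_equal(got$gene_id, want$gene_id)
  expect_equal(got$signed_tss_distance, want$d)
  ## categories partition the peak set
  expect_equal(sum(table(got$category)), n)
})

test_that("TSS profiles concentrate summits where they were placed", {
  ann <- toyAnnotation()
  ## all summits exactly at the two TSSs -> single central bin
  pairs <- makePairs("chr1", c(9900L, 31900L, 9950L), c(10100L, 32100L, 10150L),
                     summitDistance = 0L, summit = c(10000L, 32000L, 10000L))
  prof <- tssProfile(pairs, ann, halfWindow = 3000L, bin = 50L)
  expect_equal(attr(prof, "total_in_window"), 3L)
  expect_equal(sum(prof$count), 3L)
  central <- prof$bin_start == 0
  expect_equal(prof$count[central], 3L)

  ## no gene within the window -> empty profile
  far <- makePairs("chr1", 20000L, 20300L, summitDistance = 0L, summit = 20150L)
  prof2 <- tssProfile(far, ann)
  expect_equal(attr(prof2, "total_in_window"), 0L)
  expect_error(tssProfile(pairs, ann, bin = 0), "positive")
})

test_that("normally jittered summits profile to a mode near zero", {
  cfg <- simulationConfig(seed = 22, nGroups = 2L, genesPerChrom = 6L)
  genome <- simulateGenome(cfg)
  g <- genes(genome$annotation)
  set.seed(7)
  n <- 1000
  gi <- sample(length(g), n, replace = TRUE)
  d <- round(rnorm(n, 0, 300))
  pos <- ifelse(as.character(strand(g))[gi] == "+", g$tss[gi] + d,
                g$tss[gi] - d)
  pairs <- makePairs(as.character(seqnames(g))[gi], pos - 150L, pos + 150L,
                     summitDistance = 0L, summit = as.integer(pos))
  ## bins comparable to the jitter scale so the mode is well defined
  prof <- tssProfile(pairs, genome$annotation, bin = 150L)
  mode <- prof$bin_start[which.max(prof$count)]
  expect_true(mode %in% c(-150, 0))   # within one bin of the TSS
})

test_that("promoter-window target assignment respects the window bounds", {
  ann <- toyAnnotation()
  ## 1500 bp upstream of gPlus -> assigned; 150 bp downstream -> not
  up <- makePairs("chr1", 8400L, 8700L, summitDistance = 0L, summit = 8500L)
  expect_equal(assignTargetGenes(up, ann)$gene_id, "gPlus")
  downs <- makePairs("chr1", 10000L, 10300L, summitDistance = 0L,
                     summit = 10150L)
  expect_equal(nrow(assignTargetGenes(downs, ann)), 0L)
  expect_equal(nrow(assignTargetGenes(up[0], ann)), 0L)
  ## boundary: exactly +100 bp downstream is inside the window
  edge <- makePairs("chr1", 10000L, 10300L, summitDistance = 0L,
                    summit = 10100L)
  expect_equal(assignTargetGenes(edge, ann)$gene_id, "gPlus")
})

test_that("target assignment equals brute-force containment and is monotone", {
  cfg <- simulationConfig(seed = 23, nGroups = 2L, genesPerChrom = 8L)
  genome <- simulateGenome(cfg)
  set.seed(17)
  tab <- layoutTable(genome$layout)
  n <- 300
  ci <- sample(nrow(tab), n, replace = TRUE)
  pos <- as.integer(runif(n, 1000, tab$length[ci] - 1000))
  pairs <- makePairs(tab$chrom[ci], pos - 150L, pos + 150L,
                     summitDistance = 0L, summit = pos,
                     name = sprintf("pk%03d", 1:n))
  got <- assignTargetGenes(pairs, genome$annotation)
  want <- oracleTargets(pos, tab$chrom[ci], genome$annotation)
  expect_equal(nrow(got), nrow(want))
  expect_equal(got$gene_id, want$gene_id)
  expect_equal(got$signed_tss_distance, want$d)
  ## shrinking the window never adds genes
  narrower <- assignTargetGenes(pairs, genome$annotation, up = 1000, down = 50)
  expect_true(all(unique(narrower$gene_id) %in% unique(got$gene_id)))
  expect_lte(nrow(narrower), nrow(got))
})
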