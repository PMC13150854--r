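degFixture <- function() {
  ## two lines x two stages, four genes with hand-set outcomes
  expand <- expand.grid(gene_id = c("g1", "g2", "g3", "g4"),
                        line = c("RNAi_3", "RNAi_11"),
                        stage = c("white", "red"),
                        stringsAsFactors = FALSE)
  expand <- expand[order(expand$gene_id, expand$line, expand$stage), ]
  ## g1: -1.2 everywhere, significant -> selected, down
  ## g2: -0.9 everywhere -> below the two-fold rule
  ## g3: +1.5 in RNAi_3 only -> fails the both-lines rule
  ## g4: +1.4 in both lines at white only -> selected under any_stage
  expand$log2fc <- 0.1
  expand$fdr <- 0.9
  expand$log2fc[expand$gene_id == "g1"] <- -1.2
  expand$fdr[expand$gene_id == "g1"] <- 0.01
  expand$log2fc[expand$gene_id == "g2"] <- -0.9
  expand$fdr[expand$gene_id == "g2"] <- 0.01
  sel3 <- expand$gene_id == "g3" & expand$line == "RNAi_3"
  expand$log2fc[sel3] <- 1.5
  expand$fdr[sel3] <- 0.01
  sel4 <- expand$gene_id == "g4" & expand$stage == "white"
  expand$log2fc[sel4] <- 1.4
  expand$fdr[sel4] <- 0.02
  expand
}

test_that("DEG tables parse, and malformed rows carry line numbers", {
  tab <- degFixture()
  path <- tempfile(fileext = ".tsv")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  got <- readDegTable(path)
  expect_equal(nrow(got), 16L)
  expect_equal(sort(unique(got$gene_id)), c("g1", "g2", "g3", "g4"))

  bad <- tab; bad$log2fc <- as.character(bad$log2fc); bad$log2fc[3] <- "x"
  badPath <- tempfile(); write.table(bad, badPath, sep = "\t", quote = FALSE,
                                     row.names = FALSE)
  expect_error(readDegTable(badPath), "line 4.*log2fc")

  dup <- rbind(tab, tab[1, ])
  dupPath <- tempfile(); write.table(dup, dupPath, sep = "\t", quote = FALSE,
                                     row.names = FALSE)
  expect_error(readDegTable(dupPath), "duplicate")
})

test_that("a simulated DEG table round-trips through TSV", {
  cfg <- simulationConfig(seed = 31, nGroups = 3L, genesPerChrom = 30L)
  genome <- simulateGenome(cfg)
  sim <- simulateDegTable(cfg, genome, genes(genome$annotation)$gene_id[1:50],
                          dir = tempfile())
  back <- readDegTable(sim$path)
  expect_equal(nrow(back), nrow(sim$table))
  expect_equal(back$gene_id, sim$table$gene_id)
  expect_equal(back$log2fc, sim$table$log2fc)
  expect_equal(back$fdr, sim$table$fdr)
})

test_that("consistent-DEG selection honours thresholds and line/stage rules", {
  sel <- selectConsistentDegs(degFixture())
  expect_setequal(sel$gene_id, c("g1", "g4"))
  expect_equal(sel$direction[sel$gene_id == "g1"], "down")
  expect_equal(sel$direction[sel$gene_id == "g4"], "up")
  ## under both_stages, g4 (white only) drops out
  selB <- selectConsistentDegs(degFixture(), stageRule = "both_stages")
  expect_equal(selB$gene_id, "g1")
  ## not requiring both lines admits g3
  selL <- selectConsistentDegs(degFixture(), requireBothLines = FALSE)
  expect_setequal(selL$gene_id, c("g1", "g3", "g4"))
  ## boundary: |log2fc| = 1 and fdr = 0.05 are inclusive
  tab <- degFixture()
  tab$log2fc[tab$gene_id == "g2"] <- -1
  tab$fdr[tab$gene_id == "g2"] <- 0.05
  expect_true("g2" %in% selectConsistentDegs(tab)$gene_id)
})

test_that("direction is invariant to contrast ordering and flags sign conflicts", {
  tab <- degFixture()
  set.seed(1)
  shuffled <- tab[sample(nrow(tab)), ]
  expect_equal(selectConsistentDegs(tab), selectConsistentDegs(shuffled),
               ignore_attr = TRUE)
  ## opposite qualifying signs -> mixed
  conflict <- tab
  conflict$log2fc[conflict$gene_id == "g1" & conflict$stage == "red"] <- 1.2
  selC <- selectConsistentDegs(conflict)
  expect_equal(selC$direction[selC$gene_id == "g1"], "mixed")
})

test_that("direct/indirect classification joins DEGs with promoter binding", {
  selected <- data.frame(gene_id = c("gA", "gB"), direction = c("down", "up"),
                         n_qualifying = 4L)
  maps <- list(
    VL1 = data.frame(gene_id = c("gA", "gC"), peak_name = "p1",
                     level = "VL3", signed_tss_distance = -100),
    VL2 = data.frame(gene_id = c("gA", "gC"), peak_name = "p1",
                     level = "VL3", signed_tss_distance = -100),
    VL3 = data.frame(gene_id = c("gA", "gC"), peak_name = "p1",
                     level = "VL3", signed_tss_distance = -100))
  calls <- classifyDirectIndirect(selected, maps,
                                  universe = c("gA", "gB", "gC", "gD"))
  expect_equal(calls$class[calls$gene_id == "gA"], "direct")
  expect_equal(calls$bound_at[calls$gene_id == "gA"], "VL3")
  expect_equal(calls$class[calls$gene_id == "gB"], "indirect")
  expect_equal(calls$class[calls$gene_id == "gC"], "bound_not_DE")
  expect_equal(calls$class[calls$gene_id == "gD"], "neither")
  ## partition invariant
  s <- summarizeClassification(calls)
  expect_equal(s$n_direct[["VL1"]] + s$n_indirect, s$n_selected)
  expect_equal(unname(s$n_direct), c(1L, 1L, 1L))
})

test_that("homoeolog collapse counts unique groups and unmapped genes", {
  calls <- data.frame(
    gene_id = c("a1", "a2", "a3", "a4", "b1"),
    deg_status = "selected",
    bound_at = c("VL1", "VL1", "VL1", "VL1", "none"),
    class = c(rep("direct", 4), "indirect"),
    direction = "down")
  map <- c(a1 = "HG1", a2 = "HG1", a3 = "HG1", a4 = "HG1")
  col <- collapseToHomoeologs(calls, map)
  d1 <- col[col$class == "direct" & col$level == "VL1", ]
  expect_equal(d1$n_genes, 4L)
  expect_equal(d1$n_unique_homoeologs, 1L)
  ind <- col[col$class == "indirect", ]
  expect_equal(ind$n_unmapped, 1L)   # b1 is not in the map
  ## empty calls -> all zeros
  col0 <- collapseToHomoeologs(calls[0, ], map)
  expect_true(all(col0$n_genes == 0))
  expect_true(all(col0$n_unique_homoeologs == 0))
})

test_that("homoeolog collapse matches a set-based oracle on random calls", {
  set.seed(8)
  genes <- sprintf("g%03d", 1:200)
  map <- stats::setNames(sprintf("HG%02d", sample(1:50, 200, replace = TRUE)),
                         genes)
  calls <- data.frame(
    gene_id = genes, deg_status = sample(c("selected", "not_selected"), 200, TRUE),
    bound_at = sample(c("none", "VL1", "VL2", "VL3"), 200, TRUE),
    direction = "down")
  calls$class <- ifelse(calls$deg_status == "selected" & calls$bound_at != "none",
                        "direct",
                 ifelse(calls$deg_status == "selected", "indirect",
                 ifelse(calls$bound_at != "none", "bound_not_DE", "neither")))
  col <- collapseToHomoeologs(calls, map)
  for (lv in c("VL1", "VL2", "VL3")) {
    rank <- c(VL1 = 1, VL2 = 2, VL3 = 3)
    sub <- calls[calls$class == "direct" &
                   rank[calls$bound_at] >= rank[[lv]], "gene_id"]
    expect_equal(col$n_unique_homoeologs[col$class == "direct" & col$level == lv],
                 length(unique(map[sub])))
  }
})

test_that("classification summaries reproduce printed-ratio arithmetic", {
  mkCalls <- function(nSel, nDirect, nDown, nUp) {
    ## nDown + nUp <= nDirect; remaining direct genes get mixed direction
    direction <- c(rep("down", nDown), rep("up", nUp),
                   rep("mixed", nDirect - nDown - nUp),
                   rep("down", nSel - nDirect))
    data.frame(
      gene_id = sprintf("g%04d", seq_len(nSel)),
      deg_status = "selected",
      bound_at = c(rep("VL1", nDirect), rep("none", nSel - nDirect)),
      class = c(rep("direct", nDirect), rep("indirect", nSel - nDirect)),
      direction = direction)
  }
  s <- summarizeClassification(mkCalls(6109, 934, 500, 434))
  expect_equal(unname(s$pct_direct[["VL1"]]), 15.3)
  expect_equal(unname(s$pct_indirect), 84.7)

  s2 <- summarizeClassification(mkCalls(6109, 950, 581, 369))
  expect_equal(unname(s2$pct_down[["VL1"]]), 61.2)
  expect_equal(unname(s2$pct_up[["VL1"]]), 38.8)

  ## zero direct targets with a non-empty selection is 0.0, not NA
  s3 <- summarizeClassification(mkCalls(100, 0, 0, 0))
  expect_equal(unname(s3$pct_direct[["VL1"]]), 0)
  ## no selected genes -> NA percentages
  empty <- mkCalls(10, 0, 0, 0)
  empty$deg_status <- "not_selected"
  empty$class <- "neither"
  s4 <- summarizeClassification(empty)
  expect_true(is.na(s4$pct_direct[["VL1"]]))
})
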