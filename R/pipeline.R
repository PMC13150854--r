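#' Default pipeline parameters
#'
#' @return named list of every tunable of [runPipeline()] with its default:
#'   peak filter (\code{minFold}, \code{maxQ}), validation-level thresholds
#'   (\code{dVl2}, \code{dVl3}, \code{idrMax}, \code{idrScore}), promoter
#'   window (\code{promoterUp}, \code{promoterDown}), DEG selection
#'   (\code{degMinAbsLog2fc}, \code{degMaxFdr}, \code{requireBothLines},
#'   \code{stageRule}), bias test (\code{alpha}, \code{biasCorrect}),
#'   enrichment (\code{binLevel}), proximity filter
#'   (\code{baitCondition}, \code{controlCondition}).
#' @export
pipelineDefaults <- function() {
  list(minFold = 2, maxQ = 0.001,
       dVl2 = 200, dVl3 = 100, idrMax = 0.05, idrScore = "fold_enrichment",
       promoterUp = 2000, promoterDown = 100,
       degMinAbsLog2fc = 1, degMaxFdr = 0.05,
       requireBothLines = TRUE, stageRule = "any_stage",
       alpha = 0.05, biasCorrect = "none",
       binLevel = 2,
       baitCondition = "bait", controlCondition = "control")
}

writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full target-classification pipeline
#'
#' One-shot orchestration of every stage: read inputs, filter replicate
#' peaks, match them, estimate IDR, assign validation levels, annotate
#' peaks and assign promoter targets, select consistent DEGs, classify
#' direct/indirect targets, collapse to homoeologs, test subgenome bias,
#' and (when the inputs are supplied) run functional-bin enrichment of the
#' direct targets and the proximity-labeling filter. All inputs are checked
#' before any stage runs; outputs are deterministic given the inputs.
#'
#' @param inputs named list of file paths: \code{layout}, \code{gff3},
#'   \code{peaksRep1}, \code{peaksRep2}, \code{deg}, \code{homoeologMap};
#'   optional \code{binMap}, \code{proteomics}.
#' @param outDir output directory (created if needed).
#' @param params named list overriding entries of [pipelineDefaults()].
#' @return (invisibly) a list with the in-memory stage results
#'   (\code{pairs}, \code{calls}, \code{summary}, \code{bias}, ...) and
#'   \code{manifest}. Files written: \code{peaks_vl.bed},
#'   \code{feature_annotation.tsv}, \code{tss_profile.tsv},
#'   \code{target_map_VL[123].tsv}, \code{target_calls.tsv},
#'   \code{homoeolog_collapse.tsv}, \code{classification_summary.json},
#'   \code{subgenome_bias.tsv}, optional \code{enrichment.tsv} and
#'   \code{proximity_candidates.tsv}, and \code{manifest.json}.
#' @export
runPipeline <- function(inputs, outDir, params = list()) {
  p <- utils::modifyList(pipelineDefaults(), params)
  required <- c("layout", "gff3", "peaksRep1", "peaksRep2", "deg",
                "homoeologMap")
  missingKeys <- setdiff(required, names(inputs))
  if (length(missingKeys))
    stop("missing input(s): ", paste(missingKeys, collapse = ", "))
  paths <- unlist(inputs)
  absent <- paths[!file.exists(paths)]
  if (length(absent))
    stop("input file(s) not found: ", paste(absent, collapse = ", "))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  manifest <- list(
    tool = paste0("polyChIP ", as.character(utils::packageVersion("polyChIP"))),
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    params = p,
    inputs = as.list(paths),
    checksums = as.list(tools::md5sum(paths)),
    counts = list(), notes = character(0))

  layout <- readGenomeLayout(inputs$layout)
  ann <- readGeneModels(inputs$gff3, layout)
  hmap <- readHomoeologMap(inputs$homoeologMap)
  manifest$counts$n_genes <- length(genes(ann))

  rep1 <- readNarrowPeak(inputs$peaksRep1)
  rep2 <- readNarrowPeak(inputs$peaksRep2)
  manifest$counts$peaks_rep1_raw <- length(rep1)
  manifest$counts$peaks_rep2_raw <- length(rep2)
  rep1f <- filterPeaks(rep1, p$minFold, p$maxQ)
  rep2f <- filterPeaks(rep2, p$minFold, p$maxQ)
  manifest$counts$peaks_rep1_filtered <- length(rep1f)
  manifest$counts$peaks_rep2_filtered <- length(rep2f)

  pairs <- overlapReplicates(rep1f, rep2f)
  manifest$counts$pairs_matched <- length(pairs)
  idrFit <- NULL
  if (length(pairs) >= 20L) {
    idrFit <- estimateIdr(pairs, score = p$idrScore)
    manifest$counts$idr_pairs_le_0.05 <- sum(globalIdr(idrFit) <= 0.05)
  } else {
    manifest$notes <- c(manifest$notes,
                        "fewer than 20 matched pairs: IDR not estimated, levels from summit distance only")
  }
  pairs <- assignValidationLevels(pairs, idrFit, p$dVl2, p$dVl3, p$idrMax)
  lc <- levelCounts(pairs)
  manifest$counts$pairs_VL1 <- unname(lc["VL1"])
  manifest$counts$pairs_VL2 <- unname(lc["VL2"])
  manifest$counts$pairs_VL3 <- unname(lc["VL3"])
  writePeaksBed(pairs, file.path(outDir, "peaks_vl.bed"))

  feat <- classifyFeature(pairs, ann)
  writeTsv(feat, file.path(outDir, "feature_annotation.tsv"))
  prof <- tssProfile(pairs, ann)
  writeTsv(prof, file.path(outDir, "tss_profile.tsv"))
  maps <- targetMapsByLevel(pairs, ann, p$promoterUp, p$promoterDown)
  for (lv in names(maps))
    writeTsv(maps[[lv]], file.path(outDir, paste0("target_map_", lv, ".tsv")))
  manifest$counts$bound_genes_VL1 <- length(unique(maps$VL1$gene_id))
  manifest$counts$bound_genes_VL2 <- length(unique(maps$VL2$gene_id))
  manifest$counts$bound_genes_VL3 <- length(unique(maps$VL3$gene_id))

  deg <- readDegTable(inputs$deg)
  selected <- selectConsistentDegs(deg, p$degMinAbsLog2fc, p$degMaxFdr,
                                   p$requireBothLines, p$stageRule)
  manifest$counts$degs_selected <- nrow(selected)
  calls <- classifyDirectIndirect(selected, maps,
                                  universe = genes(ann)$gene_id,
                                  homoeologMap = hmap)
  writeTsv(calls, file.path(outDir, "target_calls.tsv"))
  collapse <- collapseToHomoeologs(calls)
  writeTsv(collapse, file.path(outDir, "homoeolog_collapse.tsv"))
  summ <- summarizeClassification(calls)
  summOut <- unclass(summ)
  ## keep level names in the JSON (named atomic vectors drop names otherwise)
  for (f in c("n_direct", "n_down", "n_up", "n_mixed",
              "pct_direct", "pct_down", "pct_up"))
    summOut[[f]] <- as.list(summOut[[f]])
  summOut$selection <- attr(selected, "selection")
  jsonlite::write_json(summOut, file.path(outDir, "classification_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest$counts$direct_VL1 <- unname(summ$n_direct["VL1"])
  manifest$counts$direct_VL3 <- unname(summ$n_direct["VL3"])
  manifest$counts$indirect <- summ$n_indirect

  bias <- subgenomeBiasTest(pairs, layout, p$alpha, p$biasCorrect)
  writeTsv(bias, file.path(outDir, "subgenome_bias.tsv"))

  enr <- NULL
  if (!is.null(inputs$binMap)) {
    binMap <- readBinMap(inputs$binMap)
    directGenes <- calls$gene_id[calls$class == "direct"]
    enr <- enrichBins(directGenes, genes(ann)$gene_id, binMap, p$binLevel)
    writeTsv(enr, file.path(outDir, "enrichment.tsv"))
    manifest$counts$enriched_bins_fdr_0.05 <- sum(enr$fdr <= 0.05)
  }
  prox <- NULL
  if (!is.null(inputs$proteomics)) {
    ev <- readProteinEvidence(inputs$proteomics)
    prox <- filterExclusiveCandidates(ev, bait = p$baitCondition,
                                      control = p$controlCondition)
    writeTsv(data.frame(group_id = prox$retained$group_id,
                        member_proteins = vapply(prox$retained$members,
                                                 paste, "", collapse = ";"),
                        n_peptides = lengths(prox$retained$peptides)),
             file.path(outDir, "proximity_candidates.tsv"))
    manifest$counts$proximity_groups <- prox$summary$n_groups
    manifest$counts$proximity_unique_proteins <- prox$summary$n_unique_proteins
  }

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(pairs = pairs, idrFit = idrFit, features = feat,
                 profile = prof, targetMaps = maps, selected = selected,
                 calls = calls, collapse = collapse, summary = summ,
                 bias = bias, enrichment = enr, proximity = prox,
                 manifest = manifest))
}
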