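#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator with the defaults
#' used throughout the test suite. All randomness flows from \code{seed}
#' through fixed per-stage substreams, so regenerating one stage never
#' perturbs the draws of another.
#'
#' @param seed master seed (integer).
#' @param nGroups homoeologous chromosome groups (default 7).
#' @param subgenomes subgenome labels (default four diploid ancestors).
#' @param chromLengthMean,chromLengthSd chromosome length distribution (bp).
#' @param genesPerChrom genes per chromosome (equal within a group so that
#'   homoeolog quartets are complete).
#' @param nPlantedPeaks reproducible peaks planted at gene promoters (when
#'   more than the number of genes, the excess is placed intergenically).
#' @param summitJitterSd per-replicate summit jitter, Normal(0, sd) bp.
#' @param foldMeanlog,foldSdlog log-normal fold-enrichment excess over the
#'   threshold of 2 (planted peaks always pass the VL1 fold filter).
#' @param scoreNoiseSd per-replicate multiplicative noise on the shared
#'   fold enrichment (log scale sd).
#' @param irreproduciblePeakRate irreproducible noise peaks per replicate,
#'   as a fraction of \code{nPlantedPeaks}.
#' @param weakPeakRate sub-threshold peaks (fold <= 2) per replicate, as a
#'   fraction of \code{nPlantedPeaks}; removed by [filterPeaks()].
#' @param subgenomeBiasMultiplier relative peak-placement weight per
#'   subgenome (length \code{length(subgenomes)}; all 1 = unbiased).
#' @param nPlantedDegs genes planted as consistent DEGs.
#' @param directFraction fraction of planted DEGs drawn from peak-bearing
#'   genes (the planted direct targets).
#' @param degEffectRate rate of the exponential excess over 1 of planted
#'   |log2fc| (every planted DEG passes the two-fold rule).
#' @param downFraction fraction of planted DEGs that are downregulated.
#' @param nullLog2fcSd sd of the null genes' log2fc noise.
#' @param nPlantedInteractors proximity-labeling groups exclusive to bait.
#' @param nBackgroundGroups groups present in both conditions.
#' @param dropoutRate per-replicate probability a planted interactor drops
#'   out of a bait replicate.
#' @return a list of class \code{simulationConfig}.
#' @export
simulationConfig <- function(seed = 1L,
                             nGroups = 7L,
                             subgenomes = c("Fvesca", "Fiinumae",
                                            "Fnipponica", "Fviridis"),
                             chromLengthMean = 3e5, chromLengthSd = 3e4,
                             genesPerChrom = 40L,
                             nPlantedPeaks = 300L,
                             summitJitterSd = 30,
                             foldMeanlog = 0.8, foldSdlog = 0.6,
                             scoreNoiseSd = 0.1,
                             irreproduciblePeakRate = 0.2,
                             weakPeakRate = 0.1,
                             subgenomeBiasMultiplier = rep(1, 4),
                             nPlantedDegs = 400L,
                             directFraction = 0.15,
                             degEffectRate = 1,
                             downFraction = 0.6,
                             nullLog2fcSd = 0.2,
                             nPlantedInteractors = 12L,
                             nBackgroundGroups = 30L,
                             dropoutRate = 0) {
  cfg <- as.list(environment())
  stopifnot(length(cfg$subgenomeBiasMultiplier) == length(cfg$subgenomes),
            cfg$irreproduciblePeakRate >= 0, cfg$irreproduciblePeakRate <= 1,
            cfg$dropoutRate >= 0, cfg$dropoutRate <= 1,
            cfg$directFraction >= 0, cfg$directFraction <= 1,
            cfg$downFraction >= 0, cfg$downFraction <= 1)
  class(cfg) <- "simulationConfig"
  cfg
}

#' Read a simulation configuration from YAML
#'
#' Keys mirror the arguments of [simulationConfig()]; absent keys keep
#' their defaults.
#'
#' @param path YAML file.
#' @return a \code{simulationConfig}.
#' @export
readSimulationConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(simulationConfig))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown simulation config key(s): ", paste(unknown, collapse = ", "))
  do.call(simulationConfig, vals)
}

## Named substreams: each stage reseeds from the master seed so stages are
## independent of each other's parameter changes.
stageSeed <- function(seed, stage) {
  offset <- c(genome = 101L, chip = 211L, deg = 307L, proteomics = 401L)[[stage]]
  (as.integer(seed) %% 20000000L) * 97L + offset
}

#' Simulate a polyploid genome: layout, gene models, homoeolog map
#'
#' Builds \code{nGroups} x \code{length(subgenomes)} chromosomes with genes
#' laid out on a regular grid (equal counts within a group so that every
#' gene belongs to a complete homoeolog quartet), random strands, simple
#' exon/UTR structure, and the quartet homoeolog map. Deterministic under
#' the config seed.
#'
#' @param config a [simulationConfig()].
#' @param dir optional output directory; when given, writes
#'   \code{genome_layout.tsv}, \code{genes.gff3}, \code{homoeolog_map.tsv}.
#' @return a list: \code{layout} ([GenomeLayout-class]), \code{annotation}
#'   ([GeneAnnotation-class]), \code{map} (named vector), \code{paths}
#'   (when \code{dir} given).
#' @export
simulateGenome <- function(config, dir = NULL) {
  set.seed(stageSeed(config$seed, "genome"))
  S <- length(config$subgenomes)
  grid <- expand.grid(sub = seq_len(S), group = seq_len(config$nGroups))
  minLen <- (config$genesPerChrom + 1L) * 7000L
  lens <- pmax(round(stats::rnorm(nrow(grid), config$chromLengthMean,
                                  config$chromLengthSd)),
               minLen)
  chromNames <- sprintf("chr%d%s", grid$group, LETTERS[grid$sub])
  layout <- GenomeLayout(chromNames, lens,
                         config$subgenomes[grid$sub], grid$group)

  geneRows <- list()
  exonsL <- list(); utr5L <- list(); utr3L <- list()
  for (ci in seq_len(nrow(grid))) {
    n <- config$genesPerChrom
    spacing <- lens[ci] %/% (n + 1L)
    centers <- spacing * seq_len(n)
    widths <- sample(1000:3000, n, replace = TRUE)
    starts <- pmax(centers - widths %/% 2L, 3500L)
    ends <- starts + widths - 1L
    strands <- sample(c("+", "-"), n, replace = TRUE)
    ids <- sprintf("G%02d%s_%03d", grid$group[ci], LETTERS[grid$sub[ci]],
                   seq_len(n))
    geneRows[[ci]] <- data.frame(
      chrom = chromNames[ci], start = starts, end = ends, strand = strands,
      gene_id = ids, subgenome = config$subgenomes[grid$sub[ci]],
      hg = sprintf("HG%02d_%03d", grid$group[ci], seq_len(n)),
      stringsAsFactors = FALSE)
    for (k in seq_len(n)) {
      nex <- sample(1:3, 1)
      if (nex == 1) {
        ex <- IRanges(starts[k], ends[k])
      } else {
        cuts <- sort(sample(seq(starts[k] + 100L, ends[k] - 100L, by = 50L),
                            2L * (nex - 1L)))
        bounds <- c(starts[k], cuts, ends[k])
        ex <- IRanges(bounds[seq(1, length(bounds), by = 2)],
                      bounds[seq(2, length(bounds), by = 2)])
      }
      exonsL[[ids[k]]] <- GRanges(chromNames[ci], ex, strand = strands[k])
      if (widths[k] > 800) {
        utrLen <- 150L
        if (strands[k] == "+") {
          utr5L[[ids[k]]] <- GRanges(chromNames[ci],
                                     IRanges(starts[k], starts[k] + utrLen - 1L),
                                     strand = "+")
          utr3L[[ids[k]]] <- GRanges(chromNames[ci],
                                     IRanges(ends[k] - utrLen + 1L, ends[k]),
                                     strand = "+")
        } else {
          utr5L[[ids[k]]] <- GRanges(chromNames[ci],
                                     IRanges(ends[k] - utrLen + 1L, ends[k]),
                                     strand = "-")
          utr3L[[ids[k]]] <- GRanges(chromNames[ci],
                                     IRanges(starts[k], starts[k] + utrLen - 1L),
                                     strand = "-")
        }
      }
    }
  }
  tab <- do.call(rbind, geneRows)
  ord <- order(tab$gene_id)
  tab <- tab[ord, , drop = FALSE]
  gr <- GRanges(tab$chrom, IRanges(tab$start, tab$end), strand = tab$strand)
  mcols(gr) <- DataFrame(gene_id = tab$gene_id,
                         tss = as.integer(ifelse(tab$strand == "+",
                                                 tab$start, tab$end)),
                         subgenome = tab$subgenome)
  toGrl <- function(lst) {
    keep <- tab$gene_id[tab$gene_id %in% names(lst)]
    GRangesList(lst[keep])
  }
  ann <- new("GeneAnnotation", genes = gr, exons = toGrl(exonsL),
             utr5 = toGrl(utr5L), utr3 = toGrl(utr3L), layout = layout)
  map <- stats::setNames(tab$hg, tab$gene_id)

  out <- list(layout = layout, annotation = ann, map = map)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(layout = file.path(dir, "genome_layout.tsv"),
                  gff3 = file.path(dir, "genes.gff3"),
                  map = file.path(dir, "homoeolog_map.tsv"))
    writeGenomeLayout(layout, paths$layout)
    writeGeneModelsGFF3(ann, paths$gff3)
    writeHomoeologMap(map, paths$map)
    out$paths <- paths
  }
  out
}

#' Simulate two ChIP-seq replicate peak sets
#'
#' Plants reproducible peaks at the promoters of sampled genes (sampling
#' weighted by \code{subgenomeBiasMultiplier}, so a non-uniform multiplier
#' plants subgenome binding bias) with a shared fold enrichment and
#' independent per-replicate summit jitter, then adds irreproducible noise
#' peaks and sub-threshold weak peaks independently per replicate.
#'
#' @param config a [simulationConfig()].
#' @param genome result of [simulateGenome()].
#' @param dir optional output directory; writes \code{rep1.narrowPeak} and
#'   \code{rep2.narrowPeak}.
#' @return a list: \code{rep1}, \code{rep2} (\code{GRanges} as from
#'   [readNarrowPeak()]), \code{truth} (data.frame of planted peaks:
#'   \code{peak}, \code{gene_id} (NA for intergenic excess), \code{chrom},
#'   \code{summit}), \code{targetGenes} (gene ids carrying planted promoter
#'   peaks), \code{paths} (when \code{dir} given).
#' @export
simulateChipReplicates <- function(config, genome, dir = NULL) {
  set.seed(stageSeed(config$seed, "chip"))
  ann <- genome$annotation
  g <- genes(ann)
  layoutTab <- layoutTable(genome$layout)
  mult <- stats::setNames(config$subgenomeBiasMultiplier, config$subgenomes)

  nPeaks <- config$nPlantedPeaks
  nOnGenes <- min(nPeaks, length(g))
  w <- mult[g$subgenome]
  targetIdx <- sample(length(g), nOnGenes, prob = w / sum(w))
  tssOff <- sample(-1500:50, nOnGenes, replace = TRUE)
  pos <- as.character(strand(g))[targetIdx] == "+"
  trueSummit <- ifelse(pos, g$tss[targetIdx] + tssOff,
                       g$tss[targetIdx] - tssOff)
  trueChrom <- as.character(seqnames(g))[targetIdx]
  truth <- data.frame(peak = sprintf("planted_%04d", seq_len(nOnGenes)),
                      gene_id = g$gene_id[targetIdx], chrom = trueChrom,
                      summit = as.integer(trueSummit),
                      stringsAsFactors = FALSE)
  nExtra <- nPeaks - nOnGenes
  if (nExtra > 0) {
    cw <- layoutTab$length * mult[layoutTab$subgenome]
    ci <- sample(nrow(layoutTab), nExtra, replace = TRUE, prob = cw / sum(cw))
    truth <- rbind(truth, data.frame(
      peak = sprintf("planted_%04d", nOnGenes + seq_len(nExtra)),
      gene_id = NA_character_, chrom = layoutTab$chrom[ci],
      summit = as.integer(stats::runif(nExtra, 5000,
                                       layoutTab$length[ci] - 5000)),
      stringsAsFactors = FALSE))
  }
  nAll <- nrow(truth)
  sharedFold <- 2 + stats::rlnorm(nAll, config$foldMeanlog, config$foldSdlog)
  sharedQ <- 3.05 + stats::rexp(nAll, 0.5)

  makeRep <- function(repName) {
    jitter <- if (config$summitJitterSd > 0)
      round(stats::rnorm(nAll, 0, config$summitJitterSd)) else 0L
    summit <- pmax(truth$summit + jitter, 200L)
    fold <- sharedFold * exp(stats::rnorm(nAll, 0, config$scoreNoiseSd))
    fold <- pmax(fold, 2.0001)
    q <- pmax(sharedQ + stats::rnorm(nAll, 0, 0.2), 3.01)
    gr <- GRanges(truth$chrom, IRanges(pmax(summit - 150L, 1L), summit + 150L))
    mcols(gr) <- DataFrame(
      name = paste0(repName, "_", truth$peak), score = 0L,
      foldEnrichment = fold, negLog10P = q + 1, negLog10Q = q,
      summit = as.integer(summit))
    nNoise <- round(nPeaks * config$irreproduciblePeakRate)
    nWeak <- round(nPeaks * config$weakPeakRate)
    extras <- function(n, prefix, foldv, qv) {
      if (n <= 0) return(NULL)
      ci <- sample(nrow(layoutTab), n, replace = TRUE,
                   prob = layoutTab$length / sum(layoutTab$length))
      s <- as.integer(stats::runif(n, 2000, layoutTab$length[ci] - 2000))
      e <- GRanges(layoutTab$chrom[ci], IRanges(s - 150L, s + 150L))
      mcols(e) <- DataFrame(
        name = sprintf("%s_%s_%04d", repName, prefix, seq_len(n)), score = 0L,
        foldEnrichment = foldv, negLog10P = qv + 1, negLog10Q = qv,
        summit = s)
      e
    }
    noise <- extras(nNoise, "noise",
                    2 + stats::rlnorm(max(nNoise, 0), config$foldMeanlog,
                                      config$foldSdlog),
                    3.05 + stats::rexp(max(nNoise, 0), 0.5))
    weak <- extras(nWeak, "weak",
                   stats::runif(max(nWeak, 0), 0.5, 2),
                   3.05 + stats::rexp(max(nWeak, 0), 0.5))
    out <- gr
    for (extra in list(noise, weak)) {
      if (is.null(extra)) next
      GenomeInfoDb::seqlevels(out) <- layoutTab$chrom
      GenomeInfoDb::seqlevels(extra) <- layoutTab$chrom
      out <- c(out, extra)
    }
    out[order(as.character(seqnames(out)), start(out))]
  }
  rep1 <- makeRep("r1")
  rep2 <- makeRep("r2")

  out <- list(rep1 = rep1, rep2 = rep2, truth = truth,
              targetGenes = truth$gene_id[!is.na(truth$gene_id)])
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(rep1 = file.path(dir, "rep1.narrowPeak"),
                  rep2 = file.path(dir, "rep2.narrowPeak"))
    writeNarrowPeak(rep1, paths$rep1)
    writeNarrowPeak(rep2, paths$rep2)
    out$paths <- paths
  }
  out
}

#' Simulate a differential-expression table with planted targets
#'
#' Plants \code{nPlantedDegs} consistent DEGs: a \code{directFraction}
#' share drawn from the peak-bearing genes (the planted direct targets),
#' the rest from unbound genes (planted indirect targets). Planted genes
#' get |log2fc| >= 1 (1 + exponential excess) with the same sign in every
#' contrast and FDR <= 0.045 in both synthetic RNAi lines and both stages;
#' null genes get Normal(0, \code{nullLog2fcSd}) effects and uniform FDR.
#'
#' @param config a [simulationConfig()].
#' @param genome result of [simulateGenome()].
#' @param targetGenes gene ids carrying planted promoter peaks (from
#'   [simulateChipReplicates()]).
#' @param dir optional output directory; writes \code{deg_table.tsv}.
#' @return a list: \code{table} (long-format data.frame), \code{direct},
#'   \code{indirect} (planted gene id vectors), \code{path} (when
#'   \code{dir} given).
#' @export
simulateDegTable <- function(config, genome, targetGenes, dir = NULL) {
  set.seed(stageSeed(config$seed, "deg"))
  allGenes <- genes(genome$annotation)$gene_id
  targetGenes <- intersect(unique(targetGenes), allGenes)
  nDirect <- min(round(config$directFraction * config$nPlantedDegs),
                 length(targetGenes))
  direct <- sort(sample(targetGenes, nDirect))
  unbound <- setdiff(allGenes, targetGenes)
  nIndirect <- min(config$nPlantedDegs - nDirect, length(unbound))
  indirect <- sort(sample(unbound, nIndirect))
  planted <- c(direct, indirect)

  lines <- c("RNAi_3", "RNAi_11")
  stages <- c("white", "red")
  grid <- expand.grid(gene_id = allGenes, line = lines, stage = stages,
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$gene_id, grid$line, grid$stage), , drop = FALSE]
  isPlanted <- grid$gene_id %in% planted

  sign <- stats::setNames(ifelse(stats::runif(length(planted)) <
                                   config$downFraction, -1, 1), planted)
  base <- stats::setNames(1 + stats::rexp(length(planted),
                                          config$degEffectRate), planted)
  lfc <- stats::rnorm(nrow(grid), 0, config$nullLog2fcSd)
  lfc[isPlanted] <- sign[grid$gene_id[isPlanted]] *
    (base[grid$gene_id[isPlanted]] +
       stats::runif(sum(isPlanted), 0, 0.2))
  fdr <- stats::runif(nrow(grid))
  fdr[isPlanted] <- stats::runif(sum(isPlanted), 0, 0.045)
  tab <- data.frame(gene_id = grid$gene_id, line = grid$line,
                    stage = grid$stage, log2fc = round(lfc, 4),
                    fdr = signif(fdr, 4), stringsAsFactors = FALSE)
  out <- list(table = tab, direct = direct, indirect = indirect)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    out$path <- file.path(dir, "deg_table.tsv")
    utils::write.table(tab, out$path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  out
}

#' Simulate proximity-labeling protein-group evidence
#'
#' Planted interactor groups are present in every bait replicate (subject
#' to \code{dropoutRate}) and absent from every control replicate;
#' background groups are present in both conditions. Three replicates per
#' condition.
#'
#' @param config a [simulationConfig()].
#' @param dir optional output directory; writes \code{proteomics.tsv}.
#' @return a list: \code{table} (evidence data.frame), \code{planted}
#'   (group ids of planted interactors), \code{path} (when \code{dir}
#'   given).
#' @export
simulateProteomics <- function(config, dir = NULL) {
  set.seed(stageSeed(config$seed, "proteomics"))
  nP <- config$nPlantedInteractors
  nB <- config$nBackgroundGroups
  nGroups <- nP + nB
  pool <- sprintf("PROT%04d", seq_len(nGroups * 3))
  gid <- sprintf("PG%03d", seq_len(nGroups))
  planted <- gid[seq_len(nP)]
  members <- vapply(seq_len(nGroups), function(i) {
    k <- sample(1:4, 1)
    paste(sample(pool, k), collapse = ";")
  }, character(1))
  pepCounter <- 0L
  peptides <- vapply(seq_len(nGroups), function(i) {
    k <- sample(5:40, 1)
    ids <- sprintf("pep%05d", pepCounter + seq_len(k))
    pepCounter <<- pepCounter + k
    paste(ids, collapse = ";")
  }, character(1))
  pres <- matrix(0L, nGroups, 6,
                 dimnames = list(gid, c(paste0("bait_", 1:3),
                                        paste0("control_", 1:3))))
  for (i in seq_len(nP))
    pres[i, 1:3] <- as.integer(stats::runif(3) >= config$dropoutRate)
  for (i in nP + seq_len(nB)) {
    pres[i, ] <- as.integer(stats::runif(6) < 0.8)
    pres[i, 4] <- 1L     # background is by construction seen in the control
  }
  tab <- data.frame(group_id = gid, member_proteins = members,
                    peptide_ids = peptides, stringsAsFactors = FALSE)
  tab <- cbind(tab, as.data.frame(pres))
  out <- list(table = tab, planted = planted)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    out$path <- file.path(dir, "proteomics.tsv")
    utils::write.table(tab, out$path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  out
}
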