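suppressPackageStartupMessages({
  library(GenomicRanges)
  library(S4Vectors)
  library(IRanges)
})

## Build a peak GRanges from plain vectors (same mcols as readNarrowPeak).
makePeaks <- function(chrom, start, end, summit, fold = 5, q = 5,
                      name = sprintf("p%03d", seq_along(start))) {
  gr <- GRanges(chrom, IRanges(start, end))
  mcols(gr) <- DataFrame(name = name, score = 0L,
                         foldEnrichment = rep_len(fold, length(gr)),
                         negLog10P = rep_len(q + 1, length(gr)),
                         negLog10Q = rep_len(q, length(gr)),
                         summit = as.integer(summit))
  gr
}

## Build a matched-pair GRanges directly (same mcols as overlapReplicates).
makePairs <- function(chrom, start, end, summitDistance,
                      summit = (start + end) %/% 2L,
                      fold1 = 5, fold2 = 5, q1 = 5, q2 = 5,
                      name = sprintf("pair%03d", seq_along(start))) {
  gr <- GRanges(chrom, IRanges(start, end))
  mcols(gr) <- DataFrame(name = name, name1 = paste0(name, "_1"),
                         name2 = paste0(name, "_2"),
                         summit1 = as.integer(summit),
                         summit2 = as.integer(summit + summitDistance),
                         summit = as.integer(summit),
                         summitDistance = as.integer(summitDistance),
                         fold1 = rep_len(fold1, length(gr)),
                         fold2 = rep_len(fold2, length(gr)),
                         q1 = rep_len(q1, length(gr)),
                         q2 = rep_len(q2, length(gr)))
  gr
}

## An IdrFit with prescribed global IDR values (local set equal to global,
## which satisfies the monotonicity validity).
fakeIdrFit <- function(idr) {
  o <- order(idr)
  glob <- numeric(length(idr))
  glob[o] <- cumsum(sort(idr)) / seq_along(idr)
  ## keep the prescribed values as global by using them directly: local =
  ## global = idr is valid as long as sorting idr gives non-decreasing idr
  new("IdrFit", p = 0.9, mu = 2, sigma = 1, rho = 0.8,
      localIdr = idr, globalIdr = idr,
      loglik = c(-10, -5), converged = TRUE)
}

## A small two-gene annotation on one chromosome for hand-checked cases.
##   gPlus:  10000..12000 on + (TSS 10000), exons 10000..10600, 11000..12000
##   gMinus: 30000..32000 on - (TSS 32000)
toyAnnotation <- function() {
  layout <- GenomeLayout(chrom = "chr1", length = 50000L,
                         subgenome = "A", group = 1L)
  g <- GRanges("chr1", IRanges(c(10000L, 30000L), c(12000L, 32000L)),
               strand = c("+", "-"))
  mcols(g) <- DataFrame(gene_id = c("gPlus", "gMinus"),
                        tss = c(10000L, 32000L),
                        subgenome = c("A", "A"))
  exons <- GRangesList(
    gPlus = GRanges("chr1", IRanges(c(10000L, 11000L), c(10600L, 12000L)),
                    strand = "+"),
    gMinus = GRanges("chr1", IRanges(30000L, 32000L), strand = "-"))
  new("GeneAnnotation", genes = g, exons = exons,
      utr5 = GRangesList(), utr3 = GRangesList(), layout = layout)
}

## ---- independent brute-force oracles -------------------------------------

## Quadratic all-pairs replicate matching with the nearest-summit /
## larger-overlap / lexicographic greedy rule.
oracleOverlap <- function(rep1, rep2) {
  cand <- list()
  for (i in seq_along(rep1)) {
    for (j in seq_along(rep2)) {
      if (as.character(seqnames(rep1))[i] != as.character(seqnames(rep2))[j])
        next
      lo <- max(start(rep1)[i], start(rep2)[j])
      hi <- min(end(rep1)[i], end(rep2)[j])
      if (lo > hi) next
      cand[[length(cand) + 1L]] <- data.frame(
        i = i, j = j, dist = abs(rep1$summit[i] - rep2$summit[j]),
        ovl = hi - lo + 1L, n1 = rep1$name[i], n2 = rep2$name[j])
    }
  }
  if (!length(cand)) return(data.frame(n1 = character(0), n2 = character(0)))
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$dist, -cand$ovl, cand$n1, cand$n2), , drop = FALSE]
  used1 <- used2 <- character(0)
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (!(cand$n1[k] %in% used1) && !(cand$n2[k] %in% used2)) {
      keep[k] <- TRUE
      used1 <- c(used1, cand$n1[k]); used2 <- c(used2, cand$n2[k])
    }
  }
  out <- cand[keep, c("n1", "n2")]
  out[order(out$n1), , drop = FALSE]
}

## Per-peak feature classification by direct rule evaluation.
oracleClassify <- function(summitPos, summitChrom, ann) {
  g <- polyChIP::genes(ann)
  exons <- polyChIP::geneExons(ann)
  utr5 <- ann@utr5; utr3 <- ann@utr3
  prio <- c("promoter_0_1kb", "promoter_1_2kb", "promoter_2_3kb",
            "five_prime_utr", "three_prime_utr", "exon", "intron",
            "downstream_0_3kb", "distal_intergenic")
  n <- length(summitPos)
  out <- data.frame(category = rep("distal_intergenic", n),
                    gene_id = NA_character_, d = NA_real_)
  inAny <- function(pos, gr) length(gr) && any(pos >= start(gr) & pos <= end(gr))
  for (pk in seq_len(n)) {
    pos <- summitPos[pk]
    cands <- list()
    for (gi in seq_along(g)) {
      if (as.character(seqnames(g))[gi] != summitChrom[pk]) next
      str <- as.character(strand(g))[gi]
      d <- if (str == "+") pos - g$tss[gi] else g$tss[gi] - pos
      id <- g$gene_id[gi]
      cat <- NULL
      if (d >= -1000 && d <= -1) cat <- "promoter_0_1kb"
      else if (d >= -2000 && d <= -1001) cat <- "promoter_1_2kb"
      else if (d >= -3000 && d <= -2001) cat <- "promoter_2_3kb"
      else if (pos >= start(g)[gi] && pos <= end(g)[gi]) {
        cat <- if (id %in% names(utr5) && inAny(pos, utr5[[id]])) "five_prime_utr"
        else if (id %in% names(utr3) && inAny(pos, utr3[[id]])) "three_prime_utr"
        else if (id %in% names(exons) && inAny(pos, exons[[id]])) "exon"
        else "intron"
      } else {
        past3p <- if (str == "+") pos - end(g)[gi] else start(g)[gi] - pos
        if (past3p >= 1 && past3p <= 3000) cat <- "downstream_0_3kb"
      }
      if (!is.null(cat))
        cands[[length(cands) + 1L]] <- data.frame(cat = cat, id = id, d = d)
    }
    if (!length(cands)) next
    cands <- do.call(rbind, cands)
    cands$prio <- match(cands$cat, prio)
    cands <- cands[order(cands$prio, abs(cands$d), cands$d >= 0, cands$id), ,
                   drop = FALSE]
    out$category[pk] <- cands$cat[1]
    out$gene_id[pk] <- cands$id[1]
    out$d[pk] <- cands$d[1]
  }
  out
}

## Brute-force promoter containment scan.
oracleTargets <- function(summitPos, summitChrom, ann, up = 2000, down = 100) {
  g <- polyChIP::genes(ann)
  hits <- list()
  for (gi in seq_along(g)) {
    for (pk in seq_along(summitPos)) {
      if (as.character(seqnames(g))[gi] != summitChrom[pk]) next
      str <- as.character(strand(g))[gi]
      d <- if (str == "+") summitPos[pk] - g$tss[gi] else g$tss[gi] - summitPos[pk]
      if (d >= -up && d <= down)
        hits[[length(hits) + 1L]] <- data.frame(gene_id = g$gene_id[gi],
                                                peak = pk, d = d)
    }
  }
  if (!length(hits)) return(data.frame(gene_id = character(0), peak = integer(0)))
  out <- do.call(rbind, hits)
  out[order(out$gene_id, out$peak), , drop = FALSE]
}

## Exact hypergeometric upper tail by direct summation of the pmf.
oracleHyperTail <- function(k, K, N, n) {
  js <- k:min(n, K)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}
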