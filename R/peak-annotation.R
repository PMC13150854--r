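#' @importFrom S4Vectors queryHits subjectHits
NULL

featureCategories <- c("promoter_0_1kb", "promoter_1_2kb", "promoter_2_3kb",
                       "five_prime_utr", "exon", "intron", "three_prime_utr",
                       "downstream_0_3kb", "distal_intergenic")

## Signed strand-oriented distance from a gene's TSS: negative = upstream of
## transcription, positive = downstream.
signedTssDistance <- function(pos, tss, strandChar) {
  ifelse(strandChar == "+", pos - tss, tss - pos)
}

summitPoints <- function(pairs) {
  GRanges(seqnames(pairs), IRanges(pairs$summit, width = 1L))
}

## One window GRanges per gene for a strand-oriented offset band
## [from, to] (offsets relative to the TSS in transcription direction).
tssBandWindows <- function(g, from, to) {
  pos <- as.character(strand(g)) == "+"
  s <- ifelse(pos, g$tss + from, g$tss - to)
  e <- ifelse(pos, g$tss + to, g$tss - from)
  keep <- e >= 1
  gr <- GRanges(seqnames(g)[keep], IRanges(pmax(s[keep], 1), e[keep]))
  gr$gene_id <- g$gene_id[keep]
  gr
}

unlistWithGene <- function(grl) {
  flat <- unlist(grl, use.names = FALSE)
  if (length(flat)) flat$gene_id <- rep(names(grl), lengths(grl))
  else mcols(flat)$gene_id <- character(0)
  flat
}

downstreamWindows <- function(g, len = 3000L) {
  pos <- as.character(strand(g)) == "+"
  s <- ifelse(pos, end(g) + 1L, start(g) - len)
  e <- ifelse(pos, end(g) + len, start(g) - 1L)
  keep <- e >= 1
  gr <- GRanges(seqnames(g)[keep], IRanges(pmax(s[keep], 1), e[keep]))
  gr$gene_id <- g$gene_id[keep]
  gr
}

## Pick, per query point, the best gene among category hits: nearest |TSS
## distance|, upstream preferred on ties, then lexicographic gene_id.
pickBestGene <- function(hitQ, hitGene, d) {
  ord <- order(hitQ, abs(d), d >= 0, hitGene)
  first <- !duplicated(hitQ[ord])
  list(q = hitQ[ord][first], gene = hitGene[ord][first], d = d[ord][first])
}

#' Classify reproducible peaks by genomic feature
#'
#' Assigns each peak (evaluated at its merged summit, the midpoint of the
#' two replicate summits) exactly one feature category, by fixed priority:
#' promoter tiers (0-1, 1-2, 2-3 kb upstream of a TSS), 5' UTR, 3' UTR,
#' exon, intron, downstream (0-3 kb past the gene 3' end), distal
#' intergenic. Within a category, the gene with the nearest TSS wins
#' (upstream preferred on exact distance ties, then lexicographic gene_id).
#'
#' @param pairs \code{GRanges} of matched peaks with a \code{summit} mcol.
#' @param ann a [GeneAnnotation-class].
#' @return \code{data.frame} with one row per peak: \code{name},
#'   \code{category} (factor over all categories), \code{gene_id} (NA for
#'   distal intergenic), \code{signed_tss_distance} (bp; negative =
#'   upstream; NA for distal intergenic).
#' @export
classifyFeature <- function(pairs, ann) {
  g <- genes(ann)
  pts <- summitPoints(pairs)
  n <- length(pairs)
  category <- rep("distal_intergenic", n)
  geneId <- rep(NA_character_, n)
  dist <- rep(NA_real_, n)
  geneById <- stats::setNames(seq_along(g), g$gene_id)

  tryCategory <- function(windows, label) {
    open <- which(category == "distal_intergenic")
    if (!length(open) || !length(windows)) return()
    hits <- findOverlaps(pts[open], windows)
    if (!length(hits)) return()
    qi <- open[queryHits(hits)]
    gid <- windows$gene_id[subjectHits(hits)]
    gi <- geneById[gid]
    d <- signedTssDistance(pairs$summit[qi], g$tss[gi],
                           as.character(strand(g))[gi])
    best <- pickBestGene(qi, gid, d)
    category[best$q] <<- label
    geneId[best$q] <<- best$gene
    dist[best$q] <<- best$d
  }

  tryCategory(tssBandWindows(g, -1000L, -1L), "promoter_0_1kb")
  tryCategory(tssBandWindows(g, -2000L, -1001L), "promoter_1_2kb")
  tryCategory(tssBandWindows(g, -3000L, -2001L), "promoter_2_3kb")
  tryCategory(unlistWithGene(ann@utr5), "five_prime_utr")
  tryCategory(unlistWithGene(ann@utr3), "three_prime_utr")
  tryCategory(unlistWithGene(geneExons(ann)), "exon")
  body <- g; body$gene_id <- g$gene_id
  tryCategory(body, "intron")
  tryCategory(downstreamWindows(g), "downstream_0_3kb")

  data.frame(name = pairs$name,
             category = factor(category, levels = featureCategories),
             gene_id = geneId,
             signed_tss_distance = dist,
             stringsAsFactors = FALSE)
}

#' Profile peak summits around transcription start sites
#'
#' Bins the strand-oriented signed distance from each peak summit to its
#' nearest TSS over \code{[-halfWindow, +halfWindow]}. Peaks with no TSS
#' inside the window are excluded from the total. Nearest-TSS ties prefer
#' the gene the peak is upstream of, then the lexicographically smaller
#' gene_id.
#'
#' @param pairs \code{GRanges} of matched peaks with a \code{summit} mcol.
#' @param ann a [GeneAnnotation-class].
#' @param halfWindow half-width of the profile window in bp (default 3000).
#' @param bin bin width in bp (default 50); must divide \code{2 * halfWindow}.
#' @return \code{data.frame} with columns \code{bin_start}, \code{bin_end}
#'   (signed offsets, half-open \code{[bin_start, bin_end)} except the last
#'   bin which is closed), \code{count}; attribute \code{total_in_window}
#'   holds the number of binned peaks.
#' @export
tssProfile <- function(pairs, ann, halfWindow = 3000L, bin = 50L) {
  if (bin <= 0) stop("bin width must be positive")
  if ((2 * halfWindow) %% bin != 0)
    stop("bin must divide 2 * halfWindow")
  g <- genes(ann)
  pts <- summitPoints(pairs)
  win <- GRanges(seqnames(g),
                 IRanges(pmax(g$tss - halfWindow, 1), g$tss + halfWindow))
  hits <- findOverlaps(pts, win)
  edges <- seq(-halfWindow, halfWindow, by = bin)
  counts <- integer(length(edges) - 1L)
  total <- 0L
  if (length(hits)) {
    qi <- queryHits(hits); gi <- subjectHits(hits)
    d <- signedTssDistance(pairs$summit[qi], g$tss[gi],
                           as.character(strand(g))[gi])
    keep <- abs(d) <= halfWindow   # strand-oriented window, re-checked signed
    best <- pickBestGene(qi[keep], g$gene_id[gi][keep], d[keep])
    idx <- pmin(floor((best$d + halfWindow) / bin) + 1L, length(counts))
    tab <- table(factor(idx, levels = seq_along(counts)))
    counts <- as.integer(tab)
    total <- length(best$q)
  }
  out <- data.frame(bin_start = edges[-length(edges)],
                    bin_end = edges[-1L],
                    count = counts)
  attr(out, "total_in_window") <- total
  out
}

#' Promoter windows of all genes
#'
#' Strand-oriented windows from \code{up} bp upstream to \code{down} bp
#' downstream of each TSS (both ends inclusive).
#'
#' @param ann a [GeneAnnotation-class].
#' @param up,down window extent in bp (defaults 2000 and 100).
#' @return \code{GRanges} with a \code{gene_id} mcol.
#' @export
promoterWindows <- function(ann, up = 2000L, down = 100L) {
  tssBandWindows(genes(ann), -as.integer(up), as.integer(down))
}

#' Assign peaks to candidate target genes via promoter windows
#'
#' A gene is a candidate target when at least one peak summit falls within
#' its promoter window (from \code{up} bp upstream to \code{down} bp
#' downstream of the TSS, strand-oriented, inclusive). One peak may support
#' several genes (divergent promoters).
#'
#' @param pairs \code{GRanges} of matched peaks with \code{summit} (and
#'   optionally \code{level}) mcols.
#' @param ann a [GeneAnnotation-class].
#' @param up,down promoter extent in bp (defaults 2000 and 100).
#' @return \code{data.frame} with one row per gene-peak support:
#'   \code{gene_id}, \code{peak_name}, \code{level} (NA when peaks carry no
#'   level), \code{signed_tss_distance}.
#' @export
assignTargetGenes <- function(pairs, ann, up = 2000L, down = 100L) {
  g <- genes(ann)
  win <- promoterWindows(ann, up, down)
  pts <- summitPoints(pairs)
  hits <- findOverlaps(pts, win)
  if (!length(hits))
    return(data.frame(gene_id = character(0), peak_name = character(0),
                      level = character(0), signed_tss_distance = numeric(0),
                      stringsAsFactors = FALSE))
  qi <- queryHits(hits)
  gid <- win$gene_id[subjectHits(hits)]
  gi <- match(gid, g$gene_id)
  d <- signedTssDistance(pairs$summit[qi], g$tss[gi],
                         as.character(strand(g))[gi])
  lv <- if (!is.null(pairs$level)) pairs$level[qi] else NA_character_
  out <- data.frame(gene_id = gid, peak_name = pairs$name[qi],
                    level = lv, signed_tss_distance = d,
                    stringsAsFactors = FALSE)
  out[order(out$gene_id, out$peak_name), , drop = FALSE]
}

#' Per-level candidate target maps
#'
#' Builds the cumulative promoter target map at each validation level:
#' the VL2 map uses only pairs at VL2 or VL3, and so on.
#'
#' @inheritParams assignTargetGenes
#' @return named list of [assignTargetGenes()] data.frames for
#'   \code{"VL1"}, \code{"VL2"}, \code{"VL3"}.
#' @export
targetMapsByLevel <- function(pairs, ann, up = 2000L, down = 100L) {
  stats::setNames(lapply(c("VL1", "VL2", "VL3"), function(lv)
    assignTargetGenes(pairsAtLevel(pairs, lv), ann, up, down)),
    c("VL1", "VL2", "VL3"))
}
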