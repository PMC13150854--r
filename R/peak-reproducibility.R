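#' Filter peaks on fold enrichment and q-value
#'
#' Keeps peaks with fold enrichment strictly greater than \code{minFold} and
#' q-value strictly below \code{maxQ}. These are the per-replicate quality
#' thresholds applied before replicate matching (the VL1 tier is the matched
#' set of peaks passing them in both replicates).
#'
#' @param peaks \code{GRanges} from [readNarrowPeak()].
#' @param minFold minimum fold enrichment (exclusive; default 2).
#' @param maxQ maximum q-value (exclusive; default 0.001). Compared against
#'   \code{10^-negLog10Q}.
#' @return the filtered \code{GRanges}.
#' @examples
#' \dontrun{keep <- filterPeaks(peaks, minFold = 2, maxQ = 0.001)}
#' @export
filterPeaks <- function(peaks, minFold = 2, maxQ = 0.001) {
  stopifnot(minFold > 0, maxQ > 0)
  peaks[peaks$foldEnrichment > minFold & peaks$negLog10Q > -log10(maxQ)]
}

#' Match peaks across two biological replicates
#'
#' Pairs peaks that overlap by at least one bp on the same chromosome. When
#' a peak overlaps several partners, pairs are ranked by summit distance
#' (nearest wins), then by larger overlap length, then lexicographically by
#' the two peak names, and accepted greedily so that each peak joins at most
#' one pair. The procedure is symmetric: swapping the replicates yields the
#' same matched set.
#'
#' @param rep1,rep2 \code{GRanges} of filtered peaks (see [readNarrowPeak()]).
#' @return \code{GRanges} of merged intervals (union of the paired peaks)
#'   with mcols \code{name} (pair name \code{name1|name2}), \code{name1},
#'   \code{name2}, \code{summit1}, \code{summit2}, \code{summit} (midpoint of
#'   the two summits), \code{summitDistance}, \code{fold1}, \code{fold2},
#'   \code{q1}, \code{q2} (the -log10 q scores).
#' @export
overlapReplicates <- function(rep1, rep2) {
  shared <- union(GenomeInfoDb::seqlevels(rep1), GenomeInfoDb::seqlevels(rep2))
  GenomeInfoDb::seqlevels(rep1) <- shared
  GenomeInfoDb::seqlevels(rep2) <- shared
  hits <- findOverlaps(rep1, rep2, minoverlap = 1L)
  if (!length(hits)) return(emptyPairSet())
  i <- S4Vectors::queryHits(hits); j <- S4Vectors::subjectHits(hits)
  sdist <- abs(rep1$summit[i] - rep2$summit[j])
  ovl <- width(IRanges::pintersect(IRanges::ranges(rep1)[i],
                                   IRanges::ranges(rep2)[j]))
  ord <- order(sdist, -ovl, rep1$name[i], rep2$name[j])
  used1 <- logical(length(rep1)); used2 <- logical(length(rep2))
  keep <- integer(0)
  for (k in ord) {
    if (!used1[i[k]] && !used2[j[k]]) {
      keep <- c(keep, k)
      used1[i[k]] <- TRUE; used2[j[k]] <- TRUE
    }
  }
  i <- i[keep]; j <- j[keep]
  merged <- GRanges(seqnames(rep1)[i],
                    IRanges(pmin(start(rep1)[i], start(rep2)[j]),
                            pmax(end(rep1)[i], end(rep2)[j])))
  mcols(merged) <- DataFrame(
    name = paste0(rep1$name[i], "|", rep2$name[j]),
    name1 = rep1$name[i], name2 = rep2$name[j],
    summit1 = rep1$summit[i], summit2 = rep2$summit[j],
    summit = as.integer(round((rep1$summit[i] + rep2$summit[j]) / 2)),
    summitDistance = abs(rep1$summit[i] - rep2$summit[j]),
    fold1 = rep1$foldEnrichment[i], fold2 = rep2$foldEnrichment[j],
    q1 = rep1$negLog10Q[i], q2 = rep2$negLog10Q[j])
  merged[order(as.character(seqnames(merged)), start(merged), merged$name)]
}

emptyPairSet <- function() {
  gr <- GRanges()
  mcols(gr) <- DataFrame(
    name = character(0), name1 = character(0), name2 = character(0),
    summit1 = integer(0), summit2 = integer(0), summit = integer(0),
    summitDistance = integer(0),
    fold1 = numeric(0), fold2 = numeric(0),
    q1 = numeric(0), q2 = numeric(0))
  gr
}

#' Assign nested validation levels to matched replicate peaks
#'
#' Implements the tiered confidence scheme for reproducible binding sites:
#' every matched pair is at least VL1 (found in both replicates after the
#' per-replicate fold/q filter); pairs with summit distance at most
#' \code{dVl2} bp and IDR at most \code{idrMax} are VL2; pairs with summit
#' distance at most \code{dVl3} bp and IDR at most \code{idrMax} are VL3.
#' Levels are nested: the VL3 set is a subset of VL2, which is a subset of
#' VL1, when read cumulatively (a pair labelled VL3 also satisfies VL2 and
#' VL1).
#'
#' @param pairs \code{GRanges} from [overlapReplicates()].
#' @param idrFit an [IdrFit-class] from [estimateIdr()] on the same pairs,
#'   or \code{NULL} to skip the IDR condition (summit distance only).
#' @param dVl2,dVl3 summit-distance thresholds in bp (inclusive; defaults
#'   200 and 100).
#' @param idrMax IDR threshold (inclusive; default 0.05), applied to the
#'   global IDR.
#' @return \code{pairs} with added mcols \code{idr} (global IDR, NA when no
#'   fit is supplied) and \code{level} (\code{"VL1"}, \code{"VL2"},
#'   \code{"VL3"}).
#' @export
assignValidationLevels <- function(pairs, idrFit = NULL,
                                   dVl2 = 200, dVl3 = 100, idrMax = 0.05) {
  stopifnot(dVl3 <= dVl2)
  if (is.null(idrFit)) {
    idr <- rep(NA_real_, length(pairs))
    idrOk <- rep(TRUE, length(pairs))
  } else {
    stopifnot(is(idrFit, "IdrFit"),
              length(globalIdr(idrFit)) == length(pairs))
    idr <- globalIdr(idrFit)
    idrOk <- idr <= idrMax
  }
  sd <- pairs$summitDistance
  level <- ifelse(sd <= dVl3 & idrOk, "VL3",
                  ifelse(sd <= dVl2 & idrOk, "VL2", "VL1"))
  pairs$idr <- idr
  pairs$level <- level
  pairs
}

#' Count pairs at each cumulative validation level
#'
#' @param pairs \code{GRanges} with a \code{level} mcol.
#' @return named integer vector \code{c(VL1 = , VL2 = , VL3 = )} where each
#'   count includes the stricter tiers (VL1 counts everything).
#' @export
levelCounts <- function(pairs) {
  lv <- factor(pairs$level, levels = c("VL1", "VL2", "VL3"))
  n <- table(lv)
  c(VL1 = sum(n), VL2 = unname(n["VL2"] + n["VL3"]), VL3 = unname(n["VL3"]))
}

#' Subset pairs at a cumulative validation level
#'
#' @param pairs \code{GRanges} with a \code{level} mcol.
#' @param level \code{"VL1"}, \code{"VL2"} or \code{"VL3"}.
#' @return the pairs whose level is at least \code{level}.
#' @export
pairsAtLevel <- function(pairs, level = c("VL1", "VL2", "VL3")) {
  level <- match.arg(level)
  rank <- c(VL1 = 1L, VL2 = 2L, VL3 = 3L)
  pairs[rank[pairs$level] >= rank[level]]
}
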