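narrowPeakExtraCols <- c(signalValue = "numeric", pValue = "numeric",
                         qValue = "numeric", peak = "integer")

#' Read an ENCODE narrowPeak file
#'
#' Parses the 10-column narrowPeak format into a \code{GRanges} of peaks.
#' Column 7 (signalValue) is taken as the fold enrichment, column 9 as
#' -log10(q), and column 10 (summit offset from the 0-based start) is
#' converted to an absolute 1-based summit position. A summit offset of -1
#' (no summit called) is replaced by the interval midpoint with a warning.
#'
#' @param path path to a narrowPeak file.
#' @return \code{GRanges} with mcols \code{name}, \code{score},
#'   \code{foldEnrichment}, \code{negLog10P}, \code{negLog10Q},
#'   \code{summit} (absolute bp).
#' @examples
#' \dontrun{peaks <- readNarrowPeak("rep1.narrowPeak")}
#' @export
readNarrowPeak <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  body <- which(!grepl("^(#|track|browser)", lines) & nzchar(lines))
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf != 10))
    stop("narrowPeak line ", body[which(nf != 10)[1]],
         ": expected 10 columns, got ", nf[which(nf != 10)[1]])
  gr <- rtracklayer::import(path, format = "BED", extraCols = narrowPeakExtraCols)
  off <- gr$peak
  noSummit <- off < 0
  if (any(noSummit)) {
    warning(sum(noSummit), " peak(s) without a called summit (offset -1); ",
            "using the interval midpoint")
    off[noSummit] <- width(gr)[noSummit] %/% 2L
  }
  ## BED start is 0-based; GRanges start is that + 1, so absolute 1-based
  ## summit = start(gr) + offset
  summit <- start(gr) + off
  mcols(gr) <- DataFrame(name = gr$name, score = gr$score,
                         foldEnrichment = gr$signalValue,
                         negLog10P = gr$pValue, negLog10Q = gr$qValue,
                         summit = as.integer(summit))
  gr
}

#' Write peaks to narrowPeak
#'
#' Inverse of [readNarrowPeak()]: writes 10-column narrowPeak with the
#' summit encoded as an offset from the 0-based interval start.
#'
#' @param peaks \code{GRanges} as returned by [readNarrowPeak()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeNarrowPeak <- function(peaks, path) {
  df <- data.frame(
    chrom = as.character(seqnames(peaks)),
    start = start(peaks) - 1L,
    end = end(peaks),
    name = peaks$name,
    score = peaks$score,
    strand = ".",
    signalValue = peaks$foldEnrichment,
    pValue = peaks$negLog10P,
    qValue = peaks$negLog10Q,
    peak = peaks$summit - start(peaks))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write reproducible peaks to a BED6+3 file
#'
#' One record per matched replicate pair: the merged interval (0-based
#' half-open BED coordinates) plus three extra columns \code{level},
#' \code{summitDistance}, and \code{idr}. A commented header line names the
#' columns so an empty set still produces a parseable file.
#'
#' @param pairs \code{GRanges} of matched pairs (see [overlapReplicates()],
#'   [assignValidationLevels()]).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePeaksBed <- function(pairs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#chrom\tstart\tend\tname\tscore\tstrand\t",
                    "level\tsummitDistance\tidr"), con)
  if (length(pairs)) {
    idr <- if (!is.null(pairs$idr)) pairs$idr else NA_real_
    level <- if (!is.null(pairs$level)) as.character(pairs$level) else "VL1"
    df <- data.frame(
      chrom = as.character(seqnames(pairs)),
      start = start(pairs) - 1L,
      end = end(pairs),
      name = pairs$name,
      score = 0L,
      strand = ".",
      level = level,
      summitDistance = pairs$summitDistance,
      idr = idr)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a reproducible-peak BED written by [writePeaksBed()]
#'
#' @param path path to the BED6+3 file.
#' @return \code{GRanges} with mcols \code{name}, \code{level},
#'   \code{summitDistance}, \code{idr}.
#' @export
readPeaksBed <- function(path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand",
            "level", "summitDistance", "idr")
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          col.names = cols,
                          colClasses = c("character", "integer", "integer",
                                         "character", "integer", "character",
                                         "character", "integer", "numeric"))
  if (!nrow(df)) {
    gr <- GRanges()
    mcols(gr) <- DataFrame(name = character(0), level = character(0),
                           summitDistance = integer(0), idr = numeric(0))
    return(gr)
  }
  gr <- GRanges(df$chrom, IRanges(df$start + 1L, df$end))
  mcols(gr) <- DataFrame(name = df$name, level = df$level,
                         summitDistance = df$summitDistance, idr = df$idr)
  gr
}
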