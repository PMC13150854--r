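#' Read a functional bin map
#'
#' Two-column TSV mapping genes to hierarchical bin paths (levels separated
#' by \code{"."}, e.g. \code{"metabolism.cell_wall.pectin"}). A gene may map
#' to several bins (one row each).
#'
#' @param path path to the TSV (header line \code{gene_id<TAB>bin} optional).
#' @return \code{data.frame} with columns \code{gene_id}, \code{bin}.
#' @export
readBinMap <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) && grepl("^gene_id\\b", lines[1])) lines <- lines[-1]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad))
    stop("bin map line ", bad[1], ": expected 2 tab-separated columns")
  df <- unique(data.frame(gene_id = vapply(parts, `[`, "", 1),
                          bin = vapply(parts, `[`, "", 2),
                          stringsAsFactors = FALSE))
  if (any(!nzchar(df$bin))) stop("empty bin path in bin map")
  df
}

truncateBin <- function(bin, level) {
  vapply(strsplit(bin, ".", fixed = TRUE), function(p)
    paste(p[seq_len(min(level, length(p)))], collapse = "."), character(1))
}

#' Hypergeometric over-representation of functional bins
#'
#' Tests each bin (truncated to the requested hierarchy level) for
#' over-representation of a gene list against a universe, with the one-sided
#' hypergeometric upper-tail probability
#' \eqn{P(X \ge k)} for \eqn{X \sim \mathrm{Hypergeom}(N, K, n)}, and
#' Benjamini-Hochberg adjustment across the tested bins.
#'
#' @param listGenes character vector, the gene list (must be a subset of the
#'   universe; offenders are named in the error).
#' @param universeGenes character vector, the gene universe.
#' @param binMap \code{data.frame} from [readBinMap()].
#' @param level bin hierarchy level to test at (default 2; paths shorter
#'   than the level are kept whole).
#' @param topK optional: keep only the \code{topK} most significant bins
#'   (default \code{Inf}, keep all).
#' @return \code{data.frame} sorted by p-value: \code{bin}, \code{k} (list
#'   hits), \code{n} (list size), \code{K} (universe hits), \code{N}
#'   (universe size), \code{p}, \code{fdr}.
#' @examples
#' bins <- data.frame(gene_id = paste0("g", 1:20),
#'                    bin = rep(c("a.x", "b.y"), each = 10))
#' enrichBins(paste0("g", 1:5), paste0("g", 1:20), bins, level = 2)
#' @export
enrichBins <- function(listGenes, universeGenes, binMap, level = 2L,
                       topK = Inf) {
  stopifnot(level >= 1)
  listGenes <- unique(listGenes)
  universeGenes <- unique(universeGenes)
  extra <- setdiff(listGenes, universeGenes)
  if (length(extra))
    stop("gene list is not a subset of the universe; offenders: ",
         paste(utils::head(extra, 10), collapse = ", "),
         if (length(extra) > 10) ", ..." else "")
  bm <- binMap[binMap$gene_id %in% universeGenes, , drop = FALSE]
  bm$bin <- truncateBin(bm$bin, level)
  bm <- unique(bm)
  N <- length(universeGenes)
  n <- length(listGenes)
  byBin <- split(bm$gene_id, bm$bin)
  res <- do.call(rbind, lapply(names(byBin), function(b) {
    K <- length(byBin[[b]])
    k <- sum(listGenes %in% byBin[[b]])
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(bin = b, k = k, n = n, K = K, N = N, p = p,
               stringsAsFactors = FALSE)
  }))
  if (is.null(res))
    return(data.frame(bin = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), p = numeric(0),
                      fdr = numeric(0)))
  res$fdr <- stats::p.adjust(res$p, method = "BH")
  res <- res[order(res$p, res$bin), , drop = FALSE]
  rownames(res) <- NULL
  utils::head(res, topK)
}
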