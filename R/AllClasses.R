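#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom GenomicRanges GRanges GRangesList findOverlaps seqnames start end width strand
#' @importFrom IRanges IRanges
NULL

#' GenomeLayout: chromosome complement of a polyploid genome
#'
#' Describes the chromosomes of an allopolyploid assembly: name, length,
#' parental subgenome label, and homoeologous chromosome group index.
#' The octoploid layout this package targets has 4 subgenomes x 7 groups =
#' 28 chromosomes, but any G groups x S subgenomes layout is accepted.
#'
#' @slot table a \code{data.frame} with columns \code{chrom} (unique names),
#'   \code{length} (bp, > 0), \code{subgenome} (label), \code{group}
#'   (integer 1..G).
#'
#' @seealso [readGenomeLayout()], [subgenomeBiasTest()]
#' @export
setClass("GenomeLayout", representation(table = "data.frame"))

setValidity("GenomeLayout", function(object) {
  tab <- object@table
  msgs <- character()
  need <- c("chrom", "length", "subgenome", "group")
  if (!all(need %in% names(tab)))
    return(paste("layout table must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(tab$chrom))
    msgs <- c(msgs, "chromosome names must be unique")
  if (any(!is.finite(tab$length)) || any(tab$length <= 0))
    msgs <- c(msgs, "chromosome lengths must be positive")
  if (any(is.na(tab$subgenome)) || any(!nzchar(tab$subgenome)))
    msgs <- c(msgs, "every chromosome needs a subgenome label")
  if (any(is.na(tab$group)) || any(tab$group != as.integer(tab$group)) ||
      any(tab$group < 1))
    msgs <- c(msgs, "group indices must be positive integers")
  if (length(msgs)) msgs else TRUE
})

#' Construct a GenomeLayout
#'
#' @param chrom character vector of chromosome names.
#' @param length numeric vector of chromosome lengths in bp.
#' @param subgenome character vector of subgenome labels.
#' @param group integer vector of homoeologous chromosome group indices.
#' @return a [GenomeLayout-class] object.
#' @examples
#' GenomeLayout(chrom = c("chr1A", "chr1B"), length = c(2e5, 1.8e5),
#'              subgenome = c("A", "B"), group = c(1L, 1L))
#' @export
GenomeLayout <- function(chrom, length, subgenome, group) {
  new("GenomeLayout", table = data.frame(
    chrom = as.character(chrom), length = as.numeric(length),
    subgenome = as.character(subgenome), group = as.integer(group),
    stringsAsFactors = FALSE))
}

setMethod("show", "GenomeLayout", function(object) {
  tab <- object@table
  cat("GenomeLayout with", nrow(tab), "chromosomes:",
      length(unique(tab$group)), "groups x",
      length(unique(tab$subgenome)), "subgenomes\n")
  cat("  total size:", format(sum(tab$length), big.mark = ","), "bp\n")
})

#' @describeIn GenomeLayout-class chromosome names.
#' @param x,object a \code{GenomeLayout}.
#' @export
chromNames <- function(x) x@table$chrom

#' @describeIn GenomeLayout-class named vector of chromosome lengths (bp).
#' @export
chromLengths <- function(x) stats::setNames(x@table$length, x@table$chrom)

#' @describeIn GenomeLayout-class named vector of subgenome labels per chromosome.
#' @export
chromSubgenomes <- function(x) stats::setNames(x@table$subgenome, x@table$chrom)

#' @describeIn GenomeLayout-class named integer vector of group indices per chromosome.
#' @export
chromGroups <- function(x) stats::setNames(x@table$group, x@table$chrom)

#' @describeIn GenomeLayout-class the layout as a plain data.frame.
#' @export
layoutTable <- function(x) x@table

#' GeneAnnotation: gene models on a polyploid layout
#'
#' Gene-level coordinates with strand-derived TSS and subgenome label, plus
#' exon and (optional) UTR structure used for feature classification.
#'
#' @slot genes \code{GRanges} with mcols \code{gene_id}, \code{tss}
#'   (absolute 1-based position), \code{subgenome}.
#' @slot exons \code{GRangesList} named by gene_id.
#' @slot utr5,utr3 \code{GRangesList} named by gene_id (may be empty).
#' @slot layout the [GenomeLayout-class] the genes live on.
#' @export
setClass("GeneAnnotation", representation(
  genes = "GRanges", exons = "GRangesList",
  utr5 = "GRangesList", utr3 = "GRangesList",
  layout = "GenomeLayout"))

setValidity("GeneAnnotation", function(object) {
  g <- object@genes
  msgs <- character()
  need <- c("gene_id", "tss", "subgenome")
  if (!all(need %in% names(mcols(g))))
    return(paste("genes need mcols:", paste(need, collapse = ", ")))
  if (anyDuplicated(g$gene_id))
    msgs <- c(msgs, "gene_id values must be unique")
  if (length(g)) {
    bad <- !as.character(seqnames(g)) %in% chromNames(object@layout)
    if (any(bad))
      msgs <- c(msgs, paste("genes on chromosomes absent from the layout:",
                            paste(unique(as.character(seqnames(g))[bad]), collapse = ", ")))
    pos <- as.character(strand(g)) == "+"
    want <- ifelse(pos, start(g), end(g))
    if (any(g$tss != want))
      msgs <- c(msgs, "tss must equal start on + strand and end on - strand")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "GeneAnnotation", function(object) {
  cat("GeneAnnotation with", length(object@genes), "genes on",
      length(unique(as.character(seqnames(object@genes)))), "chromosomes\n")
  cat("  exon models:", sum(lengths(object@exons) > 0), "genes;",
      "5'UTR:", sum(lengths(object@utr5) > 0),
      "; 3'UTR:", sum(lengths(object@utr3) > 0), "\n")
})

#' @describeIn GeneAnnotation-class gene-level \code{GRanges}.
#' @param x a \code{GeneAnnotation}.
#' @export
genes <- function(x) x@genes

#' @describeIn GeneAnnotation-class exon \code{GRangesList} named by gene_id.
#' @export
geneExons <- function(x) x@exons

#' @describeIn GeneAnnotation-class the underlying [GenomeLayout-class].
#' @export
genomeLayout <- function(x) x@layout

#' IdrFit: copula-mixture irreproducible discovery rate fit
#'
#' Result of fitting the two-component Gaussian copula mixture to
#' rank-transformed replicate scores. The reproducible component is a
#' bivariate normal with mean \code{mu}, scale \code{sigma}, and correlation
#' \code{rho}; the irreproducible component is standard bivariate normal with
#' zero correlation. \code{localIdr} is the posterior probability of the
#' irreproducible component per pair; \code{globalIdr} is the expected
#' irreproducible fraction among the i most reproducible pairs (the running
#' mean of sorted local idr), reported in the input pair order.
#'
#' @slot p mixing proportion of the reproducible component, in [0, 1].
#' @slot mu,sigma,rho reproducible-component parameters.
#' @slot localIdr,globalIdr numeric vectors, one value per pair, in [0, 1].
#' @slot loglik numeric vector: the log-likelihood trace over EM iterations.
#' @slot converged logical.
#' @export
setClass("IdrFit", representation(
  p = "numeric", mu = "numeric", sigma = "numeric", rho = "numeric",
  localIdr = "numeric", globalIdr = "numeric",
  loglik = "numeric", converged = "logical"))

setValidity("IdrFit", function(object) {
  msgs <- character()
  probs <- c(object@p, object@localIdr, object@globalIdr)
  if (any(probs < 0 | probs > 1)) msgs <- c(msgs, "probabilities must lie in [0, 1]")
  if (object@rho <= -1 || object@rho >= 1) msgs <- c(msgs, "rho must lie in (-1, 1)")
  if (object@sigma <= 0) msgs <- c(msgs, "sigma must be positive")
  o <- order(object@localIdr)
  if (length(o) > 1 && is.unsorted(object@globalIdr[o]))
    msgs <- c(msgs, "global IDR must be non-decreasing along the local-idr ordering")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "IdrFit", function(object) {
  cat(sprintf("IdrFit: n = %d pairs, p = %.3f, mu = %.3f, sigma = %.3f, rho = %.3f\n",
              length(object@localIdr), object@p, object@mu, object@sigma, object@rho))
  cat(sprintf("  %s after %d iterations; %d pairs with global IDR <= 0.05\n",
              if (object@converged) "converged" else "NOT converged",
              length(object@loglik), sum(object@globalIdr <= 0.05)))
})

#' @describeIn IdrFit-class per-pair local irreproducibility posterior.
#' @param x an \code{IdrFit}.
#' @export
localIdr <- function(x) x@localIdr

#' @describeIn IdrFit-class per-pair global (expected-rate) IDR.
#' @export
globalIdr <- function(x) x@globalIdr

#' @describeIn IdrFit-class fitted mixture parameters as a named list.
#' @export
idrParams <- function(x) list(p = x@p, mu = x@mu, sigma = x@sigma, rho = x@rho)
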