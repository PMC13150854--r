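#' Count peaks per chromosome group and subgenome
#'
#' Tallies peaks into an exhaustive, mutually exclusive (group x subgenome)
#' table of the layout. Peaks on chromosomes absent from the layout are an
#' error naming the offending chromosomes.
#'
#' @param peaks \code{GRanges} (any peak set; counted by chromosome).
#' @param layout a [GenomeLayout-class].
#' @return integer matrix with one row per group (rownames \code{"1"}...)
#'   and one column per subgenome label; cells for (group, subgenome)
#'   combinations absent from the layout are 0.
#' @export
countPeaksByChromosome <- function(peaks, layout) {
  tab <- layoutTable(layout)
  chrom <- as.character(seqnames(peaks))
  unknown <- setdiff(unique(chrom), tab$chrom)
  if (length(unknown))
    stop("peaks on chromosomes absent from the layout: ",
         paste(unknown, collapse = ", "))
  groups <- sort(unique(tab$group))
  subs <- unique(tab$subgenome)
  m <- matrix(0L, nrow = length(groups), ncol = length(subs),
              dimnames = list(as.character(groups), subs))
  perChrom <- table(factor(chrom, levels = tab$chrom))
  for (k in seq_len(nrow(tab)))
    m[as.character(tab$group[k]), tab$subgenome[k]] <-
      m[as.character(tab$group[k]), tab$subgenome[k]] + perChrom[[tab$chrom[k]]]
  m
}

#' Size-proportional expected peak counts within a chromosome group
#'
#' The expected count of a subgenome's chromosome is the group's total
#' observed peak count apportioned by chromosome length: \eqn{E_s = N_g
#' \cdot L_s / \sum_t L_t}. Expected counts are real-valued and sum exactly
#' to the observed total.
#'
#' @param observed named numeric vector of observed counts per subgenome
#'   (one chromosome group).
#' @param layout a [GenomeLayout-class].
#' @param group the chromosome group index.
#' @return named numeric vector of expected counts, same names as
#'   \code{observed}.
#' @export
expectedCounts <- function(observed, layout, group) {
  tab <- layoutTable(layout)
  gtab <- tab[tab$group == group, , drop = FALSE]
  if (!nrow(gtab)) stop("no chromosomes in group ", group)
  len <- stats::setNames(gtab$length, gtab$subgenome)[names(observed)]
  if (any(is.na(len)))
    stop("subgenome(s) missing from group ", group, ": ",
         paste(names(observed)[is.na(len)], collapse = ", "))
  total <- sum(len)
  if (total <= 0) stop("zero total chromosome length in group ", group)
  sum(observed) * len / total
}

#' Chi-square test of observed vs expected subgenome counts
#'
#' Pearson's chi-square statistic \eqn{\sum (O - E)^2 / E} with
#' \eqn{df = k - 1} against the size-proportional expectation, with the
#' p-value from the chi-square survival function.
#'
#' @param observed,expected numeric vectors of equal length (expected all
#'   positive; a zero expected cell is an error advising pooling).
#' @param alpha significance level for the flag (default 0.05).
#' @return a list: \code{observed}, \code{expected}, \code{chi2}, \code{df},
#'   \code{p_value}, \code{significant}.
#' @examples
#' chiSquareBias(c(40, 20, 20, 20), c(25, 25, 25, 25))
#' @export
chiSquareBias <- function(observed, expected, alpha = 0.05) {
  stopifnot(length(observed) == length(expected))
  if (any(expected <= 0))
    stop("expected cell count of zero; pool subgenomes or add peaks ",
         "before testing")
  chi2 <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  p <- stats::pchisq(chi2, df, lower.tail = FALSE)
  list(observed = observed, expected = expected, chi2 = chi2, df = df,
       p_value = p, significant = p <= alpha)
}

#' Test subgenome binding bias across all chromosome groups
#'
#' Runs the size-proportional chi-square test within every homoeologous
#' chromosome group: are binding sites distributed across the subgenomes of
#' a group in proportion to chromosome size? Reported per group, uncorrected
#' by default, with Bonferroni-adjusted p-values alongside.
#'
#' @param peaks \code{GRanges} of peaks (e.g. all reproducible peaks, or the
#'   subset with promoter-window summits for a promoter-restricted test).
#' @param layout a [GenomeLayout-class].
#' @param alpha significance level (default 0.05).
#' @param correct multiple-testing handling of the significance flag:
#'   \code{"none"} (default) or \code{"bonferroni"} across the groups.
#' @return \code{data.frame} with one row per (group, subgenome):
#'   \code{group}, \code{subgenome}, \code{observed}, \code{expected},
#'   \code{chi2}, \code{df}, \code{p_value}, \code{p_bonferroni},
#'   \code{significant} (the group-level test, repeated on each row of the
#'   group).
#' @export
subgenomeBiasTest <- function(peaks, layout, alpha = 0.05,
                              correct = c("none", "bonferroni")) {
  correct <- match.arg(correct)
  counts <- countPeaksByChromosome(peaks, layout)
  groups <- rownames(counts)
  res <- lapply(groups, function(gname) {
    g <- as.integer(gname)
    present <- layoutTable(layout)$subgenome[layoutTable(layout)$group == g]
    obs <- counts[gname, unique(present)]
    exp <- expectedCounts(obs, layout, g)
    test <- chiSquareBias(obs, exp, alpha)
    data.frame(group = g, subgenome = names(obs),
               observed = as.numeric(obs), expected = as.numeric(exp),
               chi2 = test$chi2, df = test$df, p_value = test$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  pg <- out$p_value[!duplicated(out$group)]
  padj <- stats::setNames(pmin(pg * length(groups), 1), groups)
  out$p_bonferroni <- padj[as.character(out$group)]
  out$significant <- if (correct == "none") out$p_value <= alpha
                     else out$p_bonferroni <= alpha
  rownames(out) <- NULL
  out
}
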