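#' Read a differential-expression table
#'
#' Long-format TSV with columns \code{gene_id}, \code{line}, \code{stage},
#' \code{log2fc}, \code{fdr}: one row per gene x RNAi line x ripening stage
#' contrast. Missing contrasts are permitted; duplicate
#' (gene, line, stage) rows and non-numeric statistics are errors that name
#' the offending line.
#'
#' @param path path to the TSV (with header).
#' @return \code{data.frame} with the five columns, one row per contrast.
#' @export
readDegTable <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(gene_id = "character",
                                         line = "character",
                                         stage = "character",
                                         log2fc = "character",
                                         fdr = "character"))
  need <- c("gene_id", "line", "stage", "log2fc", "fdr")
  if (!all(need %in% names(df)))
    stop("DEG table must have columns: ", paste(need, collapse = ", "))
  for (col in c("log2fc", "fdr")) {
    val <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(val) & !is.na(df[[col]]) & df[[col]] != "NA")
    if (length(bad))
      stop("DEG table line ", bad[1] + 1L, ": non-numeric ", col,
           " value '", df[[col]][bad[1]], "'")
    df[[col]] <- val
  }
  if (any(df$fdr < 0 | df$fdr > 1, na.rm = TRUE))
    stop("fdr values must lie in [0, 1]")
  key <- paste(df$gene_id, df$line, df$stage, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1, ]
    stop("duplicate contrast for gene ", d$gene_id, ", line ", d$line,
         ", stage ", d$stage)
  }
  df
}

#' Select consistently differential genes across RNAi lines
#'
#' A contrast qualifies when |log2fc| >= \code{minAbsLog2fc} and
#' FDR <= \code{maxFdr}. A gene is selected when every required RNAi line
#' qualifies under the stage rule: \code{"any_stage"} asks each line to
#' qualify in at least one stage; \code{"both_stages"} asks each line to
#' qualify in every stage it was assayed in. Direction is \code{"down"} when
#' all qualifying log2fc are negative, \code{"up"} when all positive,
#' \code{"mixed"} otherwise.
#'
#' @param deg \code{data.frame} from [readDegTable()].
#' @param minAbsLog2fc minimum absolute log2 fold change (inclusive;
#'   default 1, i.e. two-fold).
#' @param maxFdr FDR ceiling (inclusive; default 0.05).
#' @param requireBothLines when TRUE (default) every line present in the
#'   table must qualify; when FALSE one qualifying line suffices.
#' @param stageRule \code{"any_stage"} (default) or \code{"both_stages"}.
#' @return \code{data.frame} with one row per selected gene: \code{gene_id},
#'   \code{direction} (\code{"down"}, \code{"up"}, \code{"mixed"}),
#'   \code{n_qualifying} contrasts. Attribute \code{selection} records the
#'   thresholds and rule used.
#' @export
selectConsistentDegs <- function(deg, minAbsLog2fc = 1, maxFdr = 0.05,
                                 requireBothLines = TRUE,
                                 stageRule = c("any_stage", "both_stages")) {
  if (!nrow(deg)) stop("empty differential-expression table")
  stageRule <- match.arg(stageRule)
  lines <- sort(unique(deg$line))
  deg$pass <- !is.na(deg$log2fc) & !is.na(deg$fdr) &
    abs(deg$log2fc) >= minAbsLog2fc & deg$fdr <= maxFdr

  perLine <- function(sub) {
    ## does one gene x line block qualify under the stage rule?
    if (stageRule == "any_stage") any(sub$pass) else all(sub$pass)
  }
  out <- do.call(rbind, lapply(split(deg, deg$gene_id), function(gsub) {
    byLine <- vapply(split(gsub, gsub$line), perLine, logical(1))
    presentLines <- names(byLine)
    lineOk <- if (requireBothLines)
      all(lines %in% presentLines) && all(byLine)
    else any(byLine)
    if (!lineOk) return(NULL)
    q <- gsub$log2fc[gsub$pass]
    if (!length(q)) return(NULL)
    direction <- if (all(q < 0)) "down" else if (all(q > 0)) "up" else "mixed"
    data.frame(gene_id = gsub$gene_id[1], direction = direction,
               n_qualifying = sum(gsub$pass), stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(gene_id = character(0), direction = character(0),
                      n_qualifying = integer(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out <- out[order(out$gene_id), , drop = FALSE]
  attr(out, "selection") <- list(min_abs_log2fc = minAbsLog2fc,
                                 max_fdr = maxFdr,
                                 require_both_lines = requireBothLines,
                                 stage_rule = stageRule,
                                 lines = lines)
  out
}

levelRank <- c(none = 0L, VL1 = 1L, VL2 = 2L, VL3 = 3L)

#' Classify genes as direct or indirect targets
#'
#' Joins the selected DEG set with the per-level promoter target maps. A
#' selected gene bound at any level is a direct target (at every level up to
#' its highest binding tier); a selected gene with no promoter peak is an
#' indirect target; a bound, unselected gene is reported as
#' \code{bound_not_DE}; all other annotated genes are \code{neither}.
#'
#' @param selected \code{data.frame} from [selectConsistentDegs()].
#' @param targetMaps named list of per-level target maps from
#'   [targetMapsByLevel()] (cumulative: the VL2 map only contains VL2/VL3
#'   support).
#' @param universe optional character vector of all gene ids; genes outside
#'   the selected/bound sets are filled in as \code{neither}.
#' @param homoeologMap optional named vector from [readHomoeologMap()];
#'   adds a \code{homoeolog_group} column (NA when unmapped).
#' @return \code{data.frame} with one row per gene: \code{gene_id},
#'   \code{deg_status}, \code{bound_at} (\code{"none"} or the highest level
#'   with promoter support), \code{class} (\code{direct}, \code{indirect},
#'   \code{bound_not_DE}, \code{neither}), \code{direction} (NA unless
#'   selected), and optionally \code{homoeolog_group}.
#' @export
classifyDirectIndirect <- function(selected, targetMaps, universe = NULL,
                                   homoeologMap = NULL) {
  stopifnot(all(c("VL1", "VL2", "VL3") %in% names(targetMaps)))
  boundAt <- character(0)
  for (lv in c("VL1", "VL2", "VL3")) {
    gidx <- unique(targetMaps[[lv]]$gene_id)
    boundAt[gidx] <- lv     # later (stricter) levels overwrite
  }
  genesAll <- unique(c(selected$gene_id, names(boundAt), universe))
  bound <- boundAt[genesAll]
  bound[is.na(bound)] <- "none"
  sel <- genesAll %in% selected$gene_id
  cls <- ifelse(sel & bound != "none", "direct",
                ifelse(sel, "indirect",
                       ifelse(bound != "none", "bound_not_DE", "neither")))
  dirv <- selected$direction[match(genesAll, selected$gene_id)]
  out <- data.frame(gene_id = genesAll, deg_status = ifelse(sel, "selected",
                                                            "not_selected"),
                    bound_at = unname(bound), class = cls, direction = dirv,
                    stringsAsFactors = FALSE)
  if (!is.null(homoeologMap))
    out$homoeolog_group <- unname(homoeologMap[out$gene_id])
  out[order(out$gene_id), , drop = FALSE]
}

#' Collapse target calls to unique homoeolog groups
#'
#' Counts distinct homoeolog groups per class (and, for direct targets, per
#' cumulative validation level); genes missing from the map are tallied in
#' an \code{unmapped} column rather than dropped.
#'
#' @param calls \code{data.frame} from [classifyDirectIndirect()].
#' @param map named vector from [readHomoeologMap()] (ignored when
#'   \code{calls} already has a \code{homoeolog_group} column).
#' @return \code{data.frame} with columns \code{class}, \code{level},
#'   \code{n_genes}, \code{n_unique_homoeologs}, \code{n_unmapped}.
#' @export
collapseToHomoeologs <- function(calls, map = NULL) {
  if (!"homoeolog_group" %in% names(calls)) {
    if (is.null(map)) stop("no homoeolog map available")
    calls$homoeolog_group <- unname(map[calls$gene_id])
  }
  rows <- list()
  tallyRow <- function(sub, class, level) {
    data.frame(class = class, level = level, n_genes = nrow(sub),
               n_unique_homoeologs = length(unique(stats::na.omit(sub$homoeolog_group))),
               n_unmapped = sum(is.na(sub$homoeolog_group)),
               stringsAsFactors = FALSE)
  }
  for (cl in c("direct", "indirect", "bound_not_DE")) {
    sub <- calls[calls$class == cl, , drop = FALSE]
    if (cl == "direct") {
      for (lv in c("VL1", "VL2", "VL3"))
        rows[[paste(cl, lv)]] <-
          tallyRow(sub[levelRank[sub$bound_at] >= levelRank[lv], , drop = FALSE],
                   cl, lv)
    } else {
      rows[[cl]] <- tallyRow(sub, cl, NA_character_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## Round half away from zero to `digits` decimals (printed percentages use
## this, not banker's rounding).
roundHalfUp <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Summarize the direct/indirect classification
#'
#' Produces the count and percentage summary of a classified gene set, per
#' cumulative validation level. \code{pct_direct} is
#' \code{100 * n_direct / n_selected}; \code{pct_down}/\code{pct_up} are
#' percentages of the down+up dichotomy among direct targets (genes with
#' mixed direction are counted in \code{n_mixed} and excluded from that
#' denominator). Percentages are rounded half-up to one decimal; with no
#' selected genes they are NA.
#'
#' @param calls \code{data.frame} from [classifyDirectIndirect()].
#' @return a list of class \code{classificationSummary}: \code{n_selected},
#'   \code{n_indirect}, and per-level vectors \code{n_direct},
#'   \code{n_down}, \code{n_up}, \code{n_mixed}, \code{pct_direct},
#'   \code{pct_down}, \code{pct_up}, plus \code{pct_indirect}.
#' @export
summarizeClassification <- function(calls) {
  sel <- calls$deg_status == "selected"
  nSelected <- sum(sel)
  levels <- c("VL1", "VL2", "VL3")
  nDirect <- nDown <- nUp <- nMixed <- stats::setNames(integer(3), levels)
  for (lv in levels) {
    dsub <- calls[sel & levelRank[calls$bound_at] >= levelRank[lv], , drop = FALSE]
    nDirect[lv] <- nrow(dsub)
    nDown[lv] <- sum(dsub$direction == "down", na.rm = TRUE)
    nUp[lv] <- sum(dsub$direction == "up", na.rm = TRUE)
    nMixed[lv] <- sum(dsub$direction == "mixed", na.rm = TRUE)
  }
  nIndirect <- nSelected - nDirect[["VL1"]]
  pct <- function(num, den) {
    den <- rep_len(den, length(num))
    out <- rep(NA_real_, length(num))
    ok <- den > 0
    out[ok] <- roundHalfUp(100 * num[ok] / den[ok], 1)
    names(out) <- names(num)
    out
  }
  out <- list(
    n_selected = nSelected,
    n_direct = nDirect,
    n_indirect = nIndirect,
    n_down = nDown, n_up = nUp, n_mixed = nMixed,
    pct_direct = if (nSelected > 0) pct(nDirect, nSelected)
                 else stats::setNames(rep(NA_real_, 3), levels),
    pct_indirect = if (nSelected > 0) pct(nIndirect, nSelected) else NA_real_,
    pct_down = pct(nDown, nDown + nUp),
    pct_up = pct(nUp, nDown + nUp))
  class(out) <- "classificationSummary"
  out
}

#' @export
print.classificationSummary <- function(x, ...) {
  cat("Classification of", x$n_selected, "selected DEGs\n")
  for (lv in names(x$n_direct))
    cat(sprintf("  %s: %d direct (%.1f%%), %d down / %d up / %d mixed\n",
                lv, x$n_direct[[lv]], x$pct_direct[[lv]],
                x$n_down[[lv]], x$n_up[[lv]], x$n_mixed[[lv]]))
  cat(sprintf("  indirect: %d (%.1f%%)\n", x$n_indirect, x$pct_indirect))
  invisible(x)
}
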