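#' Read proximity-labeling protein-group evidence
#'
#' TSV with columns \code{group_id}, \code{member_proteins} (semicolon
#' list), \code{peptide_ids} (semicolon list), followed by one presence
#' column per condition/replicate named \code{<condition>_<replicate>}
#' (e.g. \code{bait_1 ... control_3}), holding 0/1, TRUE/FALSE, or raw
#' peptide counts. Counts are binarised at \code{minPeptides}.
#'
#' @param path path to the evidence TSV.
#' @param minPeptides count threshold for "present" when presence columns
#'   carry raw counts (default 1).
#' @return a list of class \code{proteinEvidence}: \code{groups}
#'   (data.frame \code{group_id}, \code{members}, \code{peptides} as list
#'   columns), \code{presence} (logical matrix, rows = groups, columns =
#'   \code{condition_replicate}), \code{conditions} (factor per column).
#' @export
readProteinEvidence <- function(path, minPeptides = 1L) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("group_id", "member_proteins", "peptide_ids")
  if (!all(need %in% names(df)))
    stop("evidence table must have columns: ", paste(need, collapse = ", "))
  presCols <- setdiff(names(df), need)
  if (!length(presCols)) stop("no presence columns found")
  condOf <- sub("_[^_]+$", "", presCols)
  pres <- matrix(FALSE, nrow = nrow(df), ncol = length(presCols),
                 dimnames = list(df$group_id, presCols))
  for (cn in presCols) {
    v <- df[[cn]]
    pres[, cn] <- if (is.logical(v)) v
    else if (is.numeric(v)) v >= minPeptides
    else toupper(v) %in% c("TRUE", "T", "1", "PRESENT", "YES")
  }
  splitSemi <- function(x) strsplit(as.character(x), ";", fixed = TRUE)
  groups <- data.frame(group_id = df$group_id, stringsAsFactors = FALSE)
  groups$members <- splitSemi(df$member_proteins)
  groups$peptides <- splitSemi(df$peptide_ids)
  structure(list(groups = groups, presence = pres,
                 conditions = stats::setNames(condOf, presCols)),
            class = "proteinEvidence")
}

#' Filter proximity-labeling evidence to exclusive bait candidates
#'
#' Retains protein groups reproducibly present in the bait condition and
#' absent from the control: present in at least \code{nBaitRepsRequired}
#' bait replicates (default: all of them) and, unless
#' \code{allowAnyControl}, absent in every control replicate. With
#' \code{unit = "peptide"} the table is read as one row per peptide and a
#' group counts as present in a replicate only when all of its peptide rows
#' are present there.
#'
#' @param evidence a \code{proteinEvidence} from [readProteinEvidence()].
#' @param nBaitRepsRequired number of bait replicates a group must be
#'   present in; \code{NULL} (default) means all bait replicates.
#' @param allowAnyControl when TRUE, control presence does not remove a
#'   group (default FALSE).
#' @param bait,control condition labels in the presence columns.
#' @param unit \code{"group"} (default) or \code{"peptide"} (see above).
#' @return a list: \code{retained} (data.frame of retained rows),
#'   \code{summary} with \code{n_groups}, \code{n_peptides} (unique peptide
#'   ids across retained groups), \code{n_unique_proteins} (members
#'   deduplicated across retained groups).
#' @export
filterExclusiveCandidates <- function(evidence, nBaitRepsRequired = NULL,
                                      allowAnyControl = FALSE,
                                      bait = "bait", control = "control",
                                      unit = c("group", "peptide")) {
  unit <- match.arg(unit)
  pres <- evidence$presence
  cond <- evidence$conditions
  baitCols <- names(cond)[cond == bait]
  ctrlCols <- names(cond)[cond == control]
  if (!length(baitCols)) stop("no replicates for bait condition '", bait, "'")
  if (!length(ctrlCols))
    stop("no replicates for control condition '", control, "'")
  if (is.null(nBaitRepsRequired)) nBaitRepsRequired <- length(baitCols)
  stopifnot(nBaitRepsRequired >= 1, nBaitRepsRequired <= length(baitCols))

  if (unit == "peptide") {
    ## aggregate peptide rows: group present in a replicate iff all its
    ## peptide rows are present there
    gid <- evidence$groups$group_id
    agg <- rowsum((!pres) * 1L, gid) == 0
    pres <- agg[unique(gid), , drop = FALSE]
    rowGroups <- unique(gid)
  } else {
    rowGroups <- evidence$groups$group_id
  }
  baitOk <- rowSums(pres[, baitCols, drop = FALSE]) >= nBaitRepsRequired
  ctrlOk <- allowAnyControl | rowSums(pres[, ctrlCols, drop = FALSE]) == 0
  keepGroups <- rowGroups[baitOk & ctrlOk]
  retained <- evidence$groups[evidence$groups$group_id %in% keepGroups, ,
                              drop = FALSE]
  list(retained = retained,
       summary = list(
         n_groups = length(unique(retained$group_id)),
         n_peptides = length(unique(unlist(retained$peptides))),
         n_unique_proteins = length(unique(unlist(retained$members)))))
}
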