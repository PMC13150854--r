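#' Read a genome layout from TSV or YAML
#'
#' The layout file lists one chromosome per record with its length, parental
#' subgenome label, and homoeologous chromosome group index. TSV files need a
#' header line \code{chrom length subgenome group}; YAML files hold a list of
#' mappings with the same keys (file extension .yml/.yaml selects YAML).
#'
#' @param path path to the layout file.
#' @return a [GenomeLayout-class].
#' @export
readGenomeLayout <- function(path) {
  stopifnot(file.exists(path))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    recs <- yaml::read_yaml(path)
    tab <- do.call(rbind, lapply(recs, function(r)
      data.frame(chrom = r$chrom, length = r$length,
                 subgenome = r$subgenome, group = r$group)))
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  }
  GenomeLayout(tab$chrom, tab$length, tab$subgenome, tab$group)
}

#' Write a genome layout to TSV
#'
#' @param layout a [GenomeLayout-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGenomeLayout <- function(layout, path) {
  utils::write.table(layoutTable(layout), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

## Quick structural scan so coordinate errors carry a line number; full
## parsing is delegated to rtracklayer afterwards.
checkGff3Records <- function(path) {
  lines <- readLines(path)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9)
      stop("GFF3 line ", i, ": expected 9 tab-separated columns, got ",
           length(f))
    s <- suppressWarnings(as.numeric(f[4])); e <- suppressWarnings(as.numeric(f[5]))
    if (is.na(s) || is.na(e) || s > e)
      stop("GFF3 line ", i, ": malformed coordinates (start > end or non-numeric): ",
           f[4], "..", f[5])
    if (!f[7] %in% c("+", "-"))
      stop("GFF3 line ", i, ": unknown strand '", f[7],
           "' (gene models must be stranded)")
  }
  invisible(TRUE)
}

resolveGeneParent <- function(ids, parents, geneIds) {
  ## follow Parent links until a gene feature is reached (exon -> mRNA -> gene
  ## or exon -> gene directly)
  lookup <- stats::setNames(parents, ids)
  vapply(parents, function(p) {
    seen <- 0L
    while (!is.na(p) && !(p %in% geneIds) && seen < 10L) {
      p <- lookup[[p]] %||% NA_character_
      seen <- seen + 1L
    }
    if (is.na(p) || !(p %in% geneIds)) NA_character_ else p
  }, character(1), USE.NAMES = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read gene models from a GFF3 file
#'
#' Parses gene, exon and UTR features (1-based inclusive coordinates) into a
#' [GeneAnnotation-class]. The TSS is derived from strand: \code{start} on
#' \code{+}, \code{end} on \code{-}. Exons and UTRs are attached to their
#' gene through \code{Parent} links (directly or via an mRNA). Subgenome
#' labels come from the layout.
#'
#' @param path path to a GFF3 file.
#' @param layout a [GenomeLayout-class]; genes on chromosomes absent from it
#'   are dropped with a warning (\code{unknownChrom = "warn"}) or raise an
#'   error (\code{"error"}).
#' @param unknownChrom one of \code{"warn"}, \code{"error"}.
#' @return a [GeneAnnotation-class].
#' @examples
#' \dontrun{ann <- readGeneModels("genes.gff3", layout)}
#' @export
readGeneModels <- function(path, layout, unknownChrom = c("warn", "error")) {
  unknownChrom <- match.arg(unknownChrom)
  checkGff3Records(path)
  gr <- rtracklayer::import(path, format = "gff3")
  gtypes <- tolower(as.character(gr$type))
  gn <- gr[gtypes == "gene"]
  if (!length(gn)) stop("no gene features found in ", path)
  ids <- as.character(gn$ID)

  known <- as.character(seqnames(gn)) %in% chromNames(layout)
  if (any(!known)) {
    offenders <- unique(as.character(seqnames(gn))[!known])
    msg <- paste("genes on chromosomes not in the layout:",
                 paste(offenders, collapse = ", "))
    if (unknownChrom == "error") stop(msg)
    warning(msg, "; ", sum(!known), " gene(s) dropped")
    gn <- gn[known]
    ids <- as.character(gn$ID)
  }

  sub <- chromSubgenomes(layout)[as.character(seqnames(gn))]
  tss <- ifelse(as.character(strand(gn)) == "+", start(gn), end(gn))
  genes <- GRanges(seqnames(gn), IRanges(start(gn), end(gn)), strand = strand(gn))
  mcols(genes) <- DataFrame(gene_id = ids, tss = as.integer(tss),
                            subgenome = unname(sub))
  genes <- genes[order(genes$gene_id)]

  allIds <- as.character(gr$ID)
  allParents <- vapply(gr$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
                       character(1))
  childList <- function(type) {
    sel <- gtypes == type
    if (!any(sel)) return(GRangesList(stats::setNames(list(), character(0))))
    sub <- gr[sel]
    owner <- resolveGeneParent(allIds, allParents, genes$gene_id)[sel]
    keep <- !is.na(owner)
    grl <- GenomicRanges::split(GRanges(seqnames(sub)[keep],
                                        IRanges(start(sub)[keep], end(sub)[keep]),
                                        strand = strand(sub)[keep]),
                                factor(owner[keep], levels = genes$gene_id))
    grl
  }
  new("GeneAnnotation", genes = genes,
      exons = childList("exon"),
      utr5 = childList("five_prime_utr"),
      utr3 = childList("three_prime_utr"),
      layout = layout)
}

#' Write gene models back to GFF3
#'
#' Serializes a [GeneAnnotation-class] as GFF3 (gene + exon + UTR features,
#' 1-based inclusive), suitable for round-tripping through
#' [readGeneModels()].
#'
#' @param ann a [GeneAnnotation-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGeneModelsGFF3 <- function(ann, path) {
  g <- genes(ann)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  fmt <- function(chrom, s, e, type, strandc, attrs)
    paste(chrom, "polyChIP", type, s, e, ".", strandc, ".", attrs, sep = "\t")
  for (i in seq_along(g)) {
    id <- g$gene_id[i]
    chrom <- as.character(seqnames(g))[i]
    strandc <- as.character(strand(g))[i]
    writeLines(fmt(chrom, start(g)[i], end(g)[i], "gene", strandc,
                   paste0("ID=", id)), con)
    writeChildren <- function(grl, type) {
      if (!id %in% names(grl)) return()
      ch <- grl[[id]]
      for (j in seq_along(ch))
        writeLines(fmt(chrom, start(ch)[j], end(ch)[j], type, strandc,
                       paste0("ID=", id, ".", type, j, ";Parent=", id)), con)
    }
    writeChildren(geneExons(ann), "exon")
    writeChildren(ann@utr5, "five_prime_UTR")
    writeChildren(ann@utr3, "three_prime_UTR")
  }
  invisible(path)
}

#' Read a homoeolog map
#'
#' Two-column TSV mapping octoploid gene ids to homoeolog group ids (the
#' diploid reference gene). Duplicate rows are collapsed; the same gene
#' mapped to two different groups is an error listing the offenders.
#'
#' @param path path to the TSV (header optional: a first line
#'   \code{gene_id<TAB>group_id} is recognised and skipped).
#' @return named character vector: \code{gene_id -> homoeolog_group_id}.
#'   Empty files yield an empty map with a warning.
#' @export
readHomoeologMap <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) && grepl("^gene_id\\b", lines[1])) lines <- lines[-1]
  if (!length(lines)) {
    warning("empty homoeolog map: ", path)
    return(stats::setNames(character(0), character(0)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad))
    stop("homoeolog map line ", bad[1], ": expected 2 tab-separated columns")
  tab <- unique(data.frame(gene = vapply(parts, `[`, "", 1),
                           group = vapply(parts, `[`, "", 2)))
  dups <- tab$gene[duplicated(tab$gene)]
  if (length(dups))
    stop("conflicting homoeolog groups for gene(s): ",
         paste(unique(dups), collapse = ", "))
  stats::setNames(tab$group, tab$gene)
}

#' Write a homoeolog map TSV
#'
#' @param map named character vector as returned by [readHomoeologMap()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeHomoeologMap <- function(map, path) {
  utils::write.table(data.frame(gene_id = names(map), group_id = unname(map)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
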