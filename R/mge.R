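## TA-MGE association.
##
## A TA-associated mobile element is an MGE harboring a TA locus (full
## containment of the locus span), or an IS/transposon (or IS cluster)
## whose interval to the locus span is strictly below 5 kbp. A plasmid
## replicon is itself a mobile element: every locus it carries is harbored.

MGE_CLASSES <- c("prophage", "genomic_island", "ICE", "integron",
                 "IS_transposon", "IS_cluster", "plasmid")
IS_CLASSES <- c("IS_transposon", "IS_cluster")

#' Read a table of MGE annotations
#'
#' Accepts a TSV with header (`mge_id`, `replicon_id`, `start`, `end`,
#' `class`) in 1-based inclusive coordinates, or a GFF3 file with the
#' class in a `class` (or `mge_class`) attribute. Coordinates are
#' converted to the internal 0-based half-open convention and classes are
#' validated against the closed vocabulary: prophage, genomic_island,
#' ICE, integron, IS_transposon, IS_cluster, plasmid.
#'
#' @param path input file (TSV or GFF3; GFF3 is detected by the
#'   `##gff-version` pragma or a `.gff`/`.gff3` extension).
#' @return data.frame with `mge_id`, `replicon_id`, `start`, `end`
#'   (0-based half-open), `mge_class`.
#' @export
read_mge_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  is_gff <- grepl("\\.gff3?$", path, ignore.case = TRUE) ||
    (length(first) && startsWith(first, "##gff-version"))
  if (is_gff) {
    gr <- rtracklayer::import(path, format = "gff3")
    cls <- if (!is.null(gr$class)) as.character(gr$class)
           else as.character(gr$mge_class)
    df <- data.frame(
      mge_id = if (!is.null(gr$ID)) as.character(gr$ID)
               else sprintf("MGE%04d", seq_along(gr)),
      replicon_id = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      mge_class = cls, stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE,
                             colClasses = "character")
    if (!nrow(tab))
      return(data.frame(mge_id = character(), replicon_id = character(),
                        start = integer(), end = integer(),
                        mge_class = character(), stringsAsFactors = FALSE))
    need <- c("mge_id", "replicon_id", "start", "end", "class")
    miss <- setdiff(need, names(tab))
    if (length(miss))
      stop("MGE table ", path, " is missing column(s): ",
           paste(miss, collapse = ", "))
    df <- data.frame(mge_id = tab$mge_id, replicon_id = tab$replicon_id,
                     start = as.integer(tab$start) - 1L,
                     end = as.integer(tab$end),
                     mge_class = tab$class, stringsAsFactors = FALSE)
  }
  bad <- setdiff(unique(df$mge_class), MGE_CLASSES)
  if (length(bad))
    stop("format error: unknown MGE class(es) ", paste(bad, collapse = ", "),
         "; allowed: ", paste(MGE_CLASSES, collapse = ", "))
  if (any(is.na(df$start) | is.na(df$end) | df$start < 0 |
          df$start >= df$end))
    stop("format error: MGE intervals must satisfy 1 <= start <= end")
  df
}

#' Associate TA loci with mobile genetic elements
#'
#' Emits a `harbored` link when the locus span (leftmost start to
#' rightmost end of its two features) lies fully within an MGE interval,
#' and a `flanking_IS` link when an IS/transposon (or IS cluster) is not
#' containing the locus but lies at an edge-to-edge interval `gap` with
#' `0 <= gap < flank_bp` (strictly below 5 kbp by default). Every
#' qualifying (locus, MGE) pair emits its own link -- a locus associated
#' with several MGEs, or an MGE with several loci, contributes one link
#' per pair. When `replicons` is supplied, each plasmid replicon is
#' treated as a mobile element itself: loci on it gain a harbored link to
#' an implicit whole-replicon plasmid MGE (id `plasmid:<replicon>`),
#' unless the table already contains a plasmid entry for that replicon.
#'
#' @param loci locus data.frame from [resolve_overlaps()].
#' @param mges MGE data.frame from [read_mge_table()].
#' @param flank_bp exclusive upper bound on the flanking interval (bp).
#' @param replicons optional `ta_genome$replicons` data.frame (columns
#'   `id`, `length`, `kind`) used to add implicit plasmid MGEs.
#' @return Link data.frame: `locus_id`, `mge_id`, `mge_class`,
#'   `link_kind` (`harbored`/`flanking_IS`), `gap` (0 for harbored),
#'   `straddles` (TRUE when the locus overlaps the MGE edge without being
#'   contained).
#' @export
associate <- function(loci, mges, flank_bp = ta_defaults()$flank_bp,
                      replicons = NULL) {
  if (!is.null(replicons)) {
    bad <- setdiff(unique(c(loci$replicon_id, mges$replicon_id)),
                   replicons$id)
    if (length(bad))
      stop("unknown replicon id(s) in loci/MGE input: ",
           paste(bad, collapse = ", "))
  }
  mges <- augment_plasmid_mges(mges, replicons)
  links <- list()
  for (i in seq_len(NROW(loci))) {
    l <- loci[i, ]
    ls <- min(l$toxin_start, l$antitoxin_start)
    le <- max(l$toxin_end, l$antitoxin_end)
    on_rep <- which(mges$replicon_id == l$replicon_id)
    for (mi in on_rep) {
      m <- mges[mi, ]
      contained <- ls >= m$start && le <= m$end
      overlap <- min(le, m$end) - max(ls, m$start) > 0
      if (contained) {
        links[[length(links) + 1L]] <- data.frame(
          locus_id = l$locus_id, mge_id = m$mge_id,
          mge_class = m$mge_class, link_kind = "harbored", gap = 0L,
          straddles = FALSE, stringsAsFactors = FALSE)
      } else if (m$mge_class %in% IS_CLASSES) {
        gap <- as.integer(max(ls, m$start) - min(le, m$end))
        if (gap >= 0L && gap < flank_bp)
          links[[length(links) + 1L]] <- data.frame(
            locus_id = l$locus_id, mge_id = m$mge_id,
            mge_class = m$mge_class, link_kind = "flanking_IS", gap = gap,
            straddles = overlap, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(links)) return(empty_links())
  res <- do.call(rbind, links)
  rownames(res) <- NULL
  res
}

## an MGE table entry for each plasmid replicon that lacks one
augment_plasmid_mges <- function(mges, replicons) {
  if (is.null(replicons)) return(mges)
  pl <- replicons[replicons$kind == "plasmid", , drop = FALSE]
  have <- unique(mges$replicon_id[mges$mge_class == "plasmid"])
  add <- pl[!pl$id %in% have, , drop = FALSE]
  if (!nrow(add)) return(mges)
  rbind(mges, data.frame(mge_id = paste0("plasmid:", add$id),
                         replicon_id = add$id, start = 0L,
                         end = as.integer(add$length),
                         mge_class = "plasmid", stringsAsFactors = FALSE))
}

empty_links <- function() {
  data.frame(locus_id = character(), mge_id = character(),
             mge_class = character(), link_kind = character(),
             gap = integer(), straddles = logical(),
             stringsAsFactors = FALSE)
}

#' Write / read TA-MGE links as TSV
#'
#' @param links link data.frame from [associate()].
#' @param path TSV path.
#' @return `path` (writer) or the link data.frame (reader).
#' @export
write_links_tsv <- function(links, path) {
  utils::write.table(links, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_links_tsv
#' @export
read_links_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  miss <- setdiff(names(empty_links()), names(df))
  if (length(miss))
    stop("links TSV ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  df
}
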