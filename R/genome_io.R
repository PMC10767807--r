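## Genome input/output.
##
## Internal coordinate convention: 0-based half-open [start, end) everywhere
## inside the package; conversion to/from 1-based inclusive happens only in
## the readers and writers in this file and in read_mge_table().

#' Construct an annotated genome object
#'
#' Container for one or more replicons plus their annotated features, the
#' input unit of the TA prediction pipeline. All coordinates are 0-based
#' half-open; readers perform the conversion from the 1-based inclusive
#' convention of GenBank and GFF3.
#'
#' @param replicons data.frame with columns `id`, `length`, `topology`
#'   (`linear`/`circular`), `kind` (`chromosome`/`plasmid`), `organism`.
#' @param sequences named [Biostrings::DNAStringSet], names matching
#'   `replicons$id`.
#' @param features data.frame with columns `feature_id`, `replicon_id`,
#'   `start`, `end` (0-based half-open), `strand` (`+`/`-`), `molecule`
#'   (`protein_coding`/`rna`), `product`, `translation` (empty string for
#'   RNA features).
#' @return An object of class `ta_genome`.
#' @export
ta_genome <- function(replicons, sequences, features = NULL) {
  if (is.null(features)) features <- empty_features()
  replicons <- as.data.frame(replicons, stringsAsFactors = FALSE)
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  if (nrow(features)) {
    features <- features[order(features$replicon_id, features$start), ,
                         drop = FALSE]
    rownames(features) <- NULL
  }
  g <- structure(list(replicons = replicons, sequences = sequences,
                      features = features), class = "ta_genome")
  validate_genome(g)
  g
}

empty_features <- function() {
  data.frame(feature_id = character(), replicon_id = character(),
             start = integer(), end = integer(), strand = character(),
             molecule = character(), product = character(),
             translation = character(), stringsAsFactors = FALSE)
}

validate_genome <- function(g) {
  r <- g$replicons
  if (anyDuplicated(r$id)) stop("duplicate replicon ids: ",
                                paste(r$id[duplicated(r$id)], collapse = ", "))
  if (any(r$length <= 0)) stop("replicon with non-positive length")
  if (!all(r$id %in% names(g$sequences)))
    stop("replicons without sequence: ",
         paste(setdiff(r$id, names(g$sequences)), collapse = ", "))
  f <- g$features
  if (nrow(f)) {
    bad <- setdiff(f$replicon_id, r$id)
    if (length(bad)) stop("features reference unknown replicons: ",
                          paste(unique(bad), collapse = ", "))
    len <- r$length[match(f$replicon_id, r$id)]
    if (any(f$start < 0 | f$start >= f$end | f$end > len))
      stop("feature coordinates outside [0, replicon length) convention")
    pc <- f$molecule == "protein_coding"
    if (any(pc & !nzchar(f$translation)))
      stop("protein_coding feature without translation: ",
           paste(f$feature_id[pc & !nzchar(f$translation)], collapse = ", "))
  }
  invisible(g)
}

#' @export
print.ta_genome <- function(x, ...) {
  cat(sprintf("ta_genome: %d replicon(s), %d feature(s)\n",
              nrow(x$replicons), nrow(x$features)))
  for (i in seq_len(nrow(x$replicons)))
    cat(sprintf("  %s  %s %s  %d bp  [%s]\n", x$replicons$id[i],
                x$replicons$topology[i], x$replicons$kind[i],
                x$replicons$length[i], x$replicons$organism[i]))
  invisible(x)
}

## translate a CDS span with the bacterial/archaeal code (table 11);
## internal stops produce a warning and truncate the protein there.
translate_span <- function(seq, start, end, strand, feature_id = "?") {
  dna <- Biostrings::subseq(seq, start + 1L, end)
  if (strand == "-") dna <- Biostrings::reverseComplement(dna)
  n <- floor(Biostrings::nchar(dna) / 3L) * 3L
  if (n == 0L) return("")
  aa <- suppressWarnings(as.character(Biostrings::translate(
    Biostrings::subseq(dna, 1L, n),
    genetic.code = Biostrings::getGeneticCode("11"),
    if.fuzzy.codon = "solve", no.init.codon = FALSE)))
  aa <- sub("\\*$", "", aa)
  if (grepl("*", aa, fixed = TRUE)) {
    warning("internal stop codon in translation of feature ", feature_id,
            "; truncating at first stop", call. = FALSE)
    aa <- sub("\\*.*$", "", aa)
  }
  aa
}

## GenBank location strings: "101..200", "complement(...)", "join(a..b,c..d)",
## partial markers "<"/">". Compound locations collapse to their outer span.
parse_gb_location <- function(loc) {
  strand <- if (grepl("complement", loc)) "-" else "+"
  nums <- as.numeric(regmatches(loc, gregexpr("[0-9]+", loc))[[1]])
  if (length(nums) < 2 || any(is.na(nums)))
    stop("unparseable GenBank location: ", loc)
  list(start = as.integer(min(nums) - 1L), end = as.integer(max(nums)),
       strand = strand)
}

#' Read an annotated genome from a GenBank flat file
#'
#' One replicon per record. CDS features become `protein_coding` features
#' carrying a translation (the `/translation` qualifier when present,
#' otherwise a conceptual translation with the bacterial code, table 11);
#' `ncRNA`/`misc_RNA` features become `rna` features. GenBank 1-based
#' inclusive spans are converted to the package's 0-based half-open
#' convention; compound (`join`) locations collapse to their outer span.
#' Replicons whose LOCUS or DEFINITION line mentions "plasmid" are typed as
#' plasmids, which downstream makes them mobile elements in their own right.
#'
#' @param path path to a GenBank flat file with at least one record.
#' @return A [ta_genome] object.
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec_start <- grep("^LOCUS", lines)
  if (!length(rec_start))
    stop("format error in ", path, ": no LOCUS record found")
  rec_end <- c(rec_start[-1] - 1L, length(lines))

  rep_rows <- list(); seqs <- list(); feat_rows <- list()
  for (ri in seq_along(rec_start)) {
    rec <- lines[rec_start[ri]:rec_end[ri]]
    locus_fields <- strsplit(trimws(rec[1]), "\\s+")[[1]]
    rid <- locus_fields[2]
    if (is.na(rid) || !nzchar(rid))
      stop("format error: bad LOCUS line in record ", ri)
    topology <- if (any(grepl("circular", rec[1]))) "circular" else "linear"
    def <- paste(rec[grep("^DEFINITION|^ {12}", rec[1:min(10, length(rec))])],
                 collapse = " ")
    kind <- if (grepl("plasmid", rec[1], ignore.case = TRUE) ||
                grepl("plasmid", def, ignore.case = TRUE)) "plasmid"
            else "chromosome"
    org_i <- grep("^ {2}ORGANISM", rec)
    organism <- if (length(org_i)) trimws(sub("^ +ORGANISM +", "", rec[org_i[1]]))
                else "unknown organism"

    ori <- grep("^ORIGIN", rec)
    if (!length(ori))
      stop("format error: record ", rid, " has no ORIGIN sequence block")
    seq_lines <- rec[(ori[1] + 1L):length(rec)]
    seq_lines <- seq_lines[!grepl("^//", seq_lines)]
    seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
    if (!nzchar(seq)) stop("format error: record ", rid, " has empty sequence")
    dna <- Biostrings::DNAString(gsub("[^ACGTN]", "N", seq))

    ft_i <- grep("^FEATURES", rec)
    ftab <- if (length(ft_i)) rec[(ft_i[1] + 1L):(ori[1] - 1L)] else character()
    # feature keys start at column 6; qualifier/continuation lines at column 22
    key_i <- grep("^ {5}\\S", ftab)
    for (j in seq_along(key_i)) {
      block <- ftab[key_i[j]:(if (j < length(key_i)) key_i[j + 1] - 1L
                              else length(ftab))]
      key <- sub("^ {5}(\\S+).*", "\\1", block[1])
      if (!key %in% c("CDS", "ncRNA", "misc_RNA")) next
      # location may continue over lines until the first qualifier
      qual_i <- grep("^ +/", block)
      loc_end <- if (length(qual_i)) qual_i[1] - 1L else length(block)
      loc <- gsub("\\s", "", paste(c(sub("^ {5}\\S+\\s+", "", block[1]),
                                     trimws(block[seq_len(loc_end)][-1])),
                                   collapse = ""))
      pos <- tryCatch(parse_gb_location(loc),
                      error = function(e) stop("format error in record ", rid,
                                               ": ", conditionMessage(e)))
      quals <- if (length(qual_i))
        parse_gb_qualifiers(block[qual_i[1]:length(block)], length(qual_i))
      else list()
      fid <- quals[["locus_tag"]] %||% quals[["gene"]] %||%
        sprintf("%s_f%04d", rid, j)
      product <- quals[["product"]] %||% ""
      if (key == "CDS") {
        tr <- quals[["translation"]] %||%
          translate_span(dna, pos$start, pos$end, pos$strand, fid)
        molecule <- "protein_coding"
      } else {
        tr <- ""
        molecule <- "rna"
      }
      feat_rows[[length(feat_rows) + 1L]] <- data.frame(
        feature_id = fid, replicon_id = rid, start = pos$start, end = pos$end,
        strand = pos$strand, molecule = molecule, product = product,
        translation = tr, stringsAsFactors = FALSE)
    }
    rep_rows[[ri]] <- data.frame(id = rid, length = length(dna),
                                 topology = topology, kind = kind,
                                 organism = organism, stringsAsFactors = FALSE)
    seqs[[rid]] <- dna
  }
  sequences <- Biostrings::DNAStringSet(seqs)
  ta_genome(do.call(rbind, rep_rows), sequences,
            if (length(feat_rows)) do.call(rbind, feat_rows)
            else empty_features())
}

parse_gb_qualifiers <- function(qlines, n_qual) {
  if (n_qual == 0) return(list())
  txt <- paste(trimws(qlines), collapse = "\n")
  # split on newlines that start a new qualifier; join continuations
  parts <- strsplit(txt, "\n(?=/)", perl = TRUE)[[1]]
  out <- list()
  for (p in parts) {
    p <- gsub("\n", "", p)
    if (!startsWith(p, "/")) next
    kv <- regmatches(p, regexec('^/([A-Za-z_]+)=?"?([^"]*)"?$', p))[[1]]
    if (length(kv) == 3) out[[kv[2]]] <- kv[3]
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an annotated genome from FASTA plus GFF3
#'
#' Same model as [read_genbank()]: GFF3 `CDS` rows become protein-coding
#' features whose translations are derived from the replicon sequence with
#' the bacterial genetic code (table 11); `ncRNA`-like rows (`ncRNA`,
#' `sRNA`, `misc_RNA`, `antisense_RNA`) become `rna` features. Every GFF3
#' seqid must be present in the FASTA.
#'
#' @param fasta path to replicon FASTA (nucleotide).
#' @param gff path to a GFF3 annotation of the same replicons.
#' @return A [ta_genome] object.
#' @export
read_fasta_gff <- function(fasta, gff) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (!length(seqs)) stop("format error: empty FASTA ", fasta)
  desc <- names(seqs)
  ids <- sub("\\s.*$", "", desc)
  names(seqs) <- ids
  seqs <- Biostrings::DNAStringSet(toupper(seqs))

  gr <- tryCatch(rtracklayer::import(gff, format = "gff3"),
                 error = function(e) stop("format error in ", gff, ": ",
                                          conditionMessage(e), call. = FALSE))
  seqid <- as.character(GenomicRanges::seqnames(gr))
  missing <- setdiff(unique(seqid), ids)
  if (length(missing))
    stop("GFF3 seqids absent from FASTA: ", paste(missing, collapse = ", "))

  kind <- ifelse(grepl("plasmid", desc, ignore.case = TRUE),
                 "plasmid", "chromosome")
  topology <- ifelse(grepl("circular", desc, ignore.case = TRUE),
                     "circular", "linear")
  organism <- vapply(desc, function(d) {
    m <- regmatches(d, regexec("\\[organism=([^]]+)\\]", d))[[1]]
    if (length(m) == 2) m[2] else "unknown organism"
  }, character(1), USE.NAMES = FALSE)
  replicons <- data.frame(id = ids, length = Biostrings::width(seqs),
                          topology = topology, kind = kind,
                          organism = organism, stringsAsFactors = FALSE)

  type <- as.character(gr$type)
  rna_types <- c("ncRNA", "sRNA", "misc_RNA", "antisense_RNA")
  keep <- type %in% c("CDS", rna_types)
  gr <- gr[keep]; type <- type[keep]; seqid <- seqid[keep]
  n <- length(gr)
  if (n) {
    start0 <- GenomicRanges::start(gr) - 1L
    end0 <- GenomicRanges::end(gr)
    strand <- as.character(GenomicRanges::strand(gr))
    strand[strand == "*"] <- "+"
    fid <- if (!is.null(gr$ID)) as.character(gr$ID) else rep(NA_character_, n)
    fid[is.na(fid)] <- sprintf("%s_f%04d", seqid[is.na(fid)],
                               which(is.na(fid)))
    product <- if (!is.null(gr$product)) as.character(gr$product)
               else rep("", n)
    product[is.na(product)] <- ""
    molecule <- ifelse(type == "CDS", "protein_coding", "rna")
    translation <- character(n)
    given <- if (!is.null(gr$translation)) as.character(gr$translation)
             else rep(NA_character_, n)
    for (i in which(molecule == "protein_coding"))
      translation[i] <- if (!is.na(given[i]) && nzchar(given[i])) given[i]
        else translate_span(seqs[[seqid[i]]], start0[i], end0[i],
                            strand[i], fid[i])
    features <- data.frame(feature_id = fid, replicon_id = seqid,
                           start = start0, end = end0, strand = strand,
                           molecule = molecule, product = product,
                           translation = translation, stringsAsFactors = FALSE)
  } else features <- empty_features()
  ta_genome(replicons, seqs, features)
}

gff_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  gsub(",", "%2C", x, fixed = TRUE)
}

#' Write predicted TA loci as GFF3
#'
#' One feature row per toxin and per antitoxin, grouped by a shared
#' `locus` attribute; internal 0-based half-open coordinates are converted
#' back to GFF3's 1-based inclusive convention. Attributes carry the TA
#' type, variant, family and the H-values of both partners.
#'
#' @param loci data.frame of called loci as returned by [call_loci()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_predictions_gff <- function(loci, path) {
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(NROW(loci))) {
    l <- loci[i, ]
    for (part in c("toxin", "antitoxin")) {
      s0 <- l[[paste0(part, "_start")]]
      e0 <- l[[paste0(part, "_end")]]
      attrs <- sprintf(
        "ID=%s;locus=%s;role=%s;ta_type=%s;variant=%s;family=%s;h_value=%s",
        gff_escape(paste0(l$locus_id, "_", part)), gff_escape(l$locus_id),
        part, l$ta_type, gff_escape(l$variant), gff_escape(l$family),
        format(l[[paste0(part, "_h_value")]], digits = 6))
      writeLines(sprintf("%s\ttascan\t%s\t%d\t%d\t%s\t%s\t.\t%s",
                         l$replicon_id,
                         if (part == "toxin") "toxin_gene" else "antitoxin_gene",
                         s0 + 1L, e0, format(l$score, digits = 6),
                         l[[paste0(part, "_strand")]], attrs), con)
    }
  }
  invisible(path)
}

#' Write a genome as FASTA plus GFF3
#'
#' Inverse of [read_fasta_gff()] at the feature level: coordinates go back
#' to 1-based inclusive, translations are carried in the GFF3 attributes so
#' a round trip preserves them, and replicon kind/organism are encoded in
#' the FASTA description line.
#'
#' @param genome a [ta_genome].
#' @param fasta,gff output paths.
#' @return Named list of the two paths, invisibly.
#' @export
write_genome <- function(genome, fasta, gff) {
  seqs <- genome$sequences
  r <- genome$replicons
  names(seqs) <- sprintf("%s %s %s [organism=%s]", r$id, r$topology,
                         ifelse(r$kind == "plasmid", "plasmid", "chromosome"),
                         r$organism)
  Biostrings::writeXStringSet(seqs, fasta, width = 70)
  con <- file(gff, "w"); on.exit(close(con))
  writeLines("##gff-version 3", con)
  f <- genome$features
  for (i in seq_len(nrow(f))) {
    type <- if (f$molecule[i] == "protein_coding") "CDS" else "ncRNA"
    attrs <- sprintf("ID=%s;product=%s", gff_escape(f$feature_id[i]),
                     gff_escape(f$product[i]))
    if (nzchar(f$translation[i]))
      attrs <- paste0(attrs, ";translation=", f$translation[i])
    writeLines(sprintf("%s\ttascan\t%s\t%d\t%d\t.\t%s\t%s\t%s",
                       f$replicon_id[i], type, f$start[i] + 1L, f$end[i],
                       f$strand[i], if (type == "CDS") "0" else ".",
                       attrs), con)
  }
  invisible(list(fasta = fasta, gff = gff))
}
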