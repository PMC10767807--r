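## Homology search for candidate toxins and antitoxins.
##
## Protein candidates come from local alignment of annotated translations
## against the reference proteins (Smith-Waterman, BLOSUM62, affine gaps
## open=11 extend=1 -- BLASTp-like defaults). RNA candidates come from
## nucleotide local alignment of the reference RNAs against the replicon
## sequence on both strands (match=+2, mismatch=-3, gaps open=5 extend=2 --
## megablast-like defaults). The H-value (identity x query coverage, with
## the reference as query) is the retention criterion downstream.

# Karlin-Altschul parameters for the two scoring systems, used to convert a
# raw local-alignment score into a bit score and E-value (E = K*m*n*e^(-lambda*S)).
KA_PROTEIN <- list(lambda = 0.267, K = 0.041)
KA_NUCLEOTIDE <- list(lambda = 0.625, K = 0.41)

#' Combined identity-coverage score of a homology hit (H-value)
#'
#' The candidate-retention score of the pipeline: the product of the
#' alignment identity fraction and the fraction of the reference (query)
#' covered by the alignment. Candidates are kept when the H-value is
#' strictly greater than the threshold (default 0.36, i.e. 60% identity
#' over 60% of the reference).
#'
#' @param identity fraction of identical alignment columns, in \[0,1\].
#' @param query_coverage fraction of the reference length aligned, in \[0,1\].
#' @return `identity * query_coverage`.
#' @export
#' @examples
#' h_value(0.9, 0.5)   # 0.45, passes the > 0.36 filter
#' h_value(0.6, 0.6)   # 0.36 exactly, fails the strict filter
h_value <- function(identity, query_coverage) {
  if (any(identity < 0 | identity > 1, na.rm = TRUE) ||
      any(query_coverage < 0 | query_coverage > 1, na.rm = TRUE))
    stop("identity and query_coverage must lie in [0, 1]")
  identity * query_coverage
}

#' Local alignment of a reference (query) against a target sequence
#'
#' Thin wrapper around [Biostrings::pairwiseAlignment()] in local mode with
#' the package's scoring systems. The reference plays the role of the
#' query: coverage is measured on it.
#'
#' @param ref reference sequence (character).
#' @param target target sequence (character).
#' @param molecule `"protein"` (BLOSUM62, gap open 11 extend 1) or
#'   `"dna"` (match +2 / mismatch -3, gap open 5 extend 2).
#' @return list with `score` (raw), `identity`, `query_coverage`,
#'   `h_value`, `target_start`/`target_end` (0-based half-open on the
#'   target), `query_start`/`query_end` (1-based inclusive on the
#'   reference).
#' @export
align_local <- function(ref, target, molecule = c("protein", "dna")) {
  molecule <- match.arg(molecule)
  if (molecule == "protein") {
    sm <- get_blosum62()
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(ref), Biostrings::AAString(target),
      substitutionMatrix = sm, gapOpening = 11, gapExtension = 1,
      type = "local")
  } else {
    sm <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                   baseOnly = FALSE)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(ref), Biostrings::DNAString(target),
      substitutionMatrix = sm, gapOpening = 5, gapExtension = 2,
      type = "local")
  }
  summarize_alignment(aln, nchar(ref))
}

summarize_alignment <- function(aln, ref_len) {
  alen <- Biostrings::nchar(aln)                 # alignment columns
  ident <- if (alen > 0) Biostrings::nmatch(aln) / alen else 0
  prange <- aln@pattern@range
  srange <- aln@subject@range
  qcov <- BiocGenerics::width(prange) / ref_len
  list(score = Biostrings::score(aln), identity = ident,
       query_coverage = qcov, h_value = ident * qcov,
       target_start = BiocGenerics::start(srange) - 1L,
       target_end = BiocGenerics::end(srange),
       query_start = BiocGenerics::start(prange),
       query_end = BiocGenerics::end(prange))
}

get_blosum62 <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})

ka_evalue <- function(score, m, n, ka) {
  ka$K * m * n * exp(-ka$lambda * score)
}

empty_hits <- function() {
  data.frame(feature_id = character(), replicon_id = character(),
             start = integer(), end = integer(), strand = character(),
             molecule = character(), ref_id = character(), role = character(),
             ta_type = character(), family = character(), identity = numeric(),
             query_coverage = numeric(), score = numeric(),
             bitscore = numeric(), evalue = numeric(), h_value = numeric(),
             length_aa = integer(), synthetic_feature = logical(),
             stringsAsFactors = FALSE)
}

#' Search protein references against annotated translations
#'
#' Aligns every reference protein (query) against the translation of every
#' protein-coding feature (target) with the built-in local aligner and
#' reports hits below the raw E-value ceiling, with identity, query
#' coverage and H-value populated.
#'
#' @param genome a [ta_genome].
#' @param refs protein reference data.frame from [read_reference_fasta()].
#' @param evalue_max permissive raw E-value ceiling for reporting hits.
#' @return Hit data.frame (one row per feature x reference pair retained).
#' @export
search_protein <- function(genome, refs,
                           evalue_max = ta_defaults()$evalue_blast) {
  if (is.null(refs) || nrow(refs) == 0) stop("empty protein reference set")
  stopifnot(all(refs$molecule == "protein"))
  feats <- genome$features[genome$features$molecule == "protein_coding", ,
                           drop = FALSE]
  if (!nrow(feats)) return(empty_hits())
  sm <- get_blosum62()
  pats <- Biostrings::AAStringSet(refs$sequence)
  out <- vector("list", nrow(feats))
  for (i in seq_len(nrow(feats))) {
    subj <- feats$translation[i]
    alns <- Biostrings::pairwiseAlignment(
      pats, Biostrings::AAString(subj), substitutionMatrix = sm,
      gapOpening = 11, gapExtension = 1, type = "local")
    scores <- Biostrings::score(alns)
    ev <- ka_evalue(scores, nchar(refs$sequence), nchar(subj), KA_PROTEIN)
    keep <- which(ev <= evalue_max)
    if (!length(keep)) next
    rows <- lapply(keep, function(j) {
      s <- summarize_alignment(alns[j], nchar(refs$sequence[j]))
      data.frame(feature_id = feats$feature_id[i],
                 replicon_id = feats$replicon_id[i],
                 start = feats$start[i], end = feats$end[i],
                 strand = feats$strand[i], molecule = "protein",
                 ref_id = refs$ref_id[j], role = refs$role[j],
                 ta_type = refs$ta_type[j], family = refs$family[j],
                 identity = s$identity, query_coverage = s$query_coverage,
                 score = s$score,
                 bitscore = (KA_PROTEIN$lambda * s$score - log(KA_PROTEIN$K)) / log(2),
                 evalue = ev[j], h_value = s$h_value,
                 length_aa = nchar(feats$translation[i]),
                 synthetic_feature = FALSE, stringsAsFactors = FALSE)
    })
    out[[i]] <- do.call(rbind, rows)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty_hits())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Search RNA references against replicon sequences
#'
#' Aligns each reference RNA (query) against each replicon on both strands
#' with the built-in nucleotide local aligner. Hits are reported below the
#' E-value ceiling; several non-overlapping placements of the same
#' reference are found by masking each hit and realigning. A hit that does
#' not reciprocally overlap (>= 50% of each) an annotated same-strand RNA
#' feature gives rise to a synthetic `rna` feature spanning the full
#' projection of the reference (the aligned target interval extended by the
#' reference's unaligned termini, clamped to the replicon), so that a
#' substitution-diverged copy keeps its exact planted span.
#'
#' @inheritParams search_protein
#' @param refs RNA reference data.frame (`molecule == "rna"`).
#' @param max_hits_per_ref cap on masked re-search iterations per
#'   reference/replicon/strand.
#' @return Hit data.frame; `synthetic_feature` marks hits without a
#'   matching annotated RNA feature.
#' @export
search_rna <- function(genome, refs, evalue_max = ta_defaults()$evalue_blast,
                       max_hits_per_ref = 8L) {
  if (is.null(refs) || nrow(refs) == 0) stop("empty RNA reference set")
  stopifnot(all(refs$molecule == "rna"))
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                 baseOnly = FALSE)
  ann_rna <- genome$features[genome$features$molecule == "rna", , drop = FALSE]
  out <- list()
  for (ri in seq_len(nrow(genome$replicons))) {
    rid <- genome$replicons$id[ri]
    L <- genome$replicons$length[ri]
    for (str in c("+", "-")) {
      subj <- genome$sequences[[rid]]
      if (str == "-") subj <- Biostrings::reverseComplement(subj)
      for (j in seq_len(nrow(refs))) {
        qlen <- nchar(refs$sequence[j])
        if (qlen > L) next
        work <- subj
        for (iter in seq_len(max_hits_per_ref)) {
          aln <- Biostrings::pairwiseAlignment(
            Biostrings::DNAString(refs$sequence[j]), work,
            substitutionMatrix = sm, gapOpening = 5, gapExtension = 2,
            type = "local")
          s <- summarize_alignment(aln, qlen)
          ev <- ka_evalue(s$score, qlen, L, KA_NUCLEOTIDE)
          if (ev > evalue_max || s$target_end <= s$target_start) break
          # project the full reference extent onto the target, anchored at
          # the alignment start; substitution-only divergence then yields
          # the exact source span
          fs <- s$target_start - (s$query_start - 1L)
          fe <- fs + qlen
          fs <- max(0L, fs); fe <- min(L, fe)
          if (str == "-") { tmp <- fs; fs <- L - fe; fe <- L - tmp }
          # adopt an annotated RNA feature on the same strand when the
          # reciprocal overlap reaches 50%
          fid <- NA_character_; synth <- TRUE
          if (nrow(ann_rna)) {
            cand <- ann_rna[ann_rna$replicon_id == rid &
                            ann_rna$strand == str, , drop = FALSE]
            if (nrow(cand)) {
              ov <- pmin(cand$end, fe) - pmax(cand$start, fs)
              recip <- ov >= 0.5 * (fe - fs) & ov >= 0.5 * (cand$end - cand$start)
              if (any(recip)) {
                kbest <- which(recip)[which.max(ov[recip])]
                fid <- cand$feature_id[kbest]; synth <- FALSE
                fs <- cand$start[kbest]; fe <- cand$end[kbest]
              }
            }
          }
          if (is.na(fid)) fid <- sprintf("rna_%s_%d_%d_%s", rid, fs, fe,
                                         if (str == "+") "p" else "m")
          out[[length(out) + 1L]] <- data.frame(
            feature_id = fid, replicon_id = rid, start = fs, end = fe,
            strand = str, molecule = "rna", ref_id = refs$ref_id[j],
            role = refs$role[j], ta_type = refs$ta_type[j],
            family = refs$family[j], identity = s$identity,
            query_coverage = s$query_coverage, score = s$score,
            bitscore = (KA_NUCLEOTIDE$lambda * s$score - log(KA_NUCLEOTIDE$K)) / log(2),
            evalue = ev, h_value = s$h_value, length_aa = NA_integer_,
            synthetic_feature = synth, stringsAsFactors = FALSE)
          # mask the aligned interval (in the working strand's frame)
          mask_s <- s$target_start + 1L; mask_e <- s$target_end
          work <- Biostrings::replaceLetterAt(
            work, seq(mask_s, mask_e),
            paste(rep("N", mask_e - mask_s + 1L), collapse = ""))
        }
      }
    }
  }
  if (!length(out)) return(empty_hits())
  res <- do.call(rbind, out)
  # the same placement can be reached from both masking iterations of
  # overlapping references; keep one row per (feature, ref)
  res <- res[!duplicated(res[, c("feature_id", "ref_id")]), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Scan protein features against domain profiles (HMMER)
#'
#' Runs `hmmsearch` (HMMER 3) with the given profile-HMM file against all
#' annotated translations and returns per-domain hits at or below the
#' E-value threshold. Profile names are expected to follow the
#' `family_type_role` convention (e.g. `relBE_II_toxin`) so that hits can
#' seed typed candidates; profiles without a parseable role are reported
#' with `role = NA`.
#'
#' @param genome a [ta_genome].
#' @param profiles path to a HMMER3 text-format profile file.
#' @param evalue_max domain E-value threshold (default 1e-5).
#' @return data.frame with `feature_id`, `profile_id`, `role`, `ta_type`,
#'   `family`, `evalue`, `score`.
#' @export
scan_domains <- function(genome, profiles,
                         evalue_max = ta_defaults()$evalue_hmm) {
  if (!file.exists(profiles)) stop("no such profile file: ", profiles)
  head1 <- readLines(profiles, n = 1L, warn = FALSE)
  if (!length(head1) || !grepl("^HMMER3", head1))
    stop("format error: ", profiles, " is not a HMMER3 text profile file")
  empty <- data.frame(feature_id = character(), profile_id = character(),
                      role = character(), ta_type = character(),
                      family = character(), evalue = numeric(),
                      score = numeric(), stringsAsFactors = FALSE)
  feats <- genome$features[genome$features$molecule == "protein_coding", ,
                           drop = FALSE]
  if (!nrow(feats)) return(empty)
  hmmsearch <- Sys.which("hmmsearch")
  if (!nzchar(hmmsearch)) stop("hmmsearch (HMMER 3) not found on PATH")
  faa <- tempfile(fileext = ".faa"); on.exit(unlink(faa), add = TRUE)
  aas <- Biostrings::AAStringSet(feats$translation)
  names(aas) <- feats$feature_id
  Biostrings::writeXStringSet(aas, faa)
  tbl <- tempfile(fileext = ".domtbl"); on.exit(unlink(tbl), add = TRUE)
  status <- system2(hmmsearch, c("--domtblout", shQuote(tbl), "-E", "10",
                                 "--noali", shQuote(profiles), shQuote(faa)),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("hmmsearch failed on ", profiles)
  lines <- readLines(tbl, warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) return(empty)
  f <- strsplit(trimws(lines), "\\s+")
  rows <- lapply(f, function(x) {
    prof <- x[4]
    toks <- strsplit(prof, "_", fixed = TRUE)[[1]]
    role <- if (toks[length(toks)] %in% c("toxin", "antitoxin"))
      toks[length(toks)] else NA_character_
    ta_type <- if (length(toks) >= 3 && toks[length(toks) - 1] %in% ROMAN_TYPES)
      toks[length(toks) - 1] else NA_character_
    family <- if (!is.na(ta_type))
      paste(toks[seq_len(length(toks) - 2)], collapse = "_")
    else sub("_(toxin|antitoxin)$", "", prof)
    data.frame(feature_id = x[1], profile_id = prof, role = role,
               ta_type = ta_type, family = family,
               evalue = as.numeric(x[13]),     # independent domain E-value
               score = as.numeric(x[14]), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[res$evalue <= evalue_max, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Build typed toxin/antitoxin candidates from homology evidence
#'
#' One candidate per (feature, role, TA type): retained when its best
#' alignment hit has H-value strictly greater than `h_cutoff`, or (unless
#' `require_blast`) a domain hit supports it. Protein candidates must
#' additionally have a translation length within `[len_min, len_max]`
#' amino acids, bounds inclusive. The candidate family is taken from the
#' best-scoring evidence record.
#'
#' @param hits alignment hits from [search_protein()] / [search_rna()]
#'   (may be rbind-ed).
#' @param domain_hits domain hits from [scan_domains()], or NULL.
#' @param genome the [ta_genome] the evidence came from.
#' @param h_cutoff strict lower bound on the H-value.
#' @param len_min,len_max inclusive protein length bounds (aa).
#' @param require_blast if TRUE (the stringent large-scale mode), domain
#'   evidence alone cannot retain a candidate.
#' @return Candidate data.frame sorted by decreasing H-value, columns
#'   `feature_id`, `replicon_id`, `start`, `end`, `strand`, `molecule`,
#'   `role`, `ta_type`, `family`, `h_value`, `evalue`, `evidence`,
#'   `ref_id`, `length_aa`, `synthetic_feature`.
#' @export
build_candidates <- function(hits, domain_hits = NULL, genome = NULL,
                             h_cutoff = ta_defaults()$h_value,
                             len_min = ta_defaults()$len_min,
                             len_max = ta_defaults()$len_max,
                             require_blast = FALSE) {
  if (is.null(hits)) hits <- empty_hits()
  cands <- list()
  if (nrow(hits)) {
    key <- paste(hits$feature_id, hits$role, hits$ta_type, sep = "\r")
    for (k in unique(key)) {
      grp <- hits[key == k, , drop = FALSE]
      best <- grp[order(-grp$h_value, -grp$score), , drop = FALSE][1, ]
      cands[[k]] <- data.frame(
        feature_id = best$feature_id, replicon_id = best$replicon_id,
        start = best$start, end = best$end, strand = best$strand,
        molecule = best$molecule, role = best$role, ta_type = best$ta_type,
        family = best$family, h_value = best$h_value, evalue = best$evalue,
        evidence = "blast", ref_id = best$ref_id,
        length_aa = best$length_aa,
        synthetic_feature = best$synthetic_feature, stringsAsFactors = FALSE)
    }
  }
  if (!is.null(domain_hits) && nrow(domain_hits)) {
    dh <- domain_hits[!is.na(domain_hits$role) & !is.na(domain_hits$ta_type), ,
                      drop = FALSE]
    if (nrow(dh) < nrow(domain_hits))
      warning("dropping ", nrow(domain_hits) - nrow(dh),
              " domain hit(s) without parseable role/type in profile name")
    key <- paste(dh$feature_id, dh$role, dh$ta_type, sep = "\r")
    for (k in unique(key)) {
      grp <- dh[key == k, , drop = FALSE]
      best <- grp[order(grp$evalue), , drop = FALSE][1, ]
      if (!is.null(cands[[k]])) {
        cands[[k]]$evidence <- "both"
        next
      }
      if (is.null(genome))
        stop("genome required to locate domain-only candidates")
      fi <- match(best$feature_id, genome$features$feature_id)
      if (is.na(fi)) next
      f <- genome$features[fi, ]
      cands[[k]] <- data.frame(
        feature_id = f$feature_id, replicon_id = f$replicon_id,
        start = f$start, end = f$end, strand = f$strand,
        molecule = "protein", role = best$role, ta_type = best$ta_type,
        family = best$family, h_value = NA_real_, evalue = best$evalue,
        evidence = "hmm", ref_id = best$profile_id,
        length_aa = nchar(f$translation), synthetic_feature = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(cands)) return(empty_candidates())
  res <- do.call(rbind, cands)
  pass_h <- !is.na(res$h_value) & res$h_value > h_cutoff
  has_hmm <- res$evidence %in% c("hmm", "both")
  # OR of the two evidence kinds by default; the stringent large-scale
  # mode insists on the alignment criterion
  keep <- if (require_blast) pass_h else (pass_h | has_hmm)
  res <- res[keep, , drop = FALSE]
  prot <- res$molecule == "protein"
  res <- res[!prot | (res$length_aa >= len_min & res$length_aa <= len_max), ,
             drop = FALSE]
  res <- res[order(-ifelse(is.na(res$h_value), -1, res$h_value)), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

empty_candidates <- function() {
  data.frame(feature_id = character(), replicon_id = character(),
             start = integer(), end = integer(), strand = character(),
             molecule = character(), role = character(), ta_type = character(),
             family = character(), h_value = numeric(), evalue = numeric(),
             evidence = character(), ref_id = character(),
             length_aa = integer(), synthetic_feature = logical(),
             stringsAsFactors = FALSE)
}

#' Export homology hits as a BLAST-outfmt6-like TSV
#'
#' Standard 12 columns plus `h_value`, written with the reference as query.
#'
#' @param hits hit data.frame from the search functions.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  out <- data.frame(qseqid = hits$ref_id, sseqid = hits$feature_id,
                    pident = round(hits$identity * 100, 2),
                    length = NA_integer_, mismatch = NA_integer_,
                    gapopen = NA_integer_, qstart = NA_integer_,
                    qend = NA_integer_, sstart = hits$start + 1L,
                    send = hits$end, evalue = signif(hits$evalue, 3),
                    bitscore = round(hits$bitscore, 1),
                    h_value = round(hits$h_value, 4))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
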