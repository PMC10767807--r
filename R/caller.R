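## Pairing candidates into TA loci with type-specific strand and
## intergenic-distance rules.
##
## Rule windows (bundled rules.tsv, user-overridable):
##   types II-VII : protein partners in tandem on the same strand,
##                  distance in [-20, 150] bp (negative = overlap)
##   type I       : protein toxin + antisense RNA antitoxin on opposite
##                  strands, distance <= 200 bp, overlap unlimited
##   type VIII    : RNA toxin + RNA antitoxin; creTA variant on either
##                  strand, distance <= 200 bp; SdsR-RyeA variant on
##                  opposite strands, overlap required (distance < 0)
## Type III keeps the tandem-operon window of II-VII with an RNA antitoxin.

#' TA pairing rule table
#'
#' Loads the rule table mapping each TA type (and type VIII variant) to
#' the molecules of its partners, its strand constraint, and its inclusive
#' intergenic-distance window `[dmin, dmax]` in bp (negative values are
#' overlaps; `-Inf` means unlimited overlap). The bundled table encodes
#' the windows listed above; users may supply a TSV with the same columns
#' to tighten or loosen windows without code changes.
#'
#' @param path optional path to a replacement rules TSV with columns
#'   `ta_type`, `variant`, `toxin_molecule`, `antitoxin_molecule`,
#'   `strand` (`same`/`opposite`/`either`), `dmin`, `dmax`.
#' @return data.frame of pairing rules.
#' @export
ta_rules <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "rules.tsv", package = "tascan",
                        mustWork = TRUE)
  r <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("ta_type", "variant", "toxin_molecule", "antitoxin_molecule",
            "strand", "dmin", "dmax")
  if (!all(need %in% names(r)))
    stop("rules table must have columns: ", paste(need, collapse = ", "))
  r$dmin <- as.numeric(r$dmin); r$dmax <- as.numeric(r$dmax)
  if (!all(r$strand %in% c("same", "opposite", "either")))
    stop("rules strand must be same/opposite/either")
  r
}

#' Intergenic distance between two features
#'
#' Gap between the nearest edges of two intervals on the same replicon:
#' `max(start) - min(end)` under the 0-based half-open convention.
#' Negative values are overlap lengths (-n means n bp of overlap); the
#' measure is symmetric in its arguments.
#'
#' @param a,b rows (or lists) with `replicon_id`, `start`, `end`.
#' @return Signed integer distance in bp.
#' @export
#' @examples
#' a <- list(replicon_id = "c", start = 100, end = 200)
#' b <- list(replicon_id = "c", start = 350, end = 450)
#' intergenic_distance(a, b)   # 150
intergenic_distance <- function(a, b) {
  if (!identical(as.character(a$replicon_id), as.character(b$replicon_id)))
    stop("features lie on different replicons: ", a$replicon_id, " vs ",
         b$replicon_id)
  as.integer(max(a$start, b$start) - min(a$end, b$end))
}

strand_ok <- function(constraint, s1, s2) {
  switch(constraint,
         same = s1 == s2,
         opposite = s1 != s2,
         either = TRUE,
         stop("unknown strand constraint: ", constraint))
}

## variant of a type VIII pair, decided from the candidates' families:
## any partner annotated to the SdsR-RyeA family selects the overlap-only
## variant, otherwise creTA.
viii_variant <- function(fam_toxin, fam_antitoxin) {
  if (grepl("sdsr", fam_toxin, ignore.case = TRUE) ||
      grepl("sdsr", fam_antitoxin, ignore.case = TRUE)) "VIII-sdsr"
  else "VIII-creTA"
}

#' Call TA loci from typed candidates
#'
#' Evaluates every (toxin candidate, antitoxin candidate) pair of the same
#' TA type on the same replicon exhaustively against the type's rule:
#' strand constraint and inclusive distance window. Both gene orders are
#' admissible wherever the strand constraint allows them. The locus score
#' is the minimum of the two partners' H-values -- a pair is only as
#' credible as its weaker partner.
#'
#' @param candidates candidate data.frame from [build_candidates()].
#' @param rules rule table from [ta_rules()].
#' @return Locus data.frame, one row per called pair: `locus_id`,
#'   `replicon_id`, `ta_type`, `variant`, `family`, `family_conflict`,
#'   toxin/antitoxin coordinates, strands, H-values and feature ids,
#'   `distance`, `score`.
#' @export
call_loci <- function(candidates, rules = ta_rules()) {
  loci <- list()
  if (NROW(candidates)) {
    tox <- candidates[candidates$role == "toxin", , drop = FALSE]
    ant <- candidates[candidates$role == "antitoxin", , drop = FALSE]
    for (i in seq_len(nrow(tox))) for (j in seq_len(nrow(ant))) {
      t <- tox[i, ]; a <- ant[j, ]
      if (t$ta_type != a$ta_type) next
      if (t$replicon_id != a$replicon_id) next
      if (t$feature_id == a$feature_id) next
      variant <- if (t$ta_type == "VIII") viii_variant(t$family, a$family)
                 else t$ta_type
      ri <- match(variant, rules$variant)
      if (is.na(ri)) next
      rule <- rules[ri, ]
      if (t$molecule != rule$toxin_molecule ||
          a$molecule != rule$antitoxin_molecule) next
      if (!strand_ok(rule$strand, t$strand, a$strand)) next
      d <- intergenic_distance(t, a)
      if (d < rule$dmin || d > rule$dmax) next
      conflict <- !identical(t$family, a$family)
      loci[[length(loci) + 1L]] <- data.frame(
        locus_id = NA_character_, replicon_id = t$replicon_id,
        ta_type = t$ta_type, variant = variant,
        family = t$family, family_conflict = conflict,
        toxin_feature_id = t$feature_id, toxin_start = t$start,
        toxin_end = t$end, toxin_strand = t$strand,
        toxin_h_value = t$h_value,
        antitoxin_feature_id = a$feature_id, antitoxin_start = a$start,
        antitoxin_end = a$end, antitoxin_strand = a$strand,
        antitoxin_h_value = a$h_value,
        distance = d, score = locus_score(t$h_value, a$h_value),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(loci)) return(empty_loci())
  res <- do.call(rbind, loci)
  res$locus_id <- sprintf("TA_%s_%05d", res$replicon_id,
                          seq_len(nrow(res)))
  rownames(res) <- NULL
  res
}

## a pair is as credible as its weaker partner; domain-only candidates
## (H-value NA) fall back to the partner's H-value, NA if neither has one.
locus_score <- function(h_toxin, h_antitoxin) {
  hs <- c(h_toxin, h_antitoxin)
  if (all(is.na(hs))) NA_real_ else min(hs, na.rm = TRUE)
}

empty_loci <- function() {
  data.frame(locus_id = character(), replicon_id = character(),
             ta_type = character(), variant = character(),
             family = character(), family_conflict = logical(),
             toxin_feature_id = character(), toxin_start = integer(),
             toxin_end = integer(), toxin_strand = character(),
             toxin_h_value = numeric(), antitoxin_feature_id = character(),
             antitoxin_start = integer(), antitoxin_end = integer(),
             antitoxin_strand = character(), antitoxin_h_value = numeric(),
             distance = integer(), score = numeric(),
             stringsAsFactors = FALSE)
}

#' Resolve loci sharing the same feature pair
#'
#' When the same (toxin feature, antitoxin feature) pair is called under
#' different types or families, only the highest-scoring call is kept
#' (ties broken by lower TA type number, then lexicographic family). Loci
#' sharing only one feature are all retained. Output is sorted by
#' (replicon, leftmost coordinate) and locus ids are reassigned in that
#' order.
#'
#' @param loci locus data.frame from [call_loci()].
#' @return De-duplicated, sorted locus data.frame.
#' @export
resolve_overlaps <- function(loci) {
  if (!NROW(loci)) return(empty_loci())
  key <- paste(loci$toxin_feature_id, loci$antitoxin_feature_id, sep = "\r")
  type_rank <- match(loci$ta_type, ROMAN_TYPES)
  ord <- order(key, -ifelse(is.na(loci$score), -Inf, loci$score),
               type_rank, loci$family)
  loci <- loci[ord, , drop = FALSE]
  loci <- loci[!duplicated(paste(loci$toxin_feature_id,
                                 loci$antitoxin_feature_id, sep = "\r")), ,
               drop = FALSE]
  minstart <- pmin(loci$toxin_start, loci$antitoxin_start)
  loci <- loci[order(loci$replicon_id, minstart), , drop = FALSE]
  loci$locus_id <- sprintf("TA_%s_%05d", loci$replicon_id,
                           seq_len(nrow(loci)))
  rownames(loci) <- NULL
  loci
}

#' Write / read called loci as TSV
#'
#' One row per locus; coordinates stay in the internal 0-based half-open
#' convention (the GFF3 writer is the 1-based outlet). These TSVs are the
#' interchange format between pipeline stages.
#'
#' @param loci locus data.frame.
#' @param path TSV path.
#' @return `path` (writer) or the locus data.frame (reader).
#' @export
write_loci_tsv <- function(loci, path) {
  utils::write.table(loci, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_loci_tsv
#' @export
read_loci_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- names(empty_loci())
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("loci TSV ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  df$replicon_id <- as.character(df$replicon_id)
  df
}
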