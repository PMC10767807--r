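# Independent oracles used by the test suite. These re-derive expected
# results by brute force and must stay independent of the package's own
# code paths.

# Gotoh affine-gap local alignment score; a gap of length L costs
# open + L * ext, matching the package's alignment conventions.
oracle_sw_score <- function(a, b, molecule = c("protein", "dna")) {
  molecule <- match.arg(molecule)
  if (molecule == "protein") {
    e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
    submat <- e$BLOSUM62; open <- 11; ext <- 1
  } else {
    submat <- Biostrings::nucleotideSubstitutionMatrix(match = 2,
                                                       mismatch = -3,
                                                       baseOnly = TRUE)
    open <- 5; ext <- 2
  }
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    si <- submat[av[i - 1], bv]
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - open - ext, F[i - 1, j] - ext)
      H[i, j] <- max(0, H[i - 1, j - 1] + si[j - 1], E[i, j], F[i, j])
    }
  }
  max(H)
}

# Exhaustive pair enumeration with the pairing rules hard-coded from
# their definitions (not read from the package's rule table).
oracle_call_pairs <- function(candidates) {
  rule_for <- function(ta_type, fams) {
    if (ta_type == "I")
      list(strand = "opposite", dmin = -Inf, dmax = 200,
           tox = "protein", ant = "rna")
    else if (ta_type == "VIII") {
      if (any(grepl("sdsr", fams, ignore.case = TRUE)))
        list(strand = "opposite", dmin = -Inf, dmax = -1,
             tox = "rna", ant = "rna")
      else
        list(strand = "either", dmin = -Inf, dmax = 200,
             tox = "rna", ant = "rna")
    } else
      list(strand = "same", dmin = -20, dmax = 150, tox = "protein",
           ant = if (ta_type == "III") "rna" else "protein")
  }
  out <- list()
  tox <- candidates[candidates$role == "toxin", , drop = FALSE]
  ant <- candidates[candidates$role == "antitoxin", , drop = FALSE]
  for (i in seq_len(nrow(tox))) for (j in seq_len(nrow(ant))) {
    t <- tox[i, ]; a <- ant[j, ]
    if (t$ta_type != a$ta_type) next
    if (t$replicon_id != a$replicon_id) next
    if (t$feature_id == a$feature_id) next
    # type VIII variant keys off the toxin's family first, like the caller
    r <- rule_for(t$ta_type, c(t$family, a$family))
    if (t$molecule != r$tox || a$molecule != r$ant) next
    same <- t$strand == a$strand
    if (r$strand == "same" && !same) next
    if (r$strand == "opposite" && same) next
    d <- max(t$start, a$start) - min(t$end, a$end)
    if (d < r$dmin || d > r$dmax) next
    out[[length(out) + 1L]] <- paste(t$feature_id, a$feature_id,
                                     t$ta_type, sep = "|")
  }
  if (!length(out)) character(0) else sort(unlist(out))
}

# O(loci x MGEs) association predicate, straight from the definition.
oracle_links <- function(loci, mges, flank_bp = 5000) {
  out <- list()
  for (i in seq_len(NROW(loci))) for (j in seq_len(NROW(mges))) {
    l <- loci[i, ]; m <- mges[j, ]
    if (l$replicon_id != m$replicon_id) next
    ls <- min(l$toxin_start, l$antitoxin_start)
    le <- max(l$toxin_end, l$antitoxin_end)
    if (ls >= m$start && le <= m$end) {
      out[[length(out) + 1L]] <- paste(l$locus_id, m$mge_id, "harbored",
                                       sep = "|")
    } else if (m$mge_class %in% c("IS_transposon", "IS_cluster")) {
      gap <- max(ls, m$start) - min(le, m$end)
      if (gap >= 0 && gap < flank_bp)
        out[[length(out) + 1L]] <- paste(l$locus_id, m$mge_id,
                                         "flanking_IS", sep = "|")
    }
  }
  if (!length(out)) character(0) else sort(unlist(out))
}

# Exact canonical k-mer Jaccard by full enumeration.
oracle_canonical_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character())
  subs <- substring(seq, seq_len(n - k + 1), seq_len(n - k + 1) + k - 1)
  subs <- subs[!grepl("[^ACGT]", subs)]
  if (!length(subs)) return(character())
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(subs)))
  unique(ifelse(subs <= rc, subs, rc))
}

oracle_jaccard <- function(seq_a, seq_b, k) {
  ka <- oracle_canonical_kmers(seq_a, k)
  kb <- oracle_canonical_kmers(seq_b, k)
  length(intersect(ka, kb)) / length(union(ka, kb))
}

mash_formula <- function(j, k) {
  if (j <= 0) return(1.0)
  if (j >= 1) return(0.0)
  -(1 / k) * log(2 * j / (1 + j))
}

# Random typed candidate tables for caller-oracle equivalence tests.
random_candidates <- function(seed, n_features = 50) {
  set.seed(seed)
  n <- sample.int(n_features, 1)
  types <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII")
  rows <- lapply(seq_len(n), function(i) {
    tt <- sample(types, 1)
    role <- sample(c("toxin", "antitoxin"), 1)
    mol <- if (tt == "VIII") "rna"
      else if (tt == "I") (if (role == "toxin") "protein" else "rna")
      else if (tt == "III") (if (role == "toxin") "protein" else "rna")
      else "protein"
    fam <- if (tt == "VIII") sample(c("creTA", "sdsR-ryeA"), 1)
           else paste0("fam", tt)
    start <- sample.int(20000, 1)
    len <- sample(60:900, 1)
    data.frame(feature_id = sprintf("f%03d", i),
               replicon_id = sample(c("r1", "r2"), 1),
               start = start, end = start + len,
               strand = sample(c("+", "-"), 1), molecule = mol,
               role = role, ta_type = tt, family = fam,
               h_value = runif(1, 0.4, 1), evalue = 1e-10,
               evidence = "blast", ref_id = "x", length_aa = NA_integer_,
               synthetic_feature = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Key predicted loci and truth rows by position so they can be compared.
locus_keys <- function(df, toxin_cols = c("toxin_start", "toxin_end",
                                          "toxin_strand"),
                       anti_cols = c("antitoxin_start", "antitoxin_end",
                                     "antitoxin_strand")) {
  apply(df[, c("replicon_id", "ta_type", toxin_cols, anti_cols)], 1,
        paste, collapse = "|")
}
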