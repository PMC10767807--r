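## Synthetic annotated genomes with planted TA loci and MGEs.
##
## The generator emulates the input corpus of a TA survey: replicons
## carrying TA loci of every type at controlled strand/distance
## configurations, partner sequences diverged from the bundled references
## to a controlled identity (substitutions only, so alignment coverage
## stays at 1 and the H-value tracks the identity directly), planted MGE
## intervals at controlled placements, and random background ORFs with no
## homology to the references. Everything is deterministic for a fixed
## plan seed.

#' Simulation plan for a synthetic genome
#'
#' @param seed mandatory integer seed; the whole bundle is a deterministic
#'   function of the plan.
#' @param replicons data.frame with columns `id`, `kind`
#'   (`chromosome`/`plasmid`), and optional `length` (bp; the realized
#'   length is at least what the layout needs) and `organism`.
#' @param loci data.frame of planted TA loci with columns:
#'   `replicon_id`; `ta_type` (I..VIII); `variant` (usually the type;
#'   `VIII-creTA`/`VIII-sdsr` for type VIII); `family` (must exist in the
#'   reference set); `distance` (signed bp, negative = overlap);
#'   `toxin_strand`, `antitoxin_strand` (`+`/`-`); `toxin_first` (logical:
#'   toxin is the left gene); `toxin_identity`, `antitoxin_identity`
#'   (fractions, sequence identity to the reference); optional
#'   `toxin_len_aa`, `antitoxin_len_aa` (protein partners only: truncate
#'   to / extend the reference to this many residues before divergence;
#'   NA = full length).
#' @param mges data.frame of planted MGE intervals with columns:
#'   `replicon_id`; `mge_class` (see [read_mge_table()]); `placement`
#'   (`harbored`, `gap`, `unrelated`); `locus_index` (row of `loci` the
#'   placement refers to; NA for `unrelated`); `gap_bp` (for `gap`:
#'   edge-to-edge interval to the locus span); optional `copy_of` (row of
#'   `mges` whose realized sequence this element re-uses) and
#'   `copy_identity` (nucleotide identity of the copy, default 0.998).
#' @param background_gene_density background ORFs per kb (default 0.4).
#' @param gc background GC fraction (default 0.5).
#' @param refs reference set as from [bundled_references()]; defaults to
#'   the bundled one.
#' @return Object of class `ta_plan`.
#' @export
ta_plan <- function(seed, replicons, loci = NULL, mges = NULL,
                    background_gene_density = 0.4, gc = 0.5, refs = NULL) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  replicons <- as.data.frame(replicons, stringsAsFactors = FALSE)
  if (is.null(replicons$length)) replicons$length <- NA_integer_
  if (is.null(replicons$organism))
    replicons$organism <- "Synthetica exemplaris"
  loci <- if (is.null(loci)) empty_plan_loci() else
    as.data.frame(loci, stringsAsFactors = FALSE)
  if (NROW(loci)) {
    if (is.null(loci$toxin_len_aa)) loci$toxin_len_aa <- NA_integer_
    if (is.null(loci$antitoxin_len_aa)) loci$antitoxin_len_aa <- NA_integer_
    if (is.null(loci$variant)) loci$variant <- loci$ta_type
  }
  mges <- if (is.null(mges)) empty_plan_mges() else
    as.data.frame(mges, stringsAsFactors = FALSE)
  if (NROW(mges)) {
    if (is.null(mges$gap_bp)) mges$gap_bp <- NA_integer_
    if (is.null(mges$copy_of)) mges$copy_of <- NA_integer_
    if (is.null(mges$copy_identity)) mges$copy_identity <- NA_real_
    if (is.null(mges$locus_index)) mges$locus_index <- NA_integer_
  }
  plan <- structure(list(seed = as.integer(seed), replicons = replicons,
                         loci = loci, mges = mges,
                         background_gene_density = background_gene_density,
                         gc = gc, refs = refs), class = "ta_plan")
  validate_plan(plan)
  plan
}

empty_plan_loci <- function() {
  data.frame(replicon_id = character(), ta_type = character(),
             variant = character(), family = character(),
             distance = integer(), toxin_strand = character(),
             antitoxin_strand = character(), toxin_first = logical(),
             toxin_identity = numeric(), antitoxin_identity = numeric(),
             toxin_len_aa = integer(), antitoxin_len_aa = integer(),
             stringsAsFactors = FALSE)
}

empty_plan_mges <- function() {
  data.frame(replicon_id = character(), mge_class = character(),
             placement = character(), locus_index = integer(),
             gap_bp = integer(), copy_of = integer(),
             copy_identity = numeric(), stringsAsFactors = FALSE)
}

plan_refs <- function(plan) plan$refs %||% bundled_references()

## locate the reference entry for one partner of a planted locus
find_ref <- function(refs, family, role, ta_type) {
  all <- rbind(refs$protein, refs$rna)
  hit <- all[all$family == family & all$role == role &
               all$ta_type == ta_type, , drop = FALSE]
  if (!nrow(hit))
    stop("no reference with family=", family, " role=", role,
         " type=", ta_type)
  hit[1, ]
}

## nucleotide length a planted partner will occupy
partner_nt_len <- function(ref, len_aa) {
  if (ref$molecule == "protein") {
    aa <- if (is.na(len_aa)) nchar(ref$sequence) else len_aa
    3L * aa + 3L                       # incl. stop codon
  } else nchar(ref$sequence)
}

validate_plan <- function(plan) {
  refs <- plan_refs(plan)
  loci <- plan$loci; mges <- plan$mges
  if (NROW(loci)) {
    bad <- setdiff(loci$replicon_id, plan$replicons$id)
    if (length(bad)) stop("plan loci on unknown replicon(s): ",
                          paste(unique(bad), collapse = ", "))
    for (i in seq_len(nrow(loci))) {
      l <- loci[i, ]
      rt <- find_ref(refs, l$family, "toxin", l$ta_type)
      ra <- find_ref(refs, l$family, "antitoxin", l$ta_type)
      lt <- partner_nt_len(rt, l$toxin_len_aa)
      la <- partner_nt_len(ra, l$antitoxin_len_aa)
      if (l$distance < -(min(lt, la) - 1L))
        stop("plan error: locus ", i, " overlap ", -l$distance,
             " bp exceeds the shorter partner (", min(lt, la), " bp)")
      if (!l$toxin_strand %in% c("+", "-") ||
          !l$antitoxin_strand %in% c("+", "-"))
        stop("plan error: locus ", i, " has invalid strand")
      check_identity_regime(rt$molecule, l$toxin_identity, i, "toxin")
      check_identity_regime(ra$molecule, l$antitoxin_identity, i,
                            "antitoxin")
    }
  }
  if (NROW(mges)) {
    bad <- setdiff(mges$mge_class, setdiff(MGE_CLASSES, "plasmid"))
    if (length(bad)) stop("plan error: MGE class(es) not plantable: ",
                          paste(unique(bad), collapse = ", "))
    if (!all(mges$placement %in% c("harbored", "gap", "unrelated")))
      stop("plan error: MGE placement must be harbored/gap/unrelated")
    ref_loc <- mges$placement %in% c("harbored", "gap")
    if (any(ref_loc & (is.na(mges$locus_index) |
                       mges$locus_index < 1 |
                       mges$locus_index > NROW(loci))))
      stop("plan error: harbored/gap MGE needs a valid locus_index")
    if (any(mges$placement == "gap" & (is.na(mges$gap_bp) | mges$gap_bp < 0)))
      stop("plan error: gap placement needs gap_bp >= 0")
    if (any(!is.na(mges$copy_of) &
            (mges$copy_of < 1 | mges$copy_of > nrow(mges) |
             mges$copy_of == seq_len(nrow(mges)))))
      stop("plan error: copy_of must index another planted MGE")
    ok_rep <- mges$replicon_id %in% plan$replicons$id
    if (!all(ok_rep)) stop("plan MGEs on unknown replicon(s)")
  }
  invisible(plan)
}

## Identity regimes with an unambiguous H-value outcome. Near the decision
## boundary the realized alignment H-value depends on stochastic trimming
## and gap placement, so the generator refuses identities in the band where
## the outcome is not determined by the plan alone: for proteins (BLOSUM62)
## H tracks the planted identity until ~0.3 where alignments start to
## fragment; for nucleotides (+2/-3) alignments of <60% identity fragment
## outright. Identities at or above the upper bound are reliably retained
## (H > 0.36); at or below the lower bound reliably rejected.
IDENTITY_REGIMES <- list(protein = c(reject = 0.30, retain = 0.45),
                         rna = c(reject = 0.50, retain = 0.70))

check_identity_regime <- function(molecule, identity, idx, partner) {
  reg <- IDENTITY_REGIMES[[molecule]]
  if (identity > reg[["reject"]] && identity < reg[["retain"]])
    stop("plan error: locus ", idx, " ", partner, " identity ", identity,
         " lies in the ambiguous band (", reg[["reject"]], ", ",
         reg[["retain"]], ") for ", molecule,
         " alignments; the recovery outcome would not be determined by ",
         "the plan")
  invisible(TRUE)
}

## --- sequence helpers --------------------------------------------------

AA20 <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S",
          "T","W","Y","V")

rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

rand_protein <- function(n_aa) {
  paste0("M", paste(sample(AA20, n_aa - 1L, replace = TRUE), collapse = ""))
}

revtrans_codon <- local({
  map <- NULL
  function() {
    if (is.null(map)) {
      gcode <- Biostrings::getGeneticCode("11")
      m <- character(0)
      for (aa in setdiff(unique(gcode), "*"))
        m[aa] <- sort(names(gcode)[gcode == aa])[1]
      map <<- m
    }
    map
  }
})

## deterministic reverse translation (one fixed codon per residue) plus a
## stop codon; re-translation with table 11 returns the input protein.
reverse_translate <- function(protein) {
  codons <- revtrans_codon()[strsplit(protein, "")[[1]]]
  if (anyNA(codons)) stop("cannot reverse-translate residue(s): ",
                          paste(unique(strsplit(protein, "")[[1]][
                            is.na(codons)]), collapse = ""))
  paste0(paste(codons, collapse = ""), "TAA")
}

revcomp_chr <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

#' Diverge a sequence to a target identity
#'
#' Substitution-only mutation: `round((1 - target) * length)` positions,
#' sampled uniformly without replacement, are replaced by a different
#' letter of the sequence's alphabet (nucleotide or amino acid, detected
#' from the content). The realized identity is within `1/length` of the
#' target; there are no indels, so alignment coverage of the original is
#' preserved.
#'
#' @param seq character sequence (DNA or protein).
#' @param target_identity fraction in (0, 1].
#' @param seed optional seed for the position/letter draws; when NULL the
#'   current RNG state is used (as inside [generate_bundle()]).
#' @return The diverged sequence.
#' @export
mutate_to_identity <- function(seq, target_identity, seed = NULL) {
  if (target_identity <= 0 || target_identity > 1)
    stop("target_identity must be in (0, 1]")
  n <- nchar(seq)
  if (target_identity == 1) return(seq)
  n_sub <- round((1 - target_identity) * n)
  if (n_sub == 0)
    stop("target identity ", target_identity,
         " is below the 1/", n, " resolution of this sequence")
  if (!is.null(seed)) set.seed(seed)
  chars <- strsplit(seq, "")[[1]]
  alphabet <- if (all(chars %in% c("A", "C", "G", "T")))
    c("A", "C", "G", "T") else AA20
  pos <- sample.int(n, n_sub)
  for (p in pos)
    chars[p] <- sample(setdiff(alphabet, chars[p]), 1L)
  paste(chars, collapse = "")
}

## write `sub` into `chars` (a character vector of single letters) at
## 0-based half-open [start, end)
splice_seq <- function(chars, start, sub) {
  s <- strsplit(sub, "")[[1]]
  chars[(start + 1L):(start + length(s))] <- s
  chars
}

## --- generator ---------------------------------------------------------

MGE_SPAN <- c(prophage = 12000L, genomic_island = 8000L, ICE = 10000L,
              integron = 4000L, IS_transposon = 800L, IS_cluster = 2500L)

#' Generate a synthetic genome bundle from a plan
#'
#' Lays out the planted loci left to right on each replicon (1.5 kb
#' leading margin per locus block for harbored elements, 8 kb trailing
#' margin so gap-placed IS elements never touch the next block), carves
#' the partner sequences -- reference copies diverged to the requested
#' identity -- into random background sequence, places the planted MGE
#' intervals, adds background ORFs (random codons, no homology to the
#' references), and derives the ground truth: which planted loci the
#' pipeline should call (given the pairing rules, the H-value filter and
#' the protein length filter) and which TA-MGE links should follow.
#' Protein partners are annotated features whose translations carry the
#' diverged protein; RNA partners are planted unannotated, to be
#' recovered by the nucleotide search. When two planted partners overlap
#' (negative distance), the antitoxin sequence wins the overlapping bases
#' and the toxin keeps its protein in the annotation, as in real
#' antisense arrangements.
#'
#' @param plan a [ta_plan].
#' @return List of class `ta_bundle`: `genome` ([ta_genome]), `mges`
#'   (internal-coordinate MGE data.frame), `truth` (list with `loci` and
#'   `links` data.frames; `loci$expected` flags loci the pipeline should
#'   recover), `refs`, `plan`.
#' @export
generate_bundle <- function(plan) {
  validate_plan(plan)
  set.seed(plan$seed)
  refs <- plan_refs(plan)
  rules <- ta_rules()

  rep_rows <- list(); seqs <- list(); feat_rows <- list()
  truth_loci <- list(); mge_rows <- list()
  loci <- plan$loci; mges <- plan$mges
  mge_iv <- vector("list", NROW(mges))   # realized intervals, by plan row

  for (ri in seq_len(nrow(plan$replicons))) {
    rid <- plan$replicons$id[ri]
    li_here <- which(loci$replicon_id == rid)
    cursor <- 1200L
    gene_iv <- list()                    # reserved intervals on this replicon

    for (i in li_here) {
      l <- loci[i, ]
      rt <- find_ref(refs, l$family, "toxin", l$ta_type)
      ra <- find_ref(refs, l$family, "antitoxin", l$ta_type)
      tox <- realize_partner(rt, l$toxin_identity, l$toxin_len_aa)
      ant <- realize_partner(ra, l$antitoxin_identity, l$antitoxin_len_aa)
      lt <- nchar(tox$dna); la <- nchar(ant$dna)
      block <- cursor + 1500L
      if (l$toxin_first) {
        ts <- block; te <- ts + lt
        as_ <- te + l$distance; ae <- as_ + la
      } else {
        as_ <- block; ae <- as_ + la
        ts <- ae + l$distance; te <- ts + lt
      }
      truth_loci[[i]] <- data.frame(
        locus_index = i, replicon_id = rid, ta_type = l$ta_type,
        variant = l$variant, family = l$family,
        toxin_start = ts, toxin_end = te, toxin_strand = l$toxin_strand,
        antitoxin_start = as_, antitoxin_end = ae,
        antitoxin_strand = l$antitoxin_strand,
        distance = as.integer(max(ts, as_) - min(te, ae)),
        toxin_molecule = rt$molecule, antitoxin_molecule = ra$molecule,
        stringsAsFactors = FALSE)
      feat_rows[[length(feat_rows) + 1L]] <- list(
        replicon = rid, locus_index = i,
        toxin = list(ref = rt, seq = tox, start = ts, end = te,
                     strand = l$toxin_strand, id = sprintf("L%02d_toxin", i)),
        antitoxin = list(ref = ra, seq = ant, start = as_, end = ae,
                         strand = l$antitoxin_strand,
                         id = sprintf("L%02d_antitoxin", i)))
      gene_iv <- c(gene_iv, list(c(ts, te), c(as_, ae)))
      cursor <- max(te, ae) + 8000L
    }

    # planted MGEs anchored to loci on this replicon
    for (mi in which(mges$replicon_id == rid)) {
      m <- mges[mi, ]
      span <- if (!is.na(m$copy_of)) {
        src <- mges[m$copy_of, ]
        MGE_SPAN[[src$mge_class]]
      } else MGE_SPAN[[m$mge_class]]
      if (m$placement == "harbored") {
        t <- truth_loci[[m$locus_index]]
        ls <- min(t$toxin_start, t$antitoxin_start)
        le <- max(t$toxin_end, t$antitoxin_end)
        # containment with a 600 bp pad; stays inside the block margins
        mge_iv[[mi]] <- c(max(0L, ls - 600L), le + 600L)
      } else if (m$placement == "gap") {
        t <- truth_loci[[m$locus_index]]
        le <- max(t$toxin_end, t$antitoxin_end)
        ms <- le + m$gap_bp
        mge_iv[[mi]] <- c(ms, ms + span)
        cursor <- max(cursor, ms + span + 1500L)
      } else {
        mge_iv[[mi]] <- c(cursor, cursor + span)
        cursor <- cursor + span + 1500L
      }
    }

    want <- plan$replicons$length[ri]
    L <- max(cursor + 1000L, if (is.na(want)) 0L else as.integer(want))
    chars <- strsplit(rand_dna(L, plan$gc), "")[[1]]

    # carve planted genes: toxins first, antitoxins second so an
    # antisense antitoxin wins the overlap
    for (fr in feat_rows) {
      if (!identical(fr$replicon, rid)) next
      for (part in c("toxin", "antitoxin")) {
        p <- fr[[part]]
        dna <- if (p$strand == "+") p$seq$dna else revcomp_chr(p$seq$dna)
        chars <- splice_seq(chars, p$start, dna)
      }
    }

    # background ORFs in free space
    n_bg <- round(plan$background_gene_density * L / 1000)
    reserved <- gene_iv
    bg <- list()
    tries <- 0L
    while (length(bg) < n_bg && tries < 60L * n_bg) {
      tries <- tries + 1L
      aa_len <- sample(40:160, 1L)
      glen <- 3L * aa_len + 3L
      gs <- sample.int(max(1L, L - glen - 300L), 1L) + 150L
      ge <- gs + glen
      clash <- any(vapply(c(reserved, bg), function(iv)
        min(ge, iv[2]) - max(gs, iv[1]) > -300L, logical(1)))
      if (clash) next
      prot <- rand_protein(aa_len)
      strand <- sample(c("+", "-"), 1L)
      dna <- if (strand == "+") reverse_translate(prot)
             else revcomp_chr(reverse_translate(prot))
      chars <- splice_seq(chars, gs, dna)
      bg <- c(bg, list(c(gs, ge)))
      feat_rows[[length(feat_rows) + 1L]] <- list(
        replicon = rid, background = TRUE,
        toxin = NULL, antitoxin = NULL,
        bg = list(id = sprintf("%s_bg%03d", rid, length(bg)), start = gs,
                  end = ge, strand = strand, protein = prot))
    }

    # similar-MGE copies: overwrite the copy's interval with a diverged
    # copy of the source interval's realized sequence
    for (mi in which(mges$replicon_id == rid)) {
      m <- mges[mi, ]
      if (is.na(m$copy_of)) next
      src_iv <- mge_iv[[m$copy_of]]
      src_seq <- paste(chars[(src_iv[1] + 1L):src_iv[2]], collapse = "")
      idn <- if (is.na(m$copy_identity)) 0.998 else m$copy_identity
      cp <- if (idn < 1) mutate_to_identity(src_seq, idn) else src_seq
      iv <- mge_iv[[mi]]
      iv[2] <- iv[1] + nchar(cp)
      mge_iv[[mi]] <- iv
      chars <- splice_seq(chars, iv[1], cp)
    }

    rep_rows[[ri]] <- data.frame(
      id = rid, length = L,
      topology = "linear", kind = plan$replicons$kind[ri],
      organism = plan$replicons$organism[ri], stringsAsFactors = FALSE)
    seqs[[rid]] <- Biostrings::DNAString(paste(chars, collapse = ""))
  }

  # assemble the feature table: protein partners and background ORFs are
  # annotated; RNA partners stay unannotated (found by the RNA search)
  feats <- list()
  for (fr in feat_rows) {
    if (!is.null(fr$bg)) {
      b <- fr$bg
      feats[[length(feats) + 1L]] <- data.frame(
        feature_id = b$id, replicon_id = fr$replicon, start = b$start,
        end = b$end, strand = b$strand, molecule = "protein_coding",
        product = "hypothetical protein", translation = b$protein,
        stringsAsFactors = FALSE)
      next
    }
    for (part in c("toxin", "antitoxin")) {
      p <- fr[[part]]
      if (p$ref$molecule != "protein") next
      feats[[length(feats) + 1L]] <- data.frame(
        feature_id = p$id, replicon_id = fr$replicon, start = p$start,
        end = p$end, strand = p$strand, molecule = "protein_coding",
        product = paste(p$ref$family, part), translation = p$seq$residues,
        stringsAsFactors = FALSE)
    }
  }
  genome <- ta_genome(do.call(rbind, rep_rows),
                      Biostrings::DNAStringSet(seqs),
                      if (length(feats)) do.call(rbind, feats)
                      else empty_features())

  for (mi in seq_len(NROW(mges)))
    mge_rows[[mi]] <- data.frame(
      mge_id = sprintf("MGE%02d", mi), replicon_id = mges$replicon_id[mi],
      start = mge_iv[[mi]][1], end = mge_iv[[mi]][2],
      mge_class = mges$mge_class[mi], stringsAsFactors = FALSE)
  mge_df <- if (length(mge_rows)) do.call(rbind, mge_rows)
            else data.frame(mge_id = character(), replicon_id = character(),
                            start = integer(), end = integer(),
                            mge_class = character(), stringsAsFactors = FALSE)

  truth <- build_truth(plan, refs, rules, truth_loci, mge_df)
  structure(list(genome = genome, mges = mge_df, truth = truth,
                 refs = refs, plan = plan), class = "ta_bundle")
}

## realize one partner: resized (optional) and diverged copy of the
## reference; returns residues (protein or RNA) and the DNA to plant.
realize_partner <- function(ref, identity, len_aa) {
  res <- ref$sequence
  if (ref$molecule == "protein" && !is.na(len_aa)) {
    n <- nchar(res)
    res <- if (len_aa <= n) substr(res, 1L, len_aa)
           else paste0(res, paste(sample(AA20, len_aa - n, replace = TRUE),
                                  collapse = ""))
  }
  if (identity < 1) res <- mutate_to_identity(res, identity)
  dna <- if (ref$molecule == "protein") reverse_translate(res) else res
  list(residues = res, dna = dna)
}

## ground truth: a planted locus is expected iff both partners pass the
## H-value proxy (identity x reference coverage > 0.36), protein partners
## pass the length filter, and the pair satisfies its type rule.
build_truth <- function(plan, refs, rules, truth_loci, mge_df) {
  defs <- ta_defaults()
  tl <- if (length(truth_loci)) do.call(rbind, truth_loci) else NULL
  if (!is.null(tl)) {
    exp_flags <- logical(nrow(tl)); reasons <- character(nrow(tl))
    for (i in seq_len(nrow(tl))) {
      l <- plan$loci[tl$locus_index[i], ]
      rt <- find_ref(refs, l$family, "toxin", l$ta_type)
      ra <- find_ref(refs, l$family, "antitoxin", l$ta_type)
      fail <- character()
      # H proxy: identity x coverage for proteins (coverage < 1 only via a
      # length override); nucleotide alignments additionally require the
      # retain regime, below which they fragment under +2/-3 scoring
      h_pass <- function(ref, idn, len_aa) {
        if (ref$molecule == "rna")
          return(idn >= IDENTITY_REGIMES$rna[["retain"]])
        cov <- if (!is.na(len_aa)) min(1, len_aa / nchar(ref$sequence))
               else 1
        idn * cov > defs$h_value
      }
      if (!h_pass(rt, l$toxin_identity, l$toxin_len_aa))
        fail <- c(fail, "toxin_h")
      if (!h_pass(ra, l$antitoxin_identity, l$antitoxin_len_aa))
        fail <- c(fail, "antitoxin_h")
      len_ok <- function(ref, len_aa) {
        if (ref$molecule != "protein") return(TRUE)
        n <- if (is.na(len_aa)) nchar(ref$sequence) else len_aa
        n >= defs$len_min && n <= defs$len_max
      }
      if (!len_ok(rt, l$toxin_len_aa)) fail <- c(fail, "toxin_length")
      if (!len_ok(ra, l$antitoxin_len_aa)) fail <- c(fail, "antitoxin_length")
      ru <- rules[match(l$variant, rules$variant), ]
      if (is.na(ru$variant[1])) fail <- c(fail, "no_rule")
      else {
        if (!strand_ok(ru$strand, l$toxin_strand, l$antitoxin_strand))
          fail <- c(fail, "strand")
        if (tl$distance[i] < ru$dmin || tl$distance[i] > ru$dmax)
          fail <- c(fail, "distance")
        if (rt$molecule != ru$toxin_molecule ||
            ra$molecule != ru$antitoxin_molecule)
          fail <- c(fail, "molecule")
      }
      exp_flags[i] <- length(fail) == 0L
      reasons[i] <- paste(fail, collapse = ",")
    }
    tl$expected <- exp_flags
    tl$violation <- reasons
  } else {
    tl <- cbind(empty_plan_truth(), expected = logical(),
                violation = character())
  }

  links <- list()
  defs_flank <- defs$flank_bp
  for (mi in seq_len(NROW(plan$mges))) {
    m <- plan$mges[mi, ]
    if (m$placement == "unrelated") next
    t <- tl[tl$locus_index == m$locus_index, , drop = FALSE]
    if (!nrow(t) || !t$expected) next
    if (m$placement == "harbored") {
      links[[length(links) + 1L]] <- data.frame(
        locus_index = m$locus_index, mge_id = sprintf("MGE%02d", mi),
        mge_class = m$mge_class, link_kind = "harbored", gap = 0L,
        stringsAsFactors = FALSE)
    } else if (m$mge_class %in% IS_CLASSES && m$gap_bp < defs_flank) {
      links[[length(links) + 1L]] <- data.frame(
        locus_index = m$locus_index, mge_id = sprintf("MGE%02d", mi),
        mge_class = m$mge_class, link_kind = "flanking_IS",
        gap = as.integer(m$gap_bp), stringsAsFactors = FALSE)
    }
  }
  # implicit plasmid harboring
  for (ri in seq_len(nrow(plan$replicons))) {
    if (plan$replicons$kind[ri] != "plasmid") next
    rid <- plan$replicons$id[ri]
    for (i in which(tl$replicon_id == rid & tl$expected))
      links[[length(links) + 1L]] <- data.frame(
        locus_index = tl$locus_index[i], mge_id = paste0("plasmid:", rid),
        mge_class = "plasmid", link_kind = "harbored", gap = 0L,
        stringsAsFactors = FALSE)
  }
  link_df <- if (length(links)) do.call(rbind, links)
             else data.frame(locus_index = integer(), mge_id = character(),
                             mge_class = character(), link_kind = character(),
                             gap = integer(), stringsAsFactors = FALSE)
  list(loci = tl, links = link_df)
}

empty_plan_truth <- function() {
  data.frame(locus_index = integer(), replicon_id = character(),
             ta_type = character(), variant = character(),
             family = character(), toxin_start = integer(),
             toxin_end = integer(), toxin_strand = character(),
             antitoxin_start = integer(), antitoxin_end = integer(),
             antitoxin_strand = character(), distance = integer(),
             toxin_molecule = character(), antitoxin_molecule = character(),
             stringsAsFactors = FALSE)
}

#' Write a synthetic bundle to disk
#'
#' Emits the bundle in the formats the pipeline reads: replicons as
#' FASTA + GFF3, the MGE table as a 1-based TSV, the reference sets as
#' FASTA, and the truth tables as TSVs.
#'
#' @param bundle a `ta_bundle` from [generate_bundle()].
#' @param dir output directory.
#' @return Named list of paths, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- list(fasta = file.path(dir, "genome.fna"),
            gff = file.path(dir, "genome.gff3"),
            mges = file.path(dir, "mges.tsv"),
            refs_protein = file.path(dir, "refs_protein.faa"),
            refs_rna = file.path(dir, "refs_rna.fna"),
            truth_loci = file.path(dir, "truth_loci.tsv"),
            truth_links = file.path(dir, "truth_links.tsv"))
  write_genome(bundle$genome, p$fasta, p$gff)
  out <- bundle$mges
  out <- data.frame(mge_id = out$mge_id, replicon_id = out$replicon_id,
                    start = out$start + 1L, end = out$end,
                    class = out$mge_class, stringsAsFactors = FALSE)
  utils::write.table(out, p$mges, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_reference_fasta(bundle$refs$protein, p$refs_protein)
  write_reference_fasta(bundle$refs$rna, p$refs_rna)
  utils::write.table(bundle$truth$loci, p$truth_loci, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$truth$links, p$truth_links, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(p)
}

#' @rdname read_reference_fasta
#' @param refs reference data.frame to write.
#' @export
write_reference_fasta <- function(refs, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_len(nrow(refs)))
    writeLines(sprintf(">%s|%s|%s|%s\n%s", refs$ref_id[i], refs$role[i],
                       refs$ta_type[i], refs$family[i], refs$sequence[i]),
               con)
  invisible(path)
}

#' The standard ~200 kb validation fixture plan
#'
#' Two replicons carrying one planted locus of each TA type: types I and
#' III-VIII on the chromosome (type VIII as its creTA variant) and the
#' type II locus on the plasmid, exercising the plasmid-as-MGE
#' convention. Five planted MGEs cover harbored, flanking and unrelated
#' placements, including one near-identical prophage copy for the
#' similarity network.
#'
#' @param seed plan seed (default 42).
#' @return A [ta_plan].
#' @export
standard_fixture_plan <- function(seed = 42L) {
  loci <- data.frame(
    replicon_id = c("chr1", "chr1", "chr1", "chr1", "chr1", "chr1",
                    "chr1", "p1"),
    ta_type = c("I", "III", "IV", "V", "VI", "VII", "VIII", "II"),
    variant = c("I", "III", "IV", "V", "VI", "VII", "VIII-creTA", "II"),
    family = c("hok-sok", "toxIN", "cbtA-cbeA", "ghoST", "socAB",
               "hha-tomB", "creTA", "relBE"),
    distance = c(60L, 40L, 30L, -10L, 100L, 0L, 80L, 30L),
    toxin_strand = c("+", "+", "+", "-", "+", "+", "+", "+"),
    antitoxin_strand = c("-", "+", "+", "-", "+", "+", "-", "+"),
    toxin_first = c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE),
    toxin_identity = c(1, 0.85, 0.9, 1, 0.8, 1, 0.95, 0.9),
    antitoxin_identity = c(0.9, 1, 0.85, 0.9, 1, 0.9, 0.9, 0.85),
    stringsAsFactors = FALSE)
  mges <- data.frame(
    replicon_id = c("chr1", "chr1", "chr1", "chr1", "chr1"),
    mge_class = c("prophage", "genomic_island", "IS_transposon",
                  "integron", "prophage"),
    placement = c("harbored", "harbored", "gap", "unrelated", "unrelated"),
    locus_index = c(1L, 3L, 6L, NA, NA),
    gap_bp = c(NA, NA, 1000L, NA, NA),
    copy_of = c(NA, NA, NA, NA, 1L),
    copy_identity = c(NA, NA, NA, NA, 0.999),
    stringsAsFactors = FALSE)
  ta_plan(seed = seed,
          replicons = data.frame(
            id = c("chr1", "p1"), kind = c("chromosome", "plasmid"),
            length = c(170000L, 30000L),
            organism = "Synthetica exemplaris str. SX1",
            stringsAsFactors = FALSE),
          loci = loci, mges = mges)
}
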