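# Shared fixtures, memoized across test files (generation and the full
# homology pass over the ~200 kb fixture are the expensive steps).

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

std_bundle <- function() memo("std_bundle",
                              generate_bundle(standard_fixture_plan(42)))

# full prediction pass over a bundle; rna search only when RNA-partnered
# types are planted (types I, III, VIII)
predict_bundle <- function(bundle, rna = NULL) {
  refs <- bundle$refs
  if (is.null(rna))
    rna <- any(bundle$plan$loci$ta_type %in% c("I", "III", "VIII"))
  hits <- search_protein(bundle$genome, refs$protein)
  if (rna) hits <- rbind(hits, search_rna(bundle$genome, refs$rna))
  cands <- build_candidates(hits, NULL, bundle$genome)
  list(candidates = cands,
       loci = resolve_overlaps(call_loci(cands)))
}

std_prediction <- function() memo("std_prediction",
                                  predict_bundle(std_bundle()))

# one-locus plan helper for grid/decoy tests
single_locus_plan <- function(seed, ta_type, variant, family, distance,
                              toxin_strand, antitoxin_strand,
                              toxin_first = TRUE, toxin_identity = 1,
                              antitoxin_identity = 1,
                              toxin_len_aa = NA_integer_,
                              antitoxin_len_aa = NA_integer_,
                              kind = "chromosome") {
  ta_plan(seed = seed,
          replicons = data.frame(id = "chr1", kind = kind,
                                 stringsAsFactors = FALSE),
          loci = data.frame(replicon_id = "chr1", ta_type = ta_type,
                            variant = variant, family = family,
                            distance = as.integer(distance),
                            toxin_strand = toxin_strand,
                            antitoxin_strand = antitoxin_strand,
                            toxin_first = toxin_first,
                            toxin_identity = toxin_identity,
                            antitoxin_identity = antitoxin_identity,
                            toxin_len_aa = toxin_len_aa,
                            antitoxin_len_aa = antitoxin_len_aa,
                            stringsAsFactors = FALSE),
          background_gene_density = 0.3)
}

# family/molecule facts about each variant used when building grid plans
variant_info <- function(variant) {
  switch(variant,
    "I" = list(ta_type = "I", family = "hok-sok",
               strands = list(c("+", "-"), c("-", "+"))),
    "II" = list(ta_type = "II", family = "relBE",
                strands = list(c("+", "+"), c("-", "-"))),
    "III" = list(ta_type = "III", family = "toxIN",
                 strands = list(c("+", "+"), c("-", "-"))),
    "IV" = list(ta_type = "IV", family = "cbtA-cbeA",
                strands = list(c("+", "+"), c("-", "-"))),
    "V" = list(ta_type = "V", family = "ghoST",
               strands = list(c("+", "+"), c("-", "-"))),
    "VI" = list(ta_type = "VI", family = "socAB",
                strands = list(c("+", "+"), c("-", "-"))),
    "VII" = list(ta_type = "VII", family = "hha-tomB",
                 strands = list(c("+", "+"), c("-", "-"))),
    "VIII-creTA" = list(ta_type = "VIII", family = "creTA",
                        strands = list(c("+", "+"), c("+", "-"))),
    "VIII-sdsr" = list(ta_type = "VIII", family = "sdsR-ryeA",
                       strands = list(c("+", "-"), c("-", "+"))),
    stop("unknown variant ", variant))
}

# a tiny profile-HMM fixture built from a bundled reference at test time
fixture_hmm <- function() {
  memo("fixture_hmm", {
    hmmbuild <- Sys.which("hmmbuild")
    stopifnot(nzchar(hmmbuild))
    refs <- bundled_references()
    base <- refs$protein$sequence[refs$protein$ref_id == "relE_syn"]
    set.seed(77)
    variants <- vapply(1:5, function(i) mutate_to_identity(base, 0.9), "")
    afa <- tempfile(fileext = ".afa")
    writeLines(paste0(">v", 1:5, "\n", variants), afa)
    hmm <- file.path(tempdir(), "relBE_II_toxin.hmm")
    system2(hmmbuild, c("-n", "relBE_II_toxin", hmm, afa), stdout = FALSE,
            stderr = FALSE)
    hmm
  })
}

# manual sketch construction with a controlled shared-hash count
manual_sketch <- function(id, hashes, k = 21L, s = 1000L) {
  structure(list(mge_id = id, k = k, s = s, seed = 42L,
                 hashes = sort(hashes, method = "radix")),
            class = "minhash_sketch")
}

hex_universe <- function(n) {
  vals <- seq(1000003L, by = 104729L, length.out = n)
  sort(paste0("00000000", sprintf("%08x", vals)), method = "radix")
}
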