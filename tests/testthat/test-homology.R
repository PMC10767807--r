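# Homology search, the H-value, and candidate filtering.

test_that("h_value is the identity x coverage product with domain checks", {
  expect_equal(h_value(1, 1), 1)
  expect_equal(h_value(0.6, 0.6), 0.36)
  expect_equal(h_value(0.9, 0.5), 0.45)
  expect_error(h_value(-0.1, 0.5), "\\[0, 1\\]")
  expect_error(h_value(0.5, 1.2), "\\[0, 1\\]")
})

test_that("a verbatim reference copy is a self-hit with h_value 1", {
  b <- generate_bundle(single_locus_plan(5, "II", "II", "relBE", 30,
                                         "+", "+"))
  refs <- bundled_references()
  hits <- search_protein(b$genome, refs$protein)
  self <- hits[hits$ref_id == "relE_syn" &
                 hits$feature_id == "L01_toxin", ]
  expect_equal(nrow(self), 1)
  expect_equal(self$identity, 1)
  expect_equal(self$query_coverage, 1)
  expect_equal(self$h_value, 1)
})

test_that("every bundled reference planted verbatim is recovered at h = 1", {
  pred <- std_prediction()
  cands <- pred$candidates
  planted_identity1 <- c("L01_toxin", "L04_toxin")  # identity-1 proteins
  for (f in planted_identity1)
    expect_equal(cands$h_value[cands$feature_id == f], 1)
})

test_that("shuffled sequences yield no reportable protein hit", {
  refs <- bundled_references()
  ref <- refs$protein[refs$protein$ref_id == "vapC_syn", ]
  set.seed(13)
  shuffled <- paste(sample(strsplit(ref$sequence, "")[[1]]), collapse = "")
  g <- ta_genome(
    data.frame(id = "c", length = 5000L, topology = "linear",
               kind = "chromosome", organism = "x", stringsAsFactors = FALSE),
    Biostrings::DNAStringSet(c(c = paste(
      sample(c("A", "C", "G", "T"), 5000, TRUE), collapse = ""))),
    data.frame(feature_id = "s1", replicon_id = "c", start = 10L,
               end = 10L + 3L * nchar(shuffled) + 3L, strand = "+",
               molecule = "protein_coding", product = "",
               translation = shuffled, stringsAsFactors = FALSE))
  hits <- search_protein(g, ref)
  expect_true(nrow(hits) == 0 || all(hits$h_value < 0.36))
})

test_that("half-length chimera gives coverage 0.5 and h about 0.40", {
  refs <- bundled_references()
  ref <- refs$protein[refs$protein$ref_id == "relE_syn", ]
  stopifnot(nchar(ref$sequence) > 60)
  half_len <- floor(nchar(ref$sequence) / 2)
  half <- substr(ref$sequence, 1, half_len)
  # mutate 20% of positions, keeping 3 residues at both ends intact so
  # local alignment does not trim the chimeric segment
  set.seed(21)
  chars <- strsplit(half, "")[[1]]
  n_mut <- round(0.2 * half_len)
  pos <- sample(4:(half_len - 3), n_mut)
  aa <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S",
          "T","W","Y","V")
  for (p in pos) chars[p] <- sample(setdiff(aa, chars[p]), 1)
  set.seed(22)
  tail_junk <- paste(sample(aa, 40, TRUE), collapse = "")
  chim <- paste0(paste(chars, collapse = ""), tail_junk)
  g <- ta_genome(
    data.frame(id = "c", length = 2000L, topology = "linear",
               kind = "chromosome", organism = "x", stringsAsFactors = FALSE),
    Biostrings::DNAStringSet(c(c = paste(
      rep("ACGT", 500), collapse = ""))),
    data.frame(feature_id = "chim", replicon_id = "c", start = 0L,
               end = 3L * nchar(chim) + 3L, strand = "+",
               molecule = "protein_coding", product = "",
               translation = chim, stringsAsFactors = FALSE))
  hit <- search_protein(g, ref)
  hit <- hit[which.max(hit$h_value), ]
  expect_equal(hit$query_coverage, half_len / nchar(ref$sequence),
               tolerance = 0.02)
  expect_equal(hit$identity, 0.8, tolerance = 0.02)
  expect_equal(hit$h_value, 0.8 * half_len / nchar(ref$sequence),
               tolerance = 0.02)
})

test_that("RNA search finds exact copies on either strand symmetrically", {
  refs <- bundled_references()
  sok <- refs$rna[refs$rna$ref_id == "sok_syn", ]
  set.seed(31)
  bg <- paste(sample(c("A", "C", "G", "T"), 4000, TRUE), collapse = "")
  plant_at <- 1500L
  fwd <- paste0(substr(bg, 1, plant_at), sok$sequence,
                substr(bg, plant_at + nchar(sok$sequence) + 1, 4000))
  rev <- paste0(substr(bg, 1, plant_at),
                as.character(Biostrings::reverseComplement(
                  Biostrings::DNAString(sok$sequence))),
                substr(bg, plant_at + nchar(sok$sequence) + 1, 4000))
  mk <- function(seq) ta_genome(
    data.frame(id = "c", length = nchar(seq), topology = "linear",
               kind = "chromosome", organism = "x", stringsAsFactors = FALSE),
    Biostrings::DNAStringSet(c(c = seq)), NULL)
  h_fwd <- search_rna(mk(fwd), sok)
  h_rev <- search_rna(mk(rev), sok)
  expect_equal(h_fwd$strand[which.max(h_fwd$h_value)], "+")
  expect_equal(h_rev$strand[which.max(h_rev$h_value)], "-")
  expect_equal(max(h_fwd$identity), 1)
  expect_equal(max(h_rev$identity), 1)
  # same placement coordinates regardless of strand
  expect_equal(h_rev$start[which.max(h_rev$h_value)], plant_at)
  expect_equal(h_fwd$start[which.max(h_fwd$h_value)], plant_at)
})

test_that("heavily randomized RNA copies fall below the H threshold", {
  refs <- bundled_references()
  toxi <- refs$rna[refs$rna$ref_id == "toxI_syn", ]
  # half the positions substituted: +2/-3 local alignment fragments and
  # the H-value collapses well below the 0.36 cut-off
  mut <- mutate_to_identity(toxi$sequence, 0.5, seed = 1)
  set.seed(32)
  bg <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")
  seq <- paste0(substr(bg, 1, 1000), mut, substr(bg, 1001 + nchar(mut), 3000))
  g <- ta_genome(
    data.frame(id = "c", length = nchar(seq), topology = "linear",
               kind = "chromosome", organism = "x", stringsAsFactors = FALSE),
    Biostrings::DNAStringSet(c(c = seq)), NULL)
  hits <- search_rna(g, toxi)
  cands <- build_candidates(hits, NULL, g)
  expect_true(nrow(hits) == 0 || all(hits$h_value < 0.36))
  expect_equal(nrow(cands), 0)
})

test_that("candidate filters apply strict H and inclusive length bounds", {
  hit_row <- function(h, len) {
    data.frame(feature_id = paste0("f", h, "_", len), replicon_id = "c",
               start = 0L, end = 3L * len + 3L, strand = "+",
               molecule = "protein", ref_id = "r", role = "toxin",
               ta_type = "II", family = "relBE", identity = h,
               query_coverage = 1, score = 100, bitscore = 50,
               evalue = 1e-10, h_value = h, length_aa = len,
               synthetic_feature = FALSE, stringsAsFactors = FALSE)
  }
  hits <- rbind(hit_row(0.36, 100), hit_row(0.37, 100),
                hit_row(0.9, 29), hit_row(0.37, 30),
                hit_row(0.9, 501), hit_row(0.9, 500))
  kept <- build_candidates(hits, NULL, NULL)
  expect_setequal(kept$feature_id, c("f0.37_100", "f0.37_30", "f0.9_500"))
})

test_that("raising the H threshold never enlarges the candidate set", {
  pred_hits <- memo("mono_hits", {
    b <- std_bundle()
    refs <- b$refs
    rbind(search_protein(b$genome, refs$protein),
          search_rna(b$genome, refs$rna))
  })
  prev <- NULL
  for (th in seq(0.1, 0.9, by = 0.1)) {
    ids <- build_candidates(pred_hits, NULL, NULL, h_cutoff = th)
    ids <- paste(ids$feature_id, ids$role, ids$ta_type)
    if (!is.null(prev)) expect_true(all(ids %in% prev))
    prev <- ids
  }
})

test_that("domain scan hits profiles from emitted consensus sequences", {
  hmm <- fixture_hmm()
  cons <- system2(Sys.which("hmmemit"), c("-c", hmm), stdout = TRUE)
  cons_seq <- paste(cons[-1], collapse = "")
  g <- ta_genome(
    data.frame(id = "c", length = 3L * nchar(cons_seq) + 103L,
               topology = "linear", kind = "chromosome", organism = "x",
               stringsAsFactors = FALSE),
    Biostrings::DNAStringSet(c(c = paste(
      rep("A", 3 * nchar(cons_seq) + 103), collapse = ""))),
    data.frame(feature_id = "cons", replicon_id = "c", start = 100L,
               end = 100L + 3L * nchar(cons_seq) + 3L, strand = "+",
               molecule = "protein_coding", product = "",
               translation = cons_seq, stringsAsFactors = FALSE))
  dh <- scan_domains(g, hmm)
  expect_equal(dh$feature_id, "cons")
  expect_equal(dh$role, "toxin")
  expect_equal(dh$ta_type, "II")
  expect_lte(dh$evalue, 1e-5)
  # hmm evidence alone carries a candidate unless require_blast
  cands <- build_candidates(NULL, dh, g)
  expect_equal(cands$evidence, "hmm")
  expect_equal(nrow(build_candidates(NULL, dh, g, require_blast = TRUE)), 0)
})

test_that("domain scan validates the profile file and empty inputs", {
  bad <- withr::local_tempfile()
  writeLines("", bad)
  g <- std_bundle()$genome
  expect_error(scan_domains(g, bad), "format error")
  g_empty <- ta_genome(g$replicons, g$sequences, NULL)
  expect_equal(nrow(scan_domains(g_empty, fixture_hmm())), 0)
})

test_that("built-in aligner equals the brute-force DP oracle", {
  set.seed(400)
  aa <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S",
          "T","W","Y","V")
  for (rep in 1:10) {
    n1 <- sample(20:150, 1); n2 <- sample(20:150, 1)
    a <- paste(sample(aa, n1, TRUE), collapse = "")
    b <- paste(sample(aa, n2, TRUE), collapse = "")
    if (rep %% 2 == 0) b <- paste0(substr(a, 1, floor(n1 / 2)), b)
    expect_equal(align_local(a, b, "protein")$score,
                 oracle_sw_score(a, b, "protein"))
  }
  for (rep in 1:5) {
    a <- paste(sample(c("A","C","G","T"), sample(40:200, 1), TRUE),
               collapse = "")
    b <- paste(sample(c("A","C","G","T"), sample(40:200, 1), TRUE),
               collapse = "")
    if (rep %% 2 == 0) b <- paste0(b, substr(a, 5, 80))
    expect_equal(align_local(a, b, "dna")$score,
                 oracle_sw_score(a, b, "dna"))
  }
})

test_that("reference FASTA headers parse and malformed ones error", {
  refs <- bundled_references()
  expect_true(all(refs$protein$molecule == "protein"))
  expect_true(all(refs$rna$molecule == "rna"))
  expect_setequal(unique(c(refs$protein$ta_type, refs$rna$ta_type)),
                  c("I", "II", "III", "IV", "V", "VI", "VII", "VIII"))
  bad <- withr::local_tempfile(fileext = ".faa")
  writeLines(c(">nopipes", "MKL"), bad)
  expect_error(read_reference_fasta(bad, "protein"), "ref_id\\|role")
})
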