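# Pairing rules: distance convention, locus calling, overlap resolution.

cand <- function(id, role, ta_type, start, end, strand,
                 molecule = "protein", family = "fam", replicon = "r1",
                 h = 0.9) {
  data.frame(feature_id = id, replicon_id = replicon, start = start,
             end = end, strand = strand, molecule = molecule, role = role,
             ta_type = ta_type, family = family, h_value = h,
             evalue = 1e-10, evidence = "blast", ref_id = "x",
             length_aa = NA_integer_, synthetic_feature = FALSE,
             stringsAsFactors = FALSE)
}

test_that("intergenic distance is the signed nearest-edge gap", {
  a <- list(replicon_id = "c", start = 100, end = 200)
  expect_equal(intergenic_distance(a, list(replicon_id = "c", start = 350,
                                           end = 450)), 150)
  expect_equal(intergenic_distance(a, list(replicon_id = "c", start = 180,
                                           end = 300)), -20)
  expect_equal(intergenic_distance(a, a), -100)
  b <- list(replicon_id = "c", start = 350, end = 450)
  expect_equal(intergenic_distance(a, b), intergenic_distance(b, a))
  expect_error(intergenic_distance(a, list(replicon_id = "d", start = 0,
                                           end = 10)), "different replicons")
})

test_that("type II window [-20, 150] is inclusive at both ends", {
  tox <- cand("t", "toxin", "II", 1000, 1300, "+")
  at_d <- function(d) rbind(tox, cand("a", "antitoxin", "II", 1300 + d,
                                      1560 + d, "+"))
  expect_equal(nrow(call_loci(at_d(30))), 1)
  expect_equal(nrow(call_loci(at_d(150))), 1)
  expect_equal(nrow(call_loci(at_d(151))), 0)
  expect_equal(nrow(call_loci(at_d(-20))), 1)
  expect_equal(nrow(call_loci(at_d(-21))), 0)
  # same strand required; both gene orders admissible
  opp <- rbind(tox, cand("a", "antitoxin", "II", 1330, 1560, "-"))
  expect_equal(nrow(call_loci(opp)), 0)
  upstream <- rbind(tox, cand("a", "antitoxin", "II", 700, 980, "+"))
  expect_equal(nrow(call_loci(upstream)), 1)
})

test_that("type I pairs on opposite strands within 200 bp, overlap unlimited", {
  tox <- cand("t", "toxin", "I", 500, 800, "+")
  rna_at <- function(start, strand)
    rbind(tox, cand("a", "antitoxin", "I", start, start + 100, strand,
                    molecule = "rna"))
  expect_equal(nrow(call_loci(rna_at(780, "-"))), 1)   # 20 bp overlap
  expect_equal(nrow(call_loci(rna_at(1000, "-"))), 1)  # distance 200
  expect_equal(nrow(call_loci(rna_at(1001, "-"))), 0)  # distance 201
  expect_equal(nrow(call_loci(rna_at(550, "-"))), 1)   # deep overlap
  expect_equal(nrow(call_loci(rna_at(780, "+"))), 0)   # same strand
})

test_that("type VIII variants follow creTA and SdsR-RyeA windows", {
  cre_pair <- function(d, s1 = "+", s2 = "+")
    rbind(cand("t", "toxin", "VIII", 100, 190, s1, molecule = "rna",
               family = "creTA"),
          cand("a", "antitoxin", "VIII", 190 + d, 290 + d, s2,
               molecule = "rna", family = "creTA"))
  expect_equal(nrow(call_loci(cre_pair(200))), 1)
  expect_equal(nrow(call_loci(cre_pair(201))), 0)
  expect_equal(nrow(call_loci(cre_pair(80, "+", "-"))), 1)  # either strand
  sds_pair <- function(d)
    rbind(cand("t", "toxin", "VIII", 100, 204, "+", molecule = "rna",
               family = "sdsR-ryeA"),
          cand("a", "antitoxin", "VIII", 204 + d, 324 + d, "-",
               molecule = "rna", family = "sdsR-ryeA"))
  expect_equal(nrow(call_loci(sds_pair(0))), 0)
  expect_equal(nrow(call_loci(sds_pair(-10))), 1)
  # SdsR-RyeA same strand never pairs
  same <- sds_pair(-10); same$strand <- "+"
  expect_equal(nrow(call_loci(same)), 0)
})

test_that("overlap resolution keeps the best call per feature pair", {
  l1 <- call_loci(rbind(
    cand("t", "toxin", "II", 100, 400, "+", family = "relBE", h = 0.9),
    cand("a", "antitoxin", "II", 430, 700, "+", family = "relBE", h = 0.9)))
  l2 <- call_loci(rbind(
    cand("t", "toxin", "IV", 100, 400, "+", family = "higBA", h = 0.5),
    cand("a", "antitoxin", "IV", 430, 700, "+", family = "higBA", h = 0.5)))
  res <- resolve_overlaps(rbind(l1, l2))
  expect_equal(nrow(res), 1)
  expect_equal(res$family, "relBE")
  # one antitoxin shared by two toxins: both loci retained
  shared <- call_loci(rbind(
    cand("t1", "toxin", "II", 100, 400, "+"),
    cand("t2", "toxin", "II", 800, 1100, "+"),
    cand("a", "antitoxin", "II", 430, 700, "+")))
  expect_equal(nrow(resolve_overlaps(shared)), 2)
  expect_equal(nrow(resolve_overlaps(empty_loci <- shared[0, ])), 0)
  # score ties break to the lower type number
  t1 <- call_loci(rbind(
    cand("t", "toxin", "V", 100, 400, "+", family = "zfam", h = 0.7),
    cand("a", "antitoxin", "V", 430, 700, "+", family = "zfam", h = 0.7)))
  t2 <- call_loci(rbind(
    cand("t", "toxin", "II", 100, 400, "+", family = "afam", h = 0.7),
    cand("a", "antitoxin", "II", 430, 700, "+", family = "afam", h = 0.7)))
  res <- resolve_overlaps(rbind(t1, t2))
  expect_equal(res$ta_type, "II")
})

test_that("locus calling equals exhaustive pair enumeration on random tables", {
  rules <- ta_rules()
  for (seed in 0:29) {
    cands <- random_candidates(seed)
    got <- call_loci(cands, rules)
    got_keys <- sort(paste(got$toxin_feature_id, got$antitoxin_feature_id,
                           got$ta_type, sep = "|"))
    expect_identical(got_keys, oracle_call_pairs(cands),
                     label = paste("seed", seed))
  }
})

test_that("reverse-complementing a replicon mirrors the called loci", {
  b <- generate_bundle(single_locus_plan(8, "II", "II", "vapBC", 40,
                                         "+", "+"))
  g <- b$genome
  L <- g$replicons$length[1]
  flipped <- ta_genome(
    g$replicons,
    Biostrings::DNAStringSet(setNames(
      list(Biostrings::reverseComplement(g$sequences[[1]])),
      g$replicons$id[1])),
    within(g$features, {
      tmp <- start
      start <- L - end
      end <- L - tmp
      strand <- ifelse(strand == "+", "-", "+")
      rm(tmp)
    })[, names(g$features)])
  refs <- bundled_references()
  orig <- resolve_overlaps(call_loci(build_candidates(
    search_protein(g, refs$protein), NULL, g)))
  mirr <- resolve_overlaps(call_loci(build_candidates(
    search_protein(flipped, refs$protein), NULL, flipped)))
  expect_equal(nrow(orig), 1)
  expect_equal(nrow(mirr), 1)
  expect_equal(mirr$toxin_start, L - orig$toxin_end)
  expect_equal(mirr$toxin_end, L - orig$toxin_start)
  expect_equal(mirr$toxin_strand, "-")
  expect_equal(mirr$distance, orig$distance)
  expect_equal(mirr$score, orig$score)
})

test_that("rule table round trips through user overrides", {
  rules <- ta_rules()
  path <- withr::local_tempfile(fileext = ".tsv")
  rules$dmax[rules$variant == "II"] <- 300
  write.table(rules, path, sep = "\t", quote = FALSE, row.names = FALSE)
  loose <- ta_rules(path)
  tox <- cand("t", "toxin", "II", 1000, 1300, "+")
  pair <- rbind(tox, cand("a", "antitoxin", "II", 1551, 1800, "+"))
  expect_equal(nrow(call_loci(pair)), 0)          # 251 > bundled 150
  expect_equal(nrow(call_loci(pair, loose)), 1)   # within the override
})
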