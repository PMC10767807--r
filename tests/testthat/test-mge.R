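# TA-MGE association: containment, flanking intervals, plasmid semantics.

locus_row <- function(id, start, end, replicon = "c") {
  data.frame(locus_id = id, replicon_id = replicon, ta_type = "II",
             variant = "II", family = "relBE", family_conflict = FALSE,
             toxin_feature_id = paste0(id, "_t"), toxin_start = start,
             toxin_end = start + 300L, toxin_strand = "+",
             toxin_h_value = 1,
             antitoxin_feature_id = paste0(id, "_a"),
             antitoxin_start = end - 250L, antitoxin_end = end,
             antitoxin_strand = "+", antitoxin_h_value = 1,
             distance = 30L, score = 1, stringsAsFactors = FALSE)
}

mge_row <- function(id, start, end, class, replicon = "c") {
  data.frame(mge_id = id, replicon_id = replicon, start = start, end = end,
             mge_class = class, stringsAsFactors = FALSE)
}

test_that("harbored links need full containment of the locus span", {
  l <- locus_row("L1", 10000, 11000)
  expect_equal(associate(l, mge_row("P1", 5000, 20000, "prophage"))$link_kind,
               "harbored")
  # 1 bp protrusion on either side breaks containment
  expect_equal(nrow(associate(l, mge_row("P1", 10001, 20000, "prophage"))), 0)
  expect_equal(nrow(associate(l, mge_row("P1", 5000, 10999, "prophage"))), 0)
  # non-IS classes never associate by flanking
  expect_equal(nrow(associate(l, mge_row("G1", 11500, 13000,
                                         "genomic_island"))), 0)
})

test_that("IS flanking uses a strict 5 kb edge-to-edge interval", {
  l <- locus_row("L1", 10000, 11000)
  at_gap <- function(g) associate(l, mge_row("IS1", 11000 + g,
                                             12000 + g, "IS_transposon"))
  expect_equal(at_gap(4999)$link_kind, "flanking_IS")
  expect_equal(at_gap(4999)$gap, 4999)
  expect_equal(nrow(at_gap(5000)), 0)
  expect_equal(at_gap(0)$gap, 0)
  # IS on the left flank counts too
  left <- associate(l, mge_row("IS2", 8000, 9000, "IS_cluster"))
  expect_equal(left$link_kind, "flanking_IS")
  expect_equal(left$gap, 1000)
})

test_that("plasmid replicons harbor every locus they carry", {
  l <- locus_row("L1", 2000, 3000, replicon = "p1")
  reps <- data.frame(id = "p1", length = 10000L, kind = "plasmid",
                     stringsAsFactors = FALSE)
  links <- associate(l, mge_row("x", 1, 2, "prophage")[0, ],
                     replicons = reps)
  expect_equal(nrow(links), 1)
  expect_equal(links$mge_id, "plasmid:p1")
  expect_equal(links$link_kind, "harbored")
  # unknown replicon ids are a reference error
  expect_error(associate(locus_row("L2", 10, 900, replicon = "nope"),
                         mge_row("x", 1, 2, "prophage")[0, ],
                         replicons = reps), "unknown replicon")
})

test_that("every qualifying pair emits its own link", {
  l <- locus_row("L1", 10000, 11000)
  mges <- rbind(mge_row("ICE1", 9000, 12000, "ICE"),
                mge_row("IS1", 13000, 13800, "IS_transposon"))
  links <- associate(l, mges)
  expect_equal(nrow(links), 2)
  expect_setequal(links$link_kind, c("harbored", "flanking_IS"))
})

test_that("association equals the brute-force predicate on random fixtures", {
  for (seed in 1:20) {
    set.seed(seed)
    n_l <- sample(1:8, 1); n_m <- sample(1:10, 1)
    loci <- do.call(rbind, lapply(seq_len(n_l), function(i) {
      s <- sample.int(50000, 1)
      locus_row(sprintf("L%02d", i), s, s + sample(400:1500, 1))
    }))
    mges <- do.call(rbind, lapply(seq_len(n_m), function(i) {
      s <- sample.int(60000, 1)
      mge_row(sprintf("M%02d", i), s, s + sample(500:15000, 1),
              sample(c("prophage", "genomic_island", "ICE", "integron",
                       "IS_transposon", "IS_cluster"), 1))
    }))
    got <- associate(loci, mges)
    got_keys <- sort(paste(got$locus_id, got$mge_id, got$link_kind,
                           sep = "|"))
    expect_identical(got_keys, oracle_links(loci, mges),
                     label = paste("seed", seed))
  }
})

test_that("widening the flank window never removes links", {
  set.seed(99)
  loci <- do.call(rbind, lapply(1:5, function(i) {
    s <- sample.int(40000, 1)
    locus_row(sprintf("L%02d", i), s, s + 800)
  }))
  mges <- do.call(rbind, lapply(1:12, function(i) {
    s <- sample.int(50000, 1)
    mge_row(sprintf("M%02d", i), s, s + 900, "IS_transposon")
  }))
  prev <- character()
  for (fb in c(0, 1000, 3000, 5000, 10000)) {
    links <- associate(loci, mges, flank_bp = fb)
    keys <- paste(links$locus_id, links$mge_id)
    expect_true(all(prev %in% keys))
    prev <- keys
  }
})

test_that("MGE tables read from TSV and GFF3 with class validation", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("mge_id\treplicon_id\tstart\tend\tclass",
               "P1\tchr1\t5001\t20000\tprophage"), tsv)
  m <- read_mge_table(tsv)
  expect_equal(m$start, 5000)
  expect_equal(m$end, 20000)
  writeLines(c("mge_id\treplicon_id\tstart\tend\tclass",
               "P1\tchr1\t5001\t20000\tphage"), tsv)
  expect_error(read_mge_table(tsv), "allowed")
  writeLines("mge_id\treplicon_id\tstart\tend\tclass", tsv)
  expect_equal(nrow(read_mge_table(tsv)), 0)
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tvr\tmobile_genetic_element\t5001\t20000\t.\t+\t.\tID=P1;class=prophage"),
             gff)
  mg <- read_mge_table(gff)
  expect_equal(mg$start, 5000)
  expect_equal(mg$mge_class, "prophage")
})
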