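# Genome readers/writers and the coordinate convention.

make_genbank <- function(path, seq_len = 500, records = 1,
                         features = character(), definition = "Test record.") {
  set.seed(101)
  lines <- character()
  for (r in seq_len(records)) {
    seq <- paste(sample(c("a", "c", "g", "t"), seq_len, TRUE), collapse = "")
    ori <- vapply(seq(1, seq_len, 60), function(i) {
      chunk <- substr(seq, i, min(i + 59, seq_len))
      tens <- regmatches(chunk, gregexpr(".{1,10}", chunk))[[1]]
      sprintf("%9d %s", i, paste(tens, collapse = " "))
    }, "")
    lines <- c(lines,
      sprintf("LOCUS       rec%d                %d bp    DNA     linear BCT 01-JAN-2020",
              r, seq_len),
      paste0("DEFINITION  ", definition),
      "SOURCE      Testus exemplus",
      "  ORGANISM  Testus exemplus",
      "FEATURES             Location/Qualifiers",
      features, "ORIGIN", ori, "//")
  }
  writeLines(lines, path)
  path
}

test_that("GenBank coordinates convert to 0-based half-open and strands map", {
  gb <- make_genbank(tempfile(fileext = ".gbk"), features = c(
    '     CDS             101..200',
    '                     /locus_tag="plusgene"',
    '                     /translation="MKLVHGWWATRSDKLMNPQRSTVWYACDEFGHI"',
    '     CDS             complement(101..200)',
    '                     /locus_tag="minusgene"',
    '     ncRNA           420..470',
    '                     /locus_tag="r1"'))
  # the qualifier-less minus-strand CDS over random sequence is expected
  # to warn about an internal stop in its forced conceptual translation
  g <- suppressWarnings(read_genbank(gb))
  f <- g$features
  plus <- f[f$feature_id == "plusgene", ]
  expect_equal(c(plus$start, plus$end), c(100, 200))
  expect_equal(plus$strand, "+")
  minus <- f[f$feature_id == "minusgene", ]
  expect_equal(c(minus$start, minus$end), c(100, 200))
  expect_equal(minus$strand, "-")
  expect_equal(f$molecule[f$feature_id == "r1"], "rna")
  # conceptual translation was forced for the qualifier-less CDS
  expect_gt(nchar(minus$translation), 0)
})

test_that("GenBank reader flags empty/invalid files and replicon kinds", {
  empty <- tempfile(); writeLines("", empty)
  expect_error(read_genbank(empty), "format error")
  expect_error(read_genbank(tempfile()), "no such file")
  gb <- make_genbank(tempfile(), definition = "Testus plasmid pX17.")
  expect_equal(read_genbank(gb)$replicons$kind, "plasmid")
})

test_that("internal stop codons in forced translations warn and truncate", {
  gb <- tempfile()
  # CDS 1..30 whose 4th codon is TAA
  seq <- paste0("atgaaacgc", "taa", paste(rep("gca", 6), collapse = ""))
  seq <- paste0(seq, paste(rep("a", 100 - nchar(seq)), collapse = ""))
  ori <- sprintf("%9d %s", 1, paste(regmatches(
    seq, gregexpr(".{1,10}", seq))[[1]], collapse = " "))
  writeLines(c(
    "LOCUS       stopper               100 bp    DNA     linear BCT 01-JAN-2020",
    "FEATURES             Location/Qualifiers",
    "     CDS             1..30",
    '                     /locus_tag="s1"',
    "ORIGIN", ori, "//"), gb)
  expect_warning(g <- read_genbank(gb), "internal stop")
  expect_equal(g$features$translation[1], "MKR")
})

test_that("FASTA+GFF3 round trip preserves every coordinate and strand", {
  b <- std_bundle()
  d <- withr::local_tempdir()
  p <- write_bundle(b, d)
  g2 <- read_fasta_gff(p$fasta, p$gff)
  f1 <- b$genome$features[order(b$genome$features$feature_id), ]
  f2 <- g2$features[order(g2$features$feature_id), ]
  expect_equal(f2$start, f1$start)
  expect_equal(f2$end, f1$end)
  expect_equal(f2$strand, f1$strand)
  expect_equal(f2$translation, f1$translation)
  expect_equal(g2$replicons$kind, b$genome$replicons$kind)
})

test_that("FASTA+GFF3 reader validates inputs", {
  d <- withr::local_tempdir()
  fa <- file.path(d, "g.fna"); gff <- file.path(d, "g.gff3")
  writeLines(c(">chrA", paste(rep("ACGT", 50), collapse = "")), fa)
  writeLines(c("##gff-version 3",
               "chrB\tx\tCDS\t10\t60\t.\t+\t0\tID=f1"), gff)
  expect_error(read_fasta_gff(fa, gff), "chrB")
  writeLines(c("##gff-version 3",
               "chrA\tx\tCDS\t60\t10\t.\t+\t0\tID=f1"), gff)
  expect_error(read_fasta_gff(fa, gff), "format error")
  writeLines(c("##gff-version 3",
               "chrA\tx\tncRNA\t10\t60\t.\t+\t.\tID=r1"), gff)
  g <- read_fasta_gff(fa, gff)
  expect_equal(g$features$molecule, "rna")
})

test_that("prediction GFF3 converts back to 1-based and groups by locus", {
  loci <- std_prediction()$loci
  path <- withr::local_tempfile(fileext = ".gff3")
  write_predictions_gff(loci, path)
  lines <- readLines(path)
  expect_equal(lines[1], "##gff-version 3")
  rows <- read.table(text = lines[-1], sep = "\t",
                     stringsAsFactors = FALSE)
  expect_equal(nrow(rows), 2 * nrow(loci))
  # 1-based inclusive conversion for the first toxin row
  tox1 <- rows[grepl(paste0("locus=", loci$locus_id[1], ";"), rows$V9) &
                 rows$V3 == "toxin_gene", ]
  expect_equal(tox1$V4, loci$toxin_start[1] + 1)
  expect_equal(tox1$V5, loci$toxin_end[1])
  n_locus_ids <- length(unique(sub(".*locus=([^;]+);.*", "\\1", rows$V9)))
  expect_equal(n_locus_ids, nrow(loci))
  # empty input stays a valid header-only file
  write_predictions_gff(loci[0, ], path)
  expect_equal(readLines(path), "##gff-version 3")
})

test_that("no operation outside the readers/writers emits 1-based coordinates", {
  # every stage output stays consistent with the 0-based feature table:
  # the toxin span extracted by its internal coordinates equals the
  # planted sequence span (spot check via alignment identity 1 loci)
  b <- std_bundle()
  pred <- std_prediction()
  loci <- pred$loci
  tr <- b$truth$loci
  keys_pred <- locus_keys(loci)
  keys_truth <- locus_keys(tr)
  expect_setequal(keys_pred, keys_truth[tr$expected])
})
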