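# FASTA round trips, interval extraction and feature-format conversions.

test_that("FASTA read/write round-trips byte-identical sequences", {
  set.seed(1)
  g <- genome_assembly(c(c1 = rdna(100), c2 = rdna(50)), name = "toy")
  expect_equal(nrow(chromosomes(g)), 2)
  expect_equal(total_length(g), 150)
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(g, f)
  g2 <- read_fasta(f)
  expect_identical(g2$seqs, g$seqs)
  expect_identical(names(g2$seqs), c("c1", "c2"))
})

test_that("read_fasta reports empty files, duplicate ids and bad alphabets", {
  f <- withr::local_tempfile(fileext = ".fasta")
  file.create(f)
  expect_error(read_fasta(f), "no records")
  writeLines(c(">a", "ACGT", ">a", "ACGT"), f)
  expect_error(read_fasta(f), "duplicate")
  writeLines(c(">a", "ACXT"), f)
  expect_error(read_fasta(f), "alphabet")
  # U is normalized, lower case upcased
  writeLines(c(">a", "acgu"), f)
  expect_identical(unname(read_fasta(f)$seqs[1]), "ACGT")
})

test_that("extract_interval indexes 0-based half-open and honours strand", {
  g <- genome_assembly(c(c1 = "ACGTACGT"))
  expect_identical(extract_interval(g, "c1", 2, 5), "GTA")
  expect_identical(extract_interval(g, "c1", 2, 5, "-"), "TAC")
  expect_error(extract_interval(g, "c1", 5, 5), "empty")
  expect_error(extract_interval(g, "c1", 0, 9), "length")
  expect_error(extract_interval(g, "c1", -1, 5), "lower bound")
  expect_error(extract_interval(g, "nope", 0, 5), "unknown chromosome")
})

test_that("reverse complement is an involution and matches minus-strand extraction", {
  set.seed(2)
  for (i in 1:5) {
    s <- rdna(sample(20:200, 1))
    expect_identical(reverse_complement(reverse_complement(s)), s)
  }
  g <- genome_assembly(c(c1 = rdna(300)))
  expect_identical(extract_interval(g, "c1", 37, 151, "-"),
                   reverse_complement(extract_interval(g, "c1", 37, 151)))
})

test_that("BED and GFF3 conventions converge to the same internal intervals", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("c1\t10\t20\tx\t0\t+", bed)
  fb <- read_features(bed)
  expect_equal(fb$start, 10)
  expect_equal(fb$end, 20)

  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "c1\tsrc\tregion\t11\t20\t.\t+\t.\tID=x"), gff)
  fg <- read_features(gff)
  expect_equal(fg$start, fb$start)
  expect_equal(fg$end, fb$end)
})

test_that("feature write/read round trip preserves coordinates in both formats", {
  set.seed(3)
  feats <- tibble::tibble(
    chrom = c("c1", "c1", "c2"),
    start = c(0L, 150L, 7L), end = c(100L, 175L, 9L),
    name = c("a", "b", "c"), score = c(1, 2, 3),
    strand = c("+", "-", "+"), type = "region")
  for (fmt in c("GFF3", "BED")) {
    f <- withr::local_tempfile(
      fileext = if (fmt == "BED") ".bed" else ".gff3")
    write_features(feats, f, format = fmt)
    back <- read_features(f, format = fmt)
    expect_equal(back$start, feats$start)
    expect_equal(back$end, feats$end)
    expect_equal(back$strand, feats$strand)
  }
})

test_that("malformed feature lines are reported with their line number", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("c1\t10\t20\tx\t0\t+", "c1\tnot_a_number\t30"), bed)
  expect_error(read_features(bed), "line 2")
})
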