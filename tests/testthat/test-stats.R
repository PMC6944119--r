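# Distribution statistics, density tracks, synteny chaining and the
# presence report.

test_that("chi-square uniformity matches hand-computed and degenerate cases", {
  u0 <- chi_square_uniformity(tibble::tibble(
    chrom = c("a", "b"), observed = c(10, 10), length = c(1e6, 1e6)))
  expect_equal(u0$chi2, 0)
  expect_equal(u0$p_value, 1)

  u <- chi_square_uniformity(tibble::tibble(
    chrom = c("a", "b"), observed = c(15, 15), length = c(1e6, 2e6)))
  expect_equal(u$chi2, 3.75)          # 25/10 + 25/20
  expect_equal(u$df, 1L)
  expect_equal(tidy(u)$expected, c(10, 20))

  u13 <- chi_square_uniformity(tibble::tibble(
    chrom = sprintf("c%02d", 1:13), observed = rep(5, 13),
    length = rep(1e6, 13)))
  expect_equal(u13$df, 12L)

  expect_error(chi_square_uniformity(tibble::tibble(
    chrom = "a", observed = 0, length = 1e6)), "N = 0")
})

test_that("chi-square agrees with the textbook implementation on random inputs", {
  set.seed(50)
  for (i in 1:100) {
    k <- sample(3:15, 1)
    L <- runif(k, 5e5, 5e6)
    O <- rpois(k, 20) + 1
    u <- chi_square_uniformity(tibble::tibble(
      chrom = paste0("c", 1:k), observed = O, length = L))
    ref <- suppressWarnings(stats::chisq.test(O, p = L / sum(L)))
    expect_equal(u$chi2, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(u$p_value, ref$p.value, tolerance = 1e-10)
    expect_equal(u$df, unname(ref$parameter))
    expect_equal(sum(tidy(u)$expected), sum(O))
  }
})

test_that("window density counts are conserved and assigned by start", {
  g <- genome_assembly(c(c1 = strrep("A", 100)))
  chroms <- tibble::tibble(chrom = "c1", length = 2e6)
  feats <- tibble::tibble(chrom = "c1",
                          start = c(0, 2.5e5, 5e5, 5e5 + 1, 1.9e6))
  d <- window_density(feats, chroms, window = 5e5)
  expect_equal(sum(d$count), nrow(feats))
  expect_equal(d$count, c(2, 2, 0, 1))

  # point mass
  d2 <- window_density(tibble::tibble(chrom = "c1", start = rep(7e5, 9)),
                       chroms, window = 5e5)
  expect_equal(max(d2$count), 9)
  expect_equal(sum(d2$count), 9)
})

test_that("synteny chaining recovers identity, detects deletions, ignores noise", {
  set.seed(51)
  seg <- rdna(30000)
  sb <- find_synteny_blocks(seg, seg)
  expect_equal(nrow(sb$blocks), 1)
  expect_lte(sb$blocks$a_start, 1)
  expect_gte(sb$blocks$a_end, 29500)

  # central 5 kb deletion on b: two blocks, gap spans the deleted locus
  seg_del <- paste0(substr(seg, 1, 12500), substr(seg, 17501, 30000))
  sb2 <- find_synteny_blocks(seg, seg_del)
  expect_equal(nrow(sb2$blocks), 2)
  expect_lte(abs(sb2$gaps$a_gap_start - 12500), 600)
  expect_lte(abs(sb2$gaps$a_gap_end - 17500), 600)
  expect_lte(sb2$gaps$b_gap_end - sb2$gaps$b_gap_start, 600)

  sb3 <- find_synteny_blocks(seg, rdna(30000))
  expect_equal(nrow(sb3$blocks), 0)
})

test_that("synteny chaining is symmetric under segment exchange", {
  set.seed(52)
  seg <- rdna(20000)
  seg_b <- paste0(substr(seg, 1, 8000), substr(seg, 12001, 20000))
  ab <- find_synteny_blocks(seg, seg_b)
  ba <- find_synteny_blocks(seg_b, seg)
  expect_equal(nrow(ab$blocks), nrow(ba$blocks))
  expect_equal(ab$blocks$a_start, ba$blocks$b_start, tolerance = 600)
  expect_equal(ab$blocks$b_start, ba$blocks$a_start, tolerance = 600)
})

test_that("presence report distinguishes motif-bearing subgenome chromosomes", {
  sim <- small_sim()
  tet <- make_tetraploid(sim)
  def <- motif_definition(sim$templates$unit, sim$templates$cs)
  rep <- subgenome_presence_report(tet, def)
  expect_equal(nrow(rep), 6)
  expect_true(all(rep$present[grepl("^D_", rep$chrom)]))
  expect_false(any(rep$present[grepl("^A_", rep$chrom)]))
  expect_match(attr(rep, "summary"), "none on A_chr01-A_chr03")
})

test_that("empty assemblies give an empty presence table", {
  def <- motif_definition(strrep("ACGT", 40), strrep("ACGGT", 200))
  rep <- subgenome_presence_report(
    structure(list(name = "x", seqs = character(0)),
              class = "genome_assembly"), def)
  expect_equal(nrow(rep), 0)
})
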