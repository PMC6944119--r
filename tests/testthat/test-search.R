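# Seed-and-extend search: self matches, strand symmetry, agreement with an
# exhaustive Smith-Waterman oracle, internal-consistency recounts, and the
# 80-80 screen.

test_that("an exact substring is found with identity and coverage 1", {
  set.seed(10)
  g <- genome_assembly(c(c1 = rdna(50000)))
  q <- extract_interval(g, "c1", 10000, 10400)
  h <- search_genome(g, q)
  expect_gte(nrow(h), 1)
  expect_equal(h$tstart[1], 10000)
  expect_equal(h$tend[1], 10400)
  expect_equal(h$strand[1], "+")
  expect_equal(h$identity[1], 1)
  expect_equal(h$query_coverage[1], 1)
})

test_that("search is strand-symmetric", {
  set.seed(11)
  g <- genome_assembly(c(c1 = rdna(50000)))
  q <- extract_interval(g, "c1", 20000, 20350)
  h_fwd <- search_genome(g, q)
  h_rev <- search_genome(g, reverse_complement(q))
  expect_equal(h_rev$strand[1], "-")
  expect_equal(h_rev$tstart[1], h_fwd$tstart[1])
  expect_equal(h_rev$tend[1], h_fwd$tend[1])
  expect_equal(h_rev$identity[1], 1)
})

test_that("a query shorter than the seed size errors", {
  g <- genome_assembly(c(c1 = rdna(1000)))
  expect_error(search_genome(g, "ACGT"), "seed size")
})

test_that("best-hit scores equal the exhaustive Smith-Waterman oracle", {
  set.seed(12)
  params <- search_params(k = 5, band = 220, x_drop = 500, min_score = 1)
  for (i in 1:10) {
    n <- sample(60:200, 1)
    a <- rdna(n)
    b <- mutate_k2p(a, 0.12)
    if (i %% 2 == 0) {
      p <- sample(15:40, 1)
      b <- paste0(substr(b, 1, p), substr(b, p + 4, nchar(b)))
    }
    h <- search_genome(b, a, params)
    expect_equal(max(h$score), sw_oracle_score(a, b),
                 info = paste("pair", i))
  }
})

test_that("reported identity and coverage are consistent on re-alignment", {
  set.seed(13)
  g <- genome_assembly(c(c1 = rdna(30000)))
  q <- mutate_k2p(extract_interval(g, "c1", 5000, 5600), 0.05)
  h <- search_genome(g, q)
  rc <- recount_hits(h[1, ], g, q)
  expect_equal(rc$re_matches, rc$matches)
  expect_equal(rc$re_score, rc$score)
})

test_that("the 80-80 rule is inclusive at its boundary and monotone", {
  hits <- tibble::tibble(identity = c(0.85, 0.80, 0.79, 0.95),
                         query_coverage = c(0.90, 0.80, 0.95, 0.79))
  expect_equal(passes_80_80(hits), c(TRUE, TRUE, FALSE, FALSE))
  # raising either threshold never lets more hits pass
  set.seed(14)
  rnd <- tibble::tibble(identity = runif(200), query_coverage = runif(200))
  base <- sum(passes_80_80(rnd))
  for (thr in c(0.85, 0.9, 0.99)) {
    expect_lte(sum(passes_80_80(rnd, min_identity = thr)), base)
    expect_lte(sum(passes_80_80(rnd, min_coverage = thr)), base)
  }
})

test_that("screen_genome_specific separates specific, shared and absent queries", {
  set.seed(15)
  shared <- rdna(400)
  d_only <- rdna(400)
  bg_a <- rdna(20000); bg_b <- rdna(20000)
  d_genome <- genome_assembly(
    c(c1 = paste0(bg_a, d_only, rdna(2000), shared, rdna(2000))))
  a_genome <- genome_assembly(c(c1 = paste0(bg_b, shared, rdna(4000))))
  res <- screen_genome_specific(
    c(spec = d_only, both = shared, none = rdna(400)),
    d_genome, a_genome)
  expect_equal(res$class, c("specific", "shared", "absent"))
  expect_equal(res$loci_absent_genome[1], 0)
})
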