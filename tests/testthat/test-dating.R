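# K2P distance, insertion dating, paired-LTR detection and family
# clustering.

test_that("k2p_distance matches the closed form and its domain rules", {
  expect_equal(k2p_distance(0, 0), 0)
  # independent evaluation of -1/2 log((1-2P-Q) sqrt(1-2Q)) at P=.2, Q=.1
  expect_equal(k2p_distance(0.2, 0.1), 0.40236, tolerance = 1e-5)
  expect_error(k2p_distance(0.45, 0.1), "saturated")
  expect_error(k2p_distance(0.1, 0.5), "saturated")
  expect_error(k2p_distance(-0.1, 0.1), "non-negative")
})

test_that("k2p_distance is increasing in P and Q and dominates the p-distance", {
  set.seed(40)
  for (i in 1:50) {
    P <- runif(1, 0, 0.3); Q <- runif(1, 0, 0.25)
    if (1 - 2 * P - Q <= 0.05 || 1 - 2 * Q <= 0.05) next
    d <- k2p_distance(P, Q)
    expect_gte(d, P + Q)
    expect_gt(k2p_distance(P + 0.01, Q), d)
    expect_gt(k2p_distance(P, Q + 0.01), d)
  }
})

test_that("insertion_time implements T = d / 2r with exact rate scaling", {
  expect_equal(insertion_time(0, 1.3e-8), 0)
  expect_equal(insertion_time(0.78, 1.3e-8), 3e7)
  expect_equal(insertion_time(0.26, 1.3e-8), 1e7)
  d <- 0.1234
  expect_equal(insertion_time(d, 2 * 1.3e-8),
               insertion_time(d, 1.3e-8) / 2)
  expect_error(insertion_time(0.5, 0), "> 0")
})

make_ltr_element <- function(age_mya, ltr_len = 1000, internal = 3000,
                             r = 1.3e-8) {
  tmpl <- rdna(ltr_len)
  d <- r * age_mya * 1e6
  paste0(mutate_k2p(tmpl, d), rdna(internal), mutate_k2p(tmpl, d))
}

test_that("identical LTRs are detected with P = Q = 0 and age 0", {
  set.seed(41)
  ltr <- rdna(300)
  el <- paste0(ltr, rdna(2000), ltr)
  g <- genome_assembly(c(c1 = paste0(rdna(1500), el, rdna(1500))))
  p <- detect_ltr_pairs(g, tibble::tibble(chrom = "c1", start = 1400,
                                          end = 1600 + nchar(el)))
  expect_true(p$paired)
  expect_equal(p$P, 0)
  expect_equal(p$Q, 0)
  expect_equal(p$d, 0)
  expect_equal(p$T_years, 0)
  expect_lt(abs(p$left_end - p$left_start - 300), 6)
})

test_that("divergence of a mutated pair is recovered within binomial error", {
  set.seed(42)
  tmpl <- rdna(1500)
  el <- paste0(mutate_k2p(tmpl, 0.05), rdna(2500), mutate_k2p(tmpl, 0.05))
  g <- genome_assembly(c(c1 = paste0(rdna(1000), el, rdna(1000))))
  p <- detect_ltr_pairs(g, tibble::tibble(chrom = "c1", start = 900,
                                          end = 1100 + nchar(el)))
  expect_true(p$paired)
  # two copies at 0.05 each: pair distance 0.10; allow 3 binomial SE
  n <- p$aligned_cols
  se <- sqrt(0.095 * 0.905 / n) * 1.2  # delta factor for the K2P transform
  expect_lt(abs(p$d - 0.10), 3 * se + 0.005)
})

test_that("pure random candidates stay unpaired", {
  set.seed(43)
  g <- genome_assembly(c(c1 = rdna(8000)))
  p <- detect_ltr_pairs(g, tibble::tibble(chrom = "c1", start = 500,
                                          end = 7500))
  expect_false(p$paired)
  expect_true(is.na(p$d))
})

test_that("family clustering links identical LTRs and isolates the rest", {
  set.seed(44)
  expect_equal(max(cluster_families(rep(rdna(400), 3))$family), 1)

  ltrs <- vapply(1:24, function(i) rdna(400), character(1))
  ltrs <- c(ltrs, mutate_k2p(ltrs[3], 0.05))
  fam <- cluster_families(ltrs)
  expect_equal(max(fam$family), 24)
  expect_equal(fam$family[25], fam$family[3])
  sizes <- table(fam$family)
  expect_equal(sort(as.integer(sizes), decreasing = TRUE)[1:2], c(2L, 1L))

  # partition invariant under input order
  perm <- sample(length(ltrs))
  fam2 <- cluster_families(ltrs[perm])
  part1 <- split(seq_along(ltrs), fam$family)
  part2 <- split(perm, fam2$family)
  canon <- function(p) unname(lapply(p, sort))[order(vapply(p, min, 1))]
  expect_equal(canon(part1), canon(part2))
})

test_that("activity histogram bins ages and sidelines undated elements", {
  pairs <- tibble::tibble(T_years = c(rep(3.0e7, 4), NA, NA))
  h <- activity_histogram(pairs, bin_width = 5e6)
  expect_equal(sum(h$count), 4)
  expect_equal(h$count[h$bin_start == 3e7], 4)
  expect_equal(attr(h, "n_undated"), 2)

  set.seed(45)
  ages <- stats::rnorm(100, 3e7, 5e6)
  h2 <- activity_histogram(tibble::tibble(T_years = ages), bin_width = 5e6)
  mode_bin <- h2[which.max(h2$count), ]
  expect_true(mode_bin$bin_start <= 3e7 && 3e7 <= mode_bin$bin_end)

  h0 <- activity_histogram(tibble::tibble(T_years = double(0)))
  expect_true(all(h0$count == 0))
})
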