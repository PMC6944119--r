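# Tandem array detection, consensus training and the self-similarity
# dot matrix.

test_that("a planted exact array is detected with the right unit and copies", {
  set.seed(20)
  arr <- strrep("ACGTTACGGA", 6)
  seqx <- paste0(rdna(5000), arr, rdna(5000))
  a <- detect_arrays(seqx, min_unit = 10, max_unit = 60)
  expect_equal(nrow(a), 1)
  expect_equal(a$unit_length, 10L)
  expect_lt(abs(a$copy_number - 6), 0.5)
  expect_equal(a$unit_consensus, "ACGTTACGGA")
})

test_that("a mutated 133-base array is recovered with unit 133 +- 1 and ~10 copies", {
  set.seed(21)
  unit <- rdna(133)
  units <- vapply(1:10, function(i) mutate_k2p(unit, 0.05), character(1))
  seqx <- paste0(rdna(3000), paste(units, collapse = ""), rdna(3000))
  a <- detect_arrays(seqx, min_unit = 50, max_unit = 250)
  expect_equal(nrow(a), 1)
  expect_lte(abs(a$unit_length - 133), 1)
  expect_gte(a$copy_number, 9)
  expect_lte(a$copy_number, 11)
  expect_gte(a$mean_unit_identity, 0.9)
})

test_that("random sequence yields no arrays at 50+ base units", {
  set.seed(22)
  expect_equal(nrow(detect_arrays(rdna(10000), min_unit = 50,
                                  max_unit = 200)), 0)
})

test_that("detected arrays are non-overlapping and re-validate their floor", {
  set.seed(23)
  u1 <- rdna(20); u2 <- rdna(45)
  seqx <- paste0(rdna(2000), strrep(u1, 5), rdna(1500), strrep(u2, 4),
                 rdna(2000))
  a <- detect_arrays(seqx, min_unit = 10, max_unit = 80,
                     min_unit_identity = 0.8)
  expect_gte(nrow(a), 2)
  if (nrow(a) > 1) {
    a <- a[order(a$start), ]
    expect_true(all(a$start[-1] >= a$end[-nrow(a)]))
  }
  expect_true(all(a$mean_unit_identity >= 0.8))
})

test_that("unit consensus is the column majority and keeps the unit length", {
  u <- "ACGTTACGGATTCCA"
  units <- rep(u, 5)
  substr(units[2], 7, 7) <- "G"  # one deviant base at column 7
  cons <- train_unit_consensus(paste(units, collapse = ""), nchar(u))
  expect_equal(as.character(cons), u)
  expect_equal(nchar(cons), nchar(u))
  # unanimity
  cons2 <- train_unit_consensus(strrep("ACGTTACGGA", 4), 10)
  expect_equal(as.character(cons2), "ACGTTACGGA")
  expect_equal(attr(cons2, "mean_unit_identity"), 1)
})

test_that("self-similarity matrix is symmetric with stripes at unit lags", {
  set.seed(24)
  unit <- rdna(40)
  m <- self_similarity_matrix(strrep(unit, 5), k = 8)
  expect_true(isSymmetric(unclass(m)))
  expect_true(all(diag(unclass(m))))
  # stripe: off-diagonal at lag = unit length
  n <- nrow(m)
  lag_hits <- sum(vapply(seq_len(n - 40), function(i) m[i, i + 40],
                         logical(1)))
  expect_equal(lag_hits, n - 40)
  # random sequence: off-diagonal density near the 4^-k background
  r <- self_similarity_matrix(rdna(600), k = 8)
  off <- (sum(r) - nrow(r)) / (length(r) - nrow(r))
  expect_lt(off, 10 * 4^-8 + 1e-3)
})

test_that("detected unit counts recover the planted copy-number distribution", {
  set.seed(25)
  planted <- sample(2:21, 200, replace = TRUE)
  detected <- integer(0)
  for (U in planted) {
    unit <- rdna(133)
    arr <- paste(vapply(seq_len(U), function(i) mutate_k2p(unit, 0.02),
                        character(1)), collapse = "")
    seqx <- paste0(rdna(300), arr, rdna(300))
    a <- detect_arrays(seqx, min_unit = 100, max_unit = 170)
    if (nrow(a) == 1) detected <- c(detected, round(a$copy_number))
  }
  expect_gte(length(detected), 195)
  obs <- tabulate(factor(detected, levels = 2:21))
  gof <- suppressWarnings(
    stats::chisq.test(obs, p = rep(1 / 20, 20)))
  expect_gt(gof$p.value, 0.01)
})
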