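# Simulator: K2P mutator calibration, element arithmetic, planting truth
# and the collinearity of the A-like genome.

test_that("mutate_k2p honours the zero and negative boundaries", {
  expect_identical(mutate_k2p("ACGTACGT", 0), "ACGTACGT")
  expect_error(mutate_k2p("ACGT", -0.1), ">= 0")
  expect_identical(mutate_k2p("ACGT", 0.3, seed = 5),
                   mutate_k2p("ACGT", 0.3, seed = 5))
  expect_identical(nchar(mutate_k2p(rdna(500), 0.4)), 500L)
})

test_that("mutate_k2p produces the requested expected K2P distance", {
  set.seed(42)
  d_hat <- replicate(50, {
    s <- rdna(10000)
    m <- mutate_k2p(s, 0.2, kappa = 2)
    pq <- pq_oracle(s, m)
    k2p_distance(pq$P, pq$Q)
  })
  se <- stats::sd(d_hat) / sqrt(length(d_hat))
  expect_lt(abs(mean(d_hat) - 0.2), 3 * se)
})

test_that("mutate_k2p leaves N untouched", {
  s <- paste0(strrep("N", 50), rdna(200))
  m <- mutate_k2p(s, 0.5, seed = 1)
  expect_identical(substr(m, 1, 50), strrep("N", 50))
})

test_that("motif element layout arithmetic matches unit and CS sizes", {
  cfg <- simulation_config()
  el <- build_motif_element(cfg, unit_count = 5, age_mya = 3, gap = 0,
                            seed = 2)
  lay <- el$layout
  tr <- lay[lay$part == "tr_array", ]
  cs <- lay[lay$part == "cs", ]
  expect_equal(tr$end - tr$start, 5 * 133)
  expect_equal(max(tr$end, cs$end) - min(tr$start, cs$start), 5 * 133 + 860)

  # an extreme 61-unit array spans 8113 bases (order 8 kb)
  cfg61 <- simulation_config(unit_copy_range = c(2, 61))
  el61 <- build_motif_element(cfg61, 61, age_mya = 3, seed = 3)
  tr61 <- el61$layout[el61$layout$part == "tr_array", ]
  expect_equal(tr61$end - tr61$start, 61 * 133)

  expect_error(build_motif_element(cfg, 1, 3), "unit_copy_range")
  expect_error(build_motif_element(cfg, 22, 3), "unit_copy_range")
})

test_that("age-zero elements carry identical LTR copies", {
  cfg <- simulation_config()
  el <- build_motif_element(cfg, 4, age_mya = 0, seed = 4)
  lay <- el$layout
  g <- genome_assembly(c(e = el$seq))
  left <- lay[lay$part == "left_ltr", ]
  right <- lay[lay$part == "right_ltr", ]
  expect_identical(extract_interval(g, "e", left$start, left$end),
                   extract_interval(g, "e", right$start, right$end))
})

test_that("simulation truth matches the planting request and is deterministic", {
  sim <- small_sim()
  truth <- sim$truth
  expect_equal(sum(truth$kind == "full_motif"), 8)
  expect_equal(sum(truth$kind == "LTR_TE"), 8)
  expect_equal(sum(truth$kind == "lone_TR"), 3)
  expect_equal(sum(truth$kind == "lone_CS"), 3)
  # constituent-level counts: TR in 8 motifs + 3 lone, CS likewise
  expect_equal(sum(!is.na(truth$tr_start)), 11)
  expect_equal(sum(!is.na(truth$cs_start)), 11)

  sim2 <- simulate_genome_pair(sim$cfg, seed = 11)
  expect_identical(sim2$d_genome$seqs, sim$d_genome$seqs)
  expect_identical(sim2$a_genome$seqs, sim$a_genome$seqs)
  expect_identical(sim2$truth, sim$truth)

  sim3 <- simulate_genome_pair(sim$cfg, seed = 12)
  expect_false(identical(sim3$d_genome$seqs, sim$d_genome$seqs))
})

test_that("deleting every planted locus from the D-like genome restores the A-like genome", {
  sim <- small_sim()
  planted <- sim$truth[sim$truth$kind != "full_motif", ]
  for (cid in names(sim$d_genome$seqs)) {
    s <- sim$d_genome$seqs[[cid]]
    iv <- planted[planted$chrom == cid, ]
    iv <- iv[order(-iv$start), ]
    for (i in seq_len(nrow(iv))) {
      s <- paste0(substr(s, 1, iv$start[i]),
                  substr(s, iv$end[i] + 1, nchar(s)))
    }
    expect_identical(s, sim$a_genome$seqs[[cid]])
  }
})

test_that("tetraploid concatenation renames and preserves both subgenomes", {
  sim <- small_sim()
  tet <- make_tetraploid(sim)
  expect_equal(nrow(chromosomes(tet)), 6)
  expect_identical(unname(tet$seqs[["D_chr01"]]),
                   unname(sim$d_genome$seqs[["chr01"]]))
  expect_identical(unname(tet$seqs[["A_chr02"]]),
                   unname(sim$a_genome$seqs[["chr02"]]))
})

test_that("simulation outputs serialize to disk with a valid truth GFF3", {
  sim <- small_sim()
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, dir)
  expect_true(all(file.exists(paths)))
  truth_back <- read_features(paths[["truth"]])
  expect_equal(nrow(truth_back), nrow(sim$truth))
  expect_setequal(truth_back$start, sim$truth$start)
  d_back <- read_fasta(paths[["d_fasta"]])
  expect_identical(d_back$seqs, sim$d_genome$seqs)
})

test_that("infeasible packing is rejected", {
  cfg <- simulation_config(n_chromosomes = 1, chromosome_lengths = 3e4,
                           n_motifs = 8, n_lone_tr = 0, n_lone_cs = 0)
  expect_error(simulate_genome_pair(cfg, seed = 1), "infeasible packing")
})
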