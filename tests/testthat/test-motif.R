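# Motif scanning, constituent pairing and consensus accumulation.

test_that("scan finds exactly the planted constituents, none on the A-like genome", {
  sim <- small_sim()
  def <- motif_definition(sim$templates$unit, sim$templates$cs)
  sc <- scan_constituents(sim$d_genome, def)
  expect_equal(nrow(sc$tr), 11)  # 8 in motifs + 3 lone
  expect_equal(nrow(sc$cs), 11)
  sca <- scan_constituents(sim$a_genome, def)
  expect_equal(nrow(sca$tr), 0)
  expect_equal(nrow(sca$cs), 0)
})

test_that("pairing respects the gap bound, uses each hit once and labels lone hits", {
  tr <- tibble::tibble(chrom = "c1", start = 1000, end = 1500,
                       strand = "+", n_units = 4L, copy_number = 4,
                       unit_count = 4L, identity = 0.95)
  near <- tibble::tibble(chrom = "c1", start = 1540, end = 2400,
                         strand = "+", identity = 0.95,
                         query_coverage = 0.97)
  out <- pair_constituents(list(tr = tr, cs = near), max_gap = 200)
  expect_equal(sum(out$kind == "motif"), 1)
  expect_equal(out$start, 1000)
  expect_equal(out$end, 2400)

  far <- dplyr::mutate(near, start = 6500, end = 7360)
  out2 <- pair_constituents(list(tr = tr, cs = far), max_gap = 200)
  expect_equal(sum(out2$kind == "motif"), 0)
  expect_setequal(out2$kind, c("lone_TR", "lone_CS"))

  # opposite strands never pair
  flip <- dplyr::mutate(near, strand = "-")
  out3 <- pair_constituents(list(tr = tr, cs = flip), max_gap = 200)
  expect_equal(sum(out3$kind == "motif"), 0)
})

test_that("paired calls on the simulated genome match the planted structure", {
  sim <- small_sim()
  def <- motif_definition(sim$templates$unit, sim$templates$cs)
  calls <- call_motifs(sim$d_genome, def)
  expect_equal(sum(calls$kind == "motif"), 8)
  expect_equal(sum(calls$kind == "lone_TR"), 3)
  expect_equal(sum(calls$kind == "lone_CS"), 3)
  expect_lte(sum(calls$kind == "motif"),
             min(sum(!is.na(sim$truth$tr_start)),
                 sum(!is.na(sim$truth$cs_start))))
  # boundaries within 20 bases of truth
  tm <- sim$truth[sim$truth$kind == "full_motif", ]
  cm <- calls[calls$kind == "motif", ]
  for (i in seq_len(nrow(tm))) {
    j <- which(cm$chrom == tm$chrom[i] &
                 abs(cm$start - tm$start[i]) <= 20 &
                 abs(cm$end - tm$end[i]) <= 20)
    expect_length(j, 1)
  }
  # unit counts agree within 1 for matched motifs
  ord_truth <- tm[order(tm$chrom, tm$start), ]
  ord_calls <- cm[order(cm$chrom, cm$start), ]
  expect_true(all(abs(ord_truth$unit_count - ord_calls$unit_count) <= 1))
})

test_that("motif calls serialize to GFF3 with constituent features", {
  sim <- small_sim()
  def <- motif_definition(sim$templates$unit, sim$templates$cs)
  calls <- call_motifs(sim$d_genome, def)
  f <- withr::local_tempfile(fileext = ".gff3")
  write_motif_gff3(calls, f)
  back <- read_features(f)
  expect_equal(sum(back$type == "composite_motif"), 8)
  expect_equal(sum(back$type == "motif_TR"), 11)
  expect_equal(sum(back$type == "motif_CS"), 11)
})

test_that("consensus accumulation counts unanimity and single instances correctly", {
  set.seed(30)
  ref <- rdna(400)
  h <- consensus_accumulation(rep(ref, 7), ref)
  expect_true(all(h$agreement == 7))
  expect_equal(attr(h, "n_instances"), 7)
  h1 <- consensus_accumulation(ref, ref)
  expect_true(all(h1$agreement == 1))
})

test_that("a conserved core shows as a contiguous high-agreement plateau", {
  set.seed(31)
  flank1 <- rdna(600); core <- rdna(700); flank2 <- rdna(600)
  ref <- paste0(flank1, core, flank2)
  inst <- vapply(1:12, function(i) {
    paste0(mutate_k2p(flank1, 0.4), mutate_k2p(core, 0.02),
           mutate_k2p(flank2, 0.4))
  }, character(1))
  h <- consensus_accumulation(inst, ref)
  pl <- plateau_region(h)
  expect_equal(nrow(pl), 1)
  cover <- min(pl$end, 1300) - max(pl$start, 600)
  expect_gte(cover / 700, 0.9)
})

test_that("unit content histogram tallies TR-bearing calls", {
  calls <- tibble::tibble(kind = c("motif", "motif", "lone_TR", "lone_CS"),
                          unit_count = c(3L, 3L, 7L, NA))
  hist <- unit_content_histogram(calls)
  expect_equal(hist$n[hist$unit_count == 3], 2)
  expect_equal(hist$n[hist$unit_count == 7], 1)
})
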