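# shared fixtures, all generated in code

rdna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, TRUE, prob = p), collapse = "")
}

# a small simulated pair shared across motif/pipeline tests
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(n_chromosomes = 3, chromosome_lengths = 2e5,
                               n_motifs = 8, n_lone_tr = 3, n_lone_cs = 3)
      cache <<- simulate_genome_pair(cfg, seed = 11)
    }
    cache
  }
})

# observed/expected substitution counting oracle for two equal-length strings
pq_oracle <- function(a, b) {
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  pur <- c("A", "G")
  same <- va == vb
  ts <- !same & ((va %in% pur) == (vb %in% pur))
  tv <- !same & !ts
  list(P = mean(ts), Q = mean(tv))
}

# Smith-Waterman oracle with the package's scoring scheme
sw_oracle_score <- function(a, b, match = 1, mismatch = -1,
                            gap_open = 2, gap_ext = 1) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = TRUE)
  Biostrings::score(Biostrings::pairwiseAlignment(
    a, b, type = "local", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_ext))
}
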