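# Shared internal helpers: sequence manipulation and RNG scoping.

DNA_BASES <- c("A", "C", "G", "T")

# fast random DNA string; gc = target G+C fraction
random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  codes <- c(65L, 67L, 71L, 84L)[sample.int(4L, n, replace = TRUE, prob = p)]
  intToUtf8(codes)
}

revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  x <- chartr("ACGTNacgtn", "TGCANtgcan", seq)
  intToUtf8(rev(utf8ToInt(x)))
}

seq_codes <- function(seq) utf8ToInt(seq)

codes_to_seq <- function(codes) intToUtf8(codes)

# run body with a locally-seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# derive a stream of child seeds from one master seed (kept below 2^31)
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
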