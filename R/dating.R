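# Paired-LTR detection, Kimura two-parameter distance, insertion dating
# (T = d / 2r) and LTR family clustering under the 80-80 rule.

#' Dating configuration
#'
#' @param r Substitution rate in substitutions/site/year.
#' @param min_ltr,max_ltr LTR length bounds in bases.
#' @param min_element,max_element Element span bounds in bases.
#' @param ltr_similarity_floor Minimum identity between the paired LTRs for
#'   a pair call. The default (0.70) targets confident pair calling; dating
#'   surveys of strongly diverged (old) pairs need a lower floor, since a
#'   pair 30 million years old is only ~55% identical at
#'   r = 1.3e-8/site/year.
#' @param seed_k Seed size for the LTR-vs-LTR search (small, because the
#'   repeats may be heavily diverged).
#' @param band,x_drop,min_score Extension parameters, as in
#'   [search_params()].
#' @param end_trim Aligned columns discarded at each end of the refined
#'   LTR region before substitution counting, decoupling the distance
#'   estimate from the boundary-detection columns.
#' @param boundary_ext Bases explored beyond each end of the seed hit when
#'   refining LTR boundaries. A maximal-scoring local alignment
#'   systematically trims and enriches matches, biasing distances downward
#'   for old elements; boundaries are therefore re-estimated by a rolling
#'   identity changepoint along the hit diagonal, and P/Q are counted over
#'   that fixed region's interior.
#' @param boundary_window Rolling-identity window (bases) for the
#'   changepoint.
#' @param flank_slack Extra bases searched beyond `max_ltr` at each
#'   candidate end.
#' @return A list of class `dating_config`.
#' @export
dating_config <- function(r = 1.3e-8, min_ltr = 100, max_ltr = 3000,
                          min_element = 1000, max_element = 15000,
                          ltr_similarity_floor = 0.70,
                          seed_k = 6, band = 50, x_drop = 100,
                          min_score = 30, end_trim = 50,
                          boundary_ext = 400, boundary_window = 80,
                          flank_slack = 200) {
  stopifnot(r > 0, min_ltr < max_ltr, min_element < max_element,
            ltr_similarity_floor > 0, ltr_similarity_floor <= 1)
  structure(as.list(environment()), class = "dating_config")
}

#' Kimura two-parameter distance
#'
#' `d = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))` from transition (`P`) and
#' transversion (`Q`) proportions. Outside the model's domain
#' (`1 - 2P - Q <= 0` or `1 - 2Q <= 0`) the divergence is saturated and an
#' error is raised rather than a number returned.
#'
#' @param P Transition proportion (>= 0).
#' @param Q Transversion proportion (>= 0).
#' @return Distance in substitutions/site; 0 iff `P = Q = 0`. Vectorized.
#' @export
#' @examples
#' k2p_distance(0.2, 0.1)  # 0.40236
k2p_distance <- function(P, Q) {
  if (any(P < 0) || any(Q < 0)) {
    stop("P and Q must be non-negative proportions", call. = FALSE)
  }
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (any(w1 <= 0) || any(w2 <= 0)) {
    stop("saturated divergence: K2P distance undefined for P = ",
         paste(P[w1 <= 0 | w2 <= 0], collapse = ","), ", Q = ",
         paste(Q[w1 <= 0 | w2 <= 0], collapse = ","), call. = FALSE)
  }
  -0.5 * log(w1 * sqrt(w2)) + 0  # + 0 normalizes IEEE negative zero
}

k2p_or_na <- function(P, Q) {
  tryCatch(k2p_distance(P, Q), error = function(e) NA_real_)
}

#' Insertion time from LTR divergence
#'
#' `T = d / (2 r)`: at insertion the two LTRs are identical and each
#' accumulates `r * T` substitutions/site afterwards.
#'
#' @param d K2P distance between the paired LTRs (substitutions/site).
#' @param r Substitution rate (substitutions/site/year), > 0.
#' @return Age in years. Vectorized.
#' @export
#' @examples
#' insertion_time(0.78, 1.3e-8)  # 3e7 years
insertion_time <- function(d, r = 1.3e-8) {
  if (any(r <= 0)) stop("substitution rate r must be > 0", call. = FALSE)
  if (any(d < 0, na.rm = TRUE)) stop("d must be >= 0", call. = FALSE)
  d / (2 * r)
}

# refine LTR boundaries around a seed hit by a rolling-identity
# changepoint along the hit diagonal, inside one element sequence.
# lab/rab are the hit's left/right intervals (element coordinates).
# Returns refined intervals plus the aligned strings of the region.
refine_ltr_boundaries <- function(seq, lab, rab, cfg) {
  L <- nchar(seq)
  ext <- cfg$boundary_ext
  # same-length extension of both intervals along the pairing
  lo_room <- min(lab[1], rab[1])
  hi_room <- min(L - lab[2], L - rab[2])
  e_lo <- min(ext, lo_room)
  e_hi <- min(ext, hi_room)
  l2 <- c(lab[1] - e_lo, lab[2] + e_hi)
  r2 <- c(rab[1] - e_lo, rab[2] + e_hi)
  a <- substr(seq, l2[1] + 1, l2[2])
  b <- substr(seq, r2[1] + 1, r2[2])
  # heavy gap costs: the measurement alignment must not wander across
  # diagonals chasing chance matches in diverged sequence, which would
  # inflate identity; real indels still pay off when well supported
  al <- cpp_align(a, b, gap_open = 8, gap_ext = 4, local = FALSE,
                  band = cfg$band)
  av <- strsplit(al$a_aln, "")[[1]]
  bv <- strsplit(al$b_aln, "")[[1]]
  m <- as.integer(av == bv & av %in% DNA_BASES)
  n <- length(m)
  w <- min(cfg$boundary_window, n)
  half <- w %/% 2
  cs <- cumsum(c(0, m))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  roll <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  # core identity from the central half of the original hit region
  a_off <- cumsum(av != "-")
  hit_len <- lab[2] - lab[1]
  hit_cols <- which(a_off > (e_lo + hit_len / 4) &
                      a_off <= (e_lo + 3 * hit_len / 4))
  p_core <- if (length(hit_cols) > 10) mean(m[hit_cols]) else mean(m)
  thr <- (p_core + 0.25) / 2
  center <- which.min(abs(a_off - (e_lo + hit_len / 2)))
  ok <- roll >= thr
  if (!ok[center]) return(NULL)
  lo_b <- center
  while (lo_b > 1 && ok[lo_b - 1]) lo_b <- lo_b - 1
  hi_b <- center
  while (hi_b < n && ok[hi_b + 1]) hi_b <- hi_b + 1
  cols <- lo_b:hi_b
  b_off <- cumsum(bv != "-")
  list(
    left = c(l2[1] + a_off[lo_b] - as.integer(av[lo_b] != "-"),
             l2[1] + a_off[hi_b]),
    right = c(r2[1] + b_off[lo_b] - as.integer(bv[lo_b] != "-"),
              r2[1] + b_off[hi_b]),
    a_aln = paste(av[cols], collapse = ""),
    b_aln = paste(bv[cols], collapse = ""),
    identity = mean(m[cols]),
    n_cols = length(cols))
}

# count transitions/transversions over ungapped, N-free aligned columns,
# discarding end_trim columns at each alignment end
count_substitutions <- function(a_aln, b_aln, end_trim = 0) {
  a <- strsplit(a_aln, "")[[1]]
  b <- strsplit(b_aln, "")[[1]]
  if (end_trim > 0 && length(a) > 2 * end_trim + 20) {
    idx <- (end_trim + 1):(length(a) - end_trim)
    a <- a[idx]; b <- b[idx]
  }
  ok <- a %in% DNA_BASES & b %in% DNA_BASES
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n == 0) return(list(P = NA_real_, Q = NA_real_, n = 0L))
  pur <- c("A", "G")
  same <- a == b
  ts <- !same & ((a %in% pur) == (b %in% pur))
  tv <- !same & !ts
  list(P = sum(ts) / n, Q = sum(tv) / n, n = n)
}

#' Detect paired flanking LTRs and date the insertions
#'
#' Within each candidate interval the two ends are searched for the
#' highest-scoring pair of similar direct repeats satisfying the length,
#' spacing and similarity bounds of `cfg`. Substitution proportions P and Q
#' are counted over interior ungapped aligned columns (gap and N columns
#' excluded; `end_trim` columns dropped at each end), giving the K2P
#' distance and the age `T = d / 2r`. Candidates without a qualifying pair
#' are reported unpaired and excluded from dating.
#'
#' @param genome A [genome_assembly()].
#' @param candidates Tibble with `chrom`, `start`, `end` and optionally
#'   `element_id` columns (0-based half-open element footprints).
#' @param cfg A [dating_config()].
#' @return Tibble with one row per candidate: LTR coordinates, aligned
#'   length, identity, `P`, `Q`, `d`, `T_years`, and `paired`.
#' @export
detect_ltr_pairs <- function(genome, candidates, cfg = dating_config()) {
  stopifnot(inherits(cfg, "dating_config"))
  if (nrow(candidates) == 0) {
    return(tibble(element_id = character(), chrom = character(),
                  start = double(), end = double(),
                  left_start = double(), left_end = double(),
                  right_start = double(), right_end = double(),
                  aligned_cols = integer(), identity = double(),
                  P = double(), Q = double(), d = double(),
                  T_years = double(), paired = logical()))
  }
  ids <- if ("element_id" %in% names(candidates)) {
    candidates$element_id
  } else {
    sprintf("cand%03d", seq_len(nrow(candidates)))
  }
  purrr::map_dfr(seq_len(nrow(candidates)), function(i) {
    chrom <- candidates$chrom[i]
    cs <- candidates$start[i]; ce <- candidates$end[i]
    base <- tibble(element_id = ids[i], chrom = chrom,
                   start = cs, end = ce,
                   left_start = NA_real_, left_end = NA_real_,
                   right_start = NA_real_, right_end = NA_real_,
                   aligned_cols = NA_integer_, identity = NA_real_,
                   P = NA_real_, Q = NA_real_, d = NA_real_,
                   T_years = NA_real_, paired = FALSE)
    L <- ce - cs
    wlen <- min(L, cfg$max_ltr + cfg$flank_slack)
    if (L < cfg$min_element || wlen < cfg$min_ltr) return(base)
    seq <- extract_interval(genome, chrom, cs, ce)
    left <- substr(seq, 1, wlen)
    right <- substr(seq, L - wlen + 1, L)
    roff <- L - wlen  # offset of the right window within the element
    hits <- cpp_seed_extend(left, right, k = cfg$seed_k,
                            xdrop = cfg$x_drop, band = cfg$band,
                            min_score = cfg$min_score)
    if (nrow(hits) == 0) return(base)
    hits <- hits[order(-hits$score), , drop = FALSE]
    for (h in seq_len(nrow(hits))) {
      llen <- hits$qend[h] - hits$qstart[h]
      rlen <- hits$tend[h] - hits$tstart[h]
      span <- (roff + hits$tend[h]) - hits$qstart[h]
      ident <- hits$matches[h] /
        (hits$matches[h] + hits$mismatches[h] + hits$gap_columns[h])
      ok <- llen >= cfg$min_ltr && llen <= cfg$max_ltr &&
        rlen >= cfg$min_ltr && rlen <= cfg$max_ltr &&
        span >= cfg$min_element && span <= cfg$max_element &&
        ident >= cfg$ltr_similarity_floor &&
        hits$qstart[h] < roff + hits$tstart[h]  # left precedes right
      if (!ok) next
      lab <- c(hits$qstart[h], hits$qend[h])
      rab <- c(roff + hits$tstart[h], roff + hits$tend[h])
      ref <- refine_ltr_boundaries(seq, lab, rab, cfg)
      if (is.null(ref)) next
      sub <- count_substitutions(ref$a_aln, ref$b_aln, cfg$end_trim)
      d <- if (sub$n > 0) k2p_or_na(sub$P, sub$Q) else NA_real_
      base$left_start <- cs + ref$left[1]
      base$left_end <- cs + ref$left[2]
      base$right_start <- cs + ref$right[1]
      base$right_end <- cs + ref$right[2]
      base$aligned_cols <- ref$n_cols
      base$identity <- ref$identity
      base$P <- sub$P; base$Q <- sub$Q; base$d <- d
      base$T_years <- if (is.na(d)) NA_real_ else insertion_time(d, cfg$r)
      base$paired <- TRUE
      break
    }
    base
  })
}

#' Cluster LTR sequences into families
#'
#' Single-linkage clustering where two LTRs link iff their local alignment
#' passes the 80-80 rule in both directions: identity at or above
#' `min_identity` and at least `min_coverage` of *each* sequence aligned.
#' The returned partition is invariant to input order.
#'
#' @param ltr_seqs Character vector of LTR sequences (names kept as ids).
#' @param min_identity,min_coverage 80-80 thresholds.
#' @return Tibble `member`, `family` (1-based family index in order of
#'   first appearance), `representative`.
#' @export
cluster_families <- function(ltr_seqs, min_identity = 0.80,
                             min_coverage = 0.80) {
  n <- length(ltr_seqs)
  stopifnot(n >= 1)
  ids <- names(ltr_seqs) %||% sprintf("ltr%03d", seq_len(n))
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  if (n > 1) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        al <- cpp_align(ltr_seqs[[i]], ltr_seqs[[j]], local = TRUE)
        cols <- al$matches + al$mismatches + al$gap_columns
        if (cols == 0) next
        ident <- al$matches / cols
        cov_i <- (al$a_end - al$a_start) / nchar(ltr_seqs[[i]])
        cov_j <- (al$b_end - al$b_start) / nchar(ltr_seqs[[j]])
        if (ident >= min_identity && cov_i >= min_coverage &&
            cov_j >= min_coverage) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  fam <- match(root, unique(root))
  tibble(member = ids, family = fam,
         representative = ids[match(fam, fam)])
}

#' Histogram of insertion ages
#'
#' Uniform bins of `bin_width` years from zero; undated elements (no
#' qualifying pair or saturated distance) are excluded from the bins and
#' counted in the `n_undated` attribute.
#'
#' @param pairs Tibble from [detect_ltr_pairs()] (or any tibble with a
#'   `T_years` column).
#' @param bin_width Bin width in years (default 5 million).
#' @return Tibble of class `activity_histogram` with `bin_start`,
#'   `bin_mid`, `bin_end` (years) and `count`.
#' @export
activity_histogram <- function(pairs, bin_width = 5e6) {
  t_ok <- pairs$T_years[!is.na(pairs$T_years)]
  n_undated <- nrow(pairs) - length(t_ok)
  n_bins <- if (length(t_ok) == 0) 1L else max(1L, ceiling((max(t_ok) + 1) / bin_width))
  starts <- (seq_len(n_bins) - 1) * bin_width
  counts <- vapply(starts, function(s) {
    sum(t_ok >= s & t_ok < s + bin_width)
  }, integer(1))
  structure(tibble(bin_start = starts, bin_mid = starts + bin_width / 2,
                   bin_end = starts + bin_width, count = counts),
            class = c("activity_histogram", class(tibble())),
            n_undated = n_undated)
}

#' @rdname activity_histogram
#' @param object An `activity_histogram`.
#' @param ... Unused.
#' @export
autoplot.activity_histogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_mid / 1e6,
                                       y = .data$count)) +
    ggplot2::geom_col(width = (object$bin_end[1] - object$bin_start[1]) /
                        1e6 * 0.9) +
    ggplot2::labs(x = "insertion age (million years)", y = "elements",
                  title = "LTR element activity dates") +
    ggplot2::theme_minimal()
}
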