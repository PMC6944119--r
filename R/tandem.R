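# Tandem-repeat array detection, unit-consensus training and the self
# similarity dot plot. Periods are found by lag-match autocorrelation
# (the fraction of positions agreeing with themselves shifted by p, in
# windows of one period), then refined by aligning unit frames against a
# trained consensus.

# rolling-window mean of a 0/1 vector, window w, at every start position
roll_mean <- function(x, w) {
  cs <- cumsum(c(0, x))
  n <- length(x) - w + 1
  if (n < 1) return(numeric(0))
  (cs[(w + 1):(w + n)] - cs[1:n]) / w
}

# candidate tandem regions at one lag: runs of windows at or above the floor
lag_candidates <- function(seq, p, floor) {
  m <- cpp_lag_matches(seq, p)
  if (length(m) < p) return(NULL)
  roll <- roll_mean(m, p)
  high <- roll >= floor
  if (!any(high)) return(NULL)
  r <- rle(high)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  tibble(
    start = starts[keep] - 1,            # 0-based
    end = ends[keep] - 1 + 2 * p,        # exclusive; spans both frames
    period = p,
    signal = vapply(keep, function(i) {
      mean(roll[starts[i]:ends[i]])
    }, numeric(1))
  )
}

unit_frames <- function(seq, start, end, p) {
  n_full <- (end - start) %/% p
  if (n_full < 1) return(character(0))
  vapply(seq_len(n_full), function(i) {
    substr(seq, start + (i - 1) * p + 1, start + i * p)
  }, character(1))
}

# column-majority consensus of same-length frames aligned to a reference
vote_consensus <- function(frames, consensus, band = 10) {
  p <- nchar(consensus)
  votes <- matrix(0L, nrow = 4, ncol = p,
                  dimnames = list(DNA_BASES, NULL))
  idents <- numeric(length(frames))
  for (fi in seq_along(frames)) {
    al <- cpp_align(frames[fi], consensus, local = FALSE, band = band)
    a <- strsplit(al$a_aln, "")[[1]]
    b <- strsplit(al$b_aln, "")[[1]]
    cpos <- cumsum(b != "-")   # consensus column of each alignment column
    keep <- b != "-" & a %in% DNA_BASES
    for (j in which(keep)) {
      votes[a[j], cpos[j]] <- votes[a[j], cpos[j]] + 1L
    }
    idents[fi] <- al$matches / (al$matches + al$mismatches + al$gap_columns)
  }
  cons <- paste(DNA_BASES[apply(votes, 2, which.max)], collapse = "")
  list(consensus = cons, identities = idents)
}

#' Train the unit consensus of a tandem array
#'
#' Partitions the array into unit-length frames, takes a positional
#' column-majority consensus, re-aligns every frame to it and votes again
#' (one refinement round if the consensus changed). The consensus always
#' has exactly `unit_length` bases.
#'
#' @param seq The array sequence (a DNA string).
#' @param unit_length Unit length in bases.
#' @return The consensus string, with attribute `mean_unit_identity`.
#' @export
#' @examples
#' train_unit_consensus(strrep("ACGTTACGGA", 5), 10)
train_unit_consensus <- function(seq, unit_length) {
  frames <- unit_frames(seq, 0, nchar(seq), unit_length)
  stopifnot(length(frames) >= 1)
  cons <- frames[[1]]
  res <- vote_consensus(frames, cons)
  if (res$consensus != cons) {
    res <- vote_consensus(frames, res$consensus)
  }
  structure(res$consensus, mean_unit_identity = mean(res$identities))
}

#' Detect tandem-repeat arrays in a sequence
#'
#' Candidate periods come from lag-match autocorrelation in sliding
#' windows of one period; overlapping candidates are clustered and, when a
#' period and its multiple both explain a locus, the smaller period wins
#' if its signal is within 2 points of the larger (canonical minimal
#' period). Each surviving array is refined by training a unit consensus
#' and re-measuring mean per-unit identity; arrays below `min_copies`
#' units or the identity floor are dropped. Returned arrays are mutually
#' non-overlapping.
#'
#' @param seq DNA string.
#' @param min_unit Minimum unit length (>= 10, to guard against
#'   microsatellite noise).
#' @param max_unit Maximum unit length.
#' @param min_copies Minimum copies per array.
#' @param min_unit_identity Identity floor for both window signal and
#'   refined per-unit identity.
#' @param min_score Minimum array alignment score, counting lag matches +2
#'   and lag mismatches -7; filters the short chance self-matches that any
#'   random sequence contains.
#' @return Tibble with `start`, `end` (0-based half-open), `unit_length`,
#'   `copy_number` (real), `unit_count` (floor), `unit_consensus`,
#'   `mean_unit_identity`.
#' @export
detect_arrays <- function(seq, min_unit = 10, max_unit = 250,
                          min_copies = 2, min_unit_identity = 0.75,
                          min_score = 50) {
  stopifnot(min_unit >= 10, max_unit >= min_unit)
  n <- nchar(seq)
  if (n < 2 * min_unit) return(empty_arrays())
  cands <- dplyr::bind_rows(purrr::map(
    min_unit:min(max_unit, n %/% 2),
    function(p) lag_candidates(seq, p, min_unit_identity)))
  if (is.null(cands) || nrow(cands) == 0) return(empty_arrays())

  # cluster overlapping candidates, choose the canonical period per cluster
  ir <- IRanges::IRanges(cands$start + 1L, cands$end)
  red <- IRanges::reduce(ir)
  cands$cluster <- S4Vectors::subjectHits(IRanges::findOverlaps(ir, red))
  chosen <- cands |>
    dplyr::group_by(.data$cluster) |>
    dplyr::group_modify(function(df, key) {
      top <- max(df$signal)
      elig <- df[df$signal >= top - 0.02, ]
      elig <- elig[elig$period == min(elig$period), ]
      elig[which.max(elig$end - elig$start), ]
    }) |>
    dplyr::ungroup()

  out <- purrr::pmap_dfr(
    chosen[c("start", "end", "period")],
    function(start, end, period) {
      refine_array(seq, start, end, period, min_copies, min_unit_identity,
                   min_score)
    })
  if (nrow(out) == 0) return(empty_arrays())
  dplyr::arrange(out, .data$start)
}

empty_arrays <- function() {
  tibble(start = integer(), end = integer(), unit_length = integer(),
         copy_number = double(), unit_count = integer(),
         unit_consensus = character(), mean_unit_identity = double())
}

# refine one candidate array: settle the period (+-1), train the
# consensus, and score the array's lag self-matches
refine_array <- function(seq, start, end, period, min_copies, floor,
                         min_score = 50) {
  # trim candidate bounds to the outermost run of >= 5 consecutive lag
  # matches at the candidate period (window detection overshoots slightly)
  m <- cpp_lag_matches(substr(seq, start + 1, end), period)
  if (length(m) > 0) {
    r <- rle(m == 1L)
    ends <- cumsum(r$lengths)
    runs <- which(r$values & r$lengths >= min(period, 5))
    if (length(runs) > 0) {
      first <- ends[runs[1]] - r$lengths[runs[1]] + 1
      last <- ends[runs[length(runs)]]
      new_end <- start + last + period
      start <- start + first - 1
      end <- min(end, new_end)
    }
  }
  best <- NULL
  for (p in (period - 1):(period + 1)) {
    if (p < 2 || end - start < 2 * p) next
    sub <- substr(seq, start + 1, end)
    frames <- unit_frames(sub, 0, nchar(sub), p)
    if (length(frames) < min_copies) next
    cons <- tryCatch(train_unit_consensus(sub, p), error = function(e) NULL)
    if (is.null(cons)) next
    ident <- attr(cons, "mean_unit_identity")
    if (is.null(best) || ident > best$ident) {
      best <- list(p = p, cons = as.character(cons), ident = ident)
    }
  }
  if (is.null(best) || best$ident < floor) return(empty_arrays())
  span <- end - start
  copy_number <- span / best$p
  if (copy_number < min_copies - 0.25) return(empty_arrays())
  lm <- cpp_lag_matches(substr(seq, start + 1, end), best$p)
  score <- 2 * sum(lm) - 7 * (length(lm) - sum(lm))
  if (score < min_score) return(empty_arrays())
  tibble(start = as.integer(start), end = as.integer(end),
         unit_length = as.integer(best$p),
         copy_number = copy_number,
         unit_count = as.integer(floor(copy_number + 1e-9)),
         unit_consensus = best$cons,
         mean_unit_identity = best$ident)
}

#' Self-similarity dot matrix
#'
#' Binary matrix of exact k-word matches between all position pairs of one
#' sequence; tandem arrays appear as off-diagonal stripes at lags equal to
#' multiples of the unit length. The matrix is symmetric with an all-true
#' main diagonal.
#'
#' @param seq DNA string with at least `k` bases.
#' @param k Word size.
#' @return A logical matrix of class `self_similarity`, one row/column per
#'   k-word start position.
#' @export
self_similarity_matrix <- function(seq, k = 8) {
  n <- nchar(seq)
  stopifnot(n >= k)
  v <- utf8ToInt(seq)
  code <- integer(128)
  code[utf8ToInt("A")] <- 0L; code[utf8ToInt("C")] <- 1L
  code[utf8ToInt("G")] <- 2L; code[utf8ToInt("T")] <- 3L
  valid <- v %in% utf8ToInt(paste(DNA_BASES, collapse = ""))
  cv <- code[v]
  m <- n - k + 1
  ids <- numeric(m)
  ok <- rep(TRUE, m)
  for (j in seq_len(k)) {
    ids <- ids * 4 + cv[j:(j + m - 1)]
    ok <- ok & valid[j:(j + m - 1)]
  }
  ids[!ok] <- -seq_len(sum(!ok))  # N-containing words match nothing
  mat <- outer(ids, ids, "==")
  structure(mat, class = c("self_similarity", class(mat)), k = k)
}

#' @rdname self_similarity_matrix
#' @param object A `self_similarity` matrix.
#' @param ... Unused.
#' @export
autoplot.self_similarity <- function(object, ...) {
  idx <- which(unclass(object), arr.ind = TRUE)
  df <- tibble(i = idx[, 1], j = idx[, 2])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j)) +
    ggplot2::geom_point(shape = ".", alpha = 0.6) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "position", y = "position",
                  title = "Self-similarity dot plot") +
    ggplot2::theme_minimal()
}
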