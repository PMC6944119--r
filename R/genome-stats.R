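# Chromosomal distribution statistics, window density tracks, synteny-block
# chaining and the per-chromosome presence report.

#' Chi-square test of length-proportional chromosomal distribution
#'
#' Tests whether insertion counts are proportional to chromosome size:
#' expected counts are `E_i = N * L_i / sum(L)`, the statistic is
#' `sum((O_i - E_i)^2 / E_i)` with `k - 1` degrees of freedom and an
#' upper-tail p-value. A warning flag is set when any expected count is
#' below 5 (chi-square approximation caveat).
#'
#' @param counts Tibble (or data frame) with columns `chrom`, `observed`
#'   and `length`.
#' @return An object of class `uniformity_test`.
#' @export
#' @examples
#' chi_square_uniformity(tibble::tibble(
#'   chrom = c("c1", "c2"), observed = c(15, 15), length = c(1e6, 2e6)))
chi_square_uniformity <- function(counts) {
  stopifnot(all(c("chrom", "observed", "length") %in% names(counts)))
  O <- counts$observed
  L <- counts$length
  if (any(L <= 0)) stop("all chromosome lengths must be > 0", call. = FALSE)
  N <- sum(O)
  if (N == 0) stop("no observed insertions (N = 0)", call. = FALSE)
  E <- N * L / sum(L)
  chi2 <- sum((O - E)^2 / E)
  df <- length(O) - 1L
  structure(list(
    table = tibble(chrom = counts$chrom, observed = O, length = L,
                   expected = E),
    chi2 = chi2, df = df,
    p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
    n = N, low_expected = any(E < 5)),
    class = "uniformity_test")
}

#' @export
print.uniformity_test <- function(x, ...) {
  band <- p_value_band(x$p_value)
  cat(sprintf(
    "Chi-square test of length-proportional distribution\n  chi2 = %.4g (df = %d, %s; p = %.4g), N = %d insertions on %d chromosomes\n",
    x$chi2, x$df, band, x$p_value, x$n, x$df + 1L))
  if (x$low_expected) {
    cat("  note: some expected counts < 5; chi-square approximation is rough\n")
  }
  invisible(x)
}

# report-style band for a p-value, e.g. "P > 0.9"
p_value_band <- function(p) {
  cuts <- c(0.9, 0.5, 0.1, 0.05, 0.01)
  for (c in cuts) if (p > c) return(paste0("P > ", c))
  paste0("P <= 0.01")
}

#' @rdname chi_square_uniformity
#' @param x A `uniformity_test`.
#' @param ... Unused.
#' @export
tidy.uniformity_test <- function(x, ...) {
  x$table
}

#' @rdname chi_square_uniformity
#' @export
glance.uniformity_test <- function(x, ...) {
  tibble(statistic = x$chi2, df = x$df, p.value = x$p_value,
         n = x$n, p.band = p_value_band(x$p_value),
         low_expected = x$low_expected)
}

#' @rdname chi_square_uniformity
#' @param object A `uniformity_test`.
#' @export
autoplot.uniformity_test <- function(object, ...) {
  df <- tidyr::pivot_longer(object$table, c("observed", "expected"),
                            names_to = "which", values_to = "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$chrom, y = .data$count,
                                   fill = .data$which)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(observed = "white",
                                          expected = "grey60"),
                               name = NULL) +
    ggplot2::geom_col(position = "dodge", colour = "black", alpha = 0) +
    ggplot2::labs(x = NULL, y = "insertions",
                  title = "Observed vs length-proportional expectation") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Feature counts in tiling windows
#'
#' Non-overlapping windows of `window` bases tile each chromosome; a
#' feature is assigned to the window containing its start. Per-chromosome
#' densities per megabase are included.
#'
#' @param features Tibble with `chrom` and `start` columns.
#' @param assembly A [genome_assembly()] (or a tibble with `chrom`,
#'   `length`).
#' @param window Window size in bases (default 500 kb).
#' @return Tibble `chrom`, `win_start`, `win_end`, `count`,
#'   `density_per_mb` (chromosome-level density).
#' @export
window_density <- function(features, assembly, window = 5e5) {
  stopifnot(window > 0)
  chrom_tbl <- if (inherits(assembly, "genome_assembly")) {
    chromosomes(assembly)
  } else {
    assembly
  }
  purrr::pmap_dfr(chrom_tbl, function(chrom, length) {
    clen <- length  # column name shadows base::length
    n_win <- as.integer((clen - 1) %/% window) + 1L
    starts <- (seq_len(n_win) - 1) * window
    f <- features$start[features$chrom == chrom]
    idx <- pmin(f %/% window + 1, n_win)
    counts <- tabulate(idx, nbins = n_win)
    dens <- length(f) / (clen / 1e6)
    tibble(chrom = chrom, win_start = starts,
           win_end = pmin(starts + window, clen),
           count = counts, density_per_mb = dens)
  })
}

#' Write a window-density track as bedGraph
#'
#' @param density Tibble from [window_density()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(density, path) {
  lines <- sprintf("%s\t%d\t%d\t%d", density$chrom,
                   as.integer(density$win_start),
                   as.integer(density$win_end), density$count)
  writeLines(c("track type=bedGraph", lines), path)
  invisible(path)
}

#' Chain local alignments into synteny blocks
#'
#' Anchors are 80-80-passing local hits of tiled `seg_a` chunks against
#' `seg_b`; the longest collinear (order- and orientation-consistent)
#' subset is kept by weighted longest-increasing-subsequence chaining, and
#' consecutive anchors are grouped into blocks wherever the diagonal
#' offset jumps by more than `max_offset_jump` or the anchor gap exceeds
#' `max_anchor_gap` (such breaks mark insertions/deletions, e.g. the loss
#' of an element on one segment).
#'
#' @param seg_a,seg_b DNA strings of the two homologous segments.
#' @param anchor_size Chunk size for anchor seeding.
#' @param params A [search_params()].
#' @param min_identity,min_coverage 80-80 anchor thresholds.
#' @param max_offset_jump Diagonal-offset change that splits blocks.
#' @param max_anchor_gap Anchor-to-anchor gap that splits blocks.
#' @return List with `blocks` (tibble `a_start`, `a_end`, `b_start`,
#'   `b_end`, `orientation`, `n_anchors`) and `gaps` (tibble of
#'   inter-block gaps on both segments).
#' @export
find_synteny_blocks <- function(seg_a, seg_b, anchor_size = 500,
                                params = search_params(),
                                min_identity = 0.80, min_coverage = 0.80,
                                max_offset_jump = 1000,
                                max_anchor_gap = 5000) {
  stopifnot(nzchar(seg_a), nzchar(seg_b))
  na <- nchar(seg_a)
  starts <- seq(0, max(0, na - anchor_size), by = anchor_size)
  tgt <- genome_assembly(c(b = toupper(seg_b)), name = "seg_b")
  anchors <- purrr::map_dfr(starts, function(s) {
    chunk <- substr(seg_a, s + 1, min(na, s + anchor_size))
    if (nchar(chunk) < params$k) return(NULL)
    h <- search_genome(tgt, chunk, params)
    h <- h[passes_80_80(h, min_identity, min_coverage), ]
    if (nrow(h) == 0) return(NULL)
    h <- h[which.max(h$score), ]
    tibble(a_start = s + h$qstart, a_end = s + h$qend,
           b_start = h$tstart, b_end = h$tend,
           strand = h$strand, score = h$score)
  })
  if (nrow(anchors) == 0) {
    return(list(blocks = tibble(a_start = double(), a_end = double(),
                                b_start = double(), b_end = double(),
                                orientation = character(),
                                n_anchors = integer()),
                gaps = tibble(a_gap_start = double(), a_gap_end = double(),
                              b_gap_start = double(), b_gap_end = double())))
  }
  anchors <- dplyr::arrange(anchors, .data$a_start)

  # weighted LIS on b-coordinate (per orientation), weight = anchor score
  chain_strand <- function(df, plus) {
    if (nrow(df) == 0) return(df)
    key <- if (plus) df$b_start else -df$b_start
    n <- nrow(df)
    best <- df$score; prev <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
      for (j in seq_len(i - 1)) {
        if (key[j] < key[i] && best[j] + df$score[i] > best[i]) {
          best[i] <- best[j] + df$score[i]
          prev[i] <- j
        }
      }
    }
    end <- which.max(best)
    path <- integer(0)
    while (!is.na(end)) {
      path <- c(end, path)
      end <- prev[end]
    }
    df[path, ]
  }
  ch_p <- chain_strand(anchors[anchors$strand == "+", ], TRUE)
  ch_m <- chain_strand(anchors[anchors$strand == "-", ], FALSE)
  chained <- if (sum(ch_p$score) >= sum(ch_m$score)) ch_p else ch_m
  orientation <- chained$strand[1]

  off <- chained$b_start - chained$a_start
  brk <- which(abs(diff(off)) > max_offset_jump |
                 diff(chained$a_start) > max_anchor_gap)
  grp <- cumsum(c(1, seq_len(nrow(chained) - 1) %in% brk))
  blocks <- chained |>
    dplyr::mutate(block = grp) |>
    dplyr::group_by(.data$block) |>
    dplyr::summarise(a_start = min(.data$a_start), a_end = max(.data$a_end),
                     b_start = min(.data$b_start), b_end = max(.data$b_end),
                     n_anchors = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(orientation = orientation) |>
    dplyr::select(-"block")
  gaps <- if (nrow(blocks) > 1) {
    tibble(a_gap_start = blocks$a_end[-nrow(blocks)],
           a_gap_end = blocks$a_start[-1],
           b_gap_start = blocks$b_end[-nrow(blocks)],
           b_gap_end = blocks$b_start[-1])
  } else {
    tibble(a_gap_start = double(), a_gap_end = double(),
           b_gap_start = double(), b_gap_end = double())
  }
  list(blocks = blocks, gaps = gaps)
}

#' Per-chromosome motif presence report
#'
#' Calls motifs on every chromosome and reports counts, presence flags and
#' a summary string listing motif-bearing chromosomes (the
#' subgenome-diagnostic pattern: presence on every D-subgenome chromosome,
#' absence from the A subgenome). Chromosomes carrying lone constituents
#' but no paired motif are flagged separately, since such isolated calls on
#' an otherwise motif-free subgenome suggest misplacement of a segment in
#' the assembly.
#'
#' @param assembly A [genome_assembly()] (e.g. a tetraploid with `A_`/`D_`
#'   chromosome prefixes).
#' @param def A [motif_definition()].
#' @param params A [search_params()].
#' @param calls Optional precomputed calls from [call_motifs()] for this
#'   assembly (avoids re-scanning).
#' @return Tibble of class `presence_report`: `chrom`, `n_motifs`,
#'   `n_lone_tr`, `n_lone_cs`, `present`, `lone_only`; attribute `summary`
#'   holds the presence summary string.
#' @export
subgenome_presence_report <- function(assembly, def,
                                      params = search_params(),
                                      calls = NULL) {
  chroms <- chromosomes(assembly)
  if (nrow(chroms) == 0) {
    return(structure(tibble(chrom = character(), n_motifs = integer(),
                            n_lone_tr = integer(), n_lone_cs = integer(),
                            present = logical(), lone_only = logical()),
                     summary = "no chromosomes",
                     class = c("presence_report", class(tibble()))))
  }
  if (is.null(calls)) calls <- call_motifs(assembly, def, params)
  cnt <- function(kind) {
    vapply(chroms$chrom, function(cc) {
      sum(calls$kind == kind & calls$chrom == cc)
    }, integer(1))
  }
  out <- tibble(chrom = chroms$chrom,
                n_motifs = cnt("motif"),
                n_lone_tr = cnt("lone_TR"),
                n_lone_cs = cnt("lone_CS"))
  out$present <- out$n_motifs > 0
  out$lone_only <- !out$present & (out$n_lone_tr + out$n_lone_cs > 0)
  with_motif <- out$chrom[out$present]
  without <- out$chrom[!out$present]
  summary <- paste0(
    if (length(with_motif)) paste0("motifs on ", collapse_range(with_motif))
    else "no motif-bearing chromosomes",
    if (length(without)) paste0("; none on ", collapse_range(without))
    else "")
  structure(out, summary = summary,
            class = c("presence_report", class(tibble())))
}

# "D_chr01-D_chr13" style collapsing of consecutive chromosome labels
collapse_range <- function(ids) {
  if (length(ids) <= 2) return(paste(ids, collapse = ", "))
  num <- suppressWarnings(as.integer(sub(".*?(\\d+)$", "\\1", ids)))
  pre <- sub("\\d+$", "", ids)
  if (anyNA(num) || length(unique(pre)) != 1 ||
      !all(diff(num) == 1)) {
    return(paste(ids, collapse = ", "))
  }
  paste0(ids[1], "-", ids[length(ids)])
}
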