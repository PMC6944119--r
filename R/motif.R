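# Composite-motif calling: scan a genome for the two constituents (tandem
# array of the unit consensus, and the conserved sequence), pair them into
# full motif instances, and profile conservation across host elements by
# consensus accumulation.

#' Define a composite motif
#'
#' A composite motif is a tandem array of `unit_consensus` copies adjacent
#' to one `cs_consensus` occurrence on the same strand, separated by at
#' most `max_gap` bases.
#'
#' @param unit_consensus Tandem unit consensus (~133 bases in the motivating
#'   system).
#' @param cs_consensus Conserved-sequence consensus (~860 bases).
#' @param max_gap Maximum gap between constituents in bases.
#' @param min_units Minimum tandem copies for a TR hit.
#' @param min_identity,min_coverage 80-80-rule thresholds applied to
#'   constituent hits.
#' @return A list of class `motif_definition`.
#' @export
motif_definition <- function(unit_consensus, cs_consensus,
                             max_gap = 200, min_units = 2,
                             min_identity = 0.80, min_coverage = 0.80) {
  stopifnot(nzchar(unit_consensus), nzchar(cs_consensus),
            max_gap >= 0, min_units >= 2)
  structure(list(unit_consensus = toupper(unit_consensus),
                 cs_consensus = toupper(cs_consensus),
                 max_gap = max_gap, min_units = min_units,
                 min_identity = min_identity, min_coverage = min_coverage),
            class = "motif_definition")
}

#' Scan a genome for motif constituents
#'
#' TR hits are tandem arrays of unit-consensus matches: individual unit
#' hits passing the 80-80 thresholds are merged (same chromosome and
#' strand, gap at most half a unit) into arrays with a real-valued copy
#' number; arrays below `min_units` copies are dropped. CS hits are
#' 80-80-passing hits of the conserved-sequence consensus, merged per
#' locus. Both strands are searched.
#'
#' @param genome A [genome_assembly()].
#' @param def A [motif_definition()].
#' @param params A [search_params()].
#' @return List with tibbles `tr` (chrom, start, end, strand, n_units,
#'   copy_number, unit_count, identity) and `cs` (chrom, start, end,
#'   strand, identity, query_coverage).
#' @export
scan_constituents <- function(genome, def, params = search_params()) {
  stopifnot(inherits(def, "motif_definition"))
  ulen <- nchar(def$unit_consensus)

  uh <- search_genome(genome, def$unit_consensus, params)
  uh <- uh[passes_80_80(uh, def$min_identity, def$min_coverage), ]
  tr <- merge_hit_loci(uh, max_merge_gap = ulen %/% 2)
  if (nrow(tr) > 0) {
    tr$copy_number <- (tr$tend - tr$tstart) / ulen
    tr$unit_count <- as.integer(floor(tr$copy_number + 1e-9))
    tr <- tr[tr$copy_number >= def$min_units - 0.25, ]
    tr <- tibble(chrom = tr$chrom, start = tr$tstart, end = tr$tend,
                 strand = tr$strand, n_units = tr$n_hits,
                 copy_number = tr$copy_number, unit_count = tr$unit_count,
                 identity = tr$identity)
  } else {
    tr <- tibble(chrom = character(), start = integer(), end = integer(),
                 strand = character(), n_units = integer(),
                 copy_number = double(), unit_count = integer(),
                 identity = double())
  }

  ch <- search_genome(genome, def$cs_consensus, params)
  ch <- ch[passes_80_80(ch, def$min_identity, def$min_coverage), ]
  cs <- merge_hit_loci(ch)
  if (nrow(cs) > 0) {
    cs <- tibble(chrom = cs$chrom, start = cs$tstart, end = cs$tend,
                 strand = cs$strand, identity = cs$identity,
                 query_coverage = cs$query_coverage)
  } else {
    cs <- tibble(chrom = character(), start = integer(), end = integer(),
                 strand = character(), identity = double(),
                 query_coverage = double())
  }
  list(tr = dplyr::arrange(tr, .data$chrom, .data$start),
       cs = dplyr::arrange(cs, .data$chrom, .data$start))
}

interval_gap <- function(s1, e1, s2, e2) {
  pmax(pmax(s2 - e1, s1 - e2), 0)
}

#' Pair TR and CS hits into motif instances
#'
#' Greedy nearest-neighbour pairing of same-chromosome, same-strand
#' constituent hits with an inter-constituent gap of at most `max_gap`
#' bases; the smallest gap is paired first (leftmost wins ties) and every
#' hit is used at most once. Unpaired hits are labelled lone.
#'
#' @param constituents Result of [scan_constituents()].
#' @param max_gap Maximum gap in bases.
#' @return A tibble with one row per call, `kind` in
#'   `"motif"`, `"lone_TR"`, `"lone_CS"`; motif rows carry both
#'   sub-intervals and a `full_interval` span (`start`, `end`).
#' @export
pair_constituents <- function(constituents, max_gap = 200) {
  tr <- constituents$tr
  cs <- constituents$cs
  pairs <- NULL
  if (nrow(tr) > 0 && nrow(cs) > 0) {
    cand <- tidyr::crossing(ti = seq_len(nrow(tr)), ci = seq_len(nrow(cs)))
    cand <- cand[tr$chrom[cand$ti] == cs$chrom[cand$ci] &
                   tr$strand[cand$ti] == cs$strand[cand$ci], ]
    if (nrow(cand) > 0) {
      cand$gap <- interval_gap(tr$start[cand$ti], tr$end[cand$ti],
                               cs$start[cand$ci], cs$end[cand$ci])
      cand <- cand[cand$gap <= max_gap, ]
      cand <- cand[order(cand$gap,
                         pmin(tr$start[cand$ti], cs$start[cand$ci])), ]
      used_t <- used_c <- logical(0)
      keep <- logical(nrow(cand))
      taken_t <- rep(FALSE, nrow(tr)); taken_c <- rep(FALSE, nrow(cs))
      for (i in seq_len(nrow(cand))) {
        if (!taken_t[cand$ti[i]] && !taken_c[cand$ci[i]]) {
          keep[i] <- TRUE
          taken_t[cand$ti[i]] <- TRUE
          taken_c[cand$ci[i]] <- TRUE
        }
      }
      pairs <- cand[keep, ]
    }
  }
  rows <- list()
  if (!is.null(pairs) && nrow(pairs) > 0) {
    rows$motif <- tibble(
      kind = "motif",
      chrom = tr$chrom[pairs$ti], strand = tr$strand[pairs$ti],
      start = pmin(tr$start[pairs$ti], cs$start[pairs$ci]),
      end = pmax(tr$end[pairs$ti], cs$end[pairs$ci]),
      tr_start = tr$start[pairs$ti], tr_end = tr$end[pairs$ti],
      cs_start = cs$start[pairs$ci], cs_end = cs$end[pairs$ci],
      gap = pairs$gap,
      unit_count = tr$unit_count[pairs$ti],
      copy_number = tr$copy_number[pairs$ti])
    taken_t <- seq_len(nrow(tr)) %in% pairs$ti
    taken_c <- seq_len(nrow(cs)) %in% pairs$ci
  } else {
    taken_t <- rep(FALSE, nrow(tr))
    taken_c <- rep(FALSE, nrow(cs))
  }
  if (any(!taken_t)) {
    lt <- tr[!taken_t, ]
    rows$lone_tr <- tibble(
      kind = "lone_TR", chrom = lt$chrom, strand = lt$strand,
      start = lt$start, end = lt$end,
      tr_start = lt$start, tr_end = lt$end,
      cs_start = NA_real_, cs_end = NA_real_, gap = NA_real_,
      unit_count = lt$unit_count, copy_number = lt$copy_number)
  }
  if (any(!taken_c)) {
    lc <- cs[!taken_c, ]
    rows$lone_cs <- tibble(
      kind = "lone_CS", chrom = lc$chrom, strand = lc$strand,
      start = lc$start, end = lc$end,
      tr_start = NA_real_, tr_end = NA_real_,
      cs_start = lc$start, cs_end = lc$end, gap = NA_real_,
      unit_count = NA_integer_, copy_number = NA_real_)
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(kind = character(), chrom = character(),
                  strand = character(), start = double(), end = double(),
                  tr_start = double(), tr_end = double(),
                  cs_start = double(), cs_end = double(), gap = double(),
                  unit_count = integer(), copy_number = double())
  }
  dplyr::arrange(out, .data$chrom, .data$start)
}

#' Call composite motifs on a genome
#'
#' Convenience wrapper: [scan_constituents()] then [pair_constituents()].
#'
#' @inheritParams scan_constituents
#' @return A tibble of calls (see [pair_constituents()]).
#' @export
call_motifs <- function(genome, def, params = search_params()) {
  pair_constituents(scan_constituents(genome, def, params), def$max_gap)
}

#' Consensus-accumulation histogram
#'
#' Star alignment: every instance is pairwise (globally) aligned to the
#' reference; for each reference column, the count of instances agreeing
#' with the column-majority base is returned. Conserved cores show as a
#' high plateau against divergent flanks.
#'
#' @param instances Character vector of instance sequences (>= 1).
#' @param reference Reference sequence of the element.
#' @param band Alignment band half-width (alignments are near-diagonal for
#'   collinear elements).
#' @return A tibble of class `consensus_histogram` with `position`
#'   (0-based reference column) and `agreement`; attribute `n_instances`.
#' @export
consensus_accumulation <- function(instances, reference, band = 60) {
  stopifnot(length(instances) >= 1, nzchar(reference))
  rlen <- nchar(reference)
  chars <- matrix("-", nrow = length(instances), ncol = rlen)
  for (i in seq_along(instances)) {
    al <- cpp_align(instances[[i]], reference, local = FALSE, band = band)
    a <- strsplit(al$a_aln, "")[[1]]
    b <- strsplit(al$b_aln, "")[[1]]
    rpos <- cumsum(b != "-")
    keep <- b != "-" & a != "-"
    chars[i, rpos[keep]] <- a[keep]
  }
  agreement <- integer(rlen)
  for (j in seq_len(rlen)) {
    col <- chars[, j]
    col <- col[col %in% DNA_BASES]
    if (length(col) == 0) next
    agreement[j] <- max(tabulate(factor(col, levels = DNA_BASES)))
  }
  structure(tibble(position = seq_len(rlen) - 1L, agreement = agreement),
            class = c("consensus_histogram", class(tibble())),
            n_instances = length(instances))
}

#' Locate high-agreement plateaus in a consensus histogram
#'
#' The per-column agreement is first smoothed with a centered rolling mean
#' of `smooth` columns (single-column agreement is binomially noisy; a
#' conserved core and a divergent flank separate by many standard errors
#' once averaged over tens of columns). Smoothed columns at or above
#' `threshold_frac` of the instance count are selected; runs separated by
#' gaps of at most `merge_gap` columns are merged and blocks narrower than
#' `min_width` dropped.
#'
#' @param hist A [consensus_accumulation()] result.
#' @param threshold_frac Fraction of instances a column must reach.
#' @param smooth Rolling-mean window in columns.
#' @param merge_gap Maximum dip width bridged inside one plateau.
#' @param min_width Minimum plateau width in columns; conserved
#'   constituents are hundreds of bases, chance agreement clusters tens.
#' @return Tibble of plateau `start`, `end` (0-based half-open).
#' @export
plateau_region <- function(hist, threshold_frac = 0.9, smooth = 50,
                           merge_gap = 30, min_width = 100) {
  n <- attr(hist, "n_instances")
  x <- hist$agreement
  if (smooth > 1 && length(x) > smooth) {
    half <- smooth %/% 2
    cs <- cumsum(c(0, x))
    lo <- pmax(seq_along(x) - half, 1)
    hi <- pmin(seq_along(x) + half, length(x))
    x <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  sel <- which(x >= threshold_frac * n)
  if (length(sel) == 0) {
    return(tibble(start = integer(), end = integer()))
  }
  brk <- which(diff(sel) > merge_gap)
  starts <- sel[c(1, brk + 1)]
  ends <- sel[c(brk, length(sel))]
  out <- tibble(start = hist$position[starts],
                end = hist$position[ends] + 1L)
  out[out$end - out$start >= min_width, ]
}

#' @rdname consensus_accumulation
#' @param object A `consensus_histogram`.
#' @param ... Unused.
#' @export
autoplot.consensus_histogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position,
                                       y = .data$agreement)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = "reference position",
                  y = "instances agreeing with consensus",
                  title = "Consensus accumulation") +
    ggplot2::theme_minimal()
}

#' Write motif calls as GFF3
#'
#' Feature types are `composite_motif`, `motif_TR` and `motif_CS`; full
#' motifs emit one `composite_motif` row spanning both constituents plus
#' one row per constituent.
#'
#' @param calls Tibble from [pair_constituents()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motif_gff3 <- function(calls, path) {
  rows <- list()
  mot <- calls[calls$kind == "motif", ]
  if (nrow(mot) > 0) {
    rows$full <- tibble(chrom = mot$chrom, start = mot$start, end = mot$end,
                        name = sprintf("motif%03d", seq_len(nrow(mot))),
                        strand = mot$strand, type = "composite_motif")
    rows$tr <- tibble(chrom = mot$chrom, start = mot$tr_start,
                      end = mot$tr_end,
                      name = sprintf("motif%03d_TR", seq_len(nrow(mot))),
                      strand = mot$strand, type = "motif_TR")
    rows$cs <- tibble(chrom = mot$chrom, start = mot$cs_start,
                      end = mot$cs_end,
                      name = sprintf("motif%03d_CS", seq_len(nrow(mot))),
                      strand = mot$strand, type = "motif_CS")
  }
  lone <- calls[calls$kind != "motif", ]
  if (nrow(lone) > 0) {
    rows$lone <- tibble(chrom = lone$chrom, start = lone$start,
                        end = lone$end,
                        name = sprintf("%s%03d", lone$kind,
                                       seq_len(nrow(lone))),
                        strand = lone$strand,
                        type = ifelse(lone$kind == "lone_TR",
                                      "motif_TR", "motif_CS"))
  }
  df <- dplyr::bind_rows(rows)
  write_features(df, path, format = "GFF3")
}

#' Unit-content histogram of motif calls
#'
#' Integer "unit content" (floor of the real copy number) per TR-bearing
#' call, the analog of reporting how many basic units each array carries.
#'
#' @param calls Tibble from [pair_constituents()].
#' @return Tibble `unit_count`, `n`.
#' @export
unit_content_histogram <- function(calls) {
  x <- calls$unit_count[!is.na(calls$unit_count)]
  dplyr::count(tibble(unit_count = x), .data$unit_count, name = "n")
}
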