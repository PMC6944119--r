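# Seed-and-extend local homology search and the 80-80 presence/absence
# screen. The search indexes query k-mers, streams each chromosome, and
# extends every seed on a not-yet-covered diagonal with banded, x-drop
# gapped dynamic programming (an affine Smith-Waterman restricted to the
# seed's diagonal band).

#' Search parameters
#'
#' Defaults are BLASTN-like at desk scale: match +1, mismatch -1, affine
#' gaps costing `gap_open + L * gap_ext` for a gap of length L, seed size
#' 12, x-drop 20. All knobs are exposed because published screens rarely
#' state them.
#'
#' @param k Seed (word) size.
#' @param match,mismatch Substitution scores.
#' @param gap_open,gap_ext Gap cost components (positive numbers).
#' @param x_drop Score drop at which extension rows stop.
#' @param band Half-width of the extension band around the seed diagonal.
#' @param min_score Minimum alignment score to report.
#' @return A list of class `search_params`.
#' @export
search_params <- function(k = 12, match = 1, mismatch = -1,
                          gap_open = 2, gap_ext = 1,
                          x_drop = 20, band = 32, min_score = 30) {
  stopifnot(k >= 2, k <= 31, match > 0, mismatch < 0,
            gap_open >= 0, gap_ext > 0, x_drop > 0, band >= 1)
  structure(as.list(environment()), class = "search_params")
}

empty_hits <- function() {
  tibble(chrom = character(), tstart = integer(), tend = integer(),
         qstart = integer(), qend = integer(), strand = character(),
         score = integer(), matches = integer(), mismatches = integer(),
         gap_columns = integer(), aligned_cols = integer(),
         identity = double(), query_coverage = double())
}

search_one_strand <- function(query, chrom_seq, chrom_id, strand, params) {
  qlen <- nchar(query)
  q <- if (strand == "-") revcomp(query) else query
  df <- cpp_seed_extend(q, chrom_seq,
                        k = params$k, match = params$match,
                        mismatch = params$mismatch,
                        gap_open = params$gap_open,
                        gap_ext = params$gap_ext,
                        xdrop = params$x_drop, band = params$band,
                        min_score = params$min_score)
  if (nrow(df) == 0) return(empty_hits())
  qstart <- df$qstart; qend <- df$qend
  if (strand == "-") {  # map back to original query coordinates
    tmp <- qstart
    qstart <- qlen - qend
    qend <- qlen - tmp
  }
  aligned <- df$matches + df$mismatches + df$gap_columns
  tibble(chrom = chrom_id, tstart = df$tstart, tend = df$tend,
         qstart = qstart, qend = qend, strand = strand,
         score = df$score, matches = df$matches,
         mismatches = df$mismatches, gap_columns = df$gap_columns,
         aligned_cols = aligned,
         identity = df$matches / aligned,
         query_coverage = (qend - qstart) / qlen)
}

#' Seed-and-extend local search of a query against a genome
#'
#' Both strands are searched; hits report the matched target and query
#' intervals (0-based half-open, query coordinates always on the original
#' query), alignment score and column counts, identity
#' (matches / aligned columns) and query coverage (aligned query fraction).
#' Hits are sorted by decreasing score.
#'
#' @param target A [genome_assembly()] or a single DNA string.
#' @param query DNA string, at least `k` bases.
#' @param params A [search_params()].
#' @return A tibble of hits.
#' @export
#' @examples
#' g <- genome_assembly(c(c1 = strrep("ACGT", 50)))
#' search_genome(g, strrep("ACGT", 10), search_params(k = 8, min_score = 10))
search_genome <- function(target, query, params = search_params()) {
  if (is.character(target)) {
    target <- genome_assembly(c(seq = toupper(target)), name = "target")
  }
  stopifnot(inherits(target, "genome_assembly"))
  if (nchar(query) < params$k) {
    stop("query length ", nchar(query), " is shorter than seed size k = ",
         params$k, call. = FALSE)
  }
  query <- toupper(query)
  hits <- list()
  for (cid in names(target$seqs)) {
    for (s in c("+", "-")) {
      hits[[paste(cid, s)]] <-
        search_one_strand(query, target$seqs[[cid]], cid, s, params)
    }
  }
  out <- dplyr::bind_rows(hits)
  dplyr::arrange(out, dplyr::desc(.data$score), .data$chrom, .data$tstart)
}

#' Apply the 80-80 rule to alignment hits
#'
#' A hit passes when identity and query coverage are both at least the
#' thresholds (inclusive, "greater than or equal to").
#'
#' @param hits A hit tibble from [search_genome()].
#' @param min_identity,min_coverage Inclusive thresholds (default 0.80).
#' @return Logical vector, one element per hit.
#' @export
passes_80_80 <- function(hits, min_identity = 0.80, min_coverage = 0.80) {
  hits$identity >= min_identity & hits$query_coverage >= min_coverage
}

# merge passing hits that overlap (or nearly so) on the target into loci;
# keeps per-locus extremes and the best hit's stats
merge_hit_loci <- function(hits, max_merge_gap = 0L) {
  if (nrow(hits) == 0) return(hits)
  hits |>
    dplyr::group_by(.data$chrom, .data$strand) |>
    dplyr::group_modify(function(df, key) {
      ir <- IRanges::IRanges(start = df$tstart + 1L, end = df$tend)
      red <- IRanges::reduce(ir, min.gapwidth = max_merge_gap + 1L)
      grp <- S4Vectors::subjectHits(IRanges::findOverlaps(ir, red))
      df$locus <- grp
      df |>
        dplyr::group_by(.data$locus) |>
        dplyr::summarise(
          tstart = min(.data$tstart), tend = max(.data$tend),
          n_hits = dplyr::n(), score = max(.data$score),
          identity = .data$identity[which.max(.data$score)],
          query_coverage = .data$query_coverage[which.max(.data$score)],
          .groups = "drop") |>
        dplyr::select(-"locus")
    }) |>
    dplyr::ungroup()
}

#' Classify queries as genome-specific, shared or absent
#'
#' A query is `specific` when it has at least one 80-80-passing hit in the
#' genome expected to carry it and none in the sister genome; `shared` when
#' it passes in both; `absent` when it passes in neither. Overlapping
#' passing hits are merged per target locus before counting.
#'
#' @param queries Named character vector of query sequences.
#' @param present_in,absent_from Two [genome_assembly()] objects.
#' @param params A [search_params()].
#' @param min_identity,min_coverage 80-80 thresholds.
#' @return A tibble with one row per query: locus counts in both genomes
#'   and the classification.
#' @export
screen_genome_specific <- function(queries, present_in, absent_from,
                                   params = search_params(),
                                   min_identity = 0.80,
                                   min_coverage = 0.80) {
  stopifnot(length(queries) > 0)
  if (is.null(names(queries))) {
    names(queries) <- sprintf("query%02d", seq_along(queries))
  }
  purrr::imap_dfr(queries, function(q, id) {
    hp <- search_genome(present_in, q, params)
    hp <- hp[passes_80_80(hp, min_identity, min_coverage), ]
    ha <- search_genome(absent_from, q, params)
    ha <- ha[passes_80_80(ha, min_identity, min_coverage), ]
    np <- nrow(merge_hit_loci(hp))
    na <- nrow(merge_hit_loci(ha))
    tibble(query = id,
           loci_present_genome = np, loci_absent_genome = na,
           class = dplyr::case_when(
             np >= 1 & na == 0 ~ "specific",
             np >= 1 & na >= 1 ~ "shared",
             TRUE ~ "absent"))
  })
}

#' Recount a hit's alignment statistics from sequence
#'
#' Re-aligns the reported query and target intervals with the same scoring
#' scheme and returns the recomputed counts; used to audit that reported
#' identity and coverage are internally consistent.
#'
#' @param hits Hit tibble.
#' @param target A [genome_assembly()].
#' @param query Query string.
#' @param params A [search_params()].
#' @return `hits` with `re_score`, `re_matches`, `re_aligned` columns.
#' @export
recount_hits <- function(hits, target, query, params = search_params()) {
  query <- toupper(query)
  res <- purrr::pmap_dfr(
    hits[c("chrom", "tstart", "tend", "qstart", "qend", "strand")],
    function(chrom, tstart, tend, qstart, qend, strand) {
      qseq <- substr(query, qstart + 1, qend)
      if (strand == "-") qseq <- revcomp(qseq)
      tseq <- substr(target$seqs[[chrom]], tstart + 1, tend)
      al <- cpp_align(qseq, tseq, params$match, params$mismatch,
                      params$gap_open, params$gap_ext, local = FALSE)
      tibble(re_score = al$score, re_matches = al$matches,
             re_aligned = al$matches + al$mismatches + al$gap_columns)
    })
  dplyr::bind_cols(hits, res)
}

#' Write hits as a BLAST-outfmt6-like TSV
#'
#' Coordinates are rendered 1-based inclusive, as in BLAST tabular output.
#'
#' @param hits Hit tibble.
#' @param path Output path.
#' @param query_id Query label for column 1.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path, query_id = "query") {
  out <- tibble(
    qseqid = query_id, sseqid = hits$chrom,
    pident = round(100 * hits$identity, 2),
    length = hits$aligned_cols, mismatch = hits$mismatches,
    gapopen = hits$gap_columns,
    qstart = hits$qstart + 1L, qend = hits$qend,
    sstart = ifelse(hits$strand == "+", hits$tstart + 1L, hits$tend),
    send = ifelse(hits$strand == "+", hits$tend, hits$tstart + 1L),
    score = hits$score)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
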