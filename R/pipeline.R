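# End-to-end pipeline: simulate (optional) -> specificity screen ->
# constituent scan + motif pairing -> LTR dating -> distribution statistics
# -> run report with a checksummed file manifest.

#' Pipeline configuration
#'
#' Either paths to two existing FASTA assemblies (`d_fasta`, `a_fasta`) or
#' `simulate = TRUE` with a [simulation_config()]. When simulating, the
#' motif definition defaults to the simulator's family consensus
#' sequences; for real assemblies a [motif_definition()] must be given.
#'
#' @param simulate Generate the genome pair with [simulate_genome_pair()].
#' @param sim A [simulation_config()] (used when `simulate = TRUE`).
#' @param d_fasta,a_fasta Paths to assemblies carrying / lacking the motif
#'   (used when `simulate = FALSE`).
#' @param def A [motif_definition()] or `NULL` (simulated runs only).
#' @param search A [search_params()].
#' @param dating A [dating_config()].
#' @param candidate_flank Bases added on each side of a motif call to form
#'   the host-element candidate interval for LTR detection.
#' @param window Window size for density tracks.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = TRUE, sim = simulation_config(),
                            d_fasta = NULL, a_fasta = NULL, def = NULL,
                            search = search_params(),
                            dating = dating_config(),
                            candidate_flank = 2500, window = 5e5) {
  cfg <- as.list(environment())
  if (!simulate) {
    if (is.null(d_fasta) || is.null(a_fasta)) {
      stop("d_fasta and a_fasta are required when simulate = FALSE",
           call. = FALSE)
    }
    if (is.null(def)) {
      stop("a motif_definition is required when simulate = FALSE",
           call. = FALSE)
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Executes simulate (optional), specificity screen, constituent scan and
#' motif pairing, LTR-pair dating, distribution statistics and the
#' presence report, writing every output under `out_dir` and returning a
#' run report whose manifest lists each file with its MD5 checksum.
#' Identical config and seed reproduce identical checksums.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @param seed Integer seed for all randomness.
#' @param quiet Suppress progress messages.
#' @return List of class `run_report`: stage result tables, counts and the
#'   manifest tibble.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         seed = 1, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message("[", format(Sys.time(), "%H:%M:%S"),
                                           "] ", ...)
  # validate inputs before any stage runs
  if (!config$simulate) {
    for (p in c(config$d_fasta, config$a_fasta)) {
      if (!file.exists(p)) {
        stop("input FASTA not found: ", p, call. = FALSE)
      }
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (config$simulate) {
    say("stage simulate")
    simres <- simulate_genome_pair(config$sim, seed = seed)
    d_genome <- simres$d_genome
    a_genome <- simres$a_genome
    write_simulation(simres, out_dir)
    def <- config$def %||% motif_definition(
      simres$templates$unit, simres$templates$cs)
  } else {
    say("stage load")
    d_genome <- read_fasta(config$d_fasta)
    a_genome <- read_fasta(config$a_fasta)
    def <- config$def
    simres <- NULL
  }

  say("stage screen")
  screen <- screen_genome_specific(
    c(tandem_unit = def$unit_consensus, conserved_seq = def$cs_consensus),
    d_genome, a_genome, config$search,
    def$min_identity, def$min_coverage)
  readr::write_tsv(screen, file.path(out_dir, "screen.tsv"))

  say("stage scan")
  calls_d <- call_motifs(d_genome, def, config$search)
  calls_a <- call_motifs(a_genome, def, config$search)
  write_motif_gff3(calls_d, file.path(out_dir, "motifs_D.gff3"))
  readr::write_tsv(calls_d, file.path(out_dir, "motifs_D.tsv"))
  readr::write_tsv(calls_a, file.path(out_dir, "motifs_A.tsv"))
  readr::write_tsv(unit_content_histogram(calls_d),
                   file.path(out_dir, "unit_content.tsv"))

  say("stage date")
  mot <- calls_d[calls_d$kind == "motif", ]
  lens <- stats::setNames(chromosomes(d_genome)$length,
                          chromosomes(d_genome)$chrom)
  cand <- tibble(
    element_id = sprintf("motif%03d", seq_len(nrow(mot))),
    chrom = mot$chrom,
    start = pmax(0, mot$start - config$candidate_flank),
    end = pmin(unname(lens[mot$chrom]), mot$end + config$candidate_flank))
  pairs <- detect_ltr_pairs(d_genome, cand, config$dating)
  readr::write_tsv(pairs, file.path(out_dir, "ltr_pairs.tsv"))
  ages <- activity_histogram(pairs)
  readr::write_tsv(ages, file.path(out_dir, "activity_histogram.tsv"))

  fams <- NULL
  datable <- pairs[pairs$paired, ]
  if (nrow(datable) > 0) {
    ltr_seqs <- extract_interval(d_genome, datable$chrom,
                                 datable$left_start, datable$left_end)
    names(ltr_seqs) <- datable$element_id
    fams <- cluster_families(ltr_seqs, def$min_identity, def$min_coverage)
    readr::write_tsv(fams, file.path(out_dir, "ltr_families.tsv"))
  }

  say("stage stats")
  tr_like <- calls_d[calls_d$kind %in% c("motif", "lone_TR"), ]
  counts <- dplyr::left_join(
    chromosomes(d_genome),
    dplyr::count(tr_like, .data$chrom, name = "observed"),
    by = "chrom")
  counts$observed[is.na(counts$observed)] <- 0L
  unif <- chi_square_uniformity(counts)
  readr::write_tsv(glance(unif), file.path(out_dir, "uniformity_test.tsv"))
  dens <- window_density(calls_d[calls_d$kind == "motif", ], d_genome,
                         config$window)
  write_bedgraph(dens, file.path(out_dir, "motif_density.bedgraph"))

  say("stage report")
  presence <- if (config$simulate) {
    tetra <- make_tetraploid(simres)
    subgenome_presence_report(tetra, def, config$search)
  } else {
    subgenome_presence_report(d_genome, def, config$search,
                              calls = calls_d)
  }
  readr::write_tsv(presence, file.path(out_dir, "presence_report.tsv"))
  writeLines(attr(presence, "summary"),
             file.path(out_dir, "presence_summary.txt"))

  counts_out <- list(
    n_motifs_D = sum(calls_d$kind == "motif"),
    n_lone_tr_D = sum(calls_d$kind == "lone_TR"),
    n_lone_cs_D = sum(calls_d$kind == "lone_CS"),
    n_motifs_A = sum(calls_a$kind == "motif"),
    n_constituent_hits_A = nrow(calls_a),
    n_paired_ltr = sum(pairs$paired),
    n_families = if (is.null(fams)) 0L else max(fams$family),
    chi2 = unif$chi2, chi2_p = unif$p_value)
  jsonlite::write_json(counts_out, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)

  files <- sort(list.files(out_dir, recursive = TRUE, full.names = TRUE))
  manifest <- tibble(file = basename(files),
                     md5 = unname(tools::md5sum(files)))
  readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"))

  structure(list(counts = counts_out, screen = screen, calls_d = calls_d,
                 calls_a = calls_a, ltr_pairs = pairs, families = fams,
                 uniformity = unif, presence = presence,
                 manifest = manifest, truth = simres$truth),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  for (nm in names(x$counts)) {
    cat(sprintf("  %-22s %s\n", nm, format(x$counts[[nm]], digits = 4)))
  }
  cat("  presence:", attr(x$presence, "summary"), "\n")
  invisible(x)
}
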