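# Ground-truthed simulator of a genome pair with planted composite repeat
# motifs: a "D-like" genome carrying tandem-array + conserved-sequence motifs
# embedded in degraded LTR retrotransposons, and a sister "A-like" genome in
# which every planted locus is deleted while the flanks remain collinear.

#' Simulation configuration
#'
#' Defaults emulate the cotton A/D presence-absence contrast at desk scale:
#' 13 chromosomes of 1 Mb, motifs of 133 bp tandem units repeated 2-21 times
#' next to an 860 bp conserved sequence, host elements aged 1-30 million
#' years under a Kimura two-parameter substitution process at
#' r = 1.3e-8 substitutions/site/year.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chromosome_lengths Length(s) in bases, recycled across chromosomes.
#' @param n_motifs Planted full motifs (TR array + CS inside an LTR element).
#' @param n_lone_tr,n_lone_cs Planted solitary constituents.
#' @param unit_length Tandem unit length in bases.
#' @param unit_copy_range Inclusive integer range of unit copies per array.
#' @param cs_length Conserved-sequence length in bases.
#' @param ltr_length Length of each flanking LTR in bases.
#' @param te_internal_length Non-motif internal element sequence in bases
#'   (split on both sides of the motif).
#' @param age_range Insertion-age range in million years (uniform draw).
#' @param rate Substitution rate r in substitutions/site/year.
#' @param tstv_kappa Transition/transversion rate ratio of the K2P process.
#' @param background_gc Background G+C fraction.
#' @param unit_mutation Per-unit divergence applied independently to every
#'   tandem unit (arrays are imperfect, so consensus training is non-trivial).
#' @param cs_mutation Per-instance divergence of the conserved sequence.
#' @param gap_range Range of the random spacer between TR array and CS.
#' @param flip_prob Probability that a planted element is reverse-complemented.
#' @param fraction_degraded Fraction of host elements missing one LTR (and so
#'   undatable); the default mirrors the observed preponderance of incomplete
#'   elements (47 of 72).
#' @param n_unrelated_a Unrelated random insertions added to the A-like genome.
#' @param add_decoys Add decoy microsatellite runs to both genomes
#'   (stress-testing flag; off by default for clean specificity accounting).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_chromosomes = 13,
                              chromosome_lengths = 1e6,
                              n_motifs = 20,
                              n_lone_tr = 5,
                              n_lone_cs = 5,
                              unit_length = 133,
                              unit_copy_range = c(2L, 21L),
                              cs_length = 860,
                              ltr_length = 1000,
                              te_internal_length = 1200,
                              age_range = c(1, 30),
                              rate = 1.3e-8,
                              tstv_kappa = 2,
                              background_gc = 0.35,
                              unit_mutation = 0.02,
                              cs_mutation = 0.02,
                              gap_range = c(0L, 50L),
                              flip_prob = 0.5,
                              fraction_degraded = 47 / 72,
                              n_unrelated_a = 0,
                              add_decoys = FALSE) {
  cfg <- as.list(environment())
  cfg$chromosome_lengths <-
    rep_len(as.integer(chromosome_lengths), n_chromosomes)
  stopifnot(
    all(cfg$chromosome_lengths > 0), unit_length > 0, cs_length > 0,
    ltr_length > 0, te_internal_length >= 0,
    unit_copy_range[1] >= 2, unit_copy_range[2] >= unit_copy_range[1],
    rate > 0, tstv_kappa > 0,
    background_gc > 0, background_gc < 1,
    fraction_degraded >= 0, fraction_degraded <= 1
  )
  structure(cfg, class = "simulation_config")
}

#' Mutate a sequence under the Kimura two-parameter model
#'
#' Substitutions are drawn per site with transition and transversion
#' probabilities chosen so that the expected K2P distance between input and
#' output equals `d`, at transition/transversion rate ratio `kappa`. `N`
#' bases are left untouched; the output has the same length as the input.
#'
#' @param seq DNA string.
#' @param d Expected substitutions per site (K2P distance), `>= 0`.
#' @param kappa Transition/transversion rate ratio.
#' @param seed Optional seed for a reproducible draw.
#' @return Mutated DNA string.
#' @export
#' @examples
#' mutate_k2p("ACGTACGT", 0)           # identical
#' nchar(mutate_k2p(strrep("ACGT", 25), 0.2, seed = 1))
mutate_k2p <- function(seq, d, kappa = 2, seed = NULL) {
  stopifnot(is.character(seq), length(seq) == 1L, nchar(seq) > 0)
  if (d < 0) stop("expected distance d must be >= 0", call. = FALSE)
  if (d == 0) return(seq)
  with_seed(seed, {
    # rates scaled so alpha + 2*beta integrates to d substitutions/site
    bt <- d / (kappa + 2)
    at <- kappa * bt
    P <- 0.25 + 0.25 * exp(-4 * bt) - 0.5 * exp(-2 * (at + bt))
    Q <- 0.5 - 0.5 * exp(-4 * bt)
    v <- utf8ToInt(seq)
    n <- length(v)
    # transition partners: A<->G, C<->T (codes 65<->71, 67<->84)
    ts <- integer(128)
    ts[c(65L, 71L, 67L, 84L)] <- c(71L, 65L, 84L, 67L)
    tv1 <- integer(128); tv2 <- integer(128)
    tv1[c(65L, 71L)] <- 67L; tv2[c(65L, 71L)] <- 84L
    tv1[c(67L, 84L)] <- 65L; tv2[c(67L, 84L)] <- 71L
    real <- v %in% c(65L, 67L, 71L, 84L)
    r <- stats::runif(n)
    i_ts <- real & r < P
    i_tv <- real & r >= P & r < P + Q
    v[i_ts] <- ts[v[i_ts]]
    if (any(i_tv)) {
      coin <- stats::runif(sum(i_tv)) < 0.5
      v[i_tv] <- ifelse(coin, tv1[v[i_tv]], tv2[v[i_tv]])
    }
    intToUtf8(v)
  })
}

# shared family templates for one simulated genome pair
motif_templates <- function(cfg) {
  int5 <- cfg$te_internal_length %/% 2
  list(
    ltr = random_dna(cfg$ltr_length, cfg$background_gc),
    unit = random_dna(cfg$unit_length, cfg$background_gc),
    cs = random_dna(cfg$cs_length, cfg$background_gc),
    int5 = random_dna(max(int5, 1), cfg$background_gc),
    int3 = random_dna(max(cfg$te_internal_length - int5, 1), cfg$background_gc)
  )
}

#' Build one motif-bearing LTR element
#'
#' Assembles `left LTR + internal(TR array + spacer + CS) + right LTR`.
#' Both LTRs derive from one template and are each independently mutated to
#' an expected per-copy distance of `r * age`, so the expected K2P distance
#' *between* the pair is `2 r age` and the dating estimator `T = d / (2 r)`
#' recovers the age. Tandem units and the CS receive their own light
#' mutation; the internal backbone degrades with age like the LTRs.
#'
#' @param cfg A [simulation_config()].
#' @param unit_count Number of tandem units (within `unit_copy_range`).
#' @param age_mya Insertion age in million years.
#' @param templates Family templates; drawn fresh if `NULL` (they are shared
#'   across elements of one simulated genome).
#' @param orientation `"+"` or `"-"` (element reverse-complemented).
#' @param degraded If `TRUE` the right LTR is deleted, leaving the element
#'   without a datable pair.
#' @param gap Spacer length; drawn from `cfg$gap_range` if `NULL`.
#' @param seed Optional seed.
#' @return List with `seq`, a `layout` tibble of element-relative
#'   sub-intervals (0-based half-open), and the planting parameters.
#' @export
build_motif_element <- function(cfg, unit_count, age_mya,
                                templates = NULL, orientation = "+",
                                degraded = FALSE, gap = NULL, seed = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (unit_count < cfg$unit_copy_range[1] ||
      unit_count > cfg$unit_copy_range[2]) {
    stop("unit_count ", unit_count, " outside unit_copy_range [",
         cfg$unit_copy_range[1], ",", cfg$unit_copy_range[2], "]",
         call. = FALSE)
  }
  with_seed(seed, {
    if (is.null(templates)) templates <- motif_templates(cfg)
    d_side <- cfg$rate * age_mya * 1e6  # per-copy divergence from template
    k <- cfg$tstv_kappa
    left <- mutate_k2p(templates$ltr, d_side, k)
    right <- mutate_k2p(templates$ltr, d_side, k)
    int5 <- mutate_k2p(templates$int5, d_side, k)
    int3 <- mutate_k2p(templates$int3, d_side, k)
    units <- vapply(seq_len(unit_count), function(i) {
      mutate_k2p(templates$unit, cfg$unit_mutation, k)
    }, character(1))
    tr <- paste(units, collapse = "")
    cs <- mutate_k2p(templates$cs, cfg$cs_mutation, k)
    if (is.null(gap)) {
      gap <- sample(cfg$gap_range[1]:cfg$gap_range[2], 1)
    }
    spacer <- if (gap > 0) random_dna(gap, cfg$background_gc) else ""
    parts <- c(left_ltr = left, internal5 = int5, tr_array = tr,
               spacer = spacer, cs = cs, internal3 = int3,
               right_ltr = if (degraded) "" else right)
    lens <- nchar(parts)
    ends <- cumsum(lens)
    layout <- tibble(part = names(parts),
                     start = unname(ends - lens), end = unname(ends))
    layout <- layout[layout$end > layout$start, ]
    seq <- paste(parts, collapse = "")
    if (orientation == "-") {
      L <- nchar(seq)
      seq <- revcomp(seq)
      layout <- tibble(part = layout$part,
                       start = L - layout$end, end = L - layout$start)
    }
    list(seq = seq, layout = layout, unit_count = unit_count,
         age_mya = age_mya, orientation = orientation, degraded = degraded)
  })
}

# place k insertion points on a background of length L with min spacing,
# leaving a margin at both ends; errors if packing is infeasible
place_points <- function(L, k, spacing = 3000, margin = 10000) {
  if (k == 0) return(integer(0))
  lo <- margin; hi <- L - margin
  if (hi - lo < (k - 1) * spacing || hi <= lo) {
    stop("infeasible packing: ", k, " features do not fit in ", L,
         " bases at spacing ", spacing, call. = FALSE)
  }
  for (try in 1:200) {
    pts <- sort(sample(lo:hi, k))
    if (k == 1 || min(diff(pts)) >= spacing) return(pts)
  }
  stop("infeasible packing after 200 attempts", call. = FALSE)
}

#' Simulate a D-like / A-like genome pair with ground truth
#'
#' The D-like genome carries all planted features (full motifs inside host
#' LTR elements, plus solitary TR arrays and CS copies) at recorded
#' coordinates; the A-like genome is the identical background with every
#' planted locus deleted exactly, so flanking sequence stays collinear.
#' Chromosomes receive features proportionally to their length. The same
#' seed reproduces the pair bit-for-bit.
#'
#' @param cfg A [simulation_config()].
#' @param seed Integer seed.
#' @return List with `d_genome`, `a_genome` (both [genome_assembly()]),
#'   `truth` (tibble: `element_id`, `kind` in
#'   `full_motif`/`lone_TR`/`lone_CS`/`LTR_TE`, coordinates on the D-like
#'   genome, `unit_count`, `age_mya`, `has_paired_ltrs`, TR/CS
#'   sub-intervals), `templates` (the family consensus sequences) and `cfg`.
#' @export
simulate_genome_pair <- function(cfg = simulation_config(), seed = 1) {
  stopifnot(inherits(cfg, "simulation_config"))
  with_seed(seed, {
    templates <- motif_templates(cfg)
    n_feat <- cfg$n_motifs + cfg$n_lone_tr + cfg$n_lone_cs
    kinds <- c(rep("full_motif", cfg$n_motifs),
               rep("lone_TR", cfg$n_lone_tr),
               rep("lone_CS", cfg$n_lone_cs))
    chrom_ids <- sprintf("chr%02d", seq_len(cfg$n_chromosomes))
    lens <- cfg$chromosome_lengths
    feat_chrom <- sample(chrom_ids, n_feat, replace = TRUE,
                         prob = lens / sum(lens))
    n_deg <- round(cfg$fraction_degraded * cfg$n_motifs)
    degraded <- sample(rep(c(TRUE, FALSE),
                           c(n_deg, cfg$n_motifs - n_deg)))

    # build feature sequences + element-relative layouts
    feats <- vector("list", n_feat)
    for (i in seq_len(n_feat)) {
      kind <- kinds[i]
      ori <- if (stats::runif(1) < cfg$flip_prob) "-" else "+"
      if (kind == "full_motif") {
        U <- sample(cfg$unit_copy_range[1]:cfg$unit_copy_range[2], 1)
        age <- stats::runif(1, cfg$age_range[1], cfg$age_range[2])
        el <- build_motif_element(cfg, U, age, templates, orientation = ori,
                                  degraded = degraded[i])
        feats[[i]] <- c(el, list(kind = kind))
      } else if (kind == "lone_TR") {
        U <- sample(cfg$unit_copy_range[1]:cfg$unit_copy_range[2], 1)
        units <- vapply(seq_len(U), function(j) {
          mutate_k2p(templates$unit, cfg$unit_mutation, cfg$tstv_kappa)
        }, character(1))
        seq <- paste(units, collapse = "")
        if (ori == "-") seq <- revcomp(seq)
        feats[[i]] <- list(seq = seq, kind = kind, unit_count = U,
                           orientation = ori,
                           layout = tibble(part = "tr_array", start = 0,
                                           end = nchar(seq)))
      } else {
        seq <- mutate_k2p(templates$cs, cfg$cs_mutation, cfg$tstv_kappa)
        if (ori == "-") seq <- revcomp(seq)
        feats[[i]] <- list(seq = seq, kind = kind, orientation = ori,
                           layout = tibble(part = "cs", start = 0,
                                           end = nchar(seq)))
      }
    }

    # backgrounds, insertion points, coordinate bookkeeping
    d_seqs <- a_seqs <- stats::setNames(character(length(chrom_ids)), chrom_ids)
    truth <- list()
    eid <- 0
    for (ci in seq_along(chrom_ids)) {
      cid <- chrom_ids[ci]
      bg <- random_dna(lens[ci], cfg$background_gc)
      if (cfg$add_decoys) {
        # decoy microsatellites shared by both genomes (planted into bg)
        for (dpos in place_points(lens[ci], 3, spacing = 50000)) {
          run <- strrep(substr(bg, dpos, dpos + 1), 30)
          bg <- paste0(substr(bg, 1, dpos - 1), run,
                       substr(bg, dpos + nchar(run), nchar(bg)))
        }
        bg <- substr(bg, 1, lens[ci])
      }
      idx <- which(feat_chrom == cid)
      total_inserted <- sum(vapply(feats[idx], function(f) nchar(f$seq), 0))
      if (total_inserted >= lens[ci]) {
        stop("infeasible packing: planted length ", total_inserted,
             " exceeds chromosome length ", lens[ci], call. = FALSE)
      }
      pts <- place_points(lens[ci], length(idx))
      pieces <- character(2 * length(idx) + 1)
      prev <- 0; shift <- 0
      for (j in seq_along(idx)) {
        f <- feats[[idx[j]]]
        pieces[2 * j - 1] <- substr(bg, prev + 1, pts[j])
        pieces[2 * j] <- f$seq
        gstart <- pts[j] + shift  # 0-based start of the feature on D
        eid <- eid + 1
        id <- sprintf("el%03d", eid)
        lay <- f$layout
        abs_lay <- stats::setNames(
          lapply(seq_len(nrow(lay)),
                 function(r) c(gstart + lay$start[r], gstart + lay$end[r])),
          lay$part)
        rec <- tibble(
          element_id = id, kind = f$kind, chrom = cid,
          start = gstart, end = gstart + nchar(f$seq),
          strand = f$orientation,
          unit_count = f$unit_count %||% NA_integer_,
          age_mya = f$age_mya %||% NA_real_,
          has_paired_ltrs = if (f$kind == "full_motif") !f$degraded else NA,
          tr_start = NA_real_, tr_end = NA_real_,
          cs_start = NA_real_, cs_end = NA_real_
        )
        if (f$kind == "full_motif") {
          tr <- abs_lay[["tr_array"]]; cs <- abs_lay[["cs"]]
          motif <- tibble(
            element_id = id, kind = "full_motif", chrom = cid,
            start = min(tr[1], cs[1]), end = max(tr[2], cs[2]),
            strand = f$orientation, unit_count = f$unit_count,
            age_mya = NA_real_, has_paired_ltrs = NA,
            tr_start = tr[1], tr_end = tr[2],
            cs_start = cs[1], cs_end = cs[2]
          )
          rec$kind <- "LTR_TE"; rec$unit_count <- NA_integer_
          rec <- dplyr::bind_rows(rec, motif)
        } else if (f$kind == "lone_TR") {
          tr <- abs_lay[["tr_array"]]
          rec$tr_start <- tr[1]; rec$tr_end <- tr[2]
        } else {
          cs <- abs_lay[["cs"]]
          rec$cs_start <- cs[1]; rec$cs_end <- cs[2]
        }
        truth[[length(truth) + 1]] <- rec
        shift <- shift + nchar(f$seq)
        prev <- pts[j]
      }
      pieces[2 * length(idx) + 1] <- substr(bg, prev + 1, lens[ci])
      d_seqs[cid] <- paste(pieces, collapse = "")
      a_seqs[cid] <- bg
    }

    # optional unrelated insertions on the A-like genome
    a_extra <- NULL
    if (cfg$n_unrelated_a > 0) {
      ac <- sample(chrom_ids, cfg$n_unrelated_a, replace = TRUE,
                   prob = lens / sum(lens))
      rows <- list()
      for (cid in unique(ac)) {
        k <- sum(ac == cid)
        pts <- place_points(nchar(a_seqs[cid]), k)
        shift <- 0
        for (p in pts) {
          ins <- random_dna(sample(500:3000, 1), cfg$background_gc)
          at <- p + shift
          a_seqs[cid] <- paste0(substr(a_seqs[cid], 1, at), ins,
                                substr(a_seqs[cid], at + 1,
                                       nchar(a_seqs[cid])))
          rows[[length(rows) + 1]] <-
            tibble(chrom = cid, start = at, end = at + nchar(ins))
          shift <- shift + nchar(ins)
        }
      }
      a_extra <- dplyr::bind_rows(rows)
    }

    list(
      d_genome = genome_assembly(d_seqs, name = "D_like"),
      a_genome = genome_assembly(a_seqs, name = "A_like"),
      truth = dplyr::bind_rows(truth),
      a_insertions = a_extra,
      templates = templates,
      cfg = cfg,
      seed = seed
    )
  })
}

#' Concatenate a simulated pair into a tetraploid-style assembly
#'
#' Chromosomes are renamed with `A_`/`D_` prefixes, emulating an
#' allotetraploid assembly with two subgenomes.
#'
#' @param sim Result of [simulate_genome_pair()], or a list with `a_genome`
#'   and `d_genome` assemblies.
#' @return A [genome_assembly()] named `"tetraploid"`.
#' @export
make_tetraploid <- function(sim) {
  a <- sim$a_genome$seqs; d <- sim$d_genome$seqs
  names(a) <- paste0("A_", names(a))
  names(d) <- paste0("D_", names(d))
  genome_assembly(c(a, d), name = "tetraploid")
}

#' Write a simulated pair to disk
#'
#' Writes `D_like.fasta`, `A_like.fasta`, `tetraploid.fasta`, `truth.gff3`
#' and a JSON echo of the configuration.
#'
#' @param sim Result of [simulate_genome_pair()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    d_fasta = file.path(dir, "D_like.fasta"),
    a_fasta = file.path(dir, "A_like.fasta"),
    tetraploid = file.path(dir, "tetraploid.fasta"),
    truth = file.path(dir, "truth.gff3"),
    config = file.path(dir, "config.json")
  )
  write_fasta(sim$d_genome, paths[["d_fasta"]])
  write_fasta(sim$a_genome, paths[["a_fasta"]])
  write_fasta(make_tetraploid(sim), paths[["tetraploid"]])
  tr <- sim$truth
  write_features(
    tibble(chrom = tr$chrom, start = tr$start, end = tr$end,
           name = tr$element_id, score = NA_real_, strand = tr$strand,
           type = tr$kind),
    paths[["truth"]], format = "GFF3")
  cfg <- unclass(sim$cfg)
  cfg$seed <- sim$seed
  jsonlite::write_json(cfg, paths[["config"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
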