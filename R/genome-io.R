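# Genome and feature I/O: FASTA assemblies, GFF3/BED feature tables, and
# coordinate-safe subsequence extraction. Internal coordinates are 0-based
# half-open everywhere; GFF3 is converted at the boundary.

#' Construct a genome assembly
#'
#' A genome assembly is a named, ordered set of chromosomes. Sequences are
#' plain uppercase character strings over `A`, `C`, `G`, `T`, `N`; order is
#' preserved and chromosome ids must be unique and non-empty.
#'
#' @param seqs Named character vector of chromosome sequences.
#' @param name Assembly name.
#' @return An object of class `genome_assembly`.
#' @export
#' @examples
#' g <- genome_assembly(c(c1 = "ACGTACGT", c2 = "TTTT"), name = "toy")
#' chromosomes(g)
genome_assembly <- function(seqs, name = "assembly") {
  stopifnot(is.character(seqs))
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("every chromosome needs a non-empty id", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate chromosome ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("non-nucleotide alphabet in chromosome(s): ",
         paste(ids[bad], collapse = ", "),
         " (only A, C, G, T, N are allowed)", call. = FALSE)
  }
  structure(list(name = name, seqs = seqs), class = "genome_assembly")
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat("<genome_assembly> ", x$name, ": ", length(x$seqs),
      " chromosome(s), ", format(total_length(x), big.mark = ","),
      " bases\n", sep = "")
  print(utils::head(chromosomes(x), 15))
  invisible(x)
}

#' Chromosome table of an assembly
#'
#' @param assembly A `genome_assembly`.
#' @return A tibble with columns `chrom` and `length`.
#' @export
chromosomes <- function(assembly) {
  stopifnot(inherits(assembly, "genome_assembly"))
  tibble(chrom = names(assembly$seqs),
         length = unname(nchar(assembly$seqs)))
}

#' Total assembly length in bases
#' @param assembly A `genome_assembly`.
#' @return Integer total of chromosome lengths.
#' @export
total_length <- function(assembly) {
  sum(nchar(assembly$seqs))
}

#' Read a genome assembly from FASTA
#'
#' Sequences are uppercased and `U` is normalized to `T`; record order is
#' preserved. Empty files, duplicate ids and non-nucleotide alphabets are
#' distinct errors.
#'
#' @param path Path to a (multi-record) FASTA file.
#' @param name Assembly name; defaults to the file stem.
#' @return A [genome_assembly()].
#' @export
read_fasta <- function(path, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop("no records in FASTA file: ", path, call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  seqs <- chartr("U", "T", seqs)
  # FASTA headers: id is the first whitespace-delimited token
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  genome_assembly(seqs, name = name %||% tools::file_path_sans_ext(basename(path)))
}

#' Write a genome assembly to FASTA
#'
#' @param assembly A `genome_assembly`.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(assembly, path, width = 70L) {
  stopifnot(inherits(assembly, "genome_assembly"))
  set <- Biostrings::DNAStringSet(assembly$seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Extract a subsequence from an assembly
#'
#' Coordinates are 0-based half-open. Minus-strand intervals return the
#' reverse complement. Arguments are recycled row-wise, so the function is
#' vectorized over intervals.
#'
#' @param assembly A `genome_assembly`.
#' @param chrom Chromosome id(s).
#' @param start,end 0-based half-open bounds.
#' @param strand `"+"` or `"-"`.
#' @return Character vector of sequences.
#' @export
#' @examples
#' g <- genome_assembly(c(c1 = "ACGTACGT"))
#' extract_interval(g, "c1", 2, 5)        # "GTA"
#' extract_interval(g, "c1", 2, 5, "-")   # "TAC"
extract_interval <- function(assembly, chrom, start, end, strand = "+") {
  stopifnot(inherits(assembly, "genome_assembly"))
  n <- max(length(chrom), length(start), length(end), length(strand))
  chrom <- rep_len(chrom, n); start <- rep_len(start, n)
  end <- rep_len(end, n); strand <- rep_len(strand, n)
  out <- character(n)
  lens <- stats::setNames(nchar(assembly$seqs), names(assembly$seqs))
  for (i in seq_len(n)) {
    if (!chrom[i] %in% names(lens)) {
      stop("unknown chromosome: ", chrom[i], call. = FALSE)
    }
    L <- lens[[chrom[i]]]
    if (start[i] < 0) {
      stop("interval start ", start[i], " violates lower bound 0 on ",
           chrom[i], call. = FALSE)
    }
    if (end[i] > L) {
      stop("interval end ", end[i], " violates chromosome length ", L,
           " on ", chrom[i], call. = FALSE)
    }
    if (start[i] >= end[i]) {
      stop("empty or inverted interval [", start[i], ",", end[i], ") on ",
           chrom[i], call. = FALSE)
    }
    s <- substr(assembly$seqs[[chrom[i]]], start[i] + 1L, end[i])
    out[i] <- if (strand[i] == "-") revcomp(s) else s
  }
  out
}

#' Extract the sequences of a feature table
#'
#' @param assembly A `genome_assembly`.
#' @param features Tibble with `chrom`, `start`, `end` and optionally
#'   `strand` columns (0-based half-open).
#' @return Character vector, one sequence per row.
#' @export
extract_intervals <- function(assembly, features) {
  strand <- if ("strand" %in% names(features)) features$strand else "+"
  extract_interval(assembly, features$chrom, features$start, features$end,
                   strand)
}

# ---------------------------------------------------------------------------
# Feature tables (GFF3 / BED)
# ---------------------------------------------------------------------------

validate_feature_lines <- function(path, format) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  for (i in body) {
    f <- strsplit(lines[i], "\t")[[1]]
    nmin <- if (format == "GFF3") 9L else 3L
    coords <- if (format == "GFF3") f[4:5] else f[2:3]
    ok <- length(f) >= nmin &&
      !anyNA(suppressWarnings(as.numeric(coords)))
    if (!ok) {
      stop("malformed ", format, " line ", i, " in ", path, ": ",
           substr(lines[i], 1, 60), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Read genomic features from GFF3 or BED
#'
#' BED is taken as 0-based half-open; GFF3 as 1-based inclusive and
#' converted, so identical loci in either format yield identical internal
#' coordinates. Malformed lines are reported with their line number.
#'
#' @param path Input file.
#' @param format `"GFF3"` or `"BED"`; guessed from the extension by default.
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand` and, for GFF3, `type` and `attributes`.
#' @export
read_features <- function(path, format = c("auto", "GFF3", "BED")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "BED" else "GFF3"
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  validate_feature_lines(path, format)
  gr <- rtracklayer::import(path, format = if (format == "BED") "bed" else "gff3")
  md <- as.data.frame(S4Vectors::mcols(gr))
  out <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
    end = GenomicRanges::end(gr),
    name = if ("name" %in% names(md)) as.character(md$name)
           else if ("Name" %in% names(md)) as.character(md$Name)
           else if ("ID" %in% names(md)) as.character(md$ID)
           else NA_character_,
    score = if ("score" %in% names(md)) as.numeric(md$score) else NA_real_,
    strand = as.character(GenomicRanges::strand(gr))
  )
  out$strand[out$strand == "*"] <- "+"
  if (format == "GFF3") {
    out$type <- if ("type" %in% names(md)) as.character(md$type) else NA_character_
    keep <- setdiff(names(md), c("name", "Name", "ID", "score", "type",
                                 "source", "phase"))
    out$attributes <- if (length(keep)) {
      apply(md[keep], 1, function(r) {
        r <- r[!is.na(r) & nzchar(r)]
        paste(paste0(names(r), "=", r), collapse = ";")
      })
    } else NA_character_
  }
  out
}

#' Write genomic features to GFF3 or BED
#'
#' The inverse of [read_features()]: internal 0-based half-open coordinates
#' are rendered 1-based inclusive in GFF3 and unchanged in BED, so a
#' read/write round trip preserves coordinates exactly.
#'
#' @param features Tibble with `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand`, `type` columns.
#' @param path Output file.
#' @param format `"GFF3"` or `"BED"`.
#' @param source Value of the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path, format = c("GFF3", "BED"),
                           source = "repscout") {
  format <- match.arg(format)
  n <- nrow(features)
  strand <- if ("strand" %in% names(features)) features$strand else rep("+", n)
  gr <- GenomicRanges::GRanges(
    seqnames = features$chrom,
    ranges = IRanges::IRanges(start = features$start + 1L, end = features$end),
    strand = strand
  )
  if (format == "BED") {
    S4Vectors::mcols(gr)$name <-
      if ("name" %in% names(features)) features$name else "."
    sc <- if ("score" %in% names(features)) features$score else 0
    sc[is.na(sc)] <- 0
    S4Vectors::mcols(gr)$score <- sc
    rtracklayer::export(gr, path, format = "bed")
  } else {
    S4Vectors::mcols(gr)$type <-
      if ("type" %in% names(features)) features$type else "region"
    S4Vectors::mcols(gr)$source <- source
    if ("name" %in% names(features)) S4Vectors::mcols(gr)$Name <- features$name
    if ("score" %in% names(features)) S4Vectors::mcols(gr)$score <- features$score
    rtracklayer::export(gr, path, format = "gff3")
  }
  invisible(path)
}

#' Reverse complement of a DNA string
#'
#' `N` maps to `N`; the operation is an involution.
#'
#' @param seq A character vector of DNA strings.
#' @return Reverse-complemented strings.
#' @export
reverse_complement <- function(seq) {
  vapply(seq, revcomp, character(1), USE.NAMES = FALSE)
}
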