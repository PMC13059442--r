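## Readers/writers for the plain-text formats the pipeline exchanges.
## Internal coordinates are 0-based half-open; BED is written natively,
## the GFF-like annotation is written 1-based closed with conversion at
## this boundary only.

#' Write / read a genome FASTA
#'
#' @param genome named character vector of chromosome sequences.
#' @param path file path.
#' @return `read_genome_fasta()` returns a named character vector.
#' @export
write_genome_fasta <- function(genome, path) {
  dss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(dss, filepath = path, width = 70L)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(dss), names(dss))
}

#' Write / read the exon annotation
#'
#' The on-disk format is a GFF-like TSV with 1-based closed coordinates
#' (`start1`, `end1`); in memory the annotation uses 0-based half-open
#' `start`/`end`. Columns: gene_id, exon_id, chrom, strand, role, rank.
#'
#' @param ann annotation data.frame (internal representation).
#' @param path file path.
#' @return `read_annotation()` returns the internal representation.
#' @export
write_annotation <- function(ann, path) {
  out <- data.frame(
    chrom = ann$chrom, source = "splicecode", feature = "exon",
    start1 = ann$start + 1L, end1 = ann$end,
    score = ".", strand = ann$strand,
    gene_id = ann$gene_id, exon_id = ann$exon_id,
    role = ann$role, rank = ann$rank,
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  data.frame(
    gene_id = x$gene_id, exon_id = x$exon_id, chrom = x$chrom,
    start = x$start1 - 1L, end = x$end1, strand = x$strand,
    role = x$role, rank = x$rank, stringsAsFactors = FALSE)
}

#' Write / read long-read exon chains
#'
#' TSV with columns read_id, individual, cell_type, chrom, strand, exons;
#' `exons` is a semicolon-delimited list of 0-based half-open intervals.
#'
#' @param chains chain data.frame.
#' @param path file path.
#' @return `read_chains()` returns the chain data.frame.
#' @export
write_chains <- function(chains, path) {
  utils::write.table(chains[, c("read_id", "individual", "cell_type",
                                "chrom", "strand", "exons")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_chains
#' @export
read_chains <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(read_id = "character",
                                   individual = "character",
                                   cell_type = "character",
                                   chrom = "character",
                                   strand = "character",
                                   exons = "character"))
}

#' Write / read RBP peak BED files
#'
#' One 6-column BED per RBP named `<rbp>.bed` (0-based half-open, native
#' BED convention; score 0, strand '.').
#'
#' @param peaks peak data.frame with columns rbp, chrom, start, end.
#' @param dir output directory (created if missing).
#' @param paths for the reader, a named character vector (names = RBP) or a
#'   directory containing `<rbp>.bed` files.
#' @return `write_peaks_bed()` the named vector of paths written;
#'   `read_peaks_bed()` a data.frame (rbp, chrom, start, end).
#' @export
write_peaks_bed <- function(peaks, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rbps <- sort(unique(peaks$rbp))
  paths <- stats::setNames(file.path(dir, paste0(rbps, ".bed")), rbps)
  for (r in rbps) {
    p <- peaks[peaks$rbp == r, , drop = FALSE]
    bed <- data.frame(p$chrom, p$start, p$end, r, 0L, ".")
    utils::write.table(bed, paths[[r]], sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(paths)
}

#' @rdname write_peaks_bed
#' @export
read_peaks_bed <- function(paths) {
  if (length(paths) == 1L && dir.exists(paths)) {
    files <- list.files(paths, pattern = "\\.bed$", full.names = TRUE)
    paths <- stats::setNames(files, sub("\\.bed$", "", basename(files)))
  }
  if (is.null(names(paths))) {
    names(paths) <- sub("\\.bed$", "", basename(paths))
  }
  out <- lapply(names(paths), function(r) {
    lines <- readLines(paths[[r]])
    lines <- lines[nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 3L)) {
      stop("malformed BED line ", which(nf < 3L)[1L], " in ", paths[[r]])
    }
    start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
    end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
    if (anyNA(start) || anyNA(end)) {
      stop("malformed BED line ", which(is.na(start) | is.na(end))[1L],
           " in ", paths[[r]])
    }
    data.frame(rbp = r, chrom = vapply(fields, `[[`, "", 1L),
               start = start, end = end, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write / read the variant table
#'
#' VCF-like TSV with columns CHROM, POS (1-based), REF, ALT, INTRON_START,
#' INTRON_END (0-based half-open), SLOPE, PVAL plus bookkeeping columns
#' (exon_id, label, rbp, expected sign per cell type).
#'
#' @param variants variant data.frame (internal representation).
#' @param path file path.
#' @return `read_variants()` returns the internal representation.
#' @export
write_variants <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_variants
#' @export
read_variants <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write a PSI table
#'
#' TSV with one row per exon and cell type (exon_id, chrom, start, end,
#' strand, gene, cell_type, psi_overall, psi_acceptor, psi_donor, n_reads,
#' delta_psi, variability).
#'
#' @param psi PSI table as produced by [psi_from_chains()].
#' @param path file path.
#' @export
write_psi_table <- function(psi, path) {
  utils::write.table(psi, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_psi_table
#' @export
read_psi_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
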