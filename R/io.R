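# File input/output: FASTA/FASTQ through Biostrings, BED and TSV through readr.

#' Read and write genome FASTA
#'
#' Thin wrappers around [Biostrings::readDNAStringSet()] /
#' [Biostrings::writeXStringSet()] keeping chromosome names bare.
#'
#' @param genome A `DNAStringSet`.
#' @param path File path.
#' @return `read_genome_fasta()` returns a `DNAStringSet`;
#'   `write_genome_fasta()` returns `path` invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  stopifnot(methods::is(genome, "DNAStringSet"))
  Biostrings::writeXStringSet(genome, path, format = "fasta", width = 70)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  g <- Biostrings::readDNAStringSet(path, format = "fasta")
  # keep only the first word of each header as the chromosome name
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Read and write BED interval files
#'
#' BED is 0-based half-open, matching the package's in-memory convention,
#' so columns pass through unchanged. Extra columns beyond the canonical
#' six are preserved on write and read back by position.
#'
#' @param x Interval tibble with at least `chrom`, `start`, `end`.
#' @param path File path.
#' @return `read_bed()` returns a tibble; `write_bed()` returns `path`
#'   invisibly.
#' @export
write_bed <- function(x, path) {
  x <- check_intervals(x)
  lead <- intersect(c("chrom", "start", "end", "name", "score", "strand"), names(x))
  rest <- setdiff(names(x), lead)
  readr::write_tsv(x[, c(lead, rest)], path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  x <- readr::read_tsv(path, col_names = FALSE, progress = FALSE,
                       show_col_types = FALSE, comment = "#")
  if (ncol(x) < 3) stop_invalid("BED file needs at least 3 columns")
  base <- c("chrom", "start", "end", "name", "score", "strand")
  names(x)[seq_len(min(ncol(x), 6))] <- base[seq_len(min(ncol(x), 6))]
  check_intervals(x, arg = path)
}

#' Write a read set as FASTQ
#'
#' Read origins are encoded in the read names
#' (`read_id origin=haplotype:chrom:start:strand`) so simulated truth
#' survives a round trip through disk. Qualities are constant `I`
#' (the simulator's error model is positional, not quality-driven).
#'
#' @param reads A `read_set` from [simulate_reads()].
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  stopifnot(inherits(reads, "read_set"))
  sq <- reads$reads
  o <- reads$origins
  names(sq) <- paste0(
    "r", seq_along(sq),
    " origin=", o$hap, ":", o$chrom, ":", o$start, ":", o$strand
  )
  qual <- Biostrings::BStringSet(strrep("I", Biostrings::width(sq)))
  Biostrings::writeXStringSet(sq, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read a FASTQ read set
#'
#' @param path FASTQ path.
#' @return A `read_set` (origins recovered from read names when present).
#' @export
read_reads_fastq <- function(path) {
  sq <- Biostrings::readDNAStringSet(path, format = "fastq")
  nm <- names(sq)
  origins <- NULL
  if (all(grepl(" origin=", nm))) {
    parts <- stringr::str_match(nm, "origin=([^:]+):([^:]+):(\\d+):([+-])")
    origins <- tibble(
      hap = parts[, 2], chrom = parts[, 3],
      start = as.double(parts[, 4]), strand = parts[, 5]
    )
  }
  names(sq) <- sub("\\s.*$", "", nm)
  new_read_set(sq, read_length = unique(Biostrings::width(sq)),
               depth = NA_real_, origins = origins)
}
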