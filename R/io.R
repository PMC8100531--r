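#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector or `DNAStringSet`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, filepath = path, format = "fasta")
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  setNames(as.character(x), names(x))
}

#' Write reads to a FASTQ file (Phred+33)
#'
#' @param reads Tibble with columns `read_id`, `seq`, `qual`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(reads$seq),
    Biostrings::PhredQuality(reads$qual)
  )
  names(x) <- reads$read_id
  Biostrings::writeQualityScaledXStringSet(x, filepath = path)
  invisible(path)
}

#' Read a FASTQ file (Phred+33) into a read tibble
#'
#' @param path FASTQ file path.
#' @return Tibble with columns `read_id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readQualityScaledDNAStringSet(path)
  new_read_set(names(x), as.character(x), as.character(Biostrings::quality(x)))
}

#' Write genomic intervals as BED6
#'
#' Intervals use 0-based half-open coordinates, the native BED convention.
#'
#' @param intervals Tibble with columns `chrom`, `start`, `end`, and
#'   optionally `name`, `score`, `strand`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  n <- nrow(intervals)
  col_or <- function(nm, default) {
    if (nm %in% names(intervals)) intervals[[nm]] else rep(default, n)
  }
  bed <- data.frame(
    chrom  = intervals$chrom,
    start  = intervals$start,
    end    = intervals$end,
    name   = col_or("name", "."),
    score  = col_or("score", 0L),
    strand = col_or("strand", "+")
  )
  if (n == 0L) {
    file.create(path)
    return(invisible(path))
  }
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a tibble as a TSV file
#'
#' @param x Data frame.
#' @param path Output file path.
#' @param col.names Write a header line?
#' @return `path`, invisibly.
#' @export
write_tsv_file <- function(x, path, col.names = TRUE) {
  write.table(x, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = col.names)
  invisible(path)
}
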