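#' Remove reads matching annotated ncRNA sequences
#'
#' A read is removed iff its sequence is an exact substring of any ncRNA
#' reference sequence on either strand. Filtering precedes genome mapping.
#'
#' @param reads Read tibble (`read_id`, `seq`, `qual`).
#' @param ncrna_seqs Character vector of ncRNA reference sequences
#'   (rRNA, tRNA, snRNA, snoRNA, repeats).
#' @return List with `reads` (kept) and `n_removed`.
#' @export
filter_ncrna <- function(reads, ncrna_seqs) {
  if (length(ncrna_seqs) == 0L || nrow(reads) == 0L) {
    return(list(reads = reads, n_removed = 0L))
  }
  # one haystack per strand, "+"-separated so matches cannot cross loci
  hay <- paste(c(toupper(ncrna_seqs), revcomp(toupper(ncrna_seqs))),
               collapse = "+")
  uniq <- unique(reads$seq)
  hit <- vapply(uniq, function(s) grepl(s, hay, fixed = TRUE), logical(1))
  removed <- reads$seq %in% uniq[hit]
  list(reads = reads[!removed, , drop = FALSE], n_removed = sum(removed))
}

#' Map read sequences end-to-end to a reference genome
#'
#' Reports every locus where a sequence aligns end-to-end with at most
#' `max_mismatch` substitutions (no indels), on both strands. Sequences with
#' no locus are unmapped. Coordinates are 0-based half-open.
#'
#' @param seqs Character vector of read sequences (duplicates allowed; hits
#'   are reported per distinct sequence).
#' @param genome Named character vector (or `DNAStringSet`) of chromosomes.
#' @param max_mismatch Maximum substitutions allowed (default 0).
#' @return Tibble with columns `seq`, `chrom`, `start`, `end`, `strand`,
#'   `mismatches`, sorted by (`seq`, `chrom`, `start`).
#' @export
map_reads <- function(seqs, genome, max_mismatch = 0L) {
  if (methods::is(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  empty <- tibble::tibble(seq = character(0), chrom = character(0),
                          start = integer(0), end = integer(0),
                          strand = character(0), mismatches = integer(0))
  uniq <- unique(seqs)
  uniq <- uniq[nchar(uniq) > 0L]
  if (length(uniq) == 0L || length(genome) == 0L) return(empty)
  subjects <- lapply(genome, Biostrings::DNAString)
  rows <- vector("list", length(uniq))
  for (i in seq_along(uniq)) {
    s <- uniq[i]
    pats <- c(`+` = s, `-` = revcomp(s))
    hits <- list()
    for (ch in names(subjects)) {
      glen <- nchar(genome[[ch]])
      if (nchar(s) > glen) next
      for (std in c("+", "-")) {
        m <- Biostrings::matchPattern(
          Biostrings::DNAString(pats[[std]]), subjects[[ch]],
          max.mismatch = max_mismatch, with.indels = FALSE, fixed = TRUE)
        st <- Biostrings::start(m)
        en <- Biostrings::end(m)
        ok <- st >= 1L & en <= glen
        st <- st[ok]
        if (!length(st)) next
        win <- substring(genome[[ch]], st, st + nchar(s) - 1L)
        pr <- charToRaw(pats[[std]])
        mm <- vapply(win, function(w) sum(charToRaw(w) != pr), integer(1),
                     USE.NAMES = FALSE)
        keep <- mm <= max_mismatch
        if (!any(keep)) next
        hits[[length(hits) + 1L]] <- tibble::tibble(
          seq = s, chrom = ch, start = st[keep] - 1L,
          end = st[keep] - 1L + nchar(s), strand = std,
          mismatches = as.integer(mm[keep]))
      }
    }
    rows[[i]] <- if (length(hits)) dplyr::bind_rows(hits) else NULL
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) return(empty)
  out[order(out$seq, out$chrom, out$start, out$strand), , drop = FALSE]
}

#' Construct mapping statistics
#'
#' Enforces the accounting invariant
#' `n_input = n_ncrna_removed + n_mapped + n_unmapped`.
#'
#' @param n_input Reads entering the stage (clean reads).
#' @param n_ncrna_removed Reads removed by the ncRNA filter.
#' @param n_mapped Reads with at least one genomic locus.
#' @param n_unmapped Reads with no locus.
#' @param ratio_digits Decimal places for the mapped ratio.
#' @return A list of class `mapping_stats` including `mapped_ratio` in
#'   percent of `n_input`.
#' @export
mapping_stats <- function(n_input, n_ncrna_removed, n_mapped, n_unmapped,
                          ratio_digits = 2L) {
  if (any(c(n_input, n_ncrna_removed, n_mapped, n_unmapped) < 0)) {
    stop("mapping statistics must be non-negative", call. = FALSE)
  }
  if (n_input != n_ncrna_removed + n_mapped + n_unmapped) {
    stop("invalid mapping statistics: inputs must equal removed + mapped + ",
         "unmapped", call. = FALSE)
  }
  structure(list(n_input = n_input, n_ncrna_removed = n_ncrna_removed,
                 n_mapped = n_mapped, n_unmapped = n_unmapped,
                 mapped_ratio = mapped_ratio(n_mapped, n_input,
                                             digits = ratio_digits)),
            class = "mapping_stats")
}

#' Mapped ratio in percent
#'
#' Percentage of clean reads placed on the reference, rounded to the
#' reporting precision. The denominator is the clean-read count.
#'
#' @param n_mapped Mapped read count.
#' @param n_clean Clean read count (> 0).
#' @param digits Decimal places of the reported percentage.
#' @return Numeric percentage.
#' @export
mapped_ratio <- function(n_mapped, n_clean, digits = 2L) {
  if (n_clean <= 0) {
    stop("mapped ratio is undefined for zero clean reads", call. = FALSE)
  }
  round(100 * n_mapped / n_clean, digits)
}

#' Write genome hits as BED6
#'
#' The score field carries the mismatch count.
#'
#' @param hits Hit tibble from [map_reads()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, path) {
  write_bed(tibble::tibble(chrom = hits$chrom, start = hits$start,
                           end = hits$end, name = hits$seq,
                           score = hits$mismatches, strand = hits$strand),
            path)
}
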