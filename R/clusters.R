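#' Detect piRNA clusters from mapped hits
#'
#' Density-based cluster calling in the spirit of proTRAC: hit 5' ends on
#' each chromosome are merged into maximal runs in which consecutive 5'
#' ends are at most `max_gap` nt apart; a run becomes a cluster iff its
#' genomic span is at least `min_span`, it contains at least `min_members`
#' distinct piRNA sequences, at least `min_u1` of its member sequences start
#' with a 5' U (T in DNA), and at least `min_window_frac` of members are
#' 24-32 nt long. Clusters are non-overlapping by construction.
#'
#' Multi-mapping sequences are down-weighted: each hit of a sequence with
#' `h` loci contributes `count / h` reads to the weighted read count.
#'
#' @param hits Hit tibble from [map_reads()], sorted by (`chrom`, `start`).
#' @param counts Optional named numeric vector of read counts per sequence
#'   (default: one read per distinct sequence).
#' @param min_members Minimum distinct member sequences.
#' @param min_span Minimum cluster span in nt.
#' @param max_gap Maximum gap between consecutive 5' ends in nt.
#' @param min_u1 Minimum fraction of members with a 5' U.
#' @param min_window_frac Minimum fraction of members 24-32 nt long.
#' @return Tibble with one row per cluster: `chrom`, `start`, `end`,
#'   `n_member_sequences`, `n_reads`, `u1_fraction`,
#'   `length_window_fraction`.
#' @export
detect_clusters <- function(hits, counts = NULL, min_members = 10L,
                            min_span = 1000L, max_gap = 1000L,
                            min_u1 = 0.3, min_window_frac = 0.75) {
  empty <- tibble::tibble(chrom = character(0), start = integer(0),
                          end = integer(0), n_member_sequences = integer(0),
                          n_reads = numeric(0), u1_fraction = numeric(0),
                          length_window_fraction = numeric(0))
  if (nrow(hits) == 0L) return(empty)
  ord <- order(hits$chrom, hits$start)
  if (!identical(ord, seq_len(nrow(hits)))) {
    stop("hits must be sorted by (chrom, start)", call. = FALSE)
  }
  if (is.null(counts)) {
    counts <- setNames(rep(1, length(unique(hits$seq))), unique(hits$seq))
  }
  n_hits <- table(hits$seq)
  weight <- as.numeric(counts[hits$seq]) / as.numeric(n_hits[hits$seq])
  pos5 <- ifelse(hits$strand == "+", hits$start, hits$end - 1L)

  out <- list()
  for (ch in unique(hits$chrom)) {
    idx <- which(hits$chrom == ch)
    idx <- idx[order(pos5[idx])]
    p <- pos5[idx]
    run_id <- cumsum(c(1L, as.integer(diff(p) > max_gap)))
    for (r in split(idx, run_id)) {
      members <- unique(hits$seq[r])
      span_start <- min(hits$start[r])
      span_end <- max(hits$end[r])
      cl <- tibble::tibble(
        chrom = ch, start = span_start, end = span_end,
        n_member_sequences = length(members),
        n_reads = sum(weight[r]),
        u1_fraction = mean(substr(members, 1L, 1L) == "T"),
        length_window_fraction = mean(nchar(members) >= 24L &
                                        nchar(members) <= 32L))
      if ((span_end - span_start) >= min_span &&
          cl$n_member_sequences >= min_members &&
          cl$u1_fraction >= min_u1 &&
          cl$length_window_fraction >= min_window_frac) {
        out[[length(out) + 1L]] <- cl
      }
    }
  }
  if (!length(out)) return(empty)
  res <- dplyr::bind_rows(out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

#' Quantify piRNA expression as counts and TPM per library
#'
#' piRNA identity is the distinct read sequence. TPM is the raw count scaled
#' to one million per library, without length normalisation (piRNA lengths
#' span only 24-32 nt); per-library TPM therefore sums to exactly 1e6.
#'
#' @param libs Named list of character vectors, one per library, holding the
#'   clean piRNA-range read sequences with multiplicity.
#' @param per_kilobase If `TRUE`, scale counts by sequence length in kb
#'   before normalising (classical TPM).
#' @return Long tibble with columns `pirna_seq`, `library`, `count`, `tpm`.
#' @export
quantify <- function(libs, per_kilobase = FALSE) {
  stopifnot(is.list(libs), !is.null(names(libs)))
  if (any(vapply(libs, length, integer(1)) == 0L)) {
    stop("every library must contain at least one read", call. = FALSE)
  }
  all_seqs <- sort(unique(unlist(libs, use.names = FALSE)))
  rows <- lapply(names(libs), function(nm) {
    cnt <- table(factor(libs[[nm]], levels = all_seqs))
    cnt <- as.numeric(cnt)
    x <- if (per_kilobase) cnt / (nchar(all_seqs) / 1000) else cnt
    tibble::tibble(pirna_seq = all_seqs, library = nm, count = cnt,
                   tpm = x * 1e6 / sum(x))
  })
  dplyr::bind_rows(rows)
}

#' Pivot a quantification table to a matrix
#'
#' @param quant Tibble from [quantify()].
#' @param value `"tpm"` or `"count"`.
#' @return Numeric matrix, rows = piRNA sequences, columns = libraries.
#' @export
expression_matrix <- function(quant, value = c("tpm", "count")) {
  value <- match.arg(value)
  wide <- tidyr::pivot_wider(quant[, c("pirna_seq", "library", value)],
                             names_from = "library",
                             values_from = tidyr::all_of(value),
                             values_fill = 0)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$pirna_seq
  m
}
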