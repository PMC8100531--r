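#' Predict piRNA target sites on a transcriptome
#'
#' A piRNA targets a transcript iff the reverse complement of its seed
#' region (positions `seed_start..seed_end` of the piRNA, default 2-11)
#' occurs exactly in the transcript and the full-length antisense extension
#' of the piRNA over that site has at most `max_ext_mismatch`
#' substitutions. The piRNA must sit antisense to the transcript; a
#' sense-strand occurrence is not a target. All sites are reported.
#'
#' @param pirnas Character vector of piRNA sequences.
#' @param transcripts Named character vector (or `DNAStringSet`) of
#'   transcript sequences.
#' @param seed_start,seed_end 1-based seed region bounds on the piRNA.
#' @param max_ext_mismatch Substitutions tolerated outside the seed.
#' @return Tibble with `pirna_seq`, `transcript_id`, `position` (0-based
#'   site start on the transcript) and `mismatches`.
#' @export
predict_targets <- function(pirnas, transcripts, seed_start = 2L,
                            seed_end = 11L, max_ext_mismatch = 2L) {
  if (methods::is(transcripts, "DNAStringSet")) {
    transcripts <- setNames(as.character(transcripts), names(transcripts))
  }
  empty <- tibble::tibble(pirna_seq = character(0),
                          transcript_id = character(0),
                          position = integer(0), mismatches = integer(0))
  pirnas <- unique(pirnas)
  pirnas <- pirnas[nchar(pirnas) >= seed_end]
  if (!length(pirnas) || !length(transcripts)) return(empty)
  assert_acgt(pirnas, "piRNA sequence")
  out <- list()
  for (p in pirnas) {
    L <- nchar(p)
    rc <- revcomp(p)
    # piRNA position i pairs with antisense-site position L + 1 - i
    rc_seed <- substr(rc, L - seed_end + 1L, L - seed_start + 1L)
    rc_raw <- charToRaw(rc)
    for (tx in names(transcripts)) {
      tseq <- transcripts[[tx]]
      if (nchar(tseq) < L) next
      occ <- gregexpr(rc_seed, tseq, fixed = TRUE)[[1]]
      if (occ[1] == -1L) next
      site <- as.integer(occ) - (L - seed_end)
      site <- site[site >= 1L & site + L - 1L <= nchar(tseq)]
      for (s in site) {
        win <- substr(tseq, s, s + L - 1L)
        mm <- sum(charToRaw(win) != rc_raw)
        if (mm <= max_ext_mismatch) {
          out[[length(out) + 1L]] <- tibble::tibble(
            pirna_seq = p, transcript_id = tx, position = s - 1L,
            mismatches = as.integer(mm))
        }
      }
    }
  }
  if (!length(out)) return(empty)
  dplyr::bind_rows(out)
}

#' Hypergeometric over-representation of annotation terms
#'
#' For each term, with `N` universe genes of which `K` carry the term, and
#' `n` target genes of which `k` carry it, the p-value is the
#' hypergeometric upper tail `P(X >= k)`. BH adjustment is applied within
#' each ontology separately. Terms with no annotated universe gene are
#' skipped.
#'
#' @param targets Character vector of target gene/transcript ids
#'   (must be a subset of the universe).
#' @param annotation Tibble with columns `transcript_id`, `term_id`,
#'   `ontology`.
#' @param universe Character vector of universe ids; defaults to every
#'   annotated transcript in `annotation`.
#' @return Tibble with `term_id`, `ontology`, `k`, `n`, `K`, `N`, `p`,
#'   `padj`.
#' @export
hypergeom_enrich <- function(targets, annotation, universe = NULL) {
  targets <- unique(targets)
  if (is.null(universe)) universe <- unique(annotation$transcript_id)
  universe <- unique(universe)
  missing <- setdiff(targets, universe)
  if (length(missing)) {
    stop(sprintf("target genes absent from the universe: %s",
                 paste(head(missing, 3), collapse = ", ")), call. = FALSE)
  }
  ann <- annotation[annotation$transcript_id %in% universe, , drop = FALSE]
  N <- length(universe)
  n <- length(targets)
  terms <- unique(ann[, c("term_id", "ontology")])
  if (nrow(terms) == 0L || n == 0L) {
    return(tibble::tibble(term_id = character(0), ontology = character(0),
                          k = integer(0), n = integer(0), K = integer(0),
                          N = integer(0), p = numeric(0), padj = numeric(0)))
  }
  rows <- lapply(seq_len(nrow(terms)), function(i) {
    g <- unique(ann$transcript_id[ann$term_id == terms$term_id[i] &
                                    ann$ontology == terms$ontology[i]])
    K <- length(g)
    k <- length(intersect(g, targets))
    tibble::tibble(term_id = terms$term_id[i], ontology = terms$ontology[i],
                   k = k, n = n, K = K, N = N,
                   p = phyper(k - 1, K, N - K, n, lower.tail = FALSE))
  })
  res <- dplyr::bind_rows(rows)
  res$padj <- NA_real_
  for (ont in unique(res$ontology)) {
    idx <- res$ontology == ont
    res$padj[idx] <- bh_adjust(res$p[idx])
  }
  res
}

#' Rank enrichment results and keep the top terms
#'
#' Orders by ascending adjusted p, breaking ties by descending target count
#' `k` and then by term id.
#'
#' @param results Tibble from [hypergeom_enrich()].
#' @param top_n Number of terms to keep.
#' @return The first `top_n` rows in rank order.
#' @export
rank_terms <- function(results, top_n = 10L) {
  ord <- order(results$padj, -results$k, results$term_id)
  results[ord, , drop = FALSE][seq_len(min(top_n, nrow(results))), ,
                               drop = FALSE]
}
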