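#' Match two piRNA sequences under the cross-species homology rule
#'
#' Sequences are anchored at their 5' ends and compared over positions
#' `1..min(length)`. They match iff positions 1-18 are identical and at
#' most one mismatch occurs among positions 19..min(length); any 3'
#' overhang of the longer sequence is ignored. Sequences shorter than 19 nt
#' cannot satisfy the rule. Inputs may use RNA U; it is normalised to T
#' before comparison.
#'
#' @param seq_a,seq_b Nucleotide strings (A/C/G/T/U).
#' @param seed_len Length of the 5' region that must match exactly.
#' @param max_tail_mismatch Mismatches tolerated after the seed.
#' @return A list (`seq_a`, `seq_b`, `overlap_len`, `mismatch_positions`,
#'   `n_mismatch`) on a match, otherwise `NULL`.
#' @export
match_pair <- function(seq_a, seq_b, seed_len = 18L, max_tail_mismatch = 1L) {
  a <- normalize_seq(seq_a)
  b <- normalize_seq(seq_b)
  assert_acgt(c(a, b), "piRNA sequence")
  L <- min(nchar(a), nchar(b))
  if (L < seed_len + 1L) return(NULL)
  if (substr(a, 1L, seed_len) != substr(b, 1L, seed_len)) return(NULL)
  ta <- charToRaw(substr(a, seed_len + 1L, L))
  tb <- charToRaw(substr(b, seed_len + 1L, L))
  mm <- which(ta != tb) + seed_len
  if (length(mm) > max_tail_mismatch) return(NULL)
  list(seq_a = seq_a, seq_b = seq_b, overlap_len = L,
       mismatch_positions = as.integer(mm), n_mismatch = length(mm))
}

#' Best homologous partner for a query piRNA
#'
#' Scores every matching candidate and returns the one with the fewest
#' mismatches, breaking ties by the longest overlap and then by the
#' lexicographically smallest candidate sequence, so the result is
#' deterministic.
#'
#' @param query Query piRNA sequence.
#' @param candidates Character vector of candidate sequences from the other
#'   species.
#' @inheritParams match_pair
#' @return The winning [match_pair()] result, or `NULL` if no candidate
#'   matches.
#' @export
best_pair <- function(query, candidates, seed_len = 18L,
                      max_tail_mismatch = 1L) {
  matches <- Filter(Negate(is.null),
                    lapply(candidates, function(b) {
                      match_pair(query, b, seed_len, max_tail_mismatch)
                    }))
  if (!length(matches)) return(NULL)
  mm <- vapply(matches, `[[`, integer(1), "n_mismatch")
  ov <- vapply(matches, `[[`, integer(1), "overlap_len")
  sq <- vapply(matches, `[[`, character(1), "seq_b")
  matches[[order(mm, -ov, sq)[1]]]
}

#' Partition two species' DE piRNA sets into common and unique piRNAs
#'
#' A sequence is "common" iff the homology rule matches it to at least one
#' sequence of the other species' DE set (membership-based, symmetric: if a
#' matches b, both are common); the unique sets are the complements. For
#' each common sequence of the first set the best pair is reported.
#'
#' @param de_set_a,de_set_b Character vectors of distinct DE piRNA
#'   sequences, one per species.
#' @inheritParams match_pair
#' @param one_to_one If `TRUE`, enforce strict one-to-one pairing by greedy
#'   best-score assignment; a sequence is then common only if it is part of
#'   an assigned pair.
#' @return List with `common_pairs` (tibble `seq_a`, `seq_b`,
#'   `overlap_len`, `n_mismatch`, `mismatch_positions`), `common_a`,
#'   `common_b`, `unique_a`, `unique_b`, and `counts`.
#' @export
partition_de_sets <- function(de_set_a, de_set_b, seed_len = 18L,
                              max_tail_mismatch = 1L, one_to_one = FALSE) {
  if (anyDuplicated(de_set_a) || anyDuplicated(de_set_b)) {
    stop("DE sets must be deduplicated", call. = FALSE)
  }
  a_norm <- normalize_seq(de_set_a)
  b_norm <- normalize_seq(de_set_b)
  if (length(a_norm)) assert_acgt(a_norm, "DE set A")
  if (length(b_norm)) assert_acgt(b_norm, "DE set B")

  # candidate pairs must share the exact 5' seed: group by seed prefix
  pa <- substr(a_norm, 1L, seed_len)
  pb <- substr(b_norm, 1L, seed_len)
  elig_a <- nchar(a_norm) >= seed_len + 1L
  elig_b <- nchar(b_norm) >= seed_len + 1L
  b_by_prefix <- split(which(elig_b), pb[elig_b])

  pairs <- list()
  matched_a <- logical(length(de_set_a))
  matched_b <- logical(length(de_set_b))
  for (i in which(elig_a)) {
    js <- b_by_prefix[[pa[i]]]
    if (is.null(js)) next
    best <- NULL
    for (j in js) {
      m <- match_pair(a_norm[i], b_norm[j], seed_len, max_tail_mismatch)
      if (is.null(m)) next
      matched_a[i] <- TRUE
      matched_b[j] <- TRUE
      if (is.null(best) ||
          m$n_mismatch < best$n_mismatch ||
          (m$n_mismatch == best$n_mismatch &&
             (m$overlap_len > best$overlap_len ||
                (m$overlap_len == best$overlap_len &&
                   b_norm[j] < best$seq_b)))) {
        best <- m
        best$j <- j
      }
    }
    if (!is.null(best)) {
      pairs[[length(pairs) + 1L]] <- tibble::tibble(
        seq_a = de_set_a[i], seq_b = de_set_b[best$j],
        overlap_len = best$overlap_len, n_mismatch = best$n_mismatch,
        mismatch_positions = paste(best$mismatch_positions, collapse = ","))
    }
  }
  common_pairs <- if (length(pairs)) {
    dplyr::bind_rows(pairs)
  } else {
    tibble::tibble(seq_a = character(0), seq_b = character(0),
                   overlap_len = integer(0), n_mismatch = integer(0),
                   mismatch_positions = character(0))
  }

  if (one_to_one && nrow(common_pairs)) {
    ord <- order(common_pairs$n_mismatch, -common_pairs$overlap_len,
                 common_pairs$seq_a, common_pairs$seq_b)
    used_a <- character(0); used_b <- character(0); keep <- integer(0)
    for (k in ord) {
      if (common_pairs$seq_a[k] %in% used_a ||
          common_pairs$seq_b[k] %in% used_b) next
      keep <- c(keep, k)
      used_a <- c(used_a, common_pairs$seq_a[k])
      used_b <- c(used_b, common_pairs$seq_b[k])
    }
    common_pairs <- common_pairs[sort(keep), , drop = FALSE]
    matched_a <- de_set_a %in% common_pairs$seq_a
    matched_b <- de_set_b %in% common_pairs$seq_b
  }

  res <- list(
    common_pairs = common_pairs,
    common_a = de_set_a[matched_a], common_b = de_set_b[matched_b],
    unique_a = de_set_a[!matched_a], unique_b = de_set_b[!matched_b])
  res$counts <- list(
    n_a = length(de_set_a), n_b = length(de_set_b),
    n_common_a = length(res$common_a), n_common_b = length(res$common_b),
    n_unique_a = length(res$unique_a), n_unique_b = length(res$unique_b))
  res
}

#' Construct a cross-species DE instance with a planted homology structure
#'
#' Builds two sets of distinct random piRNA sequences (lengths 24-32 nt) in
#' which exactly `n_common` cross-species pairs satisfy the homology rule
#' (positions 1-18 identical, at most one mismatch from position 19) and no
#' other cross-species pair does. Planted partners copy the first 18 bases
#' of their counterpart, may differ in length (the 3' overhang is ignored
#' by the rule), and carry one tail substitution with probability 0.5. The
#' construction is verified by an exhaustive all-pairs scan and resampled
#' until exact.
#'
#' @param n_a,n_b Set sizes.
#' @param n_common Planted rule-satisfying cross-species pairs.
#' @param seed Integer seed.
#' @param lengths Candidate sequence lengths.
#' @return List with `set_a`, `set_b` (character vectors) and `pairs`
#'   (tibble of the planted pairs).
#' @export
make_homology_instance <- function(n_a, n_b, n_common, seed = 1L,
                                   lengths = 24:32) {
  stopifnot(n_common <= n_a, n_common <= n_b, all(lengths >= 19L))
  withr::with_seed(seed, {
    repeat {
      set_a <- random_dna(sample(lengths, n_a, replace = TRUE))
      prefixes_a <- substr(set_a, 1, 18)
      if (anyDuplicated(set_a) || anyDuplicated(prefixes_a)) next

      set_b <- character(n_b)
      if (n_common > 0L) {
        for (i in seq_len(n_common)) {
          a <- set_a[i]
          lb <- sample(lengths, 1L)
          b <- if (lb <= nchar(a)) {
            substr(a, 1L, lb)
          } else {
            paste0(a, random_dna(lb - nchar(a)))
          }
          set_b[i] <- mutate_homolog(b)
        }
      }
      if (n_b > n_common) {
        idx <- seq(n_common + 1L, n_b)
        set_b[idx] <- random_dna(sample(lengths, length(idx), replace = TRUE))
      }
      prefixes_b <- substr(set_b, 1, 18)
      if (anyDuplicated(set_b) || anyDuplicated(prefixes_b)) next
      # non-planted prefixes must not collide with the other species
      extra <- setdiff(intersect(prefixes_a, prefixes_b),
                       prefixes_a[seq_len(n_common)])
      if (length(extra)) next

      # exhaustive verification of the planted structure via the seed index
      part <- partition_de_sets(set_a, set_b)
      ok <- part$counts$n_common_a == n_common &&
        part$counts$n_common_b == n_common &&
        setequal(part$common_a, set_a[seq_len(n_common)]) &&
        setequal(part$common_b, set_b[seq_len(n_common)])
      if (ok) break
    }
    list(set_a = set_a, set_b = set_b,
         pairs = tibble::tibble(seq_a = set_a[seq_len(n_common)],
                                seq_b = set_b[seq_len(n_common)]))
  })
}
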