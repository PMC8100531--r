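#' Trim the 3' sequencing adapter from reads
#'
#' Removes, from each read, the longest 3' suffix that exactly matches a
#' prefix of the adapter of length at least `min_overlap`; the quality
#' string is truncated in lockstep. Reads without such a suffix are left
#' unchanged.
#'
#' @param reads Read tibble (`read_id`, `seq`, `qual`).
#' @param adapter Adapter sequence (A/C/G/T).
#' @param min_overlap Minimum suffix/prefix overlap in nt (>= 1).
#' @return List with `reads` (trimmed tibble) and `n_trimmed` (reads that
#'   lost an adapter suffix).
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 5L) {
  stopifnot(min_overlap >= 1L)
  adapter <- toupper(adapter)
  assert_acgt(adapter, "adapter")
  seqs <- reads$seq
  n <- nchar(seqs)
  kmax <- min(nchar(adapter), max(n, 0L))
  trim_len <- integer(length(seqs))
  if (length(seqs) && kmax >= min_overlap) {
    for (k in seq(kmax, min_overlap)) {
      cand <- which(trim_len == 0L & n >= k)
      if (!length(cand)) next
      hit <- substr(seqs[cand], n[cand] - k + 1L, n[cand]) ==
        substr(adapter, 1L, k)
      trim_len[cand[hit]] <- k
    }
  }
  out <- reads
  keep_to <- n - trim_len
  out$seq <- substr(out$seq, 1L, keep_to)
  out$qual <- substr(out$qual, 1L, keep_to)
  list(reads = out, n_trimmed = sum(trim_len > 0L))
}

#' Construct read-filtering statistics
#'
#' Container for the raw/clean read accounting of a library. Enforces the
#' conservation invariant: every raw read is either clean or in exactly one
#' failure bin.
#'
#' @param n_raw,n_adapter_trimmed,n_fail_quality,n_fail_polyN
#'   ,n_fail_length_stage1,n_fail_length_stage2,n_clean Non-negative counts.
#' @return A list of class `read_stats`.
#' @export
read_stats <- function(n_raw, n_adapter_trimmed = 0L, n_fail_quality = 0L,
                       n_fail_polyN = 0L, n_fail_length_stage1 = 0L,
                       n_fail_length_stage2 = 0L, n_clean = 0L) {
  s <- list(n_raw = n_raw, n_adapter_trimmed = n_adapter_trimmed,
            n_fail_quality = n_fail_quality, n_fail_polyN = n_fail_polyN,
            n_fail_length_stage1 = n_fail_length_stage1,
            n_fail_length_stage2 = n_fail_length_stage2, n_clean = n_clean)
  if (any(unlist(s) < 0)) {
    stop("read statistics must be non-negative", call. = FALSE)
  }
  fails <- n_fail_quality + n_fail_polyN + n_fail_length_stage1 +
    n_fail_length_stage2
  if (n_clean != n_raw - fails) {
    stop("invalid read statistics: n_clean must equal n_raw minus the ",
         "failure bins", call. = FALSE)
  }
  structure(s, class = "read_stats")
}

#' Filter reads by quality, ambiguity and the two length windows
#'
#' Reads are tested, in order, against: mean Phred quality (fail if below
#' `min_mean_quality`), poly-N content (fail if more than `max_n_frac` of
#' bases are N), the stage-1 length window (the clean-read window), and the
#' stage-2 length window (the piRNA-range window). Both windows are
#' inclusive and stage 2 must be nested in stage 1. Each read lands in
#' exactly one failure bin or in the clean set.
#'
#' @param reads Read tibble (`read_id`, `seq`, `qual`).
#' @param stage1_window,stage2_window Inclusive length windows in nt.
#' @param max_n_frac Maximum tolerated fraction of N bases.
#' @param min_mean_quality Minimum mean Phred score.
#' @param n_adapter_trimmed Carried into the returned statistics.
#' @return List with `reads` (clean read tibble) and `stats`
#'   (a [read_stats()]).
#' @export
filter_reads <- function(reads, stage1_window = c(18L, 34L),
                         stage2_window = c(24L, 32L), max_n_frac = 0.1,
                         min_mean_quality = 20, n_adapter_trimmed = 0L) {
  stopifnot(stage2_window[1] >= stage1_window[1],
            stage2_window[2] <= stage1_window[2])
  n_raw <- nrow(reads)
  if (n_raw == 0L) {
    return(list(reads = reads,
                stats = read_stats(0L, n_adapter_trimmed = n_adapter_trimmed)))
  }
  len <- nchar(reads$seq)
  fail_qual <- len == 0L | mean_phred(reads$qual) < min_mean_quality
  fail_polyn <- !fail_qual & n_fraction(reads$seq) > max_n_frac
  prev <- fail_qual | fail_polyn
  fail_s1 <- !prev & (len < stage1_window[1] | len > stage1_window[2])
  prev <- prev | fail_s1
  fail_s2 <- !prev & (len < stage2_window[1] | len > stage2_window[2])
  clean <- !(prev | fail_s2)
  list(
    reads = reads[clean, , drop = FALSE],
    stats = read_stats(
      n_raw = n_raw, n_adapter_trimmed = n_adapter_trimmed,
      n_fail_quality = sum(fail_qual), n_fail_polyN = sum(fail_polyn),
      n_fail_length_stage1 = sum(fail_s1),
      n_fail_length_stage2 = sum(fail_s2), n_clean = sum(clean))
  )
}

#' Adapter-trim and filter a raw library in one step
#'
#' @inheritParams trim_adapter
#' @inheritParams filter_reads
#' @return List with `reads` (clean read tibble) and `stats`.
#' @export
clean_reads <- function(reads, adapter, min_overlap = 5L,
                        stage1_window = c(18L, 34L),
                        stage2_window = c(24L, 32L),
                        max_n_frac = 0.1, min_mean_quality = 20) {
  tr <- trim_adapter(reads, adapter, min_overlap)
  filter_reads(tr$reads, stage1_window, stage2_window, max_n_frac,
               min_mean_quality, n_adapter_trimmed = tr$n_trimmed)
}

#' Summarise read statistics as a one-row table
#'
#' Columns follow the sequencing-overview table layout: raw reads first,
#' clean reads second, then the failure bins.
#'
#' @param stats A [read_stats()].
#' @return One-row tibble.
#' @export
summarize_read_stats <- function(stats) {
  stopifnot(inherits(stats, "read_stats"))
  tibble::tibble(
    raw_reads = stats$n_raw, clean_reads = stats$n_clean,
    adapter_trimmed = stats$n_adapter_trimmed,
    fail_quality = stats$n_fail_quality, fail_polyN = stats$n_fail_polyN,
    fail_length_stage1 = stats$n_fail_length_stage1,
    fail_length_stage2 = stats$n_fail_length_stage2
  )
}
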