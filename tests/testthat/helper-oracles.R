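# Independent reference implementations used as oracles. These are written
# against the definitions directly (brute force / enumeration) and share no
# code with the package internals they check.

# Small simulation configuration used across tests.
small_cfg <- function(seed = 7L, ...) {
  args <- list(
    seed = seed, chrom_length = 30000L, n_clusters = 3L,
    cluster_span = 1200L, pirnas_per_cluster = 15L, n_ncrna_loci = 6L,
    reads_per_library = 3000L, n_transcripts = 20L,
    transcript_length = 300L, n_homolog_pairs = 4L)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

rand_seq <- function(n, len) {
  vapply(rep(len, length.out = n), function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
}

# Homology rule, straight from the definition: positions 1-18 identical,
# at most one mismatching position among 19..min(length).
oracle_match_pair <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  L <- min(length(ca), length(cb))
  if (L < 19) return(FALSE)
  if (any(ca[1:18] != cb[1:18])) return(FALSE)
  sum(ca[19:L] != cb[19:L]) <= 1
}

# Longest read suffix equal to an adapter prefix, by exhaustive scan.
oracle_trim_len <- function(seq, adapter, min_overlap) {
  best <- 0L
  for (k in seq_len(min(nchar(seq), nchar(adapter)))) {
    if (k < min_overlap) next
    if (substr(seq, nchar(seq) - k + 1L, nchar(seq)) ==
        substr(adapter, 1L, k)) {
      best <- k
    }
  }
  best
}

# Naive all-windows genome scan: every offset, both strands, count
# substitutions directly on character vectors.
oracle_map_scan <- function(s, genome, max_mismatch) {
  rc <- function(x) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    paste(rev(unname(comp[strsplit(x, "")[[1]]])), collapse = "")
  }
  out <- list()
  L <- nchar(s)
  for (ch in names(genome)) {
    gch <- strsplit(genome[[ch]], "")[[1]]
    if (L > length(gch)) next
    offsets <- seq_len(length(gch) - L + 1L)
    for (std in c("+", "-")) {
      pat <- strsplit(if (std == "+") s else rc(s), "")[[1]]
      mm <- integer(length(offsets))
      for (j in seq_len(L)) {
        mm <- mm + as.integer(gch[offsets + j - 1L] != pat[j])
      }
      hit <- which(mm <= max_mismatch)
      if (length(hit)) {
        out[[length(out) + 1L]] <- data.frame(
          seq = s, chrom = ch, start = hit - 1L, end = hit - 1L + L,
          strand = std, mismatches = mm[hit], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(seq = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0)))
  }
  do.call(rbind, out)
}

# Exact NB test by direct enumeration with an explicitly coded pmf.
oracle_nb_pmf <- function(x, mu, size) {
  exp(lgamma(x + size) - lgamma(size) - lfactorial(x) +
        size * log(size / (size + mu)) + x * log(mu / (size + mu)))
}

oracle_nb_exact <- function(ka, kb, size) {
  s <- ka + kb
  if (s == 0) return(1)
  mu <- s / 2
  probs <- numeric(s + 1L)
  for (a in 0:s) {
    probs[a + 1L] <- oracle_nb_pmf(a, mu, size) *
      oracle_nb_pmf(s - a, mu, size)
  }
  obs <- probs[ka + 1L]
  min(1, sum(probs[probs <= obs * (1 + 1e-8)]) / sum(probs))
}

# Benjamini-Hochberg step-up, from the definition.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Hypergeometric upper tail by combinatorial enumeration.
oracle_hyper_tail <- function(N, K, n, k) {
  if (k <= 0) return(1)
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Naive O(n^3) complete-linkage agglomeration; returns sorted merge heights.
oracle_complete_heights <- function(m) {
  groups <- lapply(seq_len(nrow(m)), identity)
  d <- as.matrix(dist(m))
  heights <- numeric(0)
  while (length(groups) > 1L) {
    best <- c(NA, NA)
    best_h <- Inf
    for (i in seq_along(groups)) {
      for (j in seq_along(groups)) {
        if (j <= i) next
        h <- max(d[groups[[i]], groups[[j]]])
        if (h < best_h) {
          best_h <- h
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, best_h)
    groups[[best[1]]] <- c(groups[[best[1]]], groups[[best[2]]])
    groups[[best[2]]] <- NULL
  }
  sort(heights)
}

# Exhaustive antisense target scan: every transcript offset, seed exact,
# total substitutions bounded.
oracle_target_scan <- function(pirna, transcripts, seed_start = 2L,
                               seed_end = 11L, max_mismatch = 2L) {
  rc <- function(x) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    paste(rev(unname(comp[strsplit(x, "")[[1]]])), collapse = "")
  }
  L <- nchar(pirna)
  site <- strsplit(rc(pirna), "")[[1]]
  seed_idx <- (L - seed_end + 1L):(L - seed_start + 1L)
  out <- list()
  for (tx in names(transcripts)) {
    tchr <- strsplit(transcripts[[tx]], "")[[1]]
    if (L > length(tchr)) next
    for (off in seq_len(length(tchr) - L + 1L)) {
      win <- tchr[off:(off + L - 1L)]
      if (any(win[seed_idx] != site[seed_idx])) next
      if (sum(win != site) <= max_mismatch) {
        out[[length(out) + 1L]] <- data.frame(
          pirna_seq = pirna, transcript_id = tx, position = off - 1L,
          mismatches = sum(win != site), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(pirna_seq = character(0), transcript_id = character(0),
                      position = integer(0), mismatches = integer(0)))
  }
  do.call(rbind, out)
}
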