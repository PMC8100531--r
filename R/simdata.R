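#' Simulation configuration for synthetic sperm small RNA experiments
#'
#' Builds and validates the configuration driving the synthetic-data
#' generator. The generator emulates the design of a two-species sperm
#' cryopreservation study: for each species one pooled library per condition
#' (fresh, frozen-thawed), piRNA-sized reads (24-32 nt) with a 5'-uridine
#' bias arranged in genomic clusters, ncRNA/adapter/poly-N/low-quality
#' contamination, and condition-specific negative-binomial abundance shifts.
#'
#' @param seed Integer seed; all downstream randomness derives from it.
#' @param n_chromosomes Chromosomes per toy genome.
#' @param chrom_length Chromosome length in nt.
#' @param n_clusters Planted piRNA clusters per species.
#' @param cluster_span Span of each planted cluster in nt.
#' @param pirnas_per_cluster Distinct planted piRNAs per cluster.
#' @param pirna_length_dist Named probability vector over lengths 24..32.
#' @param u1_bias Probability that a planted piRNA starts with U (T in DNA).
#' @param n_ncrna_loci ncRNA loci (rRNA/tRNA/snRNA/snoRNA/repeat) per genome.
#' @param n_homolog_pairs Cross-species piRNA pairs planted to satisfy the
#'   homology rule (positions 1-18 identical, at most one mismatch from
#'   position 19).
#' @param reads_per_library Approximate reads per simulated library.
#' @param nb_mean_range Range of per-piRNA negative-binomial mean counts.
#' @param nb_dispersion Negative-binomial dispersion (variance =
#'   mean + mean^2 * dispersion).
#' @param de_fraction Fraction of planted piRNAs that are differentially
#'   expressed between conditions.
#' @param de_up_fraction Fraction of DE piRNAs upregulated in frozen-thawed.
#' @param de_log2fc Absolute planted log2 fold change of DE piRNAs.
#' @param adapter_seq 3' sequencing adapter ligated to every read.
#' @param contam_fraction Fraction of contaminant reads per library, split
#'   evenly among ncRNA fragments, adapter dimers, poly-N reads,
#'   out-of-window genome fragments, and low-quality reads.
#' @param read_length Instrument read length in nt (reads are the insert
#'   plus the adapter, truncated at this length).
#' @param n_transcripts Synthetic transcripts per species transcriptome.
#' @param transcript_length Transcript length in nt.
#' @param species Character vector of two species labels.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chrom_length = 100000L,
                       n_clusters = 8L,
                       cluster_span = 2000L,
                       pirnas_per_cluster = 25L,
                       pirna_length_dist = c(
                         `24` = 0.08, `25` = 0.08, `26` = 0.10, `27` = 0.12,
                         `28` = 0.14, `29` = 0.16, `30` = 0.16, `31` = 0.10,
                         `32` = 0.06),
                       u1_bias = 0.8,
                       n_ncrna_loci = 20L,
                       n_homolog_pairs = 10L,
                       reads_per_library = 20000L,
                       nb_mean_range = c(20, 200),
                       nb_dispersion = 0.1,
                       de_fraction = 0.1,
                       de_up_fraction = 0.5,
                       de_log2fc = 3,
                       adapter_seq = "TGGAATTCTCGGGTGCCAAGG",
                       contam_fraction = 0.1,
                       read_length = 50L,
                       n_transcripts = 60L,
                       transcript_length = 500L,
                       species = c("species_a", "species_b")) {
  cfg <- list(
    seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.integer(chrom_length),
    n_clusters = as.integer(n_clusters),
    cluster_span = as.integer(cluster_span),
    pirnas_per_cluster = as.integer(pirnas_per_cluster),
    pirna_length_dist = pirna_length_dist, u1_bias = u1_bias,
    n_ncrna_loci = as.integer(n_ncrna_loci),
    n_homolog_pairs = as.integer(n_homolog_pairs),
    reads_per_library = as.integer(reads_per_library),
    nb_mean_range = nb_mean_range, nb_dispersion = nb_dispersion,
    de_fraction = de_fraction, de_up_fraction = de_up_fraction,
    de_log2fc = de_log2fc, adapter_seq = toupper(adapter_seq),
    contam_fraction = contam_fraction, read_length = as.integer(read_length),
    n_transcripts = as.integer(n_transcripts),
    transcript_length = as.integer(transcript_length),
    species = species
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  props <- c(u1_bias = cfg$u1_bias, de_fraction = cfg$de_fraction,
             de_up_fraction = cfg$de_up_fraction,
             contam_fraction = cfg$contam_fraction)
  if (any(props < 0 | props > 1)) {
    stop("configuration error: proportions must lie in [0, 1]", call. = FALSE)
  }
  d <- cfg$pirna_length_dist
  if (is.null(names(d)) ||
      !all(names(d) %in% as.character(24:32)) ||
      abs(sum(d) - 1) > 1e-8 || any(d < 0)) {
    stop("configuration error: pirna_length_dist must be a probability ",
         "vector named over lengths 24..32 summing to 1", call. = FALSE)
  }
  if (cfg$nb_dispersion <= 0) {
    stop("configuration error: nb_dispersion must be > 0", call. = FALSE)
  }
  if (cfg$chrom_length <= cfg$n_clusters * cfg$cluster_span) {
    stop("configuration error: chrom_length must exceed ",
         "n_clusters * cluster_span", call. = FALSE)
  }
  if (cfg$n_clusters > 0 && cfg$cluster_span < cfg$pirnas_per_cluster * 40L) {
    stop("configuration error: cluster_span must be at least 40 nt per ",
         "planted piRNA so loci do not overlap", call. = FALSE)
  }
  if (length(cfg$species) != 2L || anyDuplicated(cfg$species)) {
    stop("configuration error: exactly two distinct species labels required",
         call. = FALSE)
  }
  assert_acgt(cfg$adapter_seq, "adapter_seq")
  invisible(cfg)
}

# Lengths drawn from the configured piRNA length distribution.
draw_pirna_lengths <- function(n, cfg) {
  as.integer(sample(names(cfg$pirna_length_dist), n, replace = TRUE,
                    prob = cfg$pirna_length_dist))
}

# Place n disjoint intervals of width `span` on chromosomes, round-robin.
place_cluster_intervals <- function(cfg) {
  if (cfg$n_clusters == 0L) {
    return(tibble::tibble(chrom = character(0), start = integer(0),
                          end = integer(0), cluster_id = character(0)))
  }
  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
  assign_chrom <- chroms[((seq_len(cfg$n_clusters) - 1L) %%
                            cfg$n_chromosomes) + 1L]
  out <- lapply(chroms, function(ch) {
    k <- sum(assign_chrom == ch)
    if (k == 0L) return(NULL)
    # carve the chromosome into k equal slots and centre one cluster per slot
    slot <- cfg$chrom_length %/% k
    if (slot <= cfg$cluster_span + 2L) {
      stop("configuration error: chromosomes too short for requested clusters",
           call. = FALSE)
    }
    offs <- vapply(seq_len(k), function(i) {
      sample.int(slot - cfg$cluster_span - 1L, 1L)
    }, integer(1))
    start <- (seq_len(k) - 1L) * slot + offs
    tibble::tibble(chrom = ch, start = start, end = start + cfg$cluster_span)
  })
  res <- dplyr::bind_rows(out)
  res$cluster_id <- sprintf("cluster_%02d", seq_len(nrow(res)))
  res
}

# Non-overlapping piRNA loci within one cluster interval: a regular grid
# with per-locus jitter, spacing >= 40 nt so loci never touch.
place_pirna_loci <- function(cluster, cfg) {
  k <- cfg$pirnas_per_cluster
  pitch <- (cluster$end - cluster$start) %/% k
  lens <- draw_pirna_lengths(k, cfg)
  jitter <- vapply(seq_len(k), function(i) {
    sample.int(max(pitch - 33L, 1L), 1L) - 1L
  }, integer(1))
  start <- cluster$start + (seq_len(k) - 1L) * pitch + jitter
  tibble::tibble(chrom = cluster$chrom, start = start, end = start + lens)
}

# Introduce at most one substitution at a position >= 19 of a homolog copy.
mutate_homolog <- function(seq) {
  L <- nchar(seq)
  if (L < 19L || runif(1) < 0.5) return(seq)
  pos <- if (L == 19L) 19L else sample(19:L, 1L)
  old <- substr(seq, pos, pos)
  new <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
  paste0(substr(seq, 1L, pos - 1L), new, substr(seq, pos + 1L, L))
}

#' Generate two toy species genomes with planted piRNA truth
#'
#' Creates one random genome per species, plants `n_clusters` disjoint piRNA
#' clusters per genome (each holding `pirnas_per_cluster` distinct,
#' non-overlapping piRNA loci whose 5' base is forced to T with probability
#' `u1_bias`), plants `n_homolog_pairs` cross-species homologous piRNAs
#' satisfying the homology rule, assigns negative-binomial condition means
#' with a `de_fraction` of differentially expressed piRNAs, and verifies the
#' planted homolog list by brute force over all cross-species pairs.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `pirna_sim` with elements `genomes` (per species,
#'   named character vector of chromosome sequences) and `truth` (a list
#'   with `planted_clusters`, `planted_pirnas`, `homolog_pairs`).
#' @export
generate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  validate_sim_config(cfg)
  withr::with_seed(cfg$seed, {
    genomes <- list()
    clusters <- list()
    loci <- list()
    for (sp in cfg$species) {
      chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
      genome <- setNames(random_dna(rep(cfg$chrom_length,
                                        cfg$n_chromosomes)), chroms)
      cl <- place_cluster_intervals(cfg)
      if (nrow(cl)) {
        pl <- dplyr::bind_rows(lapply(seq_len(nrow(cl)), function(i) {
          x <- place_pirna_loci(cl[i, ], cfg)
          x$cluster_id <- cl$cluster_id[i]
          x
        }))
        # force the 5'-U (DNA T) signature directly into the genome
        u1 <- runif(nrow(pl)) < cfg$u1_bias
        for (i in which(u1)) {
          ch <- pl$chrom[i]
          substr(genome[[ch]], pl$start[i] + 1L, pl$start[i] + 1L) <- "T"
        }
      } else {
        pl <- tibble::tibble(chrom = character(0), start = integer(0),
                             end = integer(0), cluster_id = character(0))
      }
      genomes[[sp]] <- genome
      cl$species <- rep(sp, nrow(cl))
      pl$species <- rep(sp, nrow(pl))
      clusters[[sp]] <- cl
      loci[[sp]] <- pl
    }

    # plant cross-species homologs: copy (and lightly mutate) piRNA loci of
    # species A into the first loci of species B
    sp_a <- cfg$species[1]; sp_b <- cfg$species[2]
    n_hom <- min(cfg$n_homolog_pairs, nrow(loci[[sp_a]]), nrow(loci[[sp_b]]))
    if (n_hom > 0L) {
      for (i in seq_len(n_hom)) {
        a <- loci[[sp_a]][i, ]
        seq_a <- substr(genomes[[sp_a]][[a$chrom]], a$start + 1L, a$end)
        seq_b <- mutate_homolog(seq_a)
        b <- loci[[sp_b]][i, ]
        new_end <- b$start + nchar(seq_b)
        substr(genomes[[sp_b]][[b$chrom]], b$start + 1L, new_end) <- seq_b
        loci[[sp_b]]$end[i] <- new_end
      }
    }

    pl_all <- dplyr::bind_rows(loci)
    pl_all$strand <- rep("+", nrow(pl_all))
    pl_all$seq <- vapply(seq_len(nrow(pl_all)), function(i) {
      substr(genomes[[pl_all$species[i]]][[pl_all$chrom[i]]],
             pl_all$start[i] + 1L, pl_all$end[i])
    }, character(1))
    if (nrow(pl_all) &&
        anyDuplicated(paste(pl_all$species, pl_all$seq))) {
      stop("internal simulation error: planted piRNA sequences collide",
           call. = FALSE)
    }

    # condition means and planted DE labels, per species
    if (nrow(pl_all)) {
      pl_all <- dplyr::bind_rows(lapply(split(pl_all, pl_all$species),
                                        assign_expression, cfg = cfg))
    } else {
      pl_all <- tibble::tibble(
        chrom = character(0), start = integer(0), end = integer(0),
        cluster_id = character(0), species = character(0),
        strand = character(0), seq = character(0), fresh_mean = numeric(0),
        frozen_mean = numeric(0), is_de = logical(0), direction = integer(0))
    }

    truth <- list(
      planted_clusters = dplyr::bind_rows(clusters),
      planted_pirnas = pl_all,
      homolog_pairs = planted_homolog_pairs(pl_all, cfg, n_hom)
    )
    verify_homolog_truth(truth, cfg)
    structure(list(genomes = genomes, truth = truth, config = cfg),
              class = "pirna_sim")
  })
}

assign_expression <- function(pl, cfg) {
  n <- nrow(pl)
  pl$fresh_mean <- runif(n, cfg$nb_mean_range[1], cfg$nb_mean_range[2])
  n_de <- round(cfg$de_fraction * n)
  is_de <- rep(FALSE, n)
  if (n_de > 0) is_de[sample.int(n, n_de)] <- TRUE
  dir <- rep(0L, n)
  dir[is_de] <- ifelse(runif(sum(is_de)) < cfg$de_up_fraction, 1L, -1L)
  pl$frozen_mean <- pl$fresh_mean * 2^(cfg$de_log2fc * dir)
  pl$is_de <- is_de
  pl$direction <- dir
  pl
}

planted_homolog_pairs <- function(pl_all, cfg, n_hom) {
  if (n_hom == 0L) {
    return(tibble::tibble(seq_a = character(0), seq_b = character(0)))
  }
  a <- pl_all[pl_all$species == cfg$species[1], ]
  b <- pl_all[pl_all$species == cfg$species[2], ]
  tibble::tibble(seq_a = a$seq[seq_len(n_hom)], seq_b = b$seq[seq_len(n_hom)])
}

# Brute-force cross-species scan over every planted pair: the listed
# homolog pairs, and only those, must satisfy the homology rule.
verify_homolog_truth <- function(truth, cfg) {
  pl <- truth$planted_pirnas
  a <- pl$seq[pl$species == cfg$species[1]]
  b <- pl$seq[pl$species == cfg$species[2]]
  found <- list()
  for (x in a) {
    for (y in b) {
      if (!is.null(match_pair(x, y))) found[[length(found) + 1L]] <- c(x, y)
    }
  }
  found_tab <- if (length(found)) {
    do.call(rbind, found)
  } else {
    matrix(character(0), ncol = 2)
  }
  planted <- truth$homolog_pairs
  key_found <- sort(paste(found_tab[, 1], found_tab[, 2]))
  key_plant <- sort(paste(planted$seq_a, planted$seq_b))
  if (!identical(key_found, key_plant)) {
    stop("internal simulation error: planted homolog truth failed ",
         "brute-force verification", call. = FALSE)
  }
  invisible(TRUE)
}

#' Generate ncRNA loci, transcript models and GO/KEGG annotation maps
#'
#' ncRNA loci (rRNA, tRNA, snRNA, snoRNA, repeats) are genomic intervals
#' disjoint from the planted piRNA clusters; their sequences feed both the
#' ncRNA read filter and the ncRNA-fragment contaminant class. Transcript
#' models are synthetic sequences, a subset of which carry an antisense site
#' for a planted piRNA so the target-prediction stage has signal. GO and
#' KEGG maps are two-column transcript-to-term tables.
#'
#' @param sim A `pirna_sim` from [generate_genome()].
#' @param cfg The same [sim_config()].
#' @return A list of class `pirna_annotations` with per-species elements
#'   `ncrna` (BED-like tibble plus `seq`), `transcripts` (named character),
#'   `go_map` and `kegg_map` (tibbles `transcript_id`, `term_id`,
#'   `ontology`).
#' @export
generate_annotations <- function(sim, cfg = sim$config) {
  stopifnot(inherits(sim, "pirna_sim"))
  withr::with_seed(cfg$seed + 2000L, {
    ann <- list()
    for (sp in cfg$species) {
      genome <- sim$genomes[[sp]]
      clusters <- sim$truth$planted_clusters
      clusters <- clusters[clusters$species == sp, , drop = FALSE]
      ncrna <- place_ncrna_loci(genome, clusters, cfg)
      transcripts <- make_transcripts(sim, sp, cfg)
      maps <- make_annotation_maps(names(transcripts))
      ann[[sp]] <- list(ncrna = ncrna, transcripts = transcripts,
                        go_map = maps$go, kegg_map = maps$kegg)
    }
    structure(ann, class = "pirna_annotations")
  })
}

place_ncrna_loci <- function(genome, clusters, cfg) {
  classes <- c("rRNA", "tRNA", "snRNA", "snoRNA", "repeat")
  n <- cfg$n_ncrna_loci
  empty <- tibble::tibble(chrom = character(0), start = integer(0),
                          end = integer(0), name = character(0),
                          score = integer(0), strand = character(0),
                          seq = character(0))
  if (n == 0L) return(empty)
  chroms <- names(genome)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    width <- sample(80:300, 1L)
    for (try in seq_len(200L)) {
      ch <- sample(chroms, 1L)
      s <- sample.int(cfg$chrom_length - width, 1L) - 1L
      e <- s + width
      cl <- clusters[clusters$chrom == ch, , drop = FALSE]
      clash_cluster <- nrow(cl) > 0 && any(s < cl$end & e > cl$start)
      placed <- if (i > 1L) dplyr::bind_rows(out[seq_len(i - 1L)]) else NULL
      pl <- placed[placed$chrom %in% ch, , drop = FALSE]
      clash_prev <- !is.null(pl) && nrow(pl) > 0 && any(s < pl$end & e > pl$start)
      if (!clash_cluster && !clash_prev) break
    }
    if (clash_cluster || clash_prev) {
      stop("could not place ncRNA loci disjoint from planted clusters",
           call. = FALSE)
    }
    cls <- classes[((i - 1L) %% length(classes)) + 1L]
    out[[i]] <- tibble::tibble(
      chrom = ch, start = s, end = e,
      name = sprintf("%s_%02d", cls, i), score = 0L, strand = "+",
      seq = substr(genome[[ch]], s + 1L, e))
  }
  dplyr::bind_rows(out)
}

make_transcripts <- function(sim, sp, cfg) {
  n <- cfg$n_transcripts
  if (n == 0L) return(setNames(character(0), character(0)))
  tx <- random_dna(rep(cfg$transcript_length, n))
  names(tx) <- sprintf("%s_tx%03d", sp, seq_len(n))
  pl <- sim$truth$planted_pirnas
  pl <- pl[pl$species == sp, , drop = FALSE]
  if (nrow(pl)) {
    # plant antisense piRNA sites in half the transcripts
    host <- sample.int(n, n %/% 2L)
    donors <- sample(pl$seq, length(host), replace = TRUE)
    for (j in seq_along(host)) {
      site <- revcomp(donors[j])
      pos <- sample.int(cfg$transcript_length - nchar(site), 1L)
      substr(tx[[host[j]]], pos, pos + nchar(site) - 1L) <- site
    }
  }
  tx
}

make_annotation_maps <- function(tx_ids) {
  go_pool <- sprintf("GO:%07d", 1:15)
  kegg_pool <- sprintf("ko%05d", 1:8)
  draw <- function(pool, lambda, ontology) {
    rows <- lapply(tx_ids, function(id) {
      k <- min(rpois(1, lambda), length(pool))
      if (k == 0L) return(NULL)
      tibble::tibble(transcript_id = id, term_id = sample(pool, k),
                     ontology = ontology)
    })
    dplyr::bind_rows(rows)
  }
  list(go = draw(go_pool, 1.5, "GO"), kegg = draw(kegg_pool, 0.8, "KEGG"))
}

#' Draw negative-binomial counts for paired conditions
#'
#' Counts follow NB(mean, dispersion) with variance
#' `mean + mean^2 * dispersion`.
#'
#' @param fresh_mean,frozen_mean Numeric vectors of per-feature means.
#' @param dispersion NB dispersion (scalar or per-feature).
#' @param seed Optional integer seed.
#' @return Integer matrix with columns `fresh` and `frozen`.
#' @export
simulate_counts <- function(fresh_mean, frozen_mean, dispersion, seed = NULL) {
  stopifnot(length(fresh_mean) == length(frozen_mean), all(dispersion > 0))
  draw <- function() {
    cbind(fresh  = rnbinom(length(fresh_mean), mu = fresh_mean,
                           size = 1 / dispersion),
          frozen = rnbinom(length(frozen_mean), mu = frozen_mean,
                           size = 1 / dispersion))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Simulate the four condition libraries as read sets
#'
#' For each species and condition, planted piRNA read counts are drawn from
#' the truth's negative-binomial means (scaled so the signal portion of the
#' library is close to `reads_per_library * (1 - contam_fraction)`), then
#' contaminant reads are added in five equal classes: ncRNA fragments,
#' adapter dimers, poly-N reads, out-of-window genome fragments, and
#' low-quality reads. Every read carries the 3' adapter and Phred+33
#' qualities.
#'
#' @param sim A `pirna_sim` from [generate_genome()].
#' @param ann A `pirna_annotations` from [generate_annotations()]
#'   (source of ncRNA contaminant fragments).
#' @param cfg The same [sim_config()].
#' @return Named list of read tibbles, one per `<species>.<condition>` with
#'   conditions `fresh` and `frozen`.
#' @export
simulate_libraries <- function(sim, ann, cfg = sim$config) {
  stopifnot(inherits(sim, "pirna_sim"))
  if (missing(ann) || is.null(ann)) {
    stop("annotations are required (ncRNA contaminants are drawn from them); ",
         "run generate_annotations() first", call. = FALSE)
  }
  withr::with_seed(cfg$seed + 1000L, {
    libs <- list()
    for (sp in cfg$species) {
      pl <- sim$truth$planted_pirnas
      pl <- pl[pl$species == sp, , drop = FALSE]
      for (cond in c("fresh", "frozen")) {
        libs[[paste(sp, cond, sep = ".")]] <-
          simulate_one_library(pl, sim$genomes[[sp]], ann[[sp]], cfg, sp, cond)
      }
    }
    libs
  })
}

simulate_one_library <- function(pl, genome, ann_sp, cfg, sp, cond) {
  n_target <- cfg$reads_per_library
  n_contam <- round(cfg$contam_fraction * n_target)
  n_signal_target <- n_target - n_contam

  sig_seqs <- character(0)
  if (nrow(pl) && n_signal_target > 0L) {
    mu <- if (cond == "fresh") pl$fresh_mean else pl$frozen_mean
    mu <- mu * n_signal_target / sum(mu)
    counts <- rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion)
    sig_seqs <- rep(pl$seq, counts)
  }

  contam <- make_contaminants(n_contam, genome, ann_sp, cfg)
  seqs <- c(sig_seqs, contam$seq)
  lowq <- c(rep(FALSE, length(sig_seqs)), contam$lowq)
  polyn <- c(rep(FALSE, length(sig_seqs)), contam$polyn)

  # library geometry: insert + 3' adapter, truncated at the read length
  raw <- substr(paste0(seqs, cfg$adapter_seq), 1L, cfg$read_length)
  raw[polyn] <- seqs[polyn]   # poly-N junk carries no adapter
  qual <- vapply(nchar(raw), function(n) {
    paste(intToUtf8(sample(30:40, n, replace = TRUE) + 33L,
                    multiple = TRUE), collapse = "")
  }, character(1))
  if (any(lowq)) {
    qual[lowq] <- vapply(nchar(raw[lowq]), function(n) {
      paste(intToUtf8(sample(2:15, n, replace = TRUE) + 33L,
                      multiple = TRUE), collapse = "")
    }, character(1))
  }
  ord <- sample.int(length(raw))
  new_read_set(
    read_id = sprintf("%s_%s_%06d", sp, cond, seq_along(raw)),
    seq = raw[ord], qual = qual[ord]
  )
}

make_contaminants <- function(n_contam, genome, ann_sp, cfg) {
  if (n_contam <= 0L) {
    return(list(seq = character(0), lowq = logical(0), polyn = logical(0)))
  }
  per <- diff(round(seq(0, n_contam, length.out = 6L)))
  frag_from <- function(sources, lens) {
    vapply(lens, function(L) {
      src <- sources[[sample.int(length(sources), 1L)]]
      if (nchar(src) <= L) return(substr(src, 1L, L))
      s <- sample.int(nchar(src) - L, 1L)
      substr(src, s, s + L - 1L)
    }, character(1))
  }
  # 1. ncRNA fragments (clean length/quality, removed by the ncRNA filter)
  ncrna_src <- ann_sp$ncrna$seq
  if (length(ncrna_src) == 0L) ncrna_src <- random_dna(rep(200L, 3L))
  c1 <- frag_from(as.list(ncrna_src), draw_pirna_lengths(per[1], cfg))
  # 2. adapter dimers: very short inserts (fail the stage-1 length window)
  c2 <- random_dna(sample(0:10, per[2], replace = TRUE))
  # 3. poly-N reads
  c3 <- strrep("N", rep(28L, per[3]))
  # 4. genome fragments with out-of-window lengths (stage-1 or stage-2 fails)
  c4 <- frag_from(as.list(unname(genome)),
                  sample(c(16L, 17L, 22L, 23L, 33L, 35L), per[4],
                         replace = TRUE))
  # 5. well-formed fragments destined to fail the mean-quality filter
  c5 <- frag_from(as.list(unname(genome)), draw_pirna_lengths(per[5], cfg))
  list(
    seq = c(c1, c2, c3, c4, c5),
    lowq = c(rep(FALSE, per[1] + per[2] + per[3] + per[4]),
             rep(TRUE, per[5])),
    polyn = c(rep(FALSE, per[1] + per[2]), rep(TRUE, per[3]),
              rep(FALSE, per[4] + per[5]))
  )
}

#' Write all simulated artifacts to disk
#'
#' Writes per-species genome FASTA, ncRNA BED6 + FASTA, planted-cluster
#' BED6, transcript FASTA, GO/KEGG TSV maps, truth tables as TSV, and one
#' FASTQ per library.
#'
#' @param sim A `pirna_sim`.
#' @param ann A `pirna_annotations`.
#' @param libs Library list from [simulate_libraries()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, ann, libs, dir) {
  cfg <- sim$config
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sp in cfg$species) {
    write_fasta(sim$genomes[[sp]], file.path(dir, paste0(sp, "_genome.fa")))
    a <- ann[[sp]]
    write_bed(a$ncrna, file.path(dir, paste0(sp, "_ncrna.bed")))
    if (nrow(a$ncrna)) {
      write_fasta(setNames(a$ncrna$seq, a$ncrna$name),
                  file.path(dir, paste0(sp, "_ncrna.fa")))
    }
    cl <- sim$truth$planted_clusters
    cl <- cl[cl$species == sp, , drop = FALSE]
    cl$name <- cl$cluster_id
    write_bed(cl, file.path(dir, paste0(sp, "_planted_clusters.bed")))
    write_fasta(a$transcripts, file.path(dir, paste0(sp, "_transcripts.fa")))
    write_tsv_file(a$go_map, file.path(dir, paste0(sp, "_go_map.tsv")))
    write_tsv_file(a$kegg_map, file.path(dir, paste0(sp, "_kegg_map.tsv")))
  }
  write_tsv_file(sim$truth$planted_pirnas,
                 file.path(dir, "truth_planted_pirnas.tsv"))
  write_tsv_file(sim$truth$homolog_pairs,
                 file.path(dir, "truth_homolog_pairs.tsv"))
  for (nm in names(libs)) {
    write_fastq(libs[[nm]], file.path(dir, paste0(nm, ".fastq")))
  }
  invisible(dir)
}
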