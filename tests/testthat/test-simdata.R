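test_that("genome, annotation and library generation are byte-deterministic", {
  cfg <- small_cfg(seed = 11L)
  s1 <- generate_genome(cfg)
  s2 <- generate_genome(cfg)
  expect_identical(s1$genomes, s2$genomes)
  expect_identical(s1$truth, s2$truth)

  a1 <- generate_annotations(s1, cfg)
  a2 <- generate_annotations(s2, cfg)
  expect_identical(a1[[1]]$ncrna, a2[[1]]$ncrna)
  expect_identical(a1[[2]]$go_map, a2[[2]]$go_map)

  l1 <- simulate_libraries(s1, a1, cfg)
  l2 <- simulate_libraries(s2, a2, cfg)
  expect_identical(l1, l2)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulation(s1, a1, l1, d1)
  write_simulation(s2, a2, l2, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
})

test_that("planted clusters are disjoint intervals of the configured span", {
  cfg <- sim_config(seed = 3L, n_chromosomes = 2L, chrom_length = 50000L,
                    n_clusters = 5L, cluster_span = 2000L,
                    pirnas_per_cluster = 20L, n_homolog_pairs = 0L,
                    n_ncrna_loci = 0L)
  sim <- generate_genome(cfg)
  for (sp in cfg$species) {
    cl <- sim$truth$planted_clusters
    cl <- cl[cl$species == sp, ]
    expect_equal(nrow(cl), 5L)
    expect_true(all(cl$end - cl$start == 2000L))
    for (ch in unique(cl$chrom)) {
      ir <- IRanges::IRanges(start = cl$start[cl$chrom == ch] + 1L,
                             end = cl$end[cl$chrom == ch])
      expect_equal(sum(IRanges::countOverlaps(ir, ir)), length(ir))
    }
    # every planted piRNA lies inside its cluster and is a genome substring
    pl <- sim$truth$planted_pirnas
    pl <- pl[pl$species == sp, ]
    expect_equal(nrow(pl), 100L)
    for (i in sample(nrow(pl), 10L)) {
      expect_identical(
        pl$seq[i],
        substr(sim$genomes[[sp]][[pl$chrom[i]]], pl$start[i] + 1L, pl$end[i]))
      cli <- cl[cl$cluster_id == pl$cluster_id[i] & cl$chrom == pl$chrom[i], ]
      expect_true(pl$start[i] >= cli$start && pl$end[i] <= cli$end)
    }
  }
})

test_that("a cluster-free configuration yields empty truth", {
  cfg <- small_cfg(n_clusters = 0L, n_homolog_pairs = 0L)
  sim <- generate_genome(cfg)
  expect_equal(nrow(sim$truth$planted_clusters), 0L)
  expect_equal(nrow(sim$truth$planted_pirnas), 0L)
  expect_equal(nrow(sim$truth$homolog_pairs), 0L)
})

test_that("planted homolog pairs are exactly the cross-species rule matches", {
  cfg <- small_cfg(seed = 5L, n_homolog_pairs = 5L)
  sim <- generate_genome(cfg)
  pl <- sim$truth$planted_pirnas
  a <- pl$seq[pl$species == cfg$species[1]]
  b <- pl$seq[pl$species == cfg$species[2]]
  found <- character(0)
  for (x in a) {
    for (y in b) {
      if (oracle_match_pair(x, y)) found <- c(found, paste(x, y))
    }
  }
  planted <- paste(sim$truth$homolog_pairs$seq_a,
                   sim$truth$homolog_pairs$seq_b)
  expect_setequal(found, planted)
  expect_equal(length(planted), 5L)
})

test_that("simulated counts follow the NB mean-variance relationship", {
  n <- 200L
  cnt <- simulate_counts(rep(100, n), rep(100, n), dispersion = 0.1,
                         seed = 21L)
  x <- as.numeric(cnt)
  sigma2 <- 100 + 100^2 * 0.1
  se <- sqrt(sigma2 / length(x))
  expect_lt(abs(mean(x) - 100), 3 * se)
  ratio <- (length(x) - 1) * var(x) / sigma2
  band <- qchisq(c(0.005, 0.995), df = length(x) - 1)
  expect_gt(ratio, band[1])
  expect_lt(ratio, band[2])
})

test_that("a null simulation plants no expression shift", {
  cfg <- small_cfg(de_fraction = 0)
  sim <- generate_genome(cfg)
  pl <- sim$truth$planted_pirnas
  expect_true(all(pl$fresh_mean == pl$frozen_mean))
  expect_true(all(!pl$is_de))
})

test_that("contaminant-free libraries recover planted piRNAs after trimming", {
  cfg <- small_cfg(seed = 9L, contam_fraction = 0)
  sim <- generate_genome(cfg)
  ann <- generate_annotations(sim, cfg)
  libs <- simulate_libraries(sim, ann, cfg)
  planted <- sim$truth$planted_pirnas$seq[
    sim$truth$planted_pirnas$species == cfg$species[1]]
  cl <- clean_reads(libs[[1]], cfg$adapter_seq)
  expect_gt(nrow(cl$reads), 0L)
  expect_true(all(nchar(cl$reads$seq) >= 24 & nchar(cl$reads$seq) <= 32))
  expect_true(all(cl$reads$seq %in% planted))
  expect_equal(cl$stats$n_clean, cl$stats$n_raw)
  expect_equal(cl$stats$n_adapter_trimmed, cl$stats$n_raw)
})

test_that("ncRNA loci are disjoint from planted clusters", {
  cfg <- small_cfg(seed = 13L, n_ncrna_loci = 10L)
  sim <- generate_genome(cfg)
  ann <- generate_annotations(sim, cfg)
  for (sp in cfg$species) {
    nc <- ann[[sp]]$ncrna
    cl <- sim$truth$planted_clusters
    cl <- cl[cl$species == sp, ]
    expect_equal(nrow(nc), 10L)
    for (ch in unique(nc$chrom)) {
      ir_nc <- IRanges::IRanges(start = nc$start[nc$chrom == ch] + 1L,
                                end = nc$end[nc$chrom == ch])
      ir_cl <- IRanges::IRanges(start = cl$start[cl$chrom == ch] + 1L,
                                end = cl$end[cl$chrom == ch])
      expect_equal(sum(IRanges::countOverlaps(ir_nc, ir_cl)), 0L)
    }
    # locus sequences are genome substrings of the recorded interval
    i <- nrow(nc)
    expect_identical(nc$seq[i], substr(sim$genomes[[sp]][[nc$chrom[i]]],
                                       nc$start[i] + 1L, nc$end[i]))
  }
  empty <- generate_annotations(sim, small_cfg(seed = 13L, n_ncrna_loci = 0L))
  expect_equal(nrow(empty[[1]]$ncrna), 0L)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(u1_bias = 1.5), "proportions")
  expect_error(sim_config(nb_dispersion = 0), "nb_dispersion")
  expect_error(sim_config(n_clusters = 10L, cluster_span = 2000L,
                          chrom_length = 10000L), "chrom_length")
  bad_dist <- c(`24` = 0.5, `25` = 0.4)
  expect_error(sim_config(pirna_length_dist = bad_dist), "length_dist")
})
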