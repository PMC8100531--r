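test_that("targets require an antisense site with an exact seed", {
  withr::with_seed(50, {
    pirna <- rand_seq(1, 28)
    flank1 <- rand_seq(1, 100)
    flank2 <- rand_seq(1, 100)
  })
  tx_anti <- c(hit_tx = paste0(flank1, revcomp(pirna), flank2))
  hits <- predict_targets(pirna, tx_anti)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$position, 100L)
  expect_equal(hits$mismatches, 0L)

  tx_sense <- c(sense_tx = paste0(flank1, pirna, flank2))
  expect_equal(nrow(predict_targets(pirna, tx_sense)), 0L)
})

test_that("extension mismatches are tolerated up to the limit, seed is not", {
  withr::with_seed(51, pirna <- rand_seq(1, 30))
  site <- revcomp(pirna)
  mutate_site <- function(site, pirna_pos) {
    # pirna position i pairs with site position L + 1 - i
    pos <- nchar(site) + 1L - pirna_pos
    old <- substr(site, pos, pos)
    substr(site, pos, pos) <- setdiff(c("A", "C", "G", "T"), old)[1]
    site
  }
  wrap <- function(s) c(tx = paste0(strrep("A", 50), s, strrep("C", 50)))
  expect_equal(predict_targets(pirna, wrap(mutate_site(site, 15L)))$mismatches,
               1L)
  two <- mutate_site(mutate_site(site, 15L), 25L)
  expect_equal(predict_targets(pirna, wrap(two))$mismatches, 2L)
  three <- mutate_site(two, 20L)
  expect_equal(nrow(predict_targets(pirna, wrap(three))), 0L)
  in_seed <- mutate_site(site, 5L)   # position within the 2-11 seed
  expect_equal(nrow(predict_targets(pirna, wrap(in_seed))), 0L)
})

test_that("target prediction equals the exhaustive offset scan", {
  withr::with_seed(52, {
    pirnas <- rand_seq(15, sample(24:32, 15, replace = TRUE))
    tx <- setNames(rand_seq(8, 250), sprintf("tx%02d", 1:8))
    # plant sites with 0-3 substitutions
    for (i in 1:10) {
      p <- sample(pirnas, 1)
      site <- revcomp(p)
      for (k in seq_len(sample(0:3, 1))) {
        pos <- sample(nchar(site), 1)
        old <- substr(site, pos, pos)
        substr(site, pos, pos) <- sample(setdiff(c("A", "C", "G", "T"),
                                                 old), 1)
      }
      j <- sample(length(tx), 1)
      at <- sample(250 - nchar(site), 1)
      substr(tx[[j]], at, at + nchar(site) - 1L) <- site
    }
  })
  got <- predict_targets(pirnas, tx)
  want <- do.call(rbind, lapply(pirnas, oracle_target_scan,
                                transcripts = tx))
  key <- function(d) sort(paste(d$pirna_seq, d$transcript_id, d$position,
                                d$mismatches))
  expect_equal(key(got), key(want))
  expect_gt(nrow(got), 0L)
})

test_that("hypergeometric p equals combinatorial enumeration", {
  ann <- tibble::tibble(
    transcript_id = c(paste0("g", 1:4), paste0("g", 1:10)),
    term_id = c(rep("T1", 4), rep("T2", 10)),
    ontology = "GO")
  universe <- paste0("g", 1:10)
  res <- hypergeom_enrich(paste0("g", c(1, 2, 3, 7, 8)), ann, universe)
  t1 <- res[res$term_id == "T1", ]
  expect_equal(t1$k, 3L)
  expect_equal(t1$p, 66 / 252, tolerance = 1e-12)
  t2 <- res[res$term_id == "T2", ]
  expect_equal(t2$p, 1)   # all universe genes carry T2 -> k = n, p = 1

  # property: closed-form upper tail equals enumeration over small universes
  withr::with_seed(53, {
    for (i in 1:30) {
      N <- sample(5:15, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
      k <- sample(0:min(n, K), 1)
      expect_equal(phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                   oracle_hyper_tail(N, K, n, k), tolerance = 1e-12,
                   info = paste(N, K, n, k))
    }
  })
})

test_that("k = 0 and full-universe target sets give p = 1", {
  ann <- tibble::tibble(transcript_id = paste0("g", 1:6),
                        term_id = rep(c("A", "B"), each = 3),
                        ontology = "GO")
  res0 <- hypergeom_enrich("g1", ann)
  expect_equal(res0$p[res0$term_id == "B"], 1)   # k = 0
  res_all <- hypergeom_enrich(paste0("g", 1:6), ann)
  expect_true(all(res_all$p == 1))
  expect_error(hypergeom_enrich("gX", ann), "absent from the universe")
})

test_that("BH adjustment is applied within each ontology separately", {
  ann <- tibble::tibble(
    transcript_id = c("g1", "g1", "g2", "g3", "g2", "g4"),
    term_id = c("GO1", "KEGG1", "GO1", "GO2", "KEGG1", "KEGG2"),
    ontology = c("GO", "KEGG", "GO", "GO", "KEGG", "KEGG"))
  universe <- paste0("g", 1:4)
  res <- hypergeom_enrich(c("g1", "g2"), ann, universe)
  for (ont in c("GO", "KEGG")) {
    sub <- res[res$ontology == ont, ]
    expect_equal(sub$padj, oracle_bh(sub$p))
  }
})

test_that("term ranking sorts by padj, then target count, then id", {
  res <- tibble::tibble(
    term_id = c("T3", "T1", "T2", "T4"),
    ontology = "GO", k = c(5L, 5L, 2L, 9L), n = 10L, K = 10L, N = 50L,
    p = c(0.01, 0.01, 0.01, 0.2), padj = c(0.02, 0.02, 0.02, 0.2))
  ranked <- rank_terms(res, top_n = 3L)
  expect_equal(ranked$term_id, c("T1", "T3", "T2"))
  # independent sort oracle on a random table
  withr::with_seed(54, {
    tab <- tibble::tibble(
      term_id = sprintf("T%02d", sample(50)), ontology = "GO",
      k = sample(1:10, 50, replace = TRUE), n = 20L, K = 15L, N = 100L,
      p = runif(50), padj = round(runif(50), 1))
  })
  got <- rank_terms(tab, top_n = 50L)
  want <- tab[with(tab, order(padj, -k, term_id)), ]
  expect_equal(got$term_id, want$term_id)
})

test_that("a strongly enriched planted term ranks first in most runs", {
  withr::with_seed(55, {
    universe <- sprintf("g%03d", 1:200)
    term_genes <- universe[1:30]
    other_terms <- lapply(1:10, function(i) sample(universe, 20))
    ann <- dplyr::bind_rows(
      tibble::tibble(transcript_id = term_genes, term_id = "PLANTED",
                     ontology = "GO"),
      dplyr::bind_rows(lapply(seq_along(other_terms), function(i) {
        tibble::tibble(transcript_id = other_terms[[i]],
                       term_id = sprintf("BG%02d", i), ontology = "GO")
      })))
    wins <- 0L
    for (run in 1:20) {
      w <- ifelse(universe %in% term_genes, 10, 1)
      targets <- sample(universe, 30, prob = w)
      res <- hypergeom_enrich(targets, ann, universe)
      if (rank_terms(res, 1L)$term_id == "PLANTED") wins <- wins + 1L
    }
    expect_gte(wins, 19L)
  })
})
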