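sub_at <- function(s, pos) {
  old <- substr(s, pos, pos)
  substr(s, pos, pos) <- setdiff(c("A", "C", "G", "T"), old)[1]
  s
}

test_that("the pairing rule anchors the 5' seed and tolerates one tail mismatch", {
  withr::with_seed(40, a <- rand_seq(1, 30))
  expect_equal(match_pair(a, a)$n_mismatch, 0L)
  expect_equal(match_pair(a, a)$overlap_len, 30L)

  m25 <- match_pair(a, sub_at(a, 25))
  expect_equal(m25$mismatch_positions, 25L)
  expect_null(match_pair(a, sub_at(a, 10)))             # seed violated
  expect_null(match_pair(a, sub_at(sub_at(a, 20), 28))) # two tail mismatches

  b26 <- substr(a, 1, 26)
  m26 <- match_pair(a, b26)
  expect_equal(m26$overlap_len, 26L)   # 3' overhang ignored
  expect_equal(m26$n_mismatch, 0L)

  expect_null(match_pair(substr(a, 1, 18), a))  # too short for the rule
  expect_error(match_pair("ACGTX", a), "non-ACGT")
})

test_that("U and T notations are interchangeable", {
  withr::with_seed(41, a <- rand_seq(1, 28))
  u <- chartr("T", "U", a)
  expect_equal(match_pair(a, u)$n_mismatch, 0L)
})

test_that("the rule agrees with the character-level oracle on random pairs", {
  withr::with_seed(42, {
    for (i in 1:200) {
      base <- rand_seq(1, sample(19:32, 1))
      b <- if (runif(1) < 0.5) {
        s <- base
        for (k in seq_len(sample(0:2, 1))) s <- sub_at(s, sample(nchar(s), 1))
        s
      } else {
        rand_seq(1, sample(19:32, 1))
      }
      expect_equal(!is.null(match_pair(base, b)), oracle_match_pair(base, b),
                   info = paste(base, b))
    }
  })
})

test_that("best_pair minimises mismatches, then maximises overlap, then sorts", {
  withr::with_seed(43, q <- rand_seq(1, 30))
  exact <- q
  near <- sub_at(q, 22)
  expect_equal(best_pair(q, c(near, exact, near))$seq_b, exact)

  short0 <- substr(q, 1, 24)
  expect_equal(best_pair(q, c(short0, exact))$seq_b, exact)  # longer overlap

  t1 <- sub_at(q, 20); t2 <- sub_at(q, 25)
  want <- sort(c(t1, t2))[1]
  expect_equal(best_pair(q, c(t2, t1))$seq_b, want)  # lexicographic tie
  expect_null(best_pair(q, rand_seq(5, 30)))
})

test_that("partition matches exhaustive all-pairs brute force", {
  withr::with_seed(44, {
    for (trial in 1:20) {
      n_a <- sample(10:60, 1); n_b <- sample(10:60, 1)
      set_a <- unique(rand_seq(n_a, sample(19:32, n_a, replace = TRUE)))
      set_b <- unique(rand_seq(n_b, sample(19:32, n_b, replace = TRUE)))
      # plant related pairs so the comparison is non-trivial
      n_plant <- sample(0:5, 1)
      if (n_plant > 0) {
        for (i in seq_len(min(n_plant, length(set_a), length(set_b)))) {
          s <- set_a[i]
          if (runif(1) < 0.5) s <- sub_at(s, sample(19:nchar(s), 1))
          set_b[i] <- s
        }
        set_b <- unique(set_b)
      }
      part <- partition_de_sets(set_a, set_b)
      brute_a <- vapply(set_a, function(x) {
        any(vapply(set_b, function(y) oracle_match_pair(x, y), logical(1)))
      }, logical(1))
      brute_b <- vapply(set_b, function(y) {
        any(vapply(set_a, function(x) oracle_match_pair(x, y), logical(1)))
      }, logical(1))
      expect_setequal(part$common_a, set_a[brute_a])
      expect_setequal(part$common_b, set_b[brute_b])
      expect_setequal(part$unique_a, set_a[!brute_a])
      expect_equal(part$counts$n_unique_a + part$counts$n_common_a,
                   length(set_a))
    }
  })
})

test_that("partition of identical and of unrelated sets is total", {
  withr::with_seed(45, s <- rand_seq(30, 28))
  same <- partition_de_sets(s, s)
  expect_equal(same$counts$n_common_a, 30L)
  expect_equal(same$counts$n_unique_a, 0L)

  withr::with_seed(46, t <- rand_seq(25, 28))
  disjoint <- partition_de_sets(s, t)
  expect_equal(disjoint$counts$n_common_a, 0L)
  expect_equal(disjoint$counts$n_unique_a, 30L)
  expect_equal(disjoint$counts$n_unique_b, 25L)
  expect_error(partition_de_sets(c(s, s[1]), t), "deduplicated")
})

test_that("partition is symmetric and monotone under candidate addition", {
  withr::with_seed(47, {
    set_a <- rand_seq(40, 28)
    set_b <- c(set_a[1:6], rand_seq(20, 28))
  })
  ab <- partition_de_sets(set_a, set_b)
  ba <- partition_de_sets(set_b, set_a)
  expect_setequal(ab$common_a, ba$common_b)
  expect_setequal(ab$unique_a, ba$unique_b)
  expect_equal(ab$counts$n_common_a, ba$counts$n_common_b)

  grow <- partition_de_sets(set_a, c(set_b, set_a[7]))
  expect_lte(grow$counts$n_unique_a, ab$counts$n_unique_a)
})

test_that("one-to-one mode assigns each sequence to at most one pair", {
  withr::with_seed(48, q <- rand_seq(1, 30))
  # two queries share the same single candidate
  set_a <- c(q, sub_at(q, 21))
  set_b <- q
  free <- partition_de_sets(set_a, set_b)
  expect_equal(free$counts$n_common_a, 2L)
  strict <- partition_de_sets(set_a, set_b, one_to_one = TRUE)
  expect_equal(strict$counts$n_common_a, 1L)
  expect_equal(nrow(strict$common_pairs), 1L)
  expect_equal(strict$common_pairs$seq_a, q)  # exact match wins the pairing
})

test_that("constructed instances plant the requested homology structure", {
  inst <- make_homology_instance(60, 40, 7, seed = 5L)
  expect_equal(length(inst$set_a), 60L)
  expect_equal(length(inst$set_b), 40L)
  expect_false(any(duplicated(inst$set_a)))
  # exhaustive independent check of the planted structure
  cross <- outer(inst$set_a, inst$set_b,
                 Vectorize(function(x, y) oracle_match_pair(x, y)))
  expect_equal(sum(rowSums(cross) > 0), 7L)
  expect_equal(sum(colSums(cross) > 0), 7L)
  expect_setequal(inst$set_a[rowSums(cross) > 0], inst$pairs$seq_a)
})
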