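test_that("circular label shift follows (i + offset) mod n with wraparound", {
  expect_equal(circular_shift_labels(c(1, 0, 0, 0), 1), c(0, 1, 0, 0))
  expect_equal(circular_shift_labels(c(1, 0, 1), 3), c(1, 0, 1))  # identity
  expect_equal(circular_shift_labels(c(1, 1, 0, 0, 0), 2), c(0, 0, 1, 1, 0))
  # index-arithmetic oracle on random vectors
  set.seed(4)
  for (i in 1:20) {
    n <- sample(2:30, 1)
    lab <- runif(n) < 0.3
    o <- sample(n, 1)
    dest <- (seq_len(n) + o - 1) %% n + 1
    want <- logical(n); want[dest] <- lab
    expect_identical(circular_shift_labels(lab, o), want)
    expect_equal(sum(circular_shift_labels(lab, o)), sum(lab))  # conservation
  }
  expect_error(circular_shift_labels(c(1, 0), 3), "offset")
  expect_error(circular_shift_labels(c(1, 0), 0), "offset")
})

test_that("exhaustive rotation counts match enumeration on a 4-SNP chromosome", {
  cat_ <- snp_catalog(paste0("s", 1:4), rep("1", 4), c(10, 20, 30, 40), rep("x", 4))
  tr <- annotation_track("t", "1", c(5, 15), c(10, 20))  # covers pos 10 and 20
  ld0 <- structure(list(), class = "ld_map")
  m <- compute_overlap_matrix(cat_, ld0, tr)
  expect_identical(unname(m[, "t"]), c(TRUE, TRUE, FALSE, FALSE))
  status <- c(TRUE, FALSE, FALSE, FALSE)
  # enumerate all 4 offsets: hit counts {1, 0, 0, 1}, mean 0.5
  null <- run_permutations(m, status, perm_config(n_permutations = 400, seed = 1))
  seen <- tapply(null$counts[, "t"], null$offsets[, "1"], unique)
  expect_equal(as.vector(seen[as.character(1:4)]), c(1, 0, 0, 1))
  expect_equal(mean(sapply(1:4, function(o) {
    rot <- circular_shift_labels(status, o)
    sum(rot & m[, "t"])
  })), 0.5)
})

test_that("permutations conserve per-chromosome label counts and respect all-true incidence", {
  study <- simulate_study(sim_config(n_chromosomes = 2,
                                     snps_per_chromosome = 200,
                                     chromosome_length = 2e5, n_assoc = 30,
                                     tracks = default_sim_tracks()[1:2, ],
                                     planted_or = c(feat01 = 1), seed = 5))
  m <- study$matrix
  # all-true incidence column: every permuted count equals n_assoc
  m2 <- cbind(m, alltrue = TRUE)
  attr(m2, "chrom") <- attr(m, "chrom"); attr(m2, "pos") <- attr(m, "pos")
  class(m2) <- class(m)
  null <- run_permutations(m2, study$status,
                           perm_config(n_permutations = 50, seed = 2))
  expect_true(all(null$counts[, "alltrue"] == sum(study$status)))
  # per-chromosome totals conserved: rotate labels explicitly and count
  chrom <- attr(m, "chrom")
  for (p in c(1, 25, 50)) {
    for (ch in unique(chrom)) {
      rows <- which(chrom == ch)
      rot <- circular_shift_labels(study$status[rows], null$offsets[p, ch])
      expect_equal(sum(rot), sum(study$status[rows]))
    }
  }
})

test_that("label-rotation fast counts equal brute-force relabel-and-recount", {
  study <- simulate_study(sim_config(n_chromosomes = 3,
                                     snps_per_chromosome = 60,
                                     chromosome_length = 6e4, n_assoc = 12,
                                     tracks = default_sim_tracks()[c(1, 5), ],
                                     planted_or = c(feat01 = 2), seed = 6))
  cfg <- perm_config(n_permutations = 40, seed = 7)
  null <- run_permutations(study$matrix, study$status, cfg)
  brute <- brute_permutation_counts(study$catalog, study$ld, study$tracks,
                                    study$status, null$offsets)
  expect_equal(unname(null$counts), unname(brute))
})

test_that("empirical p-values count extreme permutations with a reporting floor", {
  cfg <- perm_config(n_permutations = 20000, seed = 1)
  # 19 exceedances among 20,000 -> 9.5e-4
  counts <- c(rep(0, 19981), rep(10, 19))
  pv <- empirical_pvalue(counts, 10, cfg)
  expect_equal(pv$p, 9.5e-4)
  expect_false(pv$bound)
  # zero exceedances -> bound at 1/n
  pv <- empirical_pvalue(rep(2, 20000), 50, cfg)
  expect_equal(pv$p, 5e-5)
  expect_true(pv$bound)
  # all counts equal the observation -> p = 1
  pv <- empirical_pvalue(rep(7, 100), 7, perm_config(100))
  expect_equal(pv$p, 1)
  # lower tail: observation below the null mean
  pv <- empirical_pvalue(c(rep(10, 90), rep(0, 10)), 0, perm_config(100))
  expect_equal(pv$p, 0.1)
  # doubled two-sided mode
  cfg2 <- perm_config(100, tail_mode = "two_sided_doubled")
  pv <- empirical_pvalue(c(rep(10, 95), rep(20, 5)), 20, cfg2)
  expect_equal(pv$p, 0.1)
})

test_that("permutation enrichment assembles OR, CI and p per the null-cell reading", {
  # observed 30 of 100 assoc, null mean 10 -> OR = (30*90)/(70*10)
  counts <- rep(c(8, 10, 12), length.out = 999)  # mean 10
  null <- structure(list(counts = matrix(counts, ncol = 1,
                                         dimnames = list(NULL, "t")),
                         observed = c(t = 30), n_assoc = 100,
                         cfg = perm_config(n_permutations = 999, seed = 1)),
                    class = "perm_null")
  res <- permutation_enrichment(null)
  expect_equal(res$odds_ratio, (30 * 90) / (70 * 10), tolerance = 1e-3)
  expect_equal(res$fold_enrichment, 3, tolerance = 1e-3)
  expect_true(res$ci_low <= res$odds_ratio && res$odds_ratio <= res$ci_high)
  # upper null quantile feeds ci_low, lower feeds ci_high
  expect_equal(res$ci_low, (30 * (100 - 12)) / (70 * 12))
  expect_equal(res$ci_high, (30 * (100 - 8)) / (70 * 8))
  # observed equal to the null mean -> OR 1, p ~ 1
  null$observed <- c(t = 10)
  res2 <- permutation_enrichment(null)
  expect_equal(res2$odds_ratio, 1)
  expect_gt(res2$pvalue, 0.6)
  # a zero lower null quantile sends the upper bound to Infinity
  null$counts[] <- rep(c(0, 10), length.out = 999)
  null$observed <- c(t = 30)
  res3 <- permutation_enrichment(null)
  expect_equal(res3$ci_high, Inf)
})

test_that("permutation run is deterministic given the seed", {
  study <- simulate_study(sim_config(n_chromosomes = 2,
                                     snps_per_chromosome = 150,
                                     chromosome_length = 1.5e5, n_assoc = 20,
                                     tracks = default_sim_tracks()[1:2, ],
                                     seed = 8, planted_or = c(feat01 = 1)))
  r1 <- enrichment_test(study$matrix, study$status,
                        cfg = perm_config(300, seed = 11))
  r2 <- enrichment_test(study$matrix, study$status,
                        cfg = perm_config(300, seed = 11))
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  r3 <- enrichment_test(study$matrix, study$status,
                        cfg = perm_config(300, seed = 12))
  expect_false(identical(r1$pvalue, r3$pvalue))
})
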