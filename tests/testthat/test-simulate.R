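test_that("genome simulation is deterministic, ordered, and clustered", {
  cfg <- sim_config(n_chromosomes = 2, snps_per_chromosome = 2000,
                    chromosome_length = 2e6, n_assoc = 100,
                    tracks = default_sim_tracks()[1:2, ], seed = 41,
                    planted_or = c(feat01 = 1))
  c1 <- simulate_genome(cfg)
  c2 <- simulate_genome(cfg)
  expect_identical(c1, c2)  # same seed -> identical catalog
  expect_equal(nrow(c1), 4000)
  # strictly ordered positions within chromosomes
  for (ch in unique(c1$chrom)) {
    p <- c1$pos[c1$chrom == ch]
    expect_true(all(diff(p) > 0))
  }
  # every SNP belongs to >= 1 platform group
  expect_true(all(nzchar(c1$platforms)))
  # clustering: index of dispersion of inter-SNP gaps exceeds the Poisson
  # benchmark of 1 (exponential gaps at matched density have IoD ~ 1)
  gaps <- diff(c1$pos[c1$chrom == "1"])
  iod <- var(gaps) / mean(gaps)
  expect_gt(iod, 1.5)
  # an empty genome is allowed
  c0 <- simulate_genome(sim_config(snps_per_chromosome = 0, n_assoc = 0))
  expect_equal(nrow(c0), 0)
  expect_error(simulate_genome(sim_config(snps_per_chromosome = 100,
                                          chromosome_length = 50,
                                          n_assoc = 10)),
               "capacity")
})

test_that("LD blocks respect the distance cap and block structure", {
  cfg <- sim_config(n_chromosomes = 2, snps_per_chromosome = 1500,
                    chromosome_length = 1.5e6, n_assoc = 50,
                    tracks = default_sim_tracks()[1:2, ], seed = 42,
                    planted_or = c(feat01 = 1))
  set.seed(cfg$seed)
  cat_ <- simulate_genome(cfg, .seeded = TRUE)
  ld <- suppressWarnings(simulate_ld_blocks(cat_, cfg, .seeded = TRUE))
  # no partner beyond the 250 kb cap, all on the same chromosome
  for (id in names(ld)[seq(1, length(ld), length.out = min(200, length(ld)))]) {
    i <- match(id, cat_$snp_id)
    js <- match(ld_partners(ld, id), cat_$snp_id)
    expect_true(all(cat_$chrom[js] == cat_$chrom[i]))
    expect_true(all(abs(cat_$pos[js] - cat_$pos[i]) <= 250000))
  }
  # point mass at r2 = 1 partners every intra-block pair:
  # partner counts can only grow relative to the uniform[0.5, 1] draw
  cfg_all <- sim_config(n_chromosomes = 2, snps_per_chromosome = 1500,
                        chromosome_length = 1.5e6, n_assoc = 50,
                        tracks = default_sim_tracks()[1:2, ], seed = 42,
                        within_block_r2 = function(n) rep(1, n),
                        planted_or = c(feat01 = 1))
  set.seed(cfg_all$seed)
  cat_a <- simulate_genome(cfg_all, .seeded = TRUE)
  ld_all <- suppressWarnings(simulate_ld_blocks(cat_a, cfg_all, .seeded = TRUE))
  expect_gte(sum(lengths(ld_all)), sum(lengths(ld)))
  # single-SNP "blocks" yield an empty map
  cfg1 <- sim_config(n_chromosomes = 1, snps_per_chromosome = 3,
                     chromosome_length = 3e6, n_assoc = 1,
                     ld_block_length = 5,
                     tracks = default_sim_tracks()[1, ], seed = 43,
                     planted_or = c(feat01 = 1))
  set.seed(43)
  catx <- simulate_genome(cfg1, .seeded = TRUE)
  ldx <- suppressWarnings(simulate_ld_blocks(catx, cfg1, .seeded = TRUE))
  expect_equal(length(ldx), 0L)
})

test_that("annotation simulation hits coverage targets within 10%", {
  cfg <- sim_config(n_chromosomes = 1, snps_per_chromosome = 100,
                    chromosome_length = 1e6, n_assoc = 10,
                    tracks = data.frame(name = c("half", "thin"),
                                        coverage = c(0.5, 0.02),
                                        len_mean = 2000, cluster = 4),
                    planted_or = c(half = 1), seed = 44)
  tracks <- simulate_annotations(cfg)
  half <- tracks$half
  frac <- track_coverage_bp(half) / 1e6
  expect_gte(frac, 0.45); expect_lte(frac, 0.55)
  thin <- tracks$thin
  frac2 <- track_coverage_bp(thin) / 1e6
  expect_gte(frac2, 0.018); expect_lte(frac2, 0.022)
  # per-base oracle agrees with the summed interval lengths
  expect_equal(length(track_bases(half, "1", 1e6)), track_coverage_bp(half))
  # determinism
  tracks2 <- simulate_annotations(cfg)
  expect_identical(tracks, tracks2)
})

test_that("planted associations realize the target odds ratio", {
  # no effect: realized OR ~ 1
  cfg0 <- sim_config(n_chromosomes = 2, snps_per_chromosome = 5000,
                     chromosome_length = 5e6, n_assoc = 400,
                     tracks = default_sim_tracks()[c(5, 8), ],
                     planted_or = c(feat05 = 1), seed = 45)
  s0 <- simulate_study(cfg0)
  expect_lt(abs(log(s0$truth$realized_or["feat05"])), 0.35)

  # strong planting concentrates associated SNPs inside the track
  cfg_inf <- sim_config(n_chromosomes = 2, snps_per_chromosome = 5000,
                        chromosome_length = 5e6, n_assoc = 100,
                        tracks = default_sim_tracks()[c(5, 8), ],
                        planted_or = c(feat08 = 1e9), seed = 46)
  s_inf <- simulate_study(cfg_inf)
  expect_true(all(s_inf$matrix[s_inf$status, "feat08"]))

  # planted OR 3 at ~10% incidence: realized OR within [2.6, 3.4] on average
  set.seed(47)
  ors <- replicate(12, {
    cfgr <- sim_config(n_chromosomes = 2, snps_per_chromosome = 5000,
                       chromosome_length = 5e6, n_assoc = 300,
                       tracks = default_sim_tracks()[c(3, 6), ],
                       planted_or = c(feat03 = 3),
                       seed = sample.int(1e6, 1))
    simulate_study(cfgr)$truth$realized_or[["feat03"]]
  })
  expect_gt(median(ors), 2.6)
  expect_lt(median(ors), 3.4)
})

test_that("the full simulated study is reproducible from its seed", {
  cfg <- sim_config(n_chromosomes = 2, snps_per_chromosome = 400,
                    chromosome_length = 4e5, n_assoc = 40,
                    tracks = default_sim_tracks()[1:2, ], seed = 48,
                    planted_or = c(feat02 = 2))
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$catalog, s2$catalog)
  expect_identical(unclass(s1$ld), unclass(s2$ld))
  expect_identical(s1$status, s2$status)
  expect_identical(s1$truth$realized_or, s2$truth$realized_or)
})
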