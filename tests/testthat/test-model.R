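test_that("logistic fit recovers closed-form saturated estimates", {
  # balanced response, intercept-only -> intercept 0
  y <- rep(c(TRUE, FALSE), 500)
  f0 <- fit_logistic(y, data.frame(row.names = seq_along(y)))
  expect_equal(f0$terms$estimate[1], 0, tolerance = 1e-8)
  # binary covariate with response rates 0.8 vs 0.2:
  # slope = logit(0.8) - logit(0.2)
  x <- rep(c(1, 0), each = 1000)
  y <- c(rep(c(TRUE, FALSE), c(800, 200)), rep(c(TRUE, FALSE), c(200, 800)))
  f1 <- fit_logistic(y, data.frame(x = x))
  slope <- f1$terms$estimate[f1$terms$term == "x"]
  expect_equal(slope, qlogis(0.8) - qlogis(0.2), tolerance = 1e-6)
  expect_equal(slope, 2.773, tolerance = 1e-3)
  # beta-coefficient is the Wald z; its square is the Wald chi-square
  expect_equal(f1$terms$beta_coefficient, f1$terms$estimate / f1$terms$se)
  glm_ref <- glm(y ~ x, family = binomial())
  sm <- summary(glm_ref)$coefficients
  expect_equal(f1$terms$estimate, unname(sm[, 1]), tolerance = 1e-6)
  expect_equal(f1$terms$se, unname(sm[, 2]), tolerance = 1e-5)
  expect_equal(f1$aic, AIC(glm_ref), tolerance = 1e-6)
  # AIC identity
  expect_equal(f1$aic, 2 * f1$n_par - 2 * f1$loglik)
})

test_that("separation is flagged, not silent", {
  x <- rep(c(1, 0), each = 50)
  y <- x == 1
  f <- fit_logistic(y, data.frame(x = x))
  expect_true(f$separation)
  expect_error(fit_logistic(rep(TRUE, 10), data.frame(x = rnorm(10))), "classes")
  expect_error(fit_logistic(rep(c(TRUE, FALSE), 5), data.frame(k = rep(1, 10))),
               "constant")
})

test_that("stepwise AIC keeps forced terms, selects planted effects, drops noise", {
  set.seed(31)
  n <- 20000
  plat <- data.frame(gA = rbinom(n, 1, 0.5))
  x_info <- rbinom(n, 1, 0.2)
  x_noise1 <- rbinom(n, 1, 0.2)
  x_noise2 <- rbinom(n, 1, 0.3)
  eta <- -2.5 + 0.3 * plat$gA + log(4) * x_info    # planted OR 4
  y <- runif(n) < plogis(eta)
  X <- cbind(plat, info = x_info, noise1 = x_noise1, noise2 = x_noise2)
  fit <- stepwise_aic(y, X, forced = "gA",
                      candidates = c("info", "noise1", "noise2"))
  expect_true("info" %in% fit$selected)
  expect_true("gA" %in% fit$terms$term)  # forced term never dropped
  # step log never accepts an AIC increase
  expect_true(all(diff(fit$step_log$aic) < 0))
  base <- fit_logistic(y, X[, "gA", drop = FALSE])
  expect_lte(fit$aic, base$aic)
  # cross-check final selection against stats::step on the same data
  full_scope <- y ~ gA + info + noise1 + noise2
  ref <- step(glm(y ~ gA, data = X, family = binomial()),
              scope = list(lower = y ~ gA, upper = full_scope),
              direction = "both", trace = 0)
  ref_terms <- sort(setdiff(attr(terms(ref), "term.labels"), "gA"))
  expect_identical(fit$selected, ref_terms)
})

test_that("stepwise returns the base model when no candidate is informative", {
  set.seed(32)
  n <- 50000
  plat <- data.frame(gA = rbinom(n, 1, 0.5))
  y <- runif(n) < 0.02
  X <- cbind(plat, n1 = rbinom(n, 1, 0.1), n2 = rbinom(n, 1, 0.2))
  fit <- stepwise_aic(y, X, forced = "gA", candidates = c("n1", "n2"))
  expect_lte(length(fit$selected), 1)  # chance admission of at most one noise term
  base <- fit_logistic(y, X[, "gA", drop = FALSE])
  expect_lte(fit$aic, base$aic)
})

test_that("pseudo r-squared follows the closed forms", {
  y <- rep(c(TRUE, FALSE), 500)
  x <- rep(c(1, 0), 500)
  xb <- rbinom(1000, 1, 0.5)
  f_empty <- fit_logistic(y, data.frame(row.names = seq_along(y)))
  expect_equal(pseudo_r2(f_empty, f_empty),
               list(mcfadden = 0, mckelvey_zavoina = 0))
  # direct formula: loglik ratio
  f_full <- fit_logistic(y, data.frame(x = x, xb = xb))
  pr <- pseudo_r2(f_empty, f_full)
  expect_equal(pr$mcfadden, 1 - f_full$loglik / f_empty$loglik)
  expect_equal(pr$mckelvey_zavoina,
               var(f_full$eta) / (var(f_full$eta) + pi^2 / 3))
  # Var(eta) = pi^2/3 -> McKelvey-Zavoina = 0.5 (by construction)
  fake <- f_full
  fake$eta <- sqrt(pi^2 / 3 / var(f_full$eta)) * (f_full$eta - mean(f_full$eta))
  expect_equal(var(fake$eta), pi^2 / 3)
  expect_equal(pseudo_r2(f_empty, fake)$mckelvey_zavoina, 0.5)
  # McFadden strictly increases when a truly informative covariate is added
  set.seed(33)
  n <- 5000
  xi <- rbinom(n, 1, 0.3)
  yy <- runif(n) < plogis(-1 + 1.5 * xi)
  e <- fit_logistic(yy, data.frame(row.names = seq_len(n)))
  f <- fit_logistic(yy, data.frame(xi = xi))
  expect_gt(pseudo_r2(e, f)$mcfadden, 0)
})

test_that("deviance test matches the chi-squared likelihood-ratio form", {
  set.seed(34)
  n <- 3000
  x <- rbinom(n, 1, 0.4)
  y <- runif(n) < plogis(-1 + x)
  f0 <- fit_logistic(y, data.frame(row.names = seq_len(n)))
  f1 <- fit_logistic(y, data.frame(x = x))
  cmp <- lr_deviance_test(f0, f1)
  expect_equal(cmp$deviance, 2 * (f1$loglik - f0$loglik))
  expect_equal(cmp$df, 1)
  expect_equal(cmp$pvalue, pchisq(cmp$deviance, 1, lower.tail = FALSE))
  # against stats::anova on the glm equivalents
  g0 <- glm(y ~ 1, family = binomial())
  g1 <- glm(y ~ x, family = binomial())
  ref <- anova(g0, g1, test = "Chisq")
  expect_equal(cmp$deviance, ref$Deviance[2], tolerance = 1e-8)
  # identical models -> deviance 0, p 1
  same <- lr_deviance_test(f1, f1)
  expect_equal(same$deviance, 0)
  expect_equal(same$pvalue, 1)
})

test_that("combined-annotation odds ratio uses the all-SNP 2x2 table", {
  # toy scaled from the shape (96 hits / 4 misses among assoc; 770/230 in rest)
  hit <- c(rep(TRUE, 96), rep(FALSE, 4), rep(TRUE, 770), rep(FALSE, 230))
  status <- rep(c(TRUE, FALSE), c(100, 1000))
  m <- matrix(hit, ncol = 1, dimnames = list(NULL, "t"))
  class(m) <- c("overlap_matrix", class(m))
  res <- combined_annotation_or(m, "t", status)
  expect_equal(res$odds_ratio, (96 * 230) / (4 * 770))
  expect_equal(round(res$odds_ratio, 2), 7.17)
  expect_lt(res$pvalue, 1e-3)
  # independence -> OR ~ 1 (simulated)
  set.seed(35)
  m2 <- matrix(rbinom(20000, 1, 0.3) == 1, ncol = 2,
               dimnames = list(NULL, c("a", "b")))
  class(m2) <- c("overlap_matrix", class(m2))
  st2 <- rbinom(10000, 1, 0.05) == 1
  res2 <- combined_annotation_or(m2, c("a", "b"), st2)
  expect_lt(abs(log(res2$odds_ratio)), 0.35)
  # covering all SNPs degenerates the table
  m3 <- matrix(TRUE, 100, 1, dimnames = list(NULL, "t"))
  class(m3) <- c("overlap_matrix", class(m3))
  expect_error(combined_annotation_or(m3, "t", rep(c(TRUE, FALSE), 50)),
               "degenerate")
  expect_error(combined_annotation_or(m, character(0), status), "empty")
})

test_that("upstream TSS distance respects strand and LD expansion", {
  cat_ <- snp_catalog(c("a", "b", "c"), c("1", "1", "1"),
                      c(1000, 3000, 9000), rep("x", 3))
  # plus-strand TSS at 1500 (start 1499), minus-strand TSS at 400 (end 400)
  tss <- annotation_track("tss", c("1", "1"), c(1499, 395), c(1600, 400),
                          strand = c("+", "-"))
  ld0 <- structure(list(), class = "ld_map")
  d <- distance_to_tss(cat_, ld0, tss, mode = "snp")
  expect_equal(d[1], 500)   # SNP 1000 upstream of +TSS 1500
  expect_equal(d[2], 2600)  # SNP 3000 upstream of -TSS 400 (distance 2600)
  expect_true(is.na(d[3]) || d[3] == 8600)  # only the -TSS at 400 is upstream
  expect_equal(d[3], 8600)
  # LD partner closer to a TSS shrinks the distance
  ld <- ld_map(data.frame(snpA = "b", snpB = "a", r2 = 0.95), ld_config(), cat_)
  d_ld <- distance_to_tss(cat_, ld, tss, mode = "ld")
  expect_equal(d_ld[2], 500)  # partner a is 500 bp upstream of the +TSS
  # SNP with no upstream TSS on its chromosome -> NA
  cat2 <- snp_catalog("z", "1", 5000, "x")
  tss2 <- annotation_track("tss", "1", 1000, 1100, strand = "+")
  expect_true(is.na(distance_to_tss(cat2, ld0, tss2, mode = "snp")))
})

test_that("annotation_model assembles selection, pseudo-r2 and deviance test", {
  study <- simulate_study(sim_config(n_chromosomes = 2,
                                     snps_per_chromosome = 2500,
                                     chromosome_length = 2.5e6, n_assoc = 250,
                                     tracks = default_sim_tracks()[c(1, 4, 7), ],
                                     planted_or = c(feat04 = 6), seed = 36))
  mod <- annotation_model(study$matrix, study$status, study$catalog)
  expect_s3_class(mod, "annot_logit")
  expect_true("feat04" %in% mod$fit$selected)
  expect_gte(mod$pseudo_r2$mcfadden, 0)
  expect_gt(mod$deviance_test$deviance, 0)
  expect_lte(mod$fit$aic, mod$empty_fit$aic)
  # exclusion blacklist removes a candidate entirely
  mod2 <- annotation_model(study$matrix, study$status, study$catalog,
                           exclude = "feat04")
  expect_false("feat04" %in% mod2$candidates)
})
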