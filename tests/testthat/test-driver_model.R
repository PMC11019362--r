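test_that("the exact Poisson test matches direct pmf summation", {
  expect_equal(exact_poisson_test(0, 2), 1)
  ## frozen from the pmf-summation oracle: 1 - sum_0^4 e^-0.5 0.5^k / k!
  expect_equal(exact_poisson_test(5, 0.5), 1.7211563e-4, tolerance = 1e-6)
  expect_equal(exact_poisson_test(2, 2), 1 - 3 * exp(-2), tolerance = 1e-12)
  for (lam in c(0.1, 0.7, 2, 5.5, 12)) {
    for (n in c(0:5, 10, 25, 50)) {
      expect_lt(abs(exact_poisson_test(n, lam) - oracle_poisson_tail(n, lam)),
                1e-12)
    }
  }
  ## monotone in both arguments
  lam <- 2.5
  p_n <- exact_poisson_test(0:20, lam)
  expect_true(all(diff(p_n) < 0))
  p_l <- exact_poisson_test(4, seq(0.5, 10, by = 0.5))
  expect_true(all(diff(p_l) > 0))
  expect_error(exact_poisson_test(3, 0), "lambda")
})

test_that("BH adjustment reproduces the textbook step-up", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  set.seed(19)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-14)
    expect_true(all(bh_adjust(p) <= 1))
    expect_true(all(bh_adjust(p) >= p - 1e-15))
  }
  ## per-group correction is independent across groups
  p <- c(0.01, 0.02, 0.04, 0.01, 0.02, 0.04)
  g <- rep(c("a", "b"), each = 3)
  expect_equal(bh_adjust(p, g), rep(c(0.03, 0.03, 0.04), 2))
})

test_that("background fits recover stated GLM coefficients within 3 SE", {
  cat5 <- glm_catalog(5000, "in_loop", b0 = 0, b_decile = 0.08,
                      b_dg = -0.15, b_lp = 0.3, seed = 101, min_count = 0)
  focal <- which(cat5$context_group == "TpC")[1]
  bg <- fit_background(cat5, focal, "in_loop")
  truth <- c(0, 0.08, -0.15, 0.3)
  se <- sqrt(diag(vcov(bg$fit)))
  expect_true(all(abs(bg$coefficients - truth) / se < 3))
  expect_false(bg$fallback)
  expect_equal(bg$n_background, sum(cat5$trinucleotide == cat5$trinucleotide[focal]) - 1L)
})

test_that("constant backgrounds give intercept-only expectations", {
  cat2 <- data.frame(chrom = "c", pos = 1:40, n_mut = 2L,
                     trinucleotide = "TCA", context_group = "TpC",
                     is_tpc = TRUE, in_loop = FALSE,
                     accessibility_decile = 5L, delta_g = NA_real_,
                     loop_pattern = FALSE)
  calls <- suppressWarnings(call_drivers(cat2))
  expect_equal(calls$lambda, rep(2, 40), tolerance = 1e-8)
  expect_false(any(calls$is_driver))
})

test_that("thin trinucleotide strata fall back to the pooled model", {
  cat3 <- glm_catalog(60, "outside_loop", b0 = 0.9, b_decile = 0, seed = 3)
  cat3$trinucleotide[1] <- "TCG"
  cat3$trinucleotide[-1] <- sample(c("TCA", "TCT"), nrow(cat3) - 1, TRUE)
  bg <- fit_background(cat3, 1, "outside_loop")
  expect_true(bg$fallback)
  expect_equal(bg$stratum, "pooled")
  expect_equal(bg$n_background, nrow(cat3) - 1L)
  calls <- suppressWarnings(call_drivers(cat3))
  expect_equal(calls$stratum[calls$site == 1], "pooled")
})

test_that("driver calls: spiked sites detected, ineligible sites never tested", {
  set.seed(3)
  bg <- data.frame(chrom = "s", pos = 1:600,
                   n_mut = pmax(2, rpois(600, 2.2)),
                   trinucleotide = sample(c("TCA", "TCT", "TCC"), 600, TRUE),
                   context_group = "TpC", is_tpc = TRUE, in_loop = FALSE,
                   accessibility_decile = sample(1:10, 600, TRUE),
                   delta_g = NA_real_, loop_pattern = FALSE)
  bg$n_mut[1] <- 20
  ## a non-TpC site outside loops is never tested
  bg$context_group[2] <- "ApC"
  calls <- suppressWarnings(call_drivers(bg))
  expect_true(calls$is_driver[calls$site == 1])
  expect_false(2 %in% calls$site)
  expect_true(all(calls$adj_p >= calls$p - 1e-15))
})

test_that("driver calls are invariant to catalog row order", {
  obs <- simulate_cohort(generate_synthetic_genome(power_preset(), seed = 5),
                         50, seed = 6)
  obs <- obs[obs$pos %% 7 < 5, ][1:800, ]
  calls1 <- suppressWarnings(call_drivers(obs))
  perm <- sample(nrow(obs))
  obs2 <- obs[perm, ]
  calls2 <- suppressWarnings(call_drivers(obs2))
  ## map back: site indices refer to rows of the permuted catalog
  key1 <- paste(obs$chrom[calls1$site], obs$pos[calls1$site])
  key2 <- paste(obs2$chrom[calls2$site], obs2$pos[calls2$site])
  o1 <- order(key1); o2 <- order(key2)
  expect_equal(key1[o1], key2[o2])
  expect_equal(calls1$lambda[o1], calls2$lambda[o2], tolerance = 1e-10)
  expect_equal(calls1$adj_p[o1], calls2$adj_p[o2], tolerance = 1e-10)
  expect_equal(calls1$is_driver[o1], calls2$is_driver[o2])
})

test_that("one-step leave-one-out agrees with the exact refit", {
  cat6 <- glm_catalog(1200, "outside_loop", b0 = 0.8, b_decile = 0.1, seed = 41)
  cat6$trinucleotide <- "TCA"  # a single stratum above the exact cutoff
  c_one <- suppressWarnings(call_drivers(cat6, loo = "onestep"))
  c_ex <- suppressWarnings(call_drivers(cat6, loo = "exact"))
  expect_lt(max(abs(c_one$lambda - c_ex$lambda) / c_ex$lambda), 5e-3)
  expect_equal(c_one$is_driver, c_ex$is_driver)
})

test_that("raw p-values under a null catalog are conservative, BH calls none", {
  cat0 <- glm_catalog(4000, "outside_loop", b0 = 1.6, b_decile = 0.12,
                      seed = 55)
  calls <- suppressWarnings(call_drivers(cat0))
  ## discrete exact tests: the p distribution dominates uniform
  for (q in c(0.01, 0.05, 0.1, 0.25, 0.5)) {
    frac <- mean(calls$p <= q)
    expect_lte(frac, q + 3 * sqrt(q * (1 - q) / nrow(calls)))
  }
  expect_lte(sum(calls$is_driver), 1)
})

test_that("McFadden's R2 matches an independent likelihood computation", {
  cat7 <- glm_catalog(3000, "in_loop", b0 = 0.5, b_decile = 0.1,
                      b_dg = -0.2, b_lp = 0.4, seed = 71, min_count = 0)
  bg <- fit_background(cat7, which(cat7$context_group == "TpC")[1], "in_loop")
  r2 <- mcfadden_r2(bg)
  y <- bg$fit$y
  ll1 <- sum(dpois(y, fitted(bg$fit), log = TRUE))
  ll0 <- sum(dpois(y, mean(y), log = TRUE))
  expect_equal(r2, 1 - ll1 / ll0, tolerance = 1e-10)
  ## the null model scores zero; informative covariates increase R2
  expect_equal(mcfadden_r2(bg$fit, bg$fit), 0)
  null_fit <- glm(y ~ 1, family = poisson())
  expect_gt(r2, mcfadden_r2(null_fit) + 1e-12 - 1e-12)
  expect_gt(r2, 0)
})
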