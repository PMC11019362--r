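test_that("the synthetic genome is reproducible and truncated at two", {
  cfg <- synthetic_genome_config(n_hotspot_positions = 5000, n_drivers = 5)
  g1 <- generate_synthetic_genome(cfg, seed = 10)
  g2 <- generate_synthetic_genome(cfg, seed = 10)
  expect_identical(g1, g2)
  g3 <- generate_synthetic_genome(cfg, seed = 11)
  expect_false(identical(g1$n_mut, g3$n_mut))
  expect_equal(sum(!g1$is_driver), 5000L)
  expect_equal(sum(g1$is_driver), 5L)
  expect_true(all(g1$n_mut[!g1$is_driver] >= 2))
  expect_true(all(g1$prevalence[g1$is_driver] >= 0.03 &
                    g1$prevalence[g1$is_driver] <= 0.15))
  ## infeasible truncation is refused
  expect_error(generate_synthetic_genome(
    synthetic_genome_config(n_hotspot_positions = 10, n_drivers = 0,
                            background_lambda = 1e-9), seed = 1),
    "infeasible")
})

test_that("background recurrence follows the truncated Poisson law", {
  cfg <- synthetic_genome_config(n_hotspot_positions = 2e5, n_drivers = 0)
  g <- generate_synthetic_genome(cfg, seed = 77)
  obs <- table(factor(pmin(g$n_mut, 6), levels = 2:6))
  lam <- cfg$background_lambda
  pk <- dpois(2:5, lam) / ppois(1, lam, lower.tail = FALSE)
  probs <- c(pk, 1 - sum(pk))
  chi <- suppressWarnings(chisq.test(as.numeric(obs), p = probs))
  expect_gt(chi$p.value, 0.001)
})

test_that("cohort thinning scales counts and drops sub-hotspot positions", {
  cfg <- synthetic_genome_config(n_hotspot_positions = 20000, n_drivers = 4)
  g <- generate_synthetic_genome(cfg, seed = 21)
  ## at the reference size the background catalog reproduces the genome
  same <- simulate_cohort(g, n_samples = attr(g, "config")$n_ref, seed = 3)
  expect_equal(sum(!same$is_driver), sum(!g$is_driver))
  expect_equal(sum(same$n_mut[!same$is_driver]), sum(g$n_mut[!g$is_driver]))
  ## dropout matches the analytic survival law P(Binomial(rec, n/n_ref) >= 2)
  half <- simulate_cohort(g, n_samples = 58, seed = 4)
  p_surv <- pbinom(1, g$n_mut[!g$is_driver], 58 / 115, lower.tail = FALSE)
  expect_lt(abs(sum(!half$is_driver) / sum(p_surv) - 1), 0.05)
  expect_lt(nrow(half), nrow(g))
  ## drivers: expected count n_samples * prevalence; doubling n doubles it
  set.seed(8)
  prev <- attr(half, "driver_prevalence")
  expect_equal(length(prev), 4L)
  d1 <- replicate(200, {
    s <- simulate_cohort(g, 100, seed = sample.int(1e6, 1))
    x <- s$n_mut[s$is_driver][match(g$pos[g$is_driver], s$pos[s$is_driver])]
    x[is.na(x)] <- 0
    x
  })
  expect_equal(rowMeans(d1), 100 * g$prevalence[g$is_driver], tolerance = 0.12)
  expect_error(simulate_cohort(g, 1), ">= 2")
})

test_that("a small-cohort driver at 15% prevalence frequently drops out", {
  cfg <- synthetic_genome_config(n_hotspot_positions = 500, n_drivers = 1,
                                 driver_prevalence_range = c(0.15, 0.15))
  g <- generate_synthetic_genome(cfg, seed = 5)
  present <- vapply(1:150, function(i) {
    s <- simulate_cohort(g, 10, seed = i)
    any(s$is_driver)
  }, logical(1))
  ## Binomial(10, 0.15) >= 2 with probability ~0.46
  expect_gt(mean(!present), 0.3)
  expect_lt(mean(!present), 0.75)
})

test_that("power grows with cohort size and respects the null", {
  cfg <- power_preset(n_hotspot_positions = 2000L)
  pw <- power_analysis(cfg, cohort_sizes = c(40, 150), n_replicates = 8,
                       seed = 17)
  hi <- pw[pw$prevalence_bin == ">10%", ]
  expect_equal(nrow(hi), 2L)
  ## monotone within 2 Monte-Carlo SE
  expect_gte(hi$power[hi$cohort_size == 150] + 2 * sum(hi$se),
             hi$power[hi$cohort_size == 40])
  expect_true(all(pw$false_positive_rate <= 0.01))
  ## a fully null configuration yields (almost) no BH-significant calls
  null_cfg <- power_preset(n_hotspot_positions = 2000L, n_drivers = 0L)
  g0 <- generate_synthetic_genome(null_cfg, seed = 2)
  fp <- vapply(1:3, function(i) {
    s <- simulate_cohort(g0, 75, seed = i)
    calls <- suppressWarnings(call_drivers(s))
    sum(calls$is_driver)
  }, numeric(1))
  expect_lte(sum(fp), 2)
})

test_that("stratified and pooled backgrounds agree when covariates are inert", {
  cfg <- power_preset(n_hotspot_positions = 3000L)
  g <- generate_synthetic_genome(cfg, seed = 12)
  obs <- simulate_cohort(g, 80, seed = 13)
  strat <- suppressWarnings(call_drivers(obs))
  pooled <- suppressWarnings(call_drivers(obs, min_background = .Machine$integer.max))
  expect_true(all(pooled$stratum == "pooled"))
  common <- intersect(strat$site, pooled$site)
  agree <- mean(strat$is_driver[match(common, strat$site)] ==
                  pooled$is_driver[match(common, pooled$site)])
  expect_gte(agree, 0.99)
})

test_that("sequence and cohort fixture generators are deterministic and valid", {
  r1 <- simulate_reference(c(a = 500, b = 300), seed = 6)
  r2 <- simulate_reference(c(a = 500, b = 300), seed = 6)
  expect_identical(as.character(r1), as.character(r2))
  expect_equal(Biostrings::width(r1), c(500L, 300L))
  m <- simulate_apobec_cohort(r1, n_samples = 3, muts_per_sample = 30, seed = 2)
  expect_silent(validate_mutations(m))
  expect_lte(length(unique(m$sample_id)), 3L)
  ctx <- extract_context(r1, m$chrom, m$pos, m$ref)
  ## APOBEC-like targeting enriches the TpC fraction
  expect_gt(mean(ctx$is_tpc), 0.4)
})
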