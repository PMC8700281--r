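# Seeded Monte Carlo screening cohort: determinism, parameter recovery,
# and the size-detectability curve.

test_that("cohort generation is byte-identical under a fixed seed", {
  cfg <- cohort_config(n = 2000, prevalence = 0.02, seed = 99,
                       test = test_performance(0.3, 0.99))
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  # a different seed changes the stream
  cfg2 <- cohort_config(n = 2000, prevalence = 0.02, seed = 100,
                        test = test_performance(0.3, 0.99))
  expect_false(identical(generate_cohort(cfg2), a))
})

test_that("cancer status follows the prevalence", {
  expect_equal(sum(generate_cohort(cohort_config(
    n = 500, prevalence = 0, seed = 1))$has_cancer), 0)

  cfg <- cohort_config(n = 10000, prevalence = 0.01, seed = 4)
  cases <- sum(generate_cohort(cfg)$has_cancer)
  # central 99% binomial interval around the expected 100 cases
  expect_gte(cases, qbinom(0.005, 10000, 0.01))
  expect_lte(cases, qbinom(0.995, 10000, 0.01))
})

test_that("non-cases shed nothing; case columns are consistent", {
  cfg <- cohort_config(n = 5000, prevalence = 0.1, seed = 21,
                       test = test_performance(0.10, 0.995))
  coh <- generate_cohort(cfg)
  ctrl <- coh[!coh$has_cancer, ]
  expect_true(all(ctrl$tumor_diameter == 0))
  expect_true(all(ctrl$expected_genomes == 0))
  expect_true(all(ctrl$sampled_genomes == 0))
  cases <- coh[coh$has_cancer, ]
  expect_true(all(cases$tumor_diameter > 0))
  expect_equal(cases$expected_genomes,
               total_genome_equivalents(cfg$draw, cfg$model) *
                 maf_from_volume(diameter_to_volume(cases$tumor_diameter)))
})

test_that("per-draw capture rate matches the Poisson closed form", {
  # every subject carries the same large tumor; probabilistic criterion
  d27 <- size_distribution("fixed", diameter_mm = 27)
  cfg <- cohort_config(
    n = 20000, prevalence = 1, sizes = d27, seed = 7,
    criterion = detection_criterion(mode = "probabilistic"),
    genomes_per_draw = 6000)
  coh <- generate_cohort(cfg)
  lambda <- coh$expected_genomes[1]
  hit <- mean(coh$sampled_genomes >= 1)
  expect_equal(hit, 1 - exp(-lambda), tolerance = 0.005)
  expect_true(all(coh$test_positive == (coh$sampled_genomes >= 1)))

  # a 1 cm^3 tumor: capture probability 1 - e^-0.6 = 0.451
  d1 <- size_distribution("fixed", diameter_mm = volume_to_diameter(1))
  cfg1 <- cohort_config(
    n = 20000, prevalence = 1, sizes = d1, seed = 8,
    criterion = detection_criterion(mode = "probabilistic"),
    genomes_per_draw = 6000)
  coh1 <- generate_cohort(cfg1)
  expect_equal(mean(coh1$sampled_genomes >= 1), 1 - exp(-0.6),
               tolerance = 0.015)
})

test_that("empirical metrics recover the analytic screening values", {
  test <- test_performance(0.10, 0.995)
  cfg <- cohort_config(n = 100000, prevalence = 0.01, seed = 42,
                       test = test)
  coh <- generate_cohort(cfg)
  m <- empirical_metrics(coh)
  rownames(m) <- m$metric
  scenario <- screening_scenario(test, 0.01)

  # conservation
  expect_equal(m["sensitivity", "denominator"] +
                 m["specificity", "denominator"], 100000)

  # analytic values inside the Wilson 95% intervals
  expect_gte(0.10, m["sensitivity", "lower"])
  expect_lte(0.10, m["sensitivity", "upper"])
  expect_gte(0.995, m["specificity", "lower"])
  expect_lte(0.995, m["specificity", "upper"])
  expect_gte(ppv(scenario), m["ppv", "lower"])
  expect_lte(ppv(scenario), m["ppv", "upper"])
  expect_gte(npv(scenario), m["npv", "lower"])
  expect_lte(npv(scenario), m["npv", "upper"])
})

test_that("degenerate cohorts flag undefined metrics instead of NaN", {
  coh <- data.frame(has_cancer = rep(TRUE, 10),
                    test_positive = rep(TRUE, 10))
  m <- empirical_metrics(coh)
  rownames(m) <- m$metric
  expect_equal(m["sensitivity", "estimate"], 1)
  expect_true(is.na(m["specificity", "estimate"]))
  expect_true(is.na(m["npv", "estimate"]))
})

test_that("detection fraction rises with tumor size", {
  cfg <- cohort_config(
    n = 40000, prevalence = 1,
    sizes = size_distribution("lognormal", median_mm = 10, sdlog = 0.4),
    seed = 3,
    criterion = detection_criterion(mode = "probabilistic"),
    genomes_per_draw = 6000)
  coh <- generate_cohort(cfg)
  bins <- c(0, 5, 10, 15, 20, 30)
  curve <- sensitivity_by_size(coh, bins)
  expect_equal(nrow(curve), 5)
  expect_true(all(curve$n_cases[2:4] > 100))
  expect_gt(curve$fraction[curve$bin_lower == 15],
            curve$fraction[curve$bin_lower == 5])
  # per-bin rates sit near the Poisson closed form at the bin mean
  for (i in 2:4) {
    sel <- coh$tumor_diameter >= bins[i] & coh$tumor_diameter < bins[i + 1]
    lam <- mean(coh$expected_genomes[sel])
    expect_equal(curve$fraction[i], 1 - exp(-lam), tolerance = 0.05)
  }
  # a single all-covering bin equals the overall empirical sensitivity
  all_bin <- sensitivity_by_size(coh, c(0, 1000))
  expect_equal(all_bin$fraction, mean(coh$test_positive))
  # empty bins are missing, not zero
  far <- sensitivity_by_size(coh, c(500, 600))
  expect_true(is.na(far$fraction))
  expect_error(sensitivity_by_size(coh, c(10, 10)), "increasing")
})

test_that("expected-value criterion flips at the detectability threshold", {
  thr <- min_detectable_diameter(genomes_per_draw = 6000) # 14.71 mm
  cfg <- cohort_config(
    n = 5000, prevalence = 1,
    sizes = size_distribution("lognormal", median_mm = 14, sdlog = 0.3),
    seed = 12, genomes_per_draw = 6000)
  coh <- generate_cohort(cfg)
  expect_true(all(coh$test_positive[coh$tumor_diameter > thr + 1e-6]))
  expect_true(!any(coh$test_positive[coh$tumor_diameter < thr - 1e-6]))
})

test_that("cohort CSV round-trips", {
  cfg <- cohort_config(n = 50, prevalence = 0.2, seed = 5,
                       test = test_performance(0.5, 0.99))
  coh <- generate_cohort(cfg)
  f <- tempfile(fileext = ".csv")
  write_cohort(coh, f)
  back <- read.csv(f)
  expect_equal(names(back), names(coh))
  expect_equal(back$sampled_genomes, coh$sampled_genomes)
  expect_equal(back$has_cancer, coh$has_cancer)
})
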