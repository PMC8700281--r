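# Poisson sampling limit of detection.

# Independent oracle: brute-force complement of the Poisson pmf sum
# P(X >= k) = 1 - sum_{i<k} exp(-l) l^i / i!
brute_force_tail <- function(lambda, k) {
  if (k == 0) return(rep(1, length(lambda)))
  i <- 0:(k - 1)
  sapply(lambda, function(l) 1 - sum(exp(-l) * l^i / factorial(i)))
}

test_that("detection probability matches brute-force pmf sums", {
  expect_equal(detection_probability(0), 0)
  expect_equal(detection_probability(0.6), 0.451188, tolerance = 1e-5)
  expect_equal(
    detection_probability(6, detection_criterion(min_molecules = 2)),
    0.982649, tolerance = 1e-5)

  for (k in c(1, 2, 5, 10, 20)) {
    crit <- detection_criterion(min_molecules = k)
    lambda <- c(0.01, 0.3, 0.6, 1, 3, 6, 12, 25, 50)
    expect_equal(detection_probability(lambda, crit),
                 brute_force_tail(lambda, k), tolerance = 1e-10,
                 info = paste("k =", k))
  }
})

test_that("detection probability is monotone in lambda and in k", {
  lambda <- seq(0, 20, by = 0.5)
  p1 <- detection_probability(lambda)
  expect_true(all(diff(p1) >= 0))
  for (k in 1:6) {
    pk <- detection_probability(
      5, detection_criterion(min_molecules = k))
    pk1 <- detection_probability(
      5, detection_criterion(min_molecules = k + 1))
    expect_true(pk1 < pk)
  }
  expect_error(detection_probability(-1), "non-negative")
})

test_that("evaluate_detection applies the two criterion modes", {
  # a 10 cm^3 tumor puts ~6 genomes in the draw: detectable
  res <- evaluate_detection(tumor_spec(volume_cm3 = 10),
                            genomes_per_draw = 6000)
  expect_equal(res$expected_genomes, 6.0)
  expect_true(res$detectable)

  # a 1 cm^3 tumor is expected to yield less than one complete genome
  res1 <- evaluate_detection(tumor_spec(volume_cm3 = 1),
                             genomes_per_draw = 6000)
  expect_equal(res1$expected_genomes, 0.6)
  expect_false(res1$detectable)

  res0 <- evaluate_detection(0, genomes_per_draw = 6000)
  expect_equal(res0$expected_genomes, 0)
  expect_equal(res0$p_detect, 0)
  expect_false(res0$detectable)

  # probabilistic mode flips on the probability threshold instead
  crit <- detection_criterion(mode = "probabilistic",
                              prob_threshold = 0.4)
  resp <- evaluate_detection(1, criterion = crit, genomes_per_draw = 6000)
  expect_true(resp$detectable) # p = 0.451 >= 0.4
  crit2 <- detection_criterion(mode = "probabilistic",
                               prob_threshold = 0.5)
  expect_false(evaluate_detection(1, criterion = crit2,
                                  genomes_per_draw = 6000)$detectable)
})

test_that("minimum detectable volume has the expected closed form", {
  expect_equal(min_detectable_volume(genomes_per_draw = 6000),
               1 / 0.6, tolerance = 1e-9)
  expect_equal(min_detectable_diameter(genomes_per_draw = 6000),
               14.71, tolerance = 1e-3)
  expect_equal(
    min_detectable_volume(
      criterion = detection_criterion(min_molecules = 6),
      genomes_per_draw = 6000),
    10.0, tolerance = 1e-9)
  # more genome equivalents -> smaller detectable tumor (monotone)
  vols <- sapply(c(6e3, 6e4, 6e5, 6e6),
                 function(g) min_detectable_volume(genomes_per_draw = g))
  expect_true(all(diff(vols) < 0))
  expect_lt(vols[4], 1e-2)
})

test_that("probabilistic-mode bisection brackets the criterion boundary", {
  crit <- detection_criterion(mode = "probabilistic", prob_threshold = 0.5)
  v <- min_detectable_volume(criterion = crit, genomes_per_draw = 6000)
  # closed form: lambda* = log 2, volume = lambda* / (6000 * 1e-4)
  expect_equal(v, log(2) / 0.6, tolerance = 1e-5)
  model <- shed_model()
  p_at <- function(vol) detection_probability(
    6000 * maf_from_volume(vol, model), crit)
  expect_gte(p_at(v), 0.5)
  expect_lt(p_at(v - 1e-4), 0.5)
})

test_that("MAF detection limit and its decade convention", {
  expect_equal(maf_detection_limit(genomes_per_draw = 6000), 1 / 6000)
  expect_equal(maf_decade_limit(genomes_per_draw = 6000), 1e-4)
  # default model-derived draw: 6022 genome equivalents, same decade
  expect_equal(maf_detection_limit(), 1.6606e-4, tolerance = 1e-4)
  expect_equal(maf_decade_limit(), 1e-4)

  # doubling the plasma volume exactly halves the limit
  m <- shed_model()
  lim10 <- maf_detection_limit(draw_spec(10, m), m)
  lim20 <- maf_detection_limit(draw_spec(20, m), m)
  expect_equal(lim20, lim10 / 2, tolerance = 1e-12)
  expect_equal(lim20, 8.303e-5, tolerance = 1e-4)

  # degenerate zero-molecule criterion detects anything
  expect_equal(
    maf_detection_limit(criterion = detection_criterion(min_molecules = 0),
                        genomes_per_draw = 6000), 0)

  # empty draw is an explicit no-solution signal
  expect_warning(
    lim <- maf_detection_limit(
      draw_spec(0, m), m, genomes_per_draw = NULL),
    "unsatisfiable")
  expect_true(is.na(lim))
})

test_that("largest decade strictly below a limit", {
  expect_equal(largest_decade_below(1 / 6000), 1e-4)
  expect_equal(largest_decade_below(1.67e-4), 1e-4)
  expect_equal(largest_decade_below(1e-4), 1e-5) # strictly below
  expect_equal(largest_decade_below(9.99e-3), 1e-3)
})
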