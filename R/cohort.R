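# Seeded synthetic screening population and Monte Carlo validation of the
# analytic detection / screening results.

#' Tumor-size distribution for a synthetic cohort
#'
#' @param kind `"lognormal"` (diameters lognormal on the mm scale),
#'   `"fixed"` (every case the same diameter) or `"table1_grid"` (diameters
#'   drawn uniformly from the packaged tumor-characteristics grid).
#' @param median_mm Median diameter in mm (lognormal; default 8, chosen to
#'   straddle the 10--15 mm detectability band).
#' @param sdlog Log-scale standard deviation (lognormal; default 0.5).
#' @param diameter_mm Fixed diameter in mm (fixed kind).
#' @return An object of class `size_distribution`.
#' @export
size_distribution <- function(kind = c("lognormal", "fixed", "table1_grid"),
                              median_mm = 8, sdlog = 0.5,
                              diameter_mm = NULL) {
  kind <- match.arg(kind)
  if (kind == "lognormal") {
    stopifnot(is.numeric(median_mm), median_mm > 0,
              is.numeric(sdlog), sdlog > 0)
  } else if (kind == "fixed") {
    if (is.null(diameter_mm))
      stop("fixed size distribution requires diameter_mm")
    stopifnot(is.numeric(diameter_mm), diameter_mm > 0)
  }
  structure(
    list(kind = kind, median_mm = median_mm, sdlog = sdlog,
         diameter_mm = diameter_mm),
    class = "size_distribution"
  )
}

sample_diameters <- function(dist, n) {
  if (n == 0L) return(numeric(0))
  switch(dist$kind,
    lognormal = stats::rlnorm(n, meanlog = log(dist$median_mm),
                              sdlog = dist$sdlog),
    fixed = rep(dist$diameter_mm, n),
    table1_grid = sample(table1_printed_data()$diameter_mm, n,
                         replace = TRUE)
  )
}

#' Synthetic cohort configuration
#'
#' Recipe for a simulated screening population: per-subject cancer status
#' at a stated prevalence, tumor diameters from a stated distribution, and
#' per-subject Poisson sampling of tumor genome copies into a blood draw.
#'
#' @param n Number of subjects (>= 1).
#' @param prevalence Cancer prevalence in \[0, 1\].
#' @param sizes A [size_distribution()].
#' @param seed Integer seed; fixes the full output stream.
#' @param draw A [draw_spec()].
#' @param model A [shed_model()].
#' @param criterion A [detection_criterion()].
#' @param test Optional [test_performance()]. When present, test calls are
#'   Bernoulli draws at the stated sensitivity (cases) and 1 - specificity
#'   (non-cases), emulating an assay whose error rates are known; when
#'   absent, positivity follows mechanistically from the detection
#'   criterion applied to the draw, and non-cases are never positive.
#' @param genomes_per_draw Optional override of total genome equivalents
#'   per draw.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n, prevalence, sizes = size_distribution(),
                          seed = 1L, draw = draw_spec(model = model),
                          model = shed_model(),
                          criterion = detection_criterion(),
                          test = NULL, genomes_per_draw = NULL) {
  stopifnot(
    is.numeric(n), n >= 1, n == as.integer(n),
    is.numeric(prevalence), prevalence >= 0, prevalence <= 1,
    inherits(sizes, "size_distribution"),
    is.numeric(seed), seed == as.integer(seed),
    inherits(draw, "draw_spec"), inherits(model, "shed_model"),
    inherits(criterion, "detection_criterion")
  )
  if (!is.null(test)) stopifnot(inherits(test, "test_performance"))
  structure(
    list(n = as.integer(n), prevalence = prevalence, sizes = sizes,
         seed = as.integer(seed), draw = draw, model = model,
         criterion = criterion, test = test,
         genomes_per_draw = genomes_per_draw),
    class = "cohort_config"
  )
}

#' Generate a synthetic screening cohort
#'
#' Deterministic under the config's seed: cancer status is
#' Bernoulli(prevalence); case diameters come from the size distribution;
#' the tumor genome copies captured by each case's blood draw are Poisson
#' with mean given by the shedding model; non-cases shed zero tumor
#' genomes. Test positivity follows either the attached
#' [test_performance()] (sensitivity/specificity Bernoulli draws) or, in
#' its absence, the detection criterion applied to the draw.
#'
#' @param config A [cohort_config()].
#' @return A data.frame with one row per subject: `id`, `has_cancer`,
#'   `tumor_diameter` (mm, 0 if none), `expected_genomes`,
#'   `sampled_genomes`, `test_positive`.
#' @examples
#' cfg <- cohort_config(n = 1000, prevalence = 0.01, seed = 7,
#'                      test = test_performance(0.10, 0.995))
#' cohort <- generate_cohort(cfg)
#' table(cohort$has_cancer, cohort$test_positive)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n
  set.seed(config$seed)
  has_cancer <- stats::rbinom(n, 1L, config$prevalence) == 1L
  n_cases <- sum(has_cancer)

  diameter <- numeric(n)
  diameter[has_cancer] <- sample_diameters(config$sizes, n_cases)

  total <- if (is.null(config$genomes_per_draw))
    total_genome_equivalents(config$draw, config$model)
  else config$genomes_per_draw
  expected <- numeric(n)
  expected[has_cancer] <-
    total * maf_from_volume(diameter_to_volume(diameter[has_cancer]),
                            config$model)

  sampled <- integer(n)
  sampled[has_cancer] <- stats::rpois(n_cases, expected[has_cancer])

  positive <- logical(n)
  if (!is.null(config$test)) {
    positive[has_cancer] <-
      stats::runif(n_cases) < config$test$sensitivity
    positive[!has_cancer] <-
      stats::runif(n - n_cases) < (1 - config$test$specificity)
  } else if (config$criterion$mode == "expected_value") {
    positive[has_cancer] <-
      expected[has_cancer] >= config$criterion$min_molecules
  } else {
    positive[has_cancer] <-
      sampled[has_cancer] >= config$criterion$min_molecules
  }

  data.frame(
    id = seq_len(n),
    has_cancer = has_cancer,
    tumor_diameter = diameter,
    expected_genomes = expected,
    sampled_genomes = sampled,
    test_positive = positive
  )
}

# Wilson 95% score interval via prop.test (no continuity correction)
wilson_ci <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  as.numeric(stats::prop.test(x, n, conf.level = conf,
                              correct = FALSE)$conf.int)
}

#' Empirical screening metrics from a simulated cohort
#'
#' Counts-based sensitivity, specificity, PPV and NPV with Wilson 95%
#' confidence intervals. A metric whose denominator is empty (e.g. PPV in
#' a cohort with no positive calls) is flagged undefined by returning `NA`
#' for its estimate and interval rather than propagating NaN.
#'
#' @param cohort A data.frame from [generate_cohort()] (needs
#'   `has_cancer` and `test_positive` columns).
#' @param conf Confidence level for the Wilson intervals (default 0.95).
#' @return A data.frame with columns `metric`, `estimate`, `lower`,
#'   `upper`, `numerator`, `denominator`.
#' @export
empirical_metrics <- function(cohort, conf = 0.95) {
  stopifnot(nrow(cohort) > 0,
            all(c("has_cancer", "test_positive") %in% names(cohort)))
  tp <- sum(cohort$has_cancer & cohort$test_positive)
  fp <- sum(!cohort$has_cancer & cohort$test_positive)
  tn <- sum(!cohort$has_cancer & !cohort$test_positive)
  fn <- sum(cohort$has_cancer & !cohort$test_positive)
  one <- function(metric, x, n) {
    ci <- wilson_ci(x, n, conf)
    data.frame(metric = metric,
               estimate = if (n > 0) x / n else NA_real_,
               lower = ci[1], upper = ci[2],
               numerator = x, denominator = n)
  }
  rbind(
    one("sensitivity", tp, tp + fn),
    one("specificity", tn, tn + fp),
    one("ppv", tp, tp + fp),
    one("npv", tn, tn + fn)
  )
}

#' Empirical detection fraction by tumor-size bin
#'
#' Among cancer cases, the fraction testing positive within each diameter
#' bin — the simulated counterpart of the size-detectability curve, which
#' should rise through the 10--15 mm band under the default model. Bins
#' are left-closed, right-open; empty bins are reported with `NA`
#' fractions rather than zero.
#'
#' @param cohort A data.frame from [generate_cohort()].
#' @param bin_edges Strictly increasing diameter bin edges in mm.
#' @return A data.frame with `bin_lower`, `bin_upper`, `n_cases`,
#'   `n_detected`, `fraction`.
#' @export
sensitivity_by_size <- function(cohort, bin_edges) {
  stopifnot(is.numeric(bin_edges), length(bin_edges) >= 2)
  if (any(diff(bin_edges) <= 0))
    stop("bin_edges must be strictly increasing")
  cases <- cohort[cohort$has_cancer, , drop = FALSE]
  k <- length(bin_edges) - 1L
  out <- data.frame(
    bin_lower = bin_edges[-length(bin_edges)],
    bin_upper = bin_edges[-1],
    n_cases = integer(k), n_detected = integer(k),
    fraction = rep(NA_real_, k)
  )
  idx <- findInterval(cases$tumor_diameter, bin_edges,
                      rightmost.closed = FALSE)
  for (i in seq_len(k)) {
    sel <- idx == i
    out$n_cases[i] <- sum(sel)
    out$n_detected[i] <- sum(cases$test_positive[sel])
    if (out$n_cases[i] > 0)
      out$fraction[i] <- out$n_detected[i] / out$n_cases[i]
  }
  out
}

#' Write a cohort to CSV
#'
#' One row per subject, header fixed as the subject field names.
#'
#' @param cohort A data.frame from [generate_cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
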