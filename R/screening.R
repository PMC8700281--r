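# Analytic screening-programme performance: PPV/NPV by Bayes' rule,
# expected confusion counts, and packaged reference test performance.

#' Test performance
#'
#' Sensitivity and specificity of a screening test.
#'
#' @param sensitivity Probability a case tests positive, in \[0, 1\].
#' @param specificity Probability a non-case tests negative, in \[0, 1\].
#' @param label Optional text label.
#' @return An object of class `test_performance`.
#' @export
test_performance <- function(sensitivity, specificity, label = "") {
  stopifnot(
    is.numeric(sensitivity), sensitivity >= 0, sensitivity <= 1,
    is.numeric(specificity), specificity >= 0, specificity <= 1,
    is.character(label)
  )
  structure(
    list(sensitivity = sensitivity, specificity = specificity,
         label = label),
    class = "test_performance"
  )
}

#' Screening scenario
#'
#' A test applied to a population with a given disease prevalence,
#' optionally with a population size for expected counts.
#'
#' @param test A [test_performance()].
#' @param prevalence Disease prevalence in the screened population,
#'   in \[0, 1\].
#' @param n_screened Optional number of people screened (non-negative
#'   integer).
#' @return An object of class `screening_scenario`.
#' @examples
#' # screening for a fairly common cancer with a low-sensitivity early test
#' screening_scenario(test_performance(0.10, 0.995), prevalence = 0.01)
#' @export
screening_scenario <- function(test, prevalence, n_screened = NULL) {
  stopifnot(
    inherits(test, "test_performance"),
    is.numeric(prevalence), prevalence >= 0, prevalence <= 1
  )
  if (!is.null(n_screened)) {
    stopifnot(is.numeric(n_screened), n_screened >= 0,
              n_screened == as.integer(n_screened))
    n_screened <- as.integer(n_screened)
  }
  structure(
    list(test = test, prevalence = prevalence, n_screened = n_screened),
    class = "screening_scenario"
  )
}

#' @export
print.screening_scenario <- function(x, ...) {
  cat(sprintf(
    "Screening scenario%s: sens %.4g, spec %.4g, prevalence %.4g",
    if (nzchar(x$test$label)) paste0(" [", x$test$label, "]") else "",
    x$test$sensitivity, x$test$specificity, x$prevalence))
  if (!is.null(x$n_screened)) cat(sprintf(", n = %d", x$n_screened))
  cat("\n")
  invisible(x)
}

#' Positive predictive value
#'
#' The probability that disease is present given a positive test:
#' `sens * prev / (sens * prev + (1 - spec) * (1 - prev))`. At 10%
#' sensitivity, 99.5% specificity and 1% prevalence the PPV is 0.168
#' (17% at integer-percent rounding) — a key figure for judging whether a
#' screening programme is sustainable.
#'
#' @param scenario A [screening_scenario()].
#' @return PPV in \[0, 1\], or `NA_real_` with a warning when no positive
#'   calls are possible (the conditional probability is undefined).
#' @examples
#' ppv(screening_scenario(test_performance(0.10, 0.995), 0.01))
#' @export
ppv <- function(scenario) {
  sens <- scenario$test$sensitivity
  spec <- scenario$test$specificity
  prev <- scenario$prevalence
  denom <- sens * prev + (1 - spec) * (1 - prev)
  if (denom == 0) {
    warning("PPV undefined: the test can produce no positive calls")
    return(NA_real_)
  }
  sens * prev / denom
}

#' Negative predictive value
#'
#' The probability that disease is absent given a negative test:
#' `spec * (1 - prev) / (spec * (1 - prev) + (1 - sens) * prev)`.
#'
#' @param scenario A [screening_scenario()].
#' @return NPV in \[0, 1\], or `NA_real_` with a warning when no negative
#'   calls are possible.
#' @export
npv <- function(scenario) {
  sens <- scenario$test$sensitivity
  spec <- scenario$test$specificity
  prev <- scenario$prevalence
  denom <- spec * (1 - prev) + (1 - sens) * prev
  if (denom == 0) {
    warning("NPV undefined: the test can produce no negative calls")
    return(NA_real_)
  }
  spec * (1 - prev) / denom
}

#' Expected confusion counts for a screened population
#'
#' Expected true positives, false positives, true negatives and false
#' negatives among `n_screened` people; the four counts sum to n exactly.
#' The FP count is what drives the downstream burden of unnecessary
#' confirmatory testing in low-prevalence screening.
#'
#' @param scenario A [screening_scenario()] with `n_screened` set.
#' @return Named numeric vector `c(TP, FP, TN, FN)` of expected counts
#'   (possibly fractional).
#' @examples
#' sc <- screening_scenario(test_performance(0.10, 0.995), 0.01, 100000)
#' expected_confusion(sc) # TP 100, FP 495, TN 98505, FN 900
#' @export
expected_confusion <- function(scenario) {
  if (is.null(scenario$n_screened))
    stop("expected_confusion requires n_screened in the scenario")
  n <- scenario$n_screened
  sens <- scenario$test$sensitivity
  spec <- scenario$test$specificity
  prev <- scenario$prevalence
  c(
    TP = n * prev * sens,
    FP = n * (1 - prev) * (1 - spec),
    TN = n * (1 - prev) * spec,
    FN = n * prev * (1 - sens)
  )
}

#' Reference stage-stratified sensitivities (multi-cancer methylation test)
#'
#' Published case-control performance of a targeted-methylation
#' multi-cancer early detection assay: stage-stratified sensitivities at
#' 99.5% specificity. These are external trial results packaged verbatim
#' as constants; they are never recomputed by this package.
#'
#' @return A list with `by_stage` (named vector of sensitivities),
#'   `overall` and `specificity`.
#' @examples
#' grail_ccga3()$by_stage[["Stage I"]] # 0.17
#' @export
grail_ccga3 <- function() {
  list(
    by_stage = c(
      "Stage I" = 0.17,
      "Stage II" = 0.40,
      "Stages I-II" = 0.28,
      "Stages III-VI" = 0.84
    ),
    overall = 0.52,
    specificity = 0.995
  )
}

#' Build a reference screening scenario by name
#'
#' @param name Reference test name; only `"grail-ccga3"` is packaged.
#' @param stage Stage label from [grail_ccga3()]'s `by_stage` (or
#'   `"overall"`).
#' @param prevalence Population prevalence (default 0.01, a fairly common
#'   cancer).
#' @param n_screened Optional population size.
#' @return A [screening_scenario()].
#' @export
reference_scenario <- function(name = "grail-ccga3", stage = "overall",
                               prevalence = 0.01, n_screened = NULL) {
  if (!identical(name, "grail-ccga3"))
    stop("unknown reference scenario: ", name)
  ref <- grail_ccga3()
  sens <- if (identical(stage, "overall")) ref$overall
          else unname(ref$by_stage[stage])
  if (length(sens) != 1 || is.na(sens))
    stop("unknown stage label: ", stage)
  screening_scenario(
    test_performance(sens, ref$specificity,
                     label = paste0(name, " / ", stage)),
    prevalence = prevalence, n_screened = n_screened
  )
}

#' Format a probability using the percent display convention
#'
#' Values of at least 10% are shown at the nearest integer percent
#' (0.16807 prints as "17%"); smaller values at two significant figures
#' ("2.0%", "0.05%").
#'
#' @param p Probability in \[0, 1\] (vectorized; `NA` prints as "NA").
#' @return Character vector.
#' @export
format_percent <- function(p) {
  vapply(p, function(x) {
    if (is.na(x)) return("NA")
    pct <- 100 * x
    if (pct >= 10) sprintf("%d%%", as.integer(round(pct)))
    else paste0(format(signif(pct, 2), scientific = FALSE, trim = TRUE), "%")
  }, character(1))
}
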