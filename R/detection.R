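# Poisson sampling limit of detection: converts expected tumor genome
# copies per draw into detection probabilities and inverts the chain to
# find the smallest detectable tumor / MAF.

#' Detection criterion for a single blood draw
#'
#' What counts as "detected". In `expected_value` mode a draw is deemed
#' informative only if the *expected* number of tumor genome copies meets
#' `min_molecules` — the convention behind the argument that a draw
#' expected to hold less than one complete cancer genome cannot support a
#' diagnosis. `probabilistic` mode treats the copies actually captured as
#' Poisson-distributed around that expectation and requires
#' `P(X >= min_molecules) >= prob_threshold`.
#'
#' @param min_molecules Minimum tumor genome copies for a positive call
#'   (non-negative integer; default 1; 0 is the degenerate criterion that
#'   every draw satisfies).
#' @param mode `"expected_value"` (default) or `"probabilistic"`.
#' @param prob_threshold Required detection probability in probabilistic
#'   mode, in (0, 1). Default 0.5.
#' @return An object of class `detection_criterion`.
#' @export
detection_criterion <- function(min_molecules = 1,
                                mode = c("expected_value", "probabilistic"),
                                prob_threshold = 0.5) {
  mode <- match.arg(mode)
  stopifnot(
    is.numeric(min_molecules), length(min_molecules) == 1L,
    min_molecules >= 0, min_molecules == as.integer(min_molecules),
    is.numeric(prob_threshold), prob_threshold > 0, prob_threshold < 1
  )
  structure(
    list(min_molecules = as.integer(min_molecules), mode = mode,
         prob_threshold = prob_threshold),
    class = "detection_criterion"
  )
}

#' @export
print.detection_criterion <- function(x, ...) {
  cat(sprintf("Detection criterion: >= %d molecule(s), %s mode",
              x$min_molecules, x$mode))
  if (x$mode == "probabilistic")
    cat(sprintf(" (P >= %g)", x$prob_threshold))
  cat("\n")
  invisible(x)
}

#' Probability that a draw captures enough tumor genome copies
#'
#' Genome copies are sampled into the plasma aliquot from a vastly larger
#' circulating pool at a tiny fraction, so the captured count is Poisson
#' with mean equal to the expected copies per draw. Returns
#' `P(X >= min_molecules)` for `X ~ Poisson(expected_genomes)`; for a
#' single-molecule criterion this is `1 - exp(-lambda)`.
#'
#' @param expected_genomes Expected tumor genome copies in the draw
#'   (vectorized, non-negative).
#' @param criterion A [detection_criterion()]; only `min_molecules` is
#'   used.
#' @return Detection probability in \[0, 1\].
#' @examples
#' detection_probability(0.6) # 1 - exp(-0.6) = 0.451
#' @export
detection_probability <- function(expected_genomes,
                                  criterion = detection_criterion()) {
  stopifnot(is.numeric(expected_genomes))
  if (any(expected_genomes < 0))
    stop("expected_genomes must be non-negative")
  stats::ppois(criterion$min_molecules - 1, expected_genomes,
               lower.tail = FALSE)
}

#' Evaluate detectability of a tumor in one blood draw
#'
#' Runs the full chain (volume -> MAF -> expected copies) and applies the
#' detection criterion.
#'
#' @param tumor A [tumor_spec()] or numeric tumor volume in cm^3.
#' @param draw A [draw_spec()].
#' @param model A [shed_model()].
#' @param criterion A [detection_criterion()].
#' @param genomes_per_draw Optional override of total genome equivalents
#'   per draw (see [expected_cancer_genomes()]).
#' @return A `detection_result`: list with `expected_genomes`, `p_detect`
#'   and `detectable`.
#' @examples
#' evaluate_detection(tumor_spec(volume_cm3 = 1), genomes_per_draw = 6000)
#' @export
evaluate_detection <- function(tumor, draw = draw_spec(model = model),
                               model = shed_model(),
                               criterion = detection_criterion(),
                               genomes_per_draw = NULL) {
  lambda <- expected_cancer_genomes(tumor, draw, model, genomes_per_draw)
  p <- detection_probability(lambda, criterion)
  detectable <- if (criterion$mode == "expected_value") {
    lambda >= criterion$min_molecules
  } else {
    p >= criterion$prob_threshold
  }
  structure(
    list(expected_genomes = lambda, p_detect = p, detectable = detectable),
    class = "detection_result"
  )
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf(
    "Expected tumor genomes: %.4g | P(capture) = %.4g | detectable: %s\n",
    x$expected_genomes, x$p_detect, x$detectable))
  invisible(x)
}

# Smallest Poisson mean with P(X >= k) >= p; closed form for k = 1,
# uniroot otherwise (deterministic, tolerance in lambda ~1e-12 relative).
min_lambda_for_detection <- function(k, p) {
  if (k == 0) return(0)
  if (k == 1) return(-log1p(-p))
  f <- function(l) stats::ppois(k - 1, l, lower.tail = FALSE) - p
  upper <- k + 10 * sqrt(k) + 20
  stats::uniroot(f, c(1e-12, upper), tol = 1e-12)$root
}

#' Minimum detectable tumor volume
#'
#' Smallest tumor volume whose blood draw satisfies the detection
#' criterion. In expected-value mode the closed form is
#' `min_molecules / (total_genomes * maf_per_cm3)`; in probabilistic mode
#' the volume is found by bisection to 1e-6 cm^3. Under the default
#' single-molecule expected-value criterion and a 10 mL draw the threshold
#' is about 1.66 cm^3, a diameter near 14.7 mm — inside the 10--15 mm band
#' where ctDNA-based detection becomes predictable.
#'
#' @inheritParams evaluate_detection
#' @return Volume in cm^3, or `NA_real_` (with a warning) when the
#'   criterion cannot be satisfied.
#' @examples
#' min_detectable_volume(genomes_per_draw = 6000) # 1.667 cm^3
#' @export
min_detectable_volume <- function(draw = draw_spec(model = model),
                                  model = shed_model(),
                                  criterion = detection_criterion(),
                                  genomes_per_draw = NULL) {
  maf_lim <- maf_detection_limit(draw, model, criterion, genomes_per_draw)
  if (is.na(maf_lim)) return(NA_real_)
  if (maf_lim >= 1) {
    warning("criterion unsatisfiable: required MAF reaches the cap of 1")
    return(NA_real_)
  }
  vol <- volume_from_maf(maf_lim, model)
  if (criterion$mode == "probabilistic") {
    # bisection on the volume axis to the documented 1e-6 cm^3 tolerance
    total <- if (is.null(genomes_per_draw))
      total_genome_equivalents(draw, model) else genomes_per_draw
    detect <- function(v) {
      detection_probability(total * maf_from_volume(v, model), criterion) >=
        criterion$prob_threshold
    }
    lo <- 0
    hi <- max(vol * 2, 1e-3)
    while (!detect(hi)) {
      hi <- hi * 2
      if (hi > 1e9) {
        warning("criterion unsatisfiable within any realistic tumor volume")
        return(NA_real_)
      }
    }
    while (hi - lo > 1e-6) {
      mid <- (lo + hi) / 2
      if (detect(mid)) hi <- mid else lo <- mid
    }
    vol <- hi
  }
  vol
}

#' Minimum detectable tumor diameter
#'
#' [min_detectable_volume()] pushed through the sphere inversion.
#'
#' @inheritParams evaluate_detection
#' @return Diameter in mm, or `NA_real_` when unsatisfiable.
#' @export
min_detectable_diameter <- function(draw = draw_spec(model = model),
                                    model = shed_model(),
                                    criterion = detection_criterion(),
                                    genomes_per_draw = NULL) {
  v <- min_detectable_volume(draw, model, criterion, genomes_per_draw)
  if (is.na(v)) return(NA_real_)
  volume_to_diameter(v)
}

#' MAF detection limit of a blood draw
#'
#' Smallest mutant allele fraction at which a draw satisfies the
#' criterion. Expected-value mode: `min_molecules / total_genomes`
#' (1.67e-4 for one molecule in 6000 genome equivalents). Probabilistic
#' mode: the Poisson mean required for the target detection probability,
#' divided by the total genome equivalents.
#'
#' @inheritParams evaluate_detection
#' @return MAF as a fraction, or `NA_real_` (with a warning) when the
#'   draw carries no genome equivalents.
#' @examples
#' maf_detection_limit(genomes_per_draw = 6000) # 1.667e-4
#' @export
maf_detection_limit <- function(draw = draw_spec(model = model),
                                model = shed_model(),
                                criterion = detection_criterion(),
                                genomes_per_draw = NULL) {
  total <- if (is.null(genomes_per_draw))
    total_genome_equivalents(draw, model) else genomes_per_draw
  if (total <= 0) {
    warning("criterion unsatisfiable: draw carries no genome equivalents")
    return(NA_real_)
  }
  if (criterion$mode == "expected_value") {
    criterion$min_molecules / total
  } else {
    min_lambda_for_detection(criterion$min_molecules,
                             criterion$prob_threshold) / total
  }
}

#' Largest power-of-ten MAF strictly below a detection limit
#'
#' The decade convention used when quoting detection limits: for the
#' default draw the exact expected-value threshold is 1.67e-4, and the
#' largest decade strictly below it is 1e-4, i.e. a MAF of 0.01%.
#'
#' @param limit MAF detection limit as a fraction (positive scalar).
#' @return A power of ten strictly below `limit`.
#' @examples
#' largest_decade_below(1 / 6000) # 1e-4
#' @export
largest_decade_below <- function(limit) {
  stopifnot(is.numeric(limit), length(limit) == 1L, limit > 0)
  j <- floor(log10(limit))
  if (10^j >= limit) j <- j - 1
  10^j
}

#' MAF decade detection limit
#'
#' Convenience wrapper: [maf_detection_limit()] reported at the decade
#' convention of [largest_decade_below()].
#'
#' @inheritParams evaluate_detection
#' @return A power-of-ten MAF fraction (1e-4 for the defaults, i.e.
#'   0.01%).
#' @export
maf_decade_limit <- function(draw = draw_spec(model = model),
                             model = shed_model(),
                             criterion = detection_criterion(),
                             genomes_per_draw = NULL) {
  lim <- maf_detection_limit(draw, model, criterion, genomes_per_draw)
  if (is.na(lim)) return(NA_real_)
  largest_decade_below(lim)
}
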