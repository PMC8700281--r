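# Deterministic biophysical chain: tumor size -> mutant allele fraction ->
# expected tumor genome copies per blood draw.

# Avogadro's number in Da per gram (1 g = N_A Da)
AVOGADRO <- 6.02214e23

# Total genome-equivalents convention used by the packaged tumor
# characteristics table: 6000 genomes per 10 mL blood draw (4 mL plasma at
# 5 ng cfDNA/mL with a 2e12 Da genome, rounded to 2 significant figures).
TABLE_GENOMES_PER_DRAW <- 6000

#' Shedding model constants
#'
#' Bundles the constants that link tumor volume to mutant allele fraction
#' (MAF) and plasma cell-free DNA (cfDNA) concentration to whole-genome
#' equivalents.
#'
#' The default proportionality constant anchors a 1 cm^3 tumor at a MAF of
#' 1:10,000 (so a 10 cm^3 tumor sheds at 1:1000). cfDNA in healthy plasma is
#' typically 1--10 ng/mL; the default uses the 5 ng/mL midpoint. A haploid
#' genome of 2e12 Da weighs about 3.3 pg, so 5 ng/mL corresponds to roughly
#' 1500 genome equivalents per mL of plasma.
#'
#' @param maf_per_cm3 MAF contributed per cm^3 of tumor (dimensionless per
#'   cm^3), in (0, 1]. Default `1e-4`.
#' @param genome_mass_da Mass of one haploid human genome in daltons.
#'   Default `2e12`.
#' @param cfdna_conc_ng_per_ml Total cfDNA concentration in plasma (ng/mL).
#'   Default `5`.
#' @param plasma_per_blood Plasma fraction of whole blood (mL plasma per mL
#'   blood), in (0, 1). Default `0.4` (10 mL blood yields 4 mL plasma).
#' @return An object of class `shed_model`.
#' @examples
#' m <- shed_model()
#' genome_equivalents_per_ml(m) # ~1500
#' @export
shed_model <- function(maf_per_cm3 = 1e-4,
                       genome_mass_da = 2e12,
                       cfdna_conc_ng_per_ml = 5,
                       plasma_per_blood = 0.4) {
  stopifnot(
    is.numeric(maf_per_cm3), length(maf_per_cm3) == 1L,
    maf_per_cm3 > 0, maf_per_cm3 <= 1,
    is.numeric(genome_mass_da), genome_mass_da > 0,
    is.numeric(cfdna_conc_ng_per_ml), cfdna_conc_ng_per_ml >= 0,
    is.numeric(plasma_per_blood), plasma_per_blood > 0, plasma_per_blood < 1
  )
  structure(
    list(
      maf_per_cm3 = maf_per_cm3,
      genome_mass_da = genome_mass_da,
      cfdna_conc_ng_per_ml = cfdna_conc_ng_per_ml,
      plasma_per_blood = plasma_per_blood
    ),
    class = "shed_model"
  )
}

#' @export
print.shed_model <- function(x, ...) {
  cat("ctDNA shedding model\n")
  cat(sprintf("  MAF per cm^3 tumor:   %g\n", x$maf_per_cm3))
  cat(sprintf("  genome mass:          %g Da\n", x$genome_mass_da))
  cat(sprintf("  cfDNA concentration:  %g ng/mL plasma\n",
              x$cfdna_conc_ng_per_ml))
  cat(sprintf("  plasma per blood:     %g mL/mL\n", x$plasma_per_blood))
  invisible(x)
}

#' Blood draw specification
#'
#' A blood draw of `blood_ml` millilitres of whole blood; the plasma volume
#' is derived through the governing model's plasma fraction.
#'
#' @param blood_ml Whole-blood volume in mL (default 10).
#' @param model A [shed_model()] supplying the plasma fraction.
#' @return An object of class `draw_spec` with fields `blood_ml` and
#'   `plasma_ml`.
#' @examples
#' draw_spec(10) # 4 mL plasma under the default model
#' @export
draw_spec <- function(blood_ml = 10, model = shed_model()) {
  stopifnot(is.numeric(blood_ml), length(blood_ml) == 1L, blood_ml >= 0)
  structure(
    list(blood_ml = blood_ml, plasma_ml = blood_ml * model$plasma_per_blood),
    class = "draw_spec"
  )
}

#' @export
print.draw_spec <- function(x, ...) {
  cat(sprintf("Blood draw: %g mL whole blood (%g mL plasma)\n",
              x$blood_ml, x$plasma_ml))
  invisible(x)
}

#' Convert tumor diameter to volume
#'
#' Assumes a spherical nodule: volume = (pi/6) d^3 with the diameter in mm
#' and the volume in cm^3. A 1 cm^3 tumor has a diameter of about 1.2 cm.
#'
#' @param diameter_mm Tumor diameter in mm (vectorized, non-negative).
#' @return Tumor volume in cm^3.
#' @examples
#' diameter_to_volume(12.407) # ~1 cm^3
#' @export
diameter_to_volume <- function(diameter_mm) {
  stopifnot(is.numeric(diameter_mm))
  if (any(diameter_mm < 0)) stop("diameter_mm must be non-negative")
  (pi / 6) * (diameter_mm / 10)^3
}

#' Convert tumor volume to diameter
#'
#' Inverse of [diameter_to_volume()] under the spherical-nodule assumption.
#'
#' @param volume_cm3 Tumor volume in cm^3 (vectorized, non-negative).
#' @return Tumor diameter in mm.
#' @examples
#' volume_to_diameter(1) # 12.407 mm
#' @export
volume_to_diameter <- function(volume_cm3) {
  stopifnot(is.numeric(volume_cm3))
  if (any(volume_cm3 < 0)) stop("volume_cm3 must be non-negative")
  10 * (6 * volume_cm3 / pi)^(1 / 3)
}

#' Tumor cell count from volume
#'
#' Uses the standard density figure of 1e9 cells per cm^3 (a 1 cm^3 tumor
#' weighs about 1 g and contains about one billion cells).
#'
#' @param volume_cm3 Tumor volume in cm^3 (vectorized, non-negative).
#' @return Cell count.
#' @export
volume_to_cells <- function(volume_cm3) {
  stopifnot(is.numeric(volume_cm3))
  if (any(volume_cm3 < 0)) stop("volume_cm3 must be non-negative")
  1e9 * volume_cm3
}

#' Tumor specification
#'
#' A tumor's geometric and cellular description: diameter (mm), volume
#' (cm^3), wet weight (mg) and cell count.
#'
#' In `"exact"` mode all fields are derived from the sphere model given
#' either a diameter or a volume (weight at density 1 g/cm^3, 1e9 cells per
#' cm^3). `"table"` mode accepts rounded published diameter/weight pairs
#' verbatim alongside a tabulated volume, without reconciling them against
#' sphere arithmetic.
#'
#' @param diameter_mm Tumor diameter in mm.
#' @param volume_cm3 Tumor volume in cm^3 (exact mode: supply this or the
#'   diameter; table mode: required).
#' @param weight_mg Wet weight in mg (table mode only; derived otherwise).
#' @param cell_count Cell count (table mode only; derived otherwise).
#' @param mode `"exact"` (sphere formula, default) or `"table"` (verbatim).
#' @return An object of class `tumor_spec`.
#' @examples
#' tumor_spec(diameter_mm = 12.407)
#' tumor_spec(volume_cm3 = 10)
#' @export
tumor_spec <- function(diameter_mm = NULL, volume_cm3 = NULL,
                       weight_mg = NULL, cell_count = NULL,
                       mode = c("exact", "table")) {
  mode <- match.arg(mode)
  if (mode == "exact") {
    if (is.null(diameter_mm) && is.null(volume_cm3))
      stop("supply diameter_mm or volume_cm3")
    if (is.null(volume_cm3)) volume_cm3 <- diameter_to_volume(diameter_mm)
    if (is.null(diameter_mm)) diameter_mm <- volume_to_diameter(volume_cm3)
    weight_mg <- 1000 * volume_cm3
    cell_count <- volume_to_cells(volume_cm3)
  } else {
    if (is.null(diameter_mm) || is.null(volume_cm3))
      stop("table mode requires diameter_mm and volume_cm3")
    if (is.null(weight_mg)) weight_mg <- 1000 * volume_cm3
    if (is.null(cell_count)) cell_count <- volume_to_cells(volume_cm3)
  }
  fields <- c(diameter_mm, volume_cm3, weight_mg, cell_count)
  if (any(fields < 0) || (any(fields == 0) && any(fields > 0)))
    stop("tumor_spec fields must be all strictly positive or all zero")
  structure(
    list(diameter_mm = diameter_mm, volume_cm3 = volume_cm3,
         weight_mg = weight_mg, cell_count = cell_count, mode = mode),
    class = "tumor_spec"
  )
}

#' @export
print.tumor_spec <- function(x, ...) {
  cat(sprintf(
    "Tumor: %.3g mm diameter, %.3g cm^3, %.3g mg, %.3g cells (%s mode)\n",
    x$diameter_mm, x$volume_cm3, x$weight_mg, x$cell_count, x$mode))
  invisible(x)
}

#' Mutant allele fraction from tumor volume
#'
#' MAF is modelled as proportional to tumor volume: `maf_per_cm3 * volume`,
#' capped at 1. Under the default anchor a 1 cm^3 tumor circulates at
#' 1:10,000 and a 10 cm^3 tumor at 1:1000.
#'
#' @param volume_cm3 Tumor volume in cm^3 (vectorized, non-negative).
#' @param model A [shed_model()].
#' @return MAF as a fraction in \[0, 1\].
#' @examples
#' maf_from_volume(10) # 1e-3, i.e. 1:1000
#' @export
maf_from_volume <- function(volume_cm3, model = shed_model()) {
  stopifnot(is.numeric(volume_cm3))
  if (any(volume_cm3 < 0)) stop("volume_cm3 must be non-negative")
  pmin(1, model$maf_per_cm3 * volume_cm3)
}

#' Tumor volume from mutant allele fraction
#'
#' Inverse of the volume-proportional MAF model, defined for MAF below the
#' cap.
#'
#' @param maf MAF as a fraction in \[0, 1).
#' @param model A [shed_model()].
#' @return Tumor volume in cm^3.
#' @examples
#' volume_from_maf(1e-4) # 1 cm^3
#' @export
volume_from_maf <- function(maf, model = shed_model()) {
  stopifnot(is.numeric(maf))
  if (any(maf < 0) || any(maf >= 1))
    stop("maf must lie in [0, 1)")
  maf / model$maf_per_cm3
}

#' Genome equivalents per mL of plasma
#'
#' Converts the cfDNA mass concentration into whole-genome equivalents per
#' mL: concentration divided by the mass of one genome
#' (`genome_mass_da / N_A` grams). Defaults give 1505.5, i.e. about 1500
#' genomes per mL.
#'
#' @param model A [shed_model()].
#' @return Genome equivalents per mL plasma.
#' @export
genome_equivalents_per_ml <- function(model = shed_model()) {
  genome_mass_ng <- model$genome_mass_da / AVOGADRO * 1e9
  model$cfdna_conc_ng_per_ml / genome_mass_ng
}

#' Total genome equivalents in a blood draw
#'
#' Genome equivalents per mL of plasma times the plasma volume of the draw.
#' A default 10 mL draw (4 mL plasma) carries about 6000 genome
#' equivalents.
#'
#' @param draw A [draw_spec()].
#' @param model A [shed_model()].
#' @return Total genome equivalents (count).
#' @export
total_genome_equivalents <- function(draw = draw_spec(model = model),
                                     model = shed_model()) {
  genome_equivalents_per_ml(model) * draw$plasma_ml
}

#' Expected tumor genome copies in a blood draw
#'
#' The expected (possibly fractional) number of tumor-derived genome copies
#' a draw contains: total genome equivalents times the tumor's MAF. With
#' the tabulated convention of 6000 genome equivalents per 10 mL draw
#' (`genomes_per_draw = 6000`), a 10 cm^3 tumor yields 6 copies and a
#' 1 cm^3 tumor 0.6 — less than one complete cancer genome.
#'
#' @param tumor A [tumor_spec()] or a numeric tumor volume in cm^3.
#' @param draw A [draw_spec()].
#' @param model A [shed_model()].
#' @param genomes_per_draw Optional override of the total genome
#'   equivalents per draw (e.g. the tabulated 6000); `NULL` (default)
#'   computes it from `draw` and `model`.
#' @return Expected tumor genome copies.
#' @examples
#' expected_cancer_genomes(10, genomes_per_draw = 6000) # 6
#' @export
expected_cancer_genomes <- function(tumor, draw = draw_spec(model = model),
                                    model = shed_model(),
                                    genomes_per_draw = NULL) {
  volume <- if (inherits(tumor, "tumor_spec")) tumor$volume_cm3 else tumor
  total <- if (is.null(genomes_per_draw)) {
    total_genome_equivalents(draw, model)
  } else {
    genomes_per_draw
  }
  total * maf_from_volume(volume, model)
}
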