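# Packaged tumor-characteristics reference table and its regeneration,
# plus the structured summary report.

# Published tumor characteristics grid, kept verbatim as printed: the
# diameter column follows a rounded halving series rather than exact
# sphere arithmetic (e.g. the 5 mm row lists 62 mg where the sphere gives
# 65.4 mg), and the MAF ratio column is a doubling series rounded to two
# significant figures. The progression-chance and mammographic-sensitivity
# columns are literature values keyed by diameter, never computed.
table1_printed_data <- function() {
  data.frame(
    diameter_mm = c(27, 12.5, 10, 8, 6, 5, 4, 3, 2.4, 2, 1.5, 1.1),
    weight_mg = c(10000, 1000, 500, 250, 125, 62, 31, 16, 8, 4, 2, 1),
    volume_cm3 = c(10, 1, 0.5, 0.25, 0.12, 0.06, 0.03, 0.015, 0.007,
                   0.0035, 0.0017, 0.0008),
    cell_count = c(1e10, 1e9, 5e8, 2.5e8, 1.25e8, 6.2e7, 3.2e7, 1.6e7,
                   8e6, 4e6, 2e6, 1e6),
    maf_denominator = c(1e3, 1e4, 2e4, 4e4, 8e4, 1.6e5, 3.2e5, 6.4e5,
                        1.3e6, 2.6e6, 5.2e6, 1e7),
    progression_chance = c(NA, NA, "50%", "25%", NA, "6%", NA, NA, NA,
                           NA, NA, "0.05%"),
    mammography_sensitivity = c(NA, NA, "91%", NA, NA, "26%", NA, NA,
                                NA, NA, NA, NA),
    stringsAsFactors = FALSE
  )
}

genomes_display <- function(x) {
  ifelse(x < 0.1, "<0.1",
         format(x, scientific = FALSE, trim = TRUE, drop0trailing = TRUE))
}

#' Tumor characteristics table
#'
#' The reference table linking tumor diameter, weight, volume, cell count,
#' mutant allele fraction and the expected number of cancer genomes per
#' 10 mL blood draw (6000 total genome equivalents).
#'
#' `"printed"` mode reproduces the published table: diameters, weights,
#' volumes, cell counts and MAF ratios are packaged verbatim, and the
#' genome-count column is computed from the tabulated volumes (giving 6,
#' 0.6, 0.3, 0.15, then the "<0.1" display token), together with the
#' literature columns on progression chance and mammographic screening
#' sensitivity. `"exact"` mode recomputes every derived column from the
#' sphere model at the same diameters and flags cells that differ from the
#' printed values by more than two-significant-figure rounding (relative
#' difference above 5%).
#'
#' @param mode `"printed"` (default) or `"exact"`.
#' @param genomes_per_draw Total genome equivalents per draw used for the
#'   genome-count column (default 6000, the tabulated convention).
#' @param model A [shed_model()] supplying the MAF proportionality.
#' @return A data.frame; both modes carry `maf` (fraction),
#'   `maf_ratio` ("1:N"), `genomes_per_draw_value` (numeric) and
#'   `genomes_per_draw` (display string). Exact mode adds logical
#'   `*_differs` columns.
#' @examples
#' generate_table1()[1:4, c("diameter_mm", "maf_ratio", "genomes_per_draw")]
#' @export
generate_table1 <- function(mode = c("printed", "exact"),
                            genomes_per_draw = TABLE_GENOMES_PER_DRAW,
                            model = shed_model()) {
  mode <- match.arg(mode)
  printed <- table1_printed_data()
  if (mode == "printed") {
    maf <- 1 / printed$maf_denominator
    gen <- genomes_per_draw * maf_from_volume(printed$volume_cm3, model)
    out <- data.frame(
      diameter_mm = printed$diameter_mm,
      weight_mg = printed$weight_mg,
      volume_cm3 = printed$volume_cm3,
      cell_count = printed$cell_count,
      maf = maf,
      maf_ratio = sprintf("1:%s",
                          format(printed$maf_denominator, big.mark = ",",
                                 scientific = FALSE, trim = TRUE)),
      genomes_per_draw_value = gen,
      genomes_per_draw = genomes_display(gen),
      progression_chance = printed$progression_chance,
      mammography_sensitivity = printed$mammography_sensitivity,
      stringsAsFactors = FALSE
    )
    return(out)
  }
  # exact mode: sphere model at the printed diameters
  vol <- diameter_to_volume(printed$diameter_mm)
  maf <- maf_from_volume(vol, model)
  gen <- genomes_per_draw * maf
  differs <- function(exact, print) {
    abs(exact - print) / abs(print) > 0.05
  }
  data.frame(
    diameter_mm = printed$diameter_mm,
    weight_mg = 1000 * vol,
    volume_cm3 = vol,
    cell_count = volume_to_cells(vol),
    maf = maf,
    maf_ratio = sprintf("1:%s",
                        format(round(1 / maf), big.mark = ",",
                               scientific = FALSE, trim = TRUE)),
    genomes_per_draw_value = gen,
    genomes_per_draw = genomes_display(gen),
    weight_differs = differs(1000 * vol, printed$weight_mg),
    volume_differs = differs(vol, printed$volume_cm3),
    cell_count_differs = differs(volume_to_cells(vol), printed$cell_count),
    maf_differs = differs(maf, 1 / printed$maf_denominator),
    genomes_differs = differs(
      gen, genomes_per_draw / printed$maf_denominator),
    stringsAsFactors = FALSE
  )
}

#' Serialize the tumor characteristics table
#'
#' Byte-stable TSV/CSV rendering: every numeric column is formatted with
#' a fixed rule so repeated runs produce identical files.
#'
#' @param table A data.frame from [generate_table1()].
#' @param path Optional output path; when `NULL` the lines are returned.
#' @param format `"tsv"` (default) or `"csv"`.
#' @return The serialized lines (invisibly when `path` is given).
#' @export
write_table1 <- function(table, path = NULL, format = c("tsv", "csv")) {
  format <- match.arg(format)
  sep <- if (format == "tsv") "\t" else ","
  fmt_col <- function(col) {
    if (is.numeric(col)) {
      vapply(col, function(x) format(x, scientific = FALSE, trim = TRUE,
                                     drop0trailing = TRUE), character(1))
    } else if (is.logical(col)) {
      ifelse(col, "TRUE", "FALSE")
    } else {
      ifelse(is.na(col), "-", col)
    }
  }
  cells <- vapply(table, fmt_col, character(nrow(table)))
  lines <- c(paste(names(table), collapse = sep),
             apply(cells, 1L, paste, collapse = sep))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Structured summary report
#'
#' Collects the headline quantities of the model into one deterministic
#' machine-readable object: the genome-equivalents accounting for the
#' draw, the detection limits (minimum detectable volume/diameter, MAF
#' limit and its decade convention), and the screening PPV/NPV block for
#' the supplied scenario, with all model constants echoed for provenance.
#'
#' @param draw A [draw_spec()].
#' @param model A [shed_model()].
#' @param criterion A [detection_criterion()].
#' @param scenario A [screening_scenario()] (default: 10% sensitivity,
#'   99.5% specificity, 1% prevalence).
#' @param genomes_per_draw Optional override of total genome equivalents.
#' @return An object of class `ctdna_report` (a nested list), convertible
#'   to JSON with [report_json()].
#' @examples
#' rep <- summary_report()
#' rep$detection$min_detectable_diameter_mm # ~14.7
#' @export
summary_report <- function(draw = draw_spec(model = model),
                           model = shed_model(),
                           criterion = detection_criterion(),
                           scenario = screening_scenario(
                             test_performance(0.10, 0.995), 0.01),
                           genomes_per_draw = NULL) {
  total <- if (is.null(genomes_per_draw))
    total_genome_equivalents(draw, model) else genomes_per_draw
  vol <- min_detectable_volume(draw, model, criterion, genomes_per_draw)
  maf_lim <- maf_detection_limit(draw, model, criterion, genomes_per_draw)
  p <- ppv(scenario)
  structure(list(
    constants = list(
      maf_per_cm3 = model$maf_per_cm3,
      genome_mass_da = model$genome_mass_da,
      cfdna_conc_ng_per_ml = model$cfdna_conc_ng_per_ml,
      plasma_per_blood = model$plasma_per_blood,
      blood_ml = draw$blood_ml,
      plasma_ml = draw$plasma_ml,
      min_molecules = criterion$min_molecules,
      criterion_mode = criterion$mode
    ),
    genome_accounting = list(
      genome_equivalents_per_ml = genome_equivalents_per_ml(model),
      total_genome_equivalents = total
    ),
    detection = list(
      min_detectable_volume_cm3 = vol,
      min_detectable_diameter_mm =
        if (is.na(vol)) NA_real_ else volume_to_diameter(vol),
      maf_detection_limit = maf_lim,
      maf_decade_limit =
        if (is.na(maf_lim)) NA_real_ else largest_decade_below(maf_lim),
      maf_decade_limit_percent =
        if (is.na(maf_lim)) NA_real_
        else 100 * largest_decade_below(maf_lim)
    ),
    screening = list(
      sensitivity = scenario$test$sensitivity,
      specificity = scenario$test$specificity,
      prevalence = scenario$prevalence,
      ppv = p,
      ppv_display = format_percent(p),
      npv = npv(scenario)
    )
  ), class = "ctdna_report")
}

#' @export
print.ctdna_report <- function(x, ...) {
  cat("ctDNA screening feasibility report\n")
  cat(sprintf("  genome equivalents: %.1f /mL plasma, %.0f per draw\n",
              x$genome_accounting$genome_equivalents_per_ml,
              x$genome_accounting$total_genome_equivalents))
  cat(sprintf("  min detectable tumor: %.3g cm^3 (diameter %.3g mm)\n",
              x$detection$min_detectable_volume_cm3,
              x$detection$min_detectable_diameter_mm))
  cat(sprintf("  MAF detection limit: %.3g (decade convention %g%%)\n",
              x$detection$maf_detection_limit,
              x$detection$maf_decade_limit_percent))
  cat(sprintf("  screening PPV: %s (sens %.3g, spec %.3g, prev %.3g)\n",
              x$screening$ppv_display, x$screening$sensitivity,
              x$screening$specificity, x$screening$prevalence))
  invisible(x)
}

#' Render a summary report as JSON
#'
#' @param report A `ctdna_report` from [summary_report()].
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return JSON text (invisibly when written to `path`).
#' @export
report_json <- function(report, path = NULL) {
  txt <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                          pretty = TRUE, na = "null")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
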