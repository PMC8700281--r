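# JSON/YAML round-tripping of the model configuration objects, with
# defaults embedded so partial configs are valid.

#' @export
as.list.shed_model <- function(x, ...) {
  x[c("maf_per_cm3", "genome_mass_da", "cfdna_conc_ng_per_ml",
      "plasma_per_blood")]
}

#' @export
as.list.draw_spec <- function(x, ...) x[c("blood_ml", "plasma_ml")]

#' @export
as.list.detection_criterion <- function(x, ...) {
  x[c("min_molecules", "mode", "prob_threshold")]
}

#' @export
as.list.test_performance <- function(x, ...) {
  x[c("sensitivity", "specificity", "label")]
}

#' @export
as.list.screening_scenario <- function(x, ...) {
  list(test = as.list(x$test), prevalence = x$prevalence,
       n_screened = x$n_screened)
}

#' @export
as.list.size_distribution <- function(x, ...) {
  Filter(Negate(is.null),
         x[c("kind", "median_mm", "sdlog", "diameter_mm")])
}

#' @export
as.list.cohort_config <- function(x, ...) {
  Filter(Negate(is.null), list(
    n = x$n, prevalence = x$prevalence,
    size_distribution = as.list(x$sizes), seed = x$seed,
    draw = as.list(x$draw), model = as.list(x$model),
    criterion = as.list(x$criterion),
    test = if (is.null(x$test)) NULL else as.list(x$test),
    genomes_per_draw = x$genomes_per_draw
  ))
}

config_format <- function(path) {
  if (grepl("\\.(ya?ml)$", path, ignore.case = TRUE)) "yaml" else "json"
}

#' Write a model configuration to JSON or YAML
#'
#' Serializes any of the package's configuration objects (shedding model,
#' draw, detection criterion, test performance, screening scenario,
#' cohort config) — or a named list of them — using exactly the field
#' names of the constructors. The format follows the file extension
#' (`.yaml`/`.yml` for YAML, anything else JSON).
#'
#' @param x A configuration object or a named list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @examples
#' f <- tempfile(fileext = ".json")
#' write_config(list(model = shed_model(), draw = draw_spec()), f)
#' read_config(f)$model$cfdna_conc_ng_per_ml
#' @export
write_config <- function(x, path) {
  payload <- if (is.list(x) && is.null(attr(x, "class"))) {
    lapply(x, function(el) if (is.object(el)) as.list(el) else el)
  } else {
    as.list(x)
  }
  if (config_format(path) == "yaml") {
    yaml::write_yaml(payload, path)
  } else {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Read a model configuration from JSON or YAML
#'
#' @param path Input path (format inferred from the extension).
#' @return A named list of plain values; use the `*_from_config()`
#'   helpers to rebuild typed objects.
#' @export
read_config <- function(path) {
  if (config_format(path) == "yaml") yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}

build_from_config <- function(constructor, cfg, fields) {
  args <- cfg[intersect(names(cfg), fields)]
  do.call(constructor, args)
}

#' Rebuild typed objects from a configuration list
#'
#' Each helper takes the list returned by [read_config()] (or one of its
#' sub-lists) and applies the matching constructor, filling unlisted
#' fields with the package defaults.
#'
#' @param cfg A named list (e.g. from [read_config()]).
#' @return The corresponding typed object.
#' @name config-helpers
NULL

#' @rdname config-helpers
#' @export
shed_model_from_config <- function(cfg) {
  build_from_config(shed_model, cfg,
                    c("maf_per_cm3", "genome_mass_da",
                      "cfdna_conc_ng_per_ml", "plasma_per_blood"))
}

#' @rdname config-helpers
#' @param model A [shed_model()] supplying the plasma fraction for the
#'   rebuilt draw.
#' @export
draw_spec_from_config <- function(cfg, model = shed_model()) {
  draw_spec(blood_ml = cfg$blood_ml %||% 10, model = model)
}

#' @rdname config-helpers
#' @export
criterion_from_config <- function(cfg) {
  build_from_config(detection_criterion, cfg,
                    c("min_molecules", "mode", "prob_threshold"))
}

#' @rdname config-helpers
#' @export
scenario_from_config <- function(cfg) {
  test <- build_from_config(test_performance, cfg$test,
                            c("sensitivity", "specificity", "label"))
  screening_scenario(test, prevalence = cfg$prevalence,
                     n_screened = cfg$n_screened)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
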