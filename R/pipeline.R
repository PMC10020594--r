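#' Read a gene-model candidate list from JSON
#'
#' The model spec file is a JSON array of objects
#' `{"label": "a", "mode": "recessive"}`; each top-level element may also be
#' an array of such objects, in which case every element defines one
#' candidate model. A plain string entry like `"a-b-C"` is parsed with
#' [parse_model()].
#'
#' @param path Path to the JSON file.
#' @return A list of [genetic_model()] objects.
#' @export
read_models_json <- function(path) {
  if (!file.exists(path)) stop("model spec file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  to_model <- function(entry) {
    if (is.character(entry)) return(parse_model(entry))
    if (!is.null(entry$label)) entry <- list(entry)
    genetic_model(lapply(entry, function(l) {
      if (is.null(l$label) || is.null(l$mode))
        stop("model spec entries need 'label' and 'mode' fields")
      locus(l$label, l$mode)
    }))
  }
  lapply(raw, to_model)
}

#' Read observed segregation counts
#'
#' @param path CSV with header `population,n_high,n_low`.
#' @return List with `population`, `n_high`, `n_low` (first row).
#' @export
read_observation_csv <- function(path) {
  if (!file.exists(path)) stop("observation file not found: ", path)
  d <- utils::read.csv(path, comment.char = "#")
  req <- c("population", "n_high", "n_low")
  if (!all(req %in% names(d)))
    stop("observation file must have columns: ", paste(req, collapse = ", "))
  if (nrow(d) < 1) stop("observation file is empty")
  if (any(d$n_high < 0 | d$n_low < 0) || any(d$n_high + d$n_low < 1))
    stop("counts must be non-negative with total >= 1")
  as.list(d[1L, req])
}

read_table_csv <- function(path, what, required) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(required %in% names(d)))
    stop(what, " file missing column(s): ",
         paste(setdiff(required, names(d)), collapse = ", "))
  d
}

#' Run the segregation stage: observed counts against candidate models
#'
#' @param obs Observation: a list with `n_high`/`n_low` or a CSV path for
#'   [read_observation_csv()].
#' @param models A model list, or a JSON path for [read_models_json()].
#' @param basis Expectation basis, see [fit_segregation()].
#' @param thresholds Display p-values with `< 0.01` / `< 0.05` cuts.
#' @return A `"seg_report"`: list with the full-precision `table` (columns
#'   `model,ratio,f_high,basis,chi2,df,p,rank`), the `display` table
#'   (chi-square at 2 decimals, thresholded p) and the underlying
#'   `"seg_fit"`.
#' @export
run_segregation <- function(obs, models, basis = c("printed_ratio", "exact"),
                            thresholds = TRUE) {
  basis <- match.arg(basis)
  if (is.character(obs)) obs <- read_observation_csv(obs)
  if (is.character(models) && length(models) == 1L && file.exists(models))
    models <- read_models_json(models)
  if (length(models) == 0L) stop("at least one candidate model is required")
  fit <- fit_segregation(obs$n_high, obs$n_low, models, basis = basis)
  tab <- fit$fits[, c("model", "ratio", "f_high", "basis", "chi2", "df",
                      "p", "rank")]
  display <- data.frame(model = tab$model,
                        segregation = sub(":", ": ", tab$ratio),
                        chi2 = sprintf("%.2f", tab$chi2),
                        p = format_p(tab$p, thresholds),
                        stringsAsFactors = FALSE)
  structure(list(table = tab, display = display, fit = fit),
            class = "seg_report")
}

#' @export
print.seg_report <- function(x, ...) {
  print(x$fit, ...)
  invisible(x)
}

#' Derived fold-change and percent-reduction metrics for level pairs
#'
#' @param pairs Data frame with columns `label`, `control`, `treated`.
#' @return Data frame adding full-precision `fold_change` and
#'   `percent_reduction` plus report-rounded `fold_display`
#'   (see [format_fold()]) and `percent_display` (integer percent, half
#'   away from zero).
#' @export
derived_metrics <- function(pairs) {
  stopifnot(all(c("label", "control", "treated") %in% names(pairs)))
  fc <- fold_change(pairs$control, pairs$treated)
  pr <- percent_reduction(pairs$control, pairs$treated)
  data.frame(pairs,
             fold_change = fc,
             percent_reduction = pr,
             fold_display = format_fold(fc),
             percent_display = sprintf("%d%%", as.integer(round_half_up(pr))),
             stringsAsFactors = FALSE)
}

#' Write a data frame to CSV at full double precision
#'
#' Numeric columns are serialized with 17 significant digits so that
#' reading the file back reproduces the values bit-identically; display
#' rounding belongs to the report layer, never to stored tables.
#'
#' @param x A data frame.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_csv_full <- function(x, path) {
  y <- x
  for (j in seq_along(y)) {
    if (is.double(y[[j]])) y[[j]] <- sprintf("%.17g", y[[j]])
  }
  utils::write.csv(y, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

stage_log <- function(stage, ...) {
  message(sprintf("[terpseg] %s: %s", stage, sprintf(...)))
}

#' Run the full analysis workflow on one set of input tables
#'
#' Executes the stages in their natural order — quantify (normalize + apply
#' response factors), classify against the parental reference, fit the
#' segregation models, phenotype (densities, density classes, cavity
#' volumes, density-terpene correlation) — and collects everything into a
#' report bundle with a provenance block (package version, seed, config
#' hash). Inputs may be paths to CSV files or a simulation block, in which
#' case the tables are generated first with [simulate_f2_population()].
#'
#' @param config A list (or path to a JSON file) with elements:
#'   * `simulate`: optional [simulation_config()] arguments; when present
#'     the input tables are synthesized and `seed` is taken from here.
#'   * `peaks`, `metadata`, `response_factors`, `counts`, `cavities`,
#'     `parental`: CSV paths (ignored when simulating).
#'   * `models`: model JSON path, list of models, or strings
#'     (default [table1_models()]).
#'   * `basis`, `classify_rule`, `include_pi`, `localization` (CSV path or
#'     data frame), `density_classes` (K): stage parameters.
#' @return Object of class `"report_bundle"` with elements `segregation`
#'   (a `"seg_report"`), `quantified`, `classification`, `localization`
#'   (per-sample plastidial/cytosolic totals + unmapped compounds),
#'   `density`, `density_classes`, `cavities`, `correlation`, and
#'   `provenance`.
#' @export
run_full_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::fromJSON(config,
                                                         simplifyVector = FALSE)
  stopifnot(is.list(config))
  cfg_json <- jsonlite::toJSON(config[setdiff(names(config), "models")],
                               auto_unbox = TRUE, force = TRUE, digits = NA)
  tmp <- tempfile(fileext = ".json")
  writeLines(cfg_json, tmp)
  cfg_hash <- unname(tools::md5sum(tmp))
  unlink(tmp)

  seed <- config$seed
  if (!is.null(config$simulate)) {
    sim_cfg <- do.call(simulation_config, config$simulate)
    seed <- sim_cfg$seed
    dir <- tempfile("terpseg_sim_")
    pop <- simulate_f2_population(sim_cfg)
    paths <- write_population_tables(pop, dir)
    config[names(paths)] <- paths
    stage_log("simulate", "%d plants under model %s (seed %d)",
              sim_cfg$n_plants, model_label(sim_cfg$model), sim_cfg$seed)
  }

  peaks <- read_table_csv(config$peaks, "peak table",
                          c("sample_id", "compound", "peak_area", "is_area"))
  meta <- read_table_csv(config$metadata, "metadata",
                         c("sample_id", "basis", "extraction_volume_ul",
                           "injection_volume_ul", "dilution"))
  rf <- read_table_csv(config$response_factors, "response factors",
                       c("compound", "ng_per_unit_area"))
  normalized <- normalize_peaks(peaks, meta)
  quantified <- quantify_peaks(normalized, rf)
  stage_log("quantify", "%d peaks across %d samples", nrow(quantified),
            length(unique(quantified$sample_id)))

  locmap <- config$localization
  if (is.null(locmap)) locmap <- default_localization_map()
  if (is.character(locmap))
    locmap <- read_table_csv(locmap, "localization map",
                             c("compound", "localization"))
  localization <- withCallingHandlers(
    sum_by_localization(quantified, locmap),
    warning = function(w) {
      stage_log("localization", "%s", conditionMessage(w))
      invokeRestart("muffleWarning")
    })

  parental <- read_table_csv(config$parental, "parental replicates",
                             c("terpene_ng_per_mg"))
  ref <- parental_reference(parental$terpene_ng_per_mg)
  per_sample <- tapply(quantified$quantity, quantified$sample_id, sum)
  rule <- if (is.null(config$classify_rule)) "ci_low" else config$classify_rule
  cls <- classify_high_low(as.vector(per_sample), ref, rule = rule)
  classification <- data.frame(sample_id = names(per_sample),
                               quantity = as.vector(per_sample),
                               class = cls, stringsAsFactors = FALSE,
                               row.names = NULL)
  stage_log("classify", "%d high / %d low (rule: %s)",
            sum(cls == "high"), sum(cls == "low"), rule)

  basis <- if (is.null(config$basis)) "printed_ratio" else config$basis
  models <- config$models
  if (is.null(models)) models <- table1_models()
  if (is.character(models) && length(models) == 1L && file.exists(models))
    models <- read_models_json(models)
  segregation <- run_segregation(list(n_high = sum(cls == "high"),
                                      n_low = sum(cls == "low")),
                                 models, basis = basis)
  stage_log("segregate", "best model %s (basis %s)",
            segregation$table$model[1L], basis)

  counts <- read_table_csv(config$counts, "trichome counts",
                           c("plant_id", "side", "disc_radius_mm",
                             "trichome_type", "count"))
  density <- summed_density(counts)
  K <- if (is.null(config$density_classes)) 10 else config$density_classes
  density_classes <- assign_density_classes(
    stats::setNames(density$summed_per_disc, density$plant_id), K = K)
  cav <- read_table_csv(config$cavities, "cavity measurements",
                        c("plant_id", "trichome_id", "width_um", "height_um"))
  include_pi <- isTRUE(config$include_pi)
  cav$volume_um3 <- cavity_volume(cav$width_um, cav$height_um,
                                  include_pi = include_pi)
  cav$volume_pl <- um3_to_picolitre(cav$volume_um3)
  stage_log("phenotype", "%d plants, %d cavities", nrow(density), nrow(cav))

  correlation <- NULL
  shared <- intersect(density$plant_id, classification$sample_id)
  if (length(shared) >= 3) {
    d <- density$per_mm2[match(shared, density$plant_id)]
    q <- classification$quantity[match(shared, classification$sample_id)]
    if (stats::sd(d) > 0)
      correlation <- density_terpene_correlation(d, q)[
        c("r_squared", "p_value", "slope", "intercept")]
  }

  structure(list(segregation = segregation,
                 quantified = quantified,
                 classification = classification,
                 localization = localization,
                 density = density,
                 density_classes = density_classes,
                 cavities = cav,
                 correlation = correlation,
                 provenance = list(
                   package = "terpseg",
                   version = as.character(utils::packageVersion("terpseg")),
                   seed = seed,
                   config_hash = cfg_hash)),
            class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("terpseg report bundle\n")
  cat(sprintf("  version %s | seed %s | config %s\n\n",
              x$provenance$version,
              if (is.null(x$provenance$seed)) "-" else x$provenance$seed,
              substr(x$provenance$config_hash, 1, 8)))
  print(x$segregation)
  cat(sprintf("\nClassification: %d high / %d low of %d samples\n",
              sum(x$classification$class == "high"),
              sum(x$classification$class == "low"),
              nrow(x$classification)))
  if (!is.null(x$correlation))
    cat(sprintf("Density-terpene correlation: r^2 = %.3f, p = %.3g\n",
                x$correlation$r_squared, x$correlation$p_value))
  if (length(attr(x$localization, "unmapped")))
    cat("Unmapped compounds:",
        paste(attr(x$localization, "unmapped"), collapse = ", "), "\n")
  invisible(x)
}

#' Write a report bundle's tables to CSV files
#'
#' All stored values are written at full precision; display rounding is a
#' report-layer concern only.
#'
#' @param bundle A `"report_bundle"`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
write_report_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tabs <- list(segregation = bundle$segregation$table,
               classification = bundle$classification,
               localization = bundle$localization,
               density = bundle$density,
               density_classes = bundle$density_classes,
               cavities = bundle$cavities)
  paths <- vapply(names(tabs), function(nm) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tabs[[nm]], p, row.names = FALSE)
    p
  }, character(1))
  invisible(paths)
}
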