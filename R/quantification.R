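#' Normalize integrated GC-MS peak areas
#'
#' Converts raw integrated peak areas into internal-standard-corrected areas
#' per unit of biological basis: `(peak_area / is_area) * dilution *
#' (extraction_volume_ul / injection_volume_ul) / denominator`, where the
#' denominator is mg fresh weight or the number of collected glands,
#' depending on the sample's basis. Every step is linear in `peak_area`.
#'
#' The internal standard enters as a ratio; to express results in
#' IS-equivalent nanograms instead, supply the spiked IS concentration
#' `is_ng_per_ul` (0.5 ng/uL benzyl acetate in the standard extraction
#' protocol) and the ratio is multiplied by it.
#'
#' @param peaks Data frame with columns `sample_id`, `compound`,
#'   `peak_area` (>= 0), `is_area` (> 0).
#' @param meta Data frame with columns `sample_id`, `basis`
#'   (`"fresh_weight"` or `"glands"`), `fresh_weight_mg`, `n_glands`,
#'   `extraction_volume_ul`, `injection_volume_ul`, `dilution`.
#' @param is_ng_per_ul Optional IS concentration; when given, output is in
#'   IS-equivalent ng per unit basis rather than an area ratio.
#' @return `peaks` with added columns `basis` and `norm_area`.
#' @export
normalize_peaks <- function(peaks, meta, is_ng_per_ul = NULL) {
  req_p <- c("sample_id", "compound", "peak_area", "is_area")
  req_m <- c("sample_id", "basis", "extraction_volume_ul",
             "injection_volume_ul", "dilution")
  if (!all(req_p %in% names(peaks)))
    stop("peak table missing column(s): ",
         paste(setdiff(req_p, names(peaks)), collapse = ", "))
  if (!all(req_m %in% names(meta)))
    stop("metadata missing column(s): ",
         paste(setdiff(req_m, names(meta)), collapse = ", "))
  if (any(peaks$peak_area < 0)) stop("peak_area must be >= 0")
  if (any(peaks$is_area <= 0)) stop("is_area must be > 0")
  miss <- setdiff(peaks$sample_id, meta$sample_id)
  if (length(miss))
    stop("no metadata for sample(s): ", paste(unique(miss), collapse = ", "))
  idx <- match(peaks$sample_id, meta$sample_id)
  m <- meta[idx, , drop = FALSE]
  denom <- ifelse(m$basis == "fresh_weight", m$fresh_weight_mg, m$n_glands)
  if (any(!m$basis %in% c("fresh_weight", "glands")))
    stop("basis must be 'fresh_weight' or 'glands'")
  if (any(is.na(denom) | denom <= 0))
    stop("fresh_weight_mg / n_glands must be > 0 for the declared basis")
  if (any(m$dilution < 1)) stop("dilution factor must be >= 1")
  ratio <- peaks$peak_area / peaks$is_area
  norm <- ratio * m$dilution *
    (m$extraction_volume_ul / m$injection_volume_ul) / denom
  if (!is.null(is_ng_per_ul)) norm <- norm * is_ng_per_ul
  out <- peaks
  out$basis <- m$basis
  out$norm_area <- norm
  out
}

#' Quantify normalized areas with compound response factors
#'
#' Multiplies each normalized area by the calibration slope of its compound
#' (ng per unit normalized area, from an authentic standard or a surrogate
#' such as beta-caryophyllene for 7-epizingiberene and its derivatives).
#' Compounds without a response factor are *not* dropped: they keep their
#' normalized value and are flagged `semi_quantitative`.
#'
#' @param normalized Output of [normalize_peaks()].
#' @param response_factors Data frame with columns `compound`,
#'   `standard_compound`, `ng_per_unit_area` (> 0).
#' @return `normalized` with added columns `quantity` (ng per unit basis
#'   where calibrated) and logical `semi_quantitative`.
#' @export
quantify_peaks <- function(normalized, response_factors) {
  stopifnot(all(c("compound", "norm_area") %in% names(normalized)),
            all(c("compound", "ng_per_unit_area") %in% names(response_factors)))
  if (any(response_factors$ng_per_unit_area <= 0))
    stop("response-factor slopes must be > 0")
  idx <- match(normalized$compound, response_factors$compound)
  slope <- response_factors$ng_per_unit_area[idx]
  out <- normalized
  out$semi_quantitative <- is.na(slope)
  out$quantity <- ifelse(is.na(slope), out$norm_area, out$norm_area * slope)
  if (any(out$semi_quantitative))
    warning("no response factor for: ",
            paste(unique(out$compound[out$semi_quantitative]), collapse = ", "),
            " (reported semi-quantitatively)")
  out
}

#' Parental reference level with its 95% confidence interval
#'
#' Mean, sample standard deviation and the interval
#' `mean +/- 1.96 * sd / sqrt(n)` for replicate measurements of a parental
#' genotype — the reference object against which F2 plants are classified.
#'
#' @param values Numeric vector of at least 2 replicate levels.
#' @return Object of class `"parental_ref"` with fields `mean`, `sd`, `n`,
#'   `ci_low`, `ci_high`.
#' @export
#' @examples
#' parental_reference(c(1, 2, 3, 4))
parental_reference <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2) stop("parental reference requires n >= 2 replicates")
  m <- mean(values)
  s <- stats::sd(values)
  half <- 1.96 * s / sqrt(n)
  structure(list(mean = m, sd = s, n = n,
                 ci_low = m - half, ci_high = m + half),
            class = "parental_ref")
}

#' @export
print.parental_ref <- function(x, ...) {
  cat(sprintf("Parental reference (n = %d): mean %.4g, sd %.4g, 95%% CI [%.4g, %.4g]\n",
              x$n, x$mean, x$sd, x$ci_low, x$ci_high))
  invisible(x)
}

#' Classify plants as high or low against a parental reference
#'
#' "Parental levels or higher" is operationalized as at or above the lower
#' bound of the parental 95% confidence interval (the CI is the only
#' threshold object the extraction protocol defines); set `rule = "mean"`
#' to require at least the parental mean instead. Monotone in `value`.
#'
#' @param values Numeric vector of plant-level quantities.
#' @param ref A [parental_reference()].
#' @param rule `"ci_low"` (default) or `"mean"`.
#' @return Character vector of `"high"` / `"low"`.
#' @export
classify_high_low <- function(values, ref, rule = c("ci_low", "mean")) {
  rule <- match.arg(rule)
  stopifnot(inherits(ref, "parental_ref"))
  cut <- if (rule == "ci_low") ref$ci_low else ref$mean
  ifelse(values >= cut, "high", "low")
}

#' Bin plant-level terpene quantities into parental-SD-width classes
#'
#' Histogram convention for skewed F2 metabolite distributions: the first
#' bin holds the exact zeros (non-detects), then consecutive left-open
#' right-closed bins of width one parental standard deviation starting at
#' zero; a positive value v falls in bin `ceiling(v / sd)`. Values below
#' `detection_limit` are set to exact zero first.
#'
#' @param values Non-negative numeric vector.
#' @param parental_sd Positive bin width (SD of the parental replicates).
#' @param detection_limit Values strictly below this are zeroed (default 0,
#'   i.e. only exact zeros populate the first bin).
#' @return Data frame with columns `bin` (0 = zeros), `lower`, `upper`
#'   (in units of `parental_sd`) and `count`; counts sum to
#'   `length(values)`.
#' @export
bin_levels <- function(values, parental_sd, detection_limit = 0) {
  if (any(values < 0)) stop("levels must be non-negative")
  if (!is.finite(parental_sd) || parental_sd <= 0)
    stop("parental_sd must be > 0")
  v <- ifelse(values < detection_limit, 0, values)
  idx <- ifelse(v == 0, 0L, as.integer(ceiling(v / parental_sd)))
  kmax <- max(idx, 1L)
  bins <- 0:kmax
  count <- vapply(bins, function(b) sum(idx == b), integer(1))
  data.frame(bin = bins,
             lower = c(0, (bins[-1L] - 1L) * parental_sd),
             upper = c(0, bins[-1L] * parental_sd),
             count = count)
}

#' Fold change between two levels
#'
#' @param a,b Levels; `b` must be > 0.
#' @return The ratio `a / b`.
#' @seealso [format_fold()] for the report rounding convention.
#' @export
fold_change <- function(a, b) {
  if (any(b <= 0)) stop("denominator level must be > 0")
  a / b
}

#' Report-style display of a fold change
#'
#' Rounded to the nearest integer when >= 10, one decimal otherwise
#' (half away from zero), with a tilde prefix: `"~35"`, `"~1.8"`.
#'
#' @param fold Numeric fold change(s).
#' @return Character vector.
#' @export
format_fold <- function(fold) {
  ifelse(fold >= 10,
         sprintf("~%d", as.integer(round_half_up(fold))),
         sprintf("~%.1f", round_half_up(fold, 1)))
}

#' Percent reduction of a treated level relative to a control
#'
#' `100 * (control - treated) / control`. Values are full precision;
#' reports round half away from zero to an integer percent (so a 62.5%
#' reduction prints as 63%). A treated level above the control gives a
#' negative value with a warning rather than an error.
#'
#' @param control Level > 0.
#' @param treated Level >= 0.
#' @param round_report Return the integer report value instead of full
#'   precision.
#' @return Percent reduction.
#' @export
#' @examples
#' percent_reduction(12.3, 0.21)               # 98.29...
#' percent_reduction(0.16, 0.060, round_report = TRUE)  # 63
percent_reduction <- function(control, treated, round_report = FALSE) {
  if (any(control <= 0)) stop("control level must be > 0")
  out <- 100 * (control - treated) / control
  if (any(out < 0))
    warning("treated level exceeds control; reduction is negative")
  if (round_report) round_half_up(out) else out
}

#' Default subcellular-localization map for tomato trichome terpenes
#'
#' Assigns each terpene to the compartment of its synthase: plastidial for
#' 7-epizingiberene and its oxidized derivatives, santalenes, bergamotenes
#' and the monoterpenes; cytosolic for beta-caryophyllene, alpha-humulene
#' and the germacrenes.
#'
#' @return Data frame with columns `compound` and `localization`.
#' @export
default_localization_map <- function() {
  plastidial <- c("7-epizingiberene", "R-curcumene",
                  "9-hydroxy-zingiberene", "9-hydroxy-10,11-epoxyzingiberene",
                  "alpha-santalene", "alpha-bergamotene", "beta-bergamotene",
                  "2-carene", "alpha-phellandrene", "beta-phellandrene",
                  "D-limonene", "terpinolene")
  cytosolic <- c("beta-caryophyllene", "alpha-humulene",
                 "germacrene-B", "germacrene-D")
  data.frame(compound = c(plastidial, cytosolic),
             localization = rep(c("plastidial", "cytosolic"),
                                c(length(plastidial), length(cytosolic))),
             stringsAsFactors = FALSE)
}

#' Sum quantified terpenes per sample by subcellular localization
#'
#' @param quantified Data frame with `sample_id`, `compound` and a value
#'   column (`quantity` by default).
#' @param map Data frame `compound`/`localization`
#'   (default [default_localization_map()]).
#' @param value Name of the value column.
#' @return Data frame `sample_id`, `plastidial`, `cytosolic`. Compounds
#'   absent from the map are never silently included: they are excluded from
#'   both totals, listed in the `"unmapped"` attribute and reported in a
#'   warning.
#' @export
sum_by_localization <- function(quantified, map = default_localization_map(),
                                value = "quantity") {
  stopifnot(all(c("sample_id", "compound", value) %in% names(quantified)),
            all(c("compound", "localization") %in% names(map)))
  loc <- map$localization[match(quantified$compound, map$compound)]
  unmapped <- sort(unique(quantified$compound[is.na(loc)]))
  if (length(unmapped))
    warning("unmapped compound(s) excluded from totals: ",
            paste(unmapped, collapse = ", "))
  ids <- unique(quantified$sample_id)
  sum_loc <- function(id, what) {
    sel <- quantified$sample_id == id & !is.na(loc) & loc == what
    sum(quantified[[value]][sel])
  }
  out <- data.frame(sample_id = ids,
                    plastidial = vapply(ids, sum_loc, numeric(1), "plastidial"),
                    cytosolic = vapply(ids, sum_loc, numeric(1), "cytosolic"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "unmapped") <- unmapped
  out
}
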