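#' Summed two-sided trichome density per plant
#'
#' From per-disc counts on the abaxial and adaxial leaf surfaces: replicate
#' discs are averaged within each side first, then the two sides are summed
#' to give the two-sided count per leaf-disc area (`summed_per_disc`).
#' `per_mm2` divides that two-sided sum by the area of one disc, pi * r^2
#' (12.566 mm^2 for the standard r = 2 mm disc) — both conventions are
#' reported because field summaries use both.
#'
#' @param counts Data frame with columns `plant_id`, `side`
#'   (`"abaxial"`/`"adaxial"`), `disc_radius_mm`, `trichome_type`, `count`;
#'   one row per disc (replicate discs allowed).
#' @param type Trichome type to summarize (default `"typeVI"`).
#' @return Data frame `plant_id`, `summed_per_disc`, `per_mm2`.
#' @export
summed_density <- function(counts, type = "typeVI") {
  req <- c("plant_id", "side", "disc_radius_mm", "trichome_type", "count")
  if (!all(req %in% names(counts)))
    stop("counts table missing column(s): ",
         paste(setdiff(req, names(counts)), collapse = ", "))
  d <- counts[counts$trichome_type == type, , drop = FALSE]
  if (nrow(d) == 0L) stop("no rows for trichome type '", type, "'")
  if (any(d$count < 0)) stop("counts must be non-negative")
  if (any(d$disc_radius_mm <= 0)) stop("disc radius must be > 0")
  if (!all(d$side %in% c("abaxial", "adaxial")))
    stop("side must be 'abaxial' or 'adaxial'")
  ids <- unique(d$plant_id)
  one <- function(id) {
    p <- d[d$plant_id == id, , drop = FALSE]
    if (!all(c("abaxial", "adaxial") %in% p$side))
      stop("plant ", id, ": both leaf sides are required")
    r <- unique(p$disc_radius_mm)
    if (length(r) != 1L)
      stop("plant ", id, ": mixed disc radii are not supported")
    per_side <- tapply(p$count, p$side, mean)
    total <- sum(per_side[c("abaxial", "adaxial")])
    c(total = total, per_mm2 = total / (pi * r^2))
  }
  res <- t(vapply(ids, one, numeric(2)))
  data.frame(plant_id = ids, summed_per_disc = res[, "total"],
             per_mm2 = res[, "per_mm2"], stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Assign plants to equal-width trichome-density classes
#'
#' K equal-width, right-closed bins spanning the observed [min, max] of the
#' summed counts (the lowest bin is closed on both sides); every plant is
#' assigned exactly once. Bin edges are returned in the `"edges"` attribute
#' for audit.
#'
#' @param summed_counts Numeric vector of summed two-sided counts, named by
#'   plant id (names optional).
#' @param K Number of classes (default 10).
#' @return Data frame `plant_id`, `summed_count`, `class_index` (1..K) with
#'   attribute `"edges"`. If all counts are equal a single class is used
#'   with a warning.
#' @export
assign_density_classes <- function(summed_counts, K = 10) {
  stopifnot(K >= 1, length(summed_counts) >= 1)
  ids <- names(summed_counts)
  if (is.null(ids)) ids <- as.character(seq_along(summed_counts))
  lo <- min(summed_counts)
  hi <- max(summed_counts)
  if (lo == hi) {
    warning("all summed counts equal; assigning a single class")
    out <- data.frame(plant_id = ids, summed_count = as.vector(summed_counts),
                      class_index = 1L, stringsAsFactors = FALSE)
    attr(out, "edges") <- c(lo, hi)
    return(out)
  }
  edges <- seq(lo, hi, length.out = K + 1)
  idx <- findInterval(summed_counts, edges, rightmost.closed = TRUE,
                      left.open = TRUE)
  idx[summed_counts == lo] <- 1L  # lowest bin closed at the minimum
  out <- data.frame(plant_id = ids, summed_count = as.vector(summed_counts),
                    class_index = as.integer(idx), stringsAsFactors = FALSE)
  attr(out, "edges") <- edges
  out
}

#' Storage-cavity volume of a type-VI gland as a prolate spheroid
#'
#' From the measured width (transverse-plane diameter) and height
#' (medial-plane diameter) in micrometres, with semi-axes a = width/2 and
#' b = height/2. The default volume is `(4/3) * a^2 * b` — the formula as
#' printed in the field's cavity-measurement protocols, which omits the
#' factor pi of the true spheroid volume. Set `include_pi = TRUE` for the
#' geometric `(4/3) * pi * a^2 * b`. Ratio-based summaries (fold changes,
#' percent reductions) are identical under either convention.
#'
#' @param width_um,height_um Positive diameters in micrometres (vectorized).
#' @param include_pi Use the geometric spheroid formula.
#' @return Volume(s) in cubic micrometres.
#' @export
#' @examples
#' cavity_volume(2, 2)                     # 4/3
#' cavity_volume(2, 2, include_pi = TRUE)  # 4*pi/3
cavity_volume <- function(width_um, height_um, include_pi = FALSE) {
  if (any(width_um <= 0) || any(height_um <= 0))
    stop("cavity dimensions must be > 0")
  a <- width_um / 2
  b <- height_um / 2
  v <- (4 / 3) * a^2 * b
  if (include_pi) v <- v * pi
  v
}

#' Convert cubic micrometres to picolitres
#'
#' 1 picolitre = 1000 cubic micrometres.
#'
#' @param v_um3 Volume(s) in cubic micrometres, >= 0.
#' @return Volume(s) in picolitres.
#' @export
um3_to_picolitre <- function(v_um3) {
  if (any(v_um3 < 0)) stop("volume must be >= 0")
  v_um3 / 1000
}

#' @rdname um3_to_picolitre
#' @param v_pl Volume(s) in picolitres.
#' @export
picolitre_to_um3 <- function(v_pl) {
  if (any(v_pl < 0)) stop("volume must be >= 0")
  v_pl * 1000
}

#' Linear correlation between trichome density and terpene quantity
#'
#' Ordinary least squares of terpene totals on type-VI density, reporting
#' the squared Pearson correlation, the two-sided p-value for a non-zero
#' slope, the fitted line and a 95% confidence band — the standard check of
#' whether gland density alone explains leaf-level terpene quantities.
#'
#' @param density Numeric vector, trichomes per mm^2.
#' @param terpene Numeric vector (same length, n >= 3), e.g. ng/mg FW.
#' @return List with `r_squared`, `p_value`, `slope`, `intercept`, the
#'   underlying `lm` fit, and `band(x)` returning the fit with 95%
#'   confidence limits at new density values.
#' @export
density_terpene_correlation <- function(density, terpene) {
  stopifnot(length(density) == length(terpene))
  if (length(density) < 3) stop("need n >= 3 paired observations")
  if (stats::sd(density) == 0) stop("density is constant; slope undefined")
  fit <- stats::lm(terpene ~ density)
  sm <- summary(fit)
  list(r_squared = sm$r.squared,
       p_value = sm$coefficients["density", "Pr(>|t|)"],
       slope = unname(stats::coef(fit)[["density"]]),
       intercept = unname(stats::coef(fit)[["(Intercept)"]]),
       fit = fit,
       band = function(x) {
         as.data.frame(stats::predict(fit, data.frame(density = x),
                                      interval = "confidence", level = 0.95))
       })
}
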