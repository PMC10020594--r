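#' Define a single locus requirement
#'
#' A locus requirement states what an F2 plant must carry at one unlinked
#' locus for the qualitative phenotype (e.g. "high 7-epizingiberene") to be
#' expressed: `"recessive"` means homozygous for the wild-parent allele,
#' `"dominant"` means at least one wild-parent allele.
#'
#' @param label Short identifier, e.g. `"a"`. Case does not encode the mode;
#'   use `mode` (labels are stored lower-case, display casing follows mode).
#' @param mode Either `"recessive"` or `"dominant"`.
#' @return An object of class `"locus"`.
#' @seealso [genetic_model()], [parse_model()]
#' @export
#' @examples
#' locus("a", "recessive")
locus <- function(label, mode = c("recessive", "dominant")) {
  mode <- match.arg(mode)
  if (!is.character(label) || length(label) != 1L || !nzchar(label))
    stop("locus label must be a non-empty string")
  structure(list(label = tolower(label), mode = mode), class = "locus")
}

#' Define a multi-locus Mendelian model for a selfed-F1 (F2) population
#'
#' A genetic model is an ordered set of unlinked locus requirements, all of
#' which must be satisfied for a plant to express the phenotype. Loci are
#' assumed unlinked (independent assortment) and the F1 fully heterozygous,
#' so each locus segregates 1:2:1 in the F2.
#'
#' @param ... [locus()] objects, or a single list of them.
#' @return An object of class `"genetic_model"`.
#' @export
#' @examples
#' genetic_model(locus("a", "recessive"), locus("b", "recessive"))
#' parse_model("a-b-C-D")   # equivalent shorthand, capitals = dominant
genetic_model <- function(...) {
  loci <- list(...)
  if (length(loci) == 1L && is.list(loci[[1L]]) && !inherits(loci[[1L]], "locus"))
    loci <- loci[[1L]]
  if (length(loci) == 0L) stop("model must contain >=1 locus")
  if (!all(vapply(loci, inherits, logical(1), "locus")))
    stop("all arguments must be 'locus' objects")
  labs <- vapply(loci, `[[`, character(1), "label")
  if (anyDuplicated(labs)) stop("locus labels must be unique")
  structure(list(loci = loci), class = "genetic_model")
}

#' Parse the compact field notation for a gene model
#'
#' The field convention writes recessive loci as lower-case letters and
#' dominant loci as capitals, joined by dashes: `"a-b-C-D"` is two recessive
#' plus two dominant loci. Whitespace around dashes is ignored.
#'
#' @param spec A string such as `"a - b - C"`.
#' @return A [genetic_model()].
#' @export
parse_model <- function(spec) {
  stopifnot(is.character(spec), length(spec) == 1L)
  parts <- strsplit(gsub("[[:space:]]", "", spec), "-", fixed = TRUE)[[1L]]
  parts <- parts[nzchar(parts)]
  if (length(parts) == 0L) stop("model must contain >=1 locus")
  loci <- lapply(parts, function(p) {
    locus(p, if (p == toupper(p) && p != tolower(p)) "dominant" else "recessive")
  })
  genetic_model(loci)
}

locus_modes <- function(model) {
  vapply(model$loci, `[[`, character(1), "mode")
}

locus_labels <- function(model) {
  vapply(model$loci, `[[`, character(1), "label")
}

#' Display label of a model in the field's case convention
#'
#' @param model A [genetic_model()].
#' @param sep Separator between loci.
#' @return A string such as `"a - b - C - D"`.
#' @export
model_label <- function(model, sep = " - ") {
  stopifnot(inherits(model, "genetic_model"))
  labs <- locus_labels(model)
  dom <- locus_modes(model) == "dominant"
  labs[dom] <- toupper(labs[dom])
  paste(labs, collapse = sep)
}

#' @export
print.genetic_model <- function(x, ...) {
  cat("Gene model:", model_label(x), "\n")
  cat(sprintf("  %d loci (%d recessive, %d dominant); expected high fraction %.6g (%s)\n",
              length(x$loci),
              sum(locus_modes(x) == "recessive"),
              sum(locus_modes(x) == "dominant"),
              expected_high_fraction(x),
              segregation_ratio(x)))
  invisible(x)
}

#' Expected fraction of phenotype-positive plants in an F2
#'
#' Under independent assortment from a fully heterozygous F1, each recessive
#' requirement is met with probability 1/4 and each dominant requirement with
#' probability 3/4; the phenotype requires all loci jointly, so the expected
#' "high" fraction is the product over loci.
#'
#' @param model A [genetic_model()].
#' @return The expected fraction in (0, 1).
#' @export
#' @examples
#' expected_high_fraction(parse_model("a-b"))       # 1/16
#' expected_high_fraction(parse_model("a-b-c-D"))   # 3/256
expected_high_fraction <- function(model) {
  stopifnot(inherits(model, "genetic_model"))
  if (length(model$loci) == 0L) stop("model must contain >=1 locus")
  prod(ifelse(locus_modes(model) == "recessive", 1 / 4, 3 / 4))
}

#' Round half away from zero
#'
#' Commercial rounding, used for segregation ratios and reported percentages
#' (base [round()] rounds half to even, which would print 62 where the field
#' convention prints 63).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Expected segregation ratio as a display string "1:k"
#'
#' The odds against the phenotype-positive class, `k = (1 - f) / f`, rounded
#' half away from zero. Exact odds may be non-integer (e.g. 61:3 for two
#' recessive plus one dominant locus, displayed as "1:20").
#'
#' @param model A [genetic_model()].
#' @return A string `"1:k"`.
#' @export
#' @examples
#' segregation_ratio(parse_model("a-b-c-d"))  # "1:255"
segregation_ratio <- function(model) {
  f <- expected_high_fraction(model)
  sprintf("1:%d", as.integer(round_half_up((1 - f) / f)))
}

#' Enumerate all F2 genotype classes of a model with their probabilities
#'
#' Brute-force joint table over the per-locus genotype classes `WW`
#' (homozygous wild), `Wc` (heterozygous) and `cc` (homozygous cultivar),
#' with 1:2:1 marginals and independence across loci. Serves as the
#' enumeration counterpart of the closed-form [expected_high_fraction()].
#'
#' @param model A [genetic_model()] with at most 8 loci.
#' @return A data frame with one column per locus (values `WW`/`Wc`/`cc`),
#'   a `prob` column summing to 1, and a logical `high` column marking
#'   phenotype-positive classes.
#' @export
f2_genotype_classes <- function(model) {
  stopifnot(inherits(model, "genetic_model"))
  L <- length(model$loci)
  if (L > 8L) stop("enumeration limit: at most 8 loci (3^8 rows)")
  classes <- c("WW", "Wc", "cc")
  marg <- c(WW = 1 / 4, Wc = 1 / 2, cc = 1 / 4)
  grid <- expand.grid(rep(list(classes), L), stringsAsFactors = FALSE)
  names(grid) <- locus_labels(model)
  prob <- apply(grid, 1L, function(row) prod(marg[row]))
  modes <- locus_modes(model)
  ok <- rep(TRUE, nrow(grid))
  for (j in seq_len(L)) {
    ok <- ok & if (modes[j] == "recessive") grid[[j]] == "WW"
               else grid[[j]] %in% c("WW", "Wc")
  }
  out <- cbind(grid, prob = prob, high = ok)
  rownames(out) <- NULL
  out
}

#' Classify a genotype as phenotype-positive under a model
#'
#' A plant is "high" iff every recessive locus is homozygous for the wild
#' allele and every dominant locus carries at least one wild allele. Phase is
#' irrelevant; genotypes are wild-allele dosages.
#'
#' @param genotype Named integer vector (or single-row matrix) of wild-allele
#'   counts in 0..2, named by locus label; names must cover the model's loci.
#' @param model A [genetic_model()].
#' @return Logical scalar (or vector for a dosage matrix with one row per
#'   plant).
#' @export
#' @examples
#' classify_phenotype(c(a = 2L), parse_model("a"))          # TRUE
#' classify_phenotype(c(a = 2L, b = 0L), parse_model("a-B")) # FALSE
classify_phenotype <- function(genotype, model) {
  stopifnot(inherits(model, "genetic_model"))
  labs <- locus_labels(model)
  if (is.matrix(genotype)) {
    if (!all(labs %in% colnames(genotype)))
      stop("genotype missing locus: ",
           paste(setdiff(labs, colnames(genotype)), collapse = ", "))
    g <- genotype[, labs, drop = FALSE]
  } else {
    if (!all(labs %in% names(genotype)))
      stop("genotype missing locus: ",
           paste(setdiff(labs, names(genotype)), collapse = ", "))
    g <- matrix(genotype[labs], nrow = 1L, dimnames = list(NULL, labs))
  }
  if (any(g < 0 | g > 2)) stop("wild-allele dosages must be in 0..2")
  modes <- locus_modes(model)
  need <- ifelse(modes == "recessive", 2L, 1L)
  ok <- rep(TRUE, nrow(g))
  for (j in seq_along(labs)) ok <- ok & g[, j] >= need[j]
  if (!is.matrix(genotype)) ok[[1L]] else unname(ok)
}

#' Pearson chi-square goodness-of-fit for a two-class segregation
#'
#' Tests observed high/low counts against an expected high fraction with the
#' uncorrected Pearson statistic on the two phenotype cells (df = 1, no
#' estimated parameters). A Yates continuity correction is available behind
#' `correct` but is off by default: the classical segregation tables in this
#' field are computed without it.
#'
#' @param n_high,n_low Non-negative observed counts.
#' @param f_high Expected fraction of high plants, strictly in (0, 1).
#' @param correct Apply the Yates continuity correction.
#' @return A list with `chi2`, `df` (always 1) and upper-tail `p`.
#' @export
#' @examples
#' pearson_gof(12, 380, 1 / 16)$chi2  # 6.80
pearson_gof <- function(n_high, n_low, f_high, correct = FALSE) {
  if (!is.finite(f_high) || f_high <= 0 || f_high >= 1)
    stop("f_high must be strictly inside (0, 1)")
  if (n_high < 0 || n_low < 0) stop("counts must be non-negative")
  n <- n_high + n_low
  if (n < 1) stop("total count must be >= 1")
  e_high <- n * f_high
  e_low <- n * (1 - f_high)
  d_high <- abs(n_high - e_high)
  d_low <- abs(n_low - e_low)
  if (correct) {
    d_high <- max(0, d_high - 0.5)
    d_low <- max(0, d_low - 0.5)
  }
  chi2 <- d_high^2 / e_high + d_low^2 / e_low
  list(chi2 = chi2, df = 1L, p = chi2_sf(chi2))
}

#' Upper-tail probability of the chi-square distribution with 1 df
#'
#' @param x Non-negative statistic (vectorized).
#' @return Upper-tail probability in [0, 1].
#' @export
#' @examples
#' chi2_sf(3.841)  # ~0.05
chi2_sf <- function(x) {
  if (any(x < 0)) stop("chi-square statistic must be >= 0")
  stats::pchisq(x, df = 1L, lower.tail = FALSE)
}
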