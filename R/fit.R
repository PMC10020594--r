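#' Fit candidate Mendelian segregation models to observed F2 counts
#'
#' The central model-selection routine: for each candidate multi-locus model
#' it computes the expected high fraction, the displayed segregation ratio,
#' and the Pearson chi-square goodness-of-fit against the observed high/low
#' counts, then ranks models by descending p-value (equivalently ascending
#' chi-square at fixed df = 1). Ties are broken by fewer loci, then by the
#' model label lexicographically; equal models keep their input order.
#'
#' Two expectation bases are supported. `"exact"` uses the product-form
#' fraction (e.g. 3/64 for two recessive + one dominant locus).
#' `"printed_ratio"` first rounds the odds to the integer ratio "1:k" and
#' uses f = 1/(k + 1) — the convention under which the classical published
#' segregation tables in this field were computed (their chi-square for the
#' 1:20 model is only reproduced with f = 1/21). The default is
#' `"printed_ratio"` for table reproduction; use `"exact"` for simulation
#' work.
#'
#' @param n_high,n_low Observed counts of phenotype-positive ("high") and
#'   -negative plants. Alternatively pass a list/one-row data frame with
#'   `n_high`/`n_low` as `n_high` and leave `n_low` missing.
#' @param models A list of [genetic_model()] objects (or strings parseable by
#'   [parse_model()]).
#' @param basis `"printed_ratio"` (default) or `"exact"`.
#' @param correct Yates continuity correction, passed to [pearson_gof()].
#' @return An object of class `"seg_fit"`: a list with `fits` (data frame
#'   with columns `model`, `ratio`, `f_high`, `basis`, `chi2`, `df`, `p`,
#'   `rank`), `obs`, `basis`, and `models`.
#' @seealso [table1_models()] for the canonical six-model candidate set.
#' @export
#' @examples
#' fit <- fit_segregation(12, 380, table1_models())
#' fit
#' coef(fit)
fit_segregation <- function(n_high, n_low, models,
                            basis = c("printed_ratio", "exact"),
                            correct = FALSE) {
  basis <- match.arg(basis)
  if (is.list(n_high) && missing(n_low)) {
    obs <- n_high
    n_high <- obs$n_high
    n_low <- obs$n_low
  }
  stopifnot(length(n_high) == 1L, length(n_low) == 1L)
  if (n_high < 0 || n_low < 0 || n_high + n_low < 1)
    stop("observed counts must be non-negative with total >= 1")
  if (length(models) == 0L) stop("at least one candidate model is required")
  if (inherits(models, "genetic_model")) models <- list(models)
  models <- lapply(models, function(m)
    if (is.character(m)) parse_model(m) else m)

  rows <- lapply(models, function(m) {
    f_exact <- expected_high_fraction(m)
    ratio <- segregation_ratio(m)
    f <- if (basis == "exact") f_exact else {
      k <- as.numeric(sub("^1:", "", ratio))
      if (k < 1) f_exact else 1 / (k + 1)  # degenerate "1:0" falls back to exact
    }
    g <- pearson_gof(n_high, n_low, f, correct = correct)
    data.frame(model = model_label(m), ratio = ratio, f_high = f,
               basis = basis, chi2 = g$chi2, df = g$df, p = g$p,
               n_loci = length(m$loci), stringsAsFactors = FALSE)
  })
  fits <- do.call(rbind, rows)
  ord <- order(-fits$p, fits$n_loci, fits$model)
  fits <- fits[ord, , drop = FALSE]
  fits$rank <- seq_len(nrow(fits))
  rownames(fits) <- NULL
  structure(list(fits = fits, obs = c(n_high = n_high, n_low = n_low),
                 basis = basis, models = models[ord], correct = correct),
            class = "seg_fit")
}

#' The six canonical candidate gene models
#'
#' The standard candidate set for a rare recessive-looking F2 phenotype:
#' two to four loci, each recessive or dominant, written in the field's
#' case notation.
#'
#' @return A list of six [genetic_model()] objects.
#' @export
table1_models <- function() {
  lapply(c("a-b", "a-b-C", "a-b-c", "a-b-C-D", "a-b-c-D", "a-b-c-d"),
         parse_model)
}

#' Format a p-value with the conventional reporting thresholds
#'
#' @param p Numeric vector of p-values.
#' @param thresholds Use `"< 0.01"` / `"< 0.05"` below those cuts (default);
#'   otherwise print two decimals everywhere.
#' @return Character vector.
#' @export
format_p <- function(p, thresholds = TRUE) {
  out <- sprintf("%.2f", p)
  if (thresholds) {
    out[p < 0.05] <- "< 0.05"
    out[p < 0.01] <- "< 0.01"
  }
  out
}

#' @export
print.seg_fit <- function(x, thresholds = TRUE, ...) {
  n <- sum(x$obs)
  cat(sprintf("Segregation model fit: %d high / %d low (n = %d, observed 1:%d)\n",
              x$obs[["n_high"]], x$obs[["n_low"]], n,
              as.integer(round_half_up(x$obs[["n_low"]] / x$obs[["n_high"]]))))
  cat(sprintf("Expectation basis: %s%s\n\n", x$basis,
              if (isTRUE(x$correct)) " (Yates-corrected)" else ""))
  tab <- data.frame(`Gene model` = x$fits$model,
                    Segregation = sub(":", ": ", x$fits$ratio),
                    `Chi-sq` = sprintf("%.2f", x$fits$chi2),
                    `p-value` = format_p(x$fits$p, thresholds),
                    check.names = FALSE)
  print(tab, row.names = FALSE, right = FALSE)
  invisible(x)
}

#' @export
summary.seg_fit <- function(object, alpha = 0.05, ...) {
  fits <- object$fits
  structure(list(fits = fits, obs = object$obs, basis = object$basis,
                 alpha = alpha,
                 best = fits$model[1L],
                 rejected = fits$model[fits$p < alpha]),
            class = "summary.seg_fit")
}

#' @export
print.summary.seg_fit <- function(x, ...) {
  print.seg_fit(structure(list(fits = x$fits, obs = x$obs, basis = x$basis,
                               correct = FALSE), class = "seg_fit"),
                thresholds = FALSE)
  cat(sprintf("\nBest-fitting model: %s\n", x$best))
  if (length(x$rejected))
    cat(sprintf("Rejected at alpha = %.2g: %s\n", x$alpha,
                paste(x$rejected, collapse = "; ")))
  else
    cat(sprintf("No model rejected at alpha = %.2g\n", x$alpha))
  invisible(x)
}

#' @export
coef.seg_fit <- function(object, ...) {
  stats::setNames(object$fits$f_high, object$fits$model)
}

#' Expected high/low counts under each candidate model
#'
#' @param object A `"seg_fit"`.
#' @param n Total population size; defaults to the fitted observation's.
#' @param ... Unused.
#' @return Data frame with expected counts per model.
#' @export
predict.seg_fit <- function(object, n = NULL, ...) {
  if (is.null(n)) n <- sum(object$obs)
  data.frame(model = object$fits$model,
             e_high = n * object$fits$f_high,
             e_low = n * (1 - object$fits$f_high),
             stringsAsFactors = FALSE)
}

#' Pearson residuals of the two phenotype cells per model
#'
#' @param object A `"seg_fit"`.
#' @param ... Unused.
#' @return Matrix with one row per model, columns `high` and `low`.
#' @export
residuals.seg_fit <- function(object, ...) {
  n <- sum(object$obs)
  e_high <- n * object$fits$f_high
  e_low <- n - e_high
  r <- cbind(high = (object$obs[["n_high"]] - e_high) / sqrt(e_high),
             low = (object$obs[["n_low"]] - e_low) / sqrt(e_low))
  rownames(r) <- object$fits$model
  r
}

#' Simulate F2 high counts under fitted candidate models
#'
#' Draws binomial high-plant counts at the fitted population size under each
#' model's expected fraction — the parametric bootstrap counterpart of the
#' goodness-of-fit test.
#'
#' @param object A `"seg_fit"`.
#' @param nsim Number of simulated populations per model.
#' @param seed Optional integer seed.
#' @param model Restrict to one model label (default: all).
#' @param ... Unused.
#' @return Matrix of high counts, `nsim` rows, one column per model.
#' @export
simulate.seg_fit <- function(object, nsim = 1, seed = NULL, model = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  fits <- object$fits
  if (!is.null(model)) fits <- fits[fits$model %in% model, , drop = FALSE]
  n <- sum(object$obs)
  out <- vapply(fits$f_high, function(f) stats::rbinom(nsim, n, f),
                numeric(nsim))
  out <- matrix(out, nrow = nsim,
                dimnames = list(NULL, fits$model))
  out
}

#' @export
plot.seg_fit <- function(x, alpha = 0.05, ...) {
  fits <- x$fits
  bp <- graphics::barplot(fits$p, names.arg = fits$model, las = 2,
                          ylab = "GOF p-value",
                          main = "Segregation model fit", ...)
  graphics::abline(h = alpha, lty = 2)
  invisible(bp)
}
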