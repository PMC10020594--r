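#' Configuration for a synthetic F2 population
#'
#' Bundles the genetic model and the measurement-level parameters used by
#' [simulate_f2_population()]. Defaults emulate the studied interspecific
#' tomato cross: a parental-level 7-epizingiberene class around 70 ng/mg FW,
#' a low class around the F1 level of 1.1 ng/mg with a large zero-inflated
#' non-detect fraction, overdispersed per-disc trichome counts independent
#' of the terpene phenotype, and an active/lazy gland latent class with a
#' ~150-fold spread in per-gland content (17.7 vs 0.118 ng/gland). Levels
#' are lognormal (strictly positive, right-skewed) with class-specific
#' coefficients of variation.
#'
#' @param model A [genetic_model()] (or string for [parse_model()]).
#' @param n_plants Number of F2 individuals.
#' @param seed Integer seed; the generator uses one global RNG stream.
#' @param high_level_mean,high_cv Mean ng/mg and CV of the high class.
#' @param low_level_mean,low_cv Mean ng/mg and CV of the (non-zero) low
#'   class.
#' @param zero_fraction_low Probability a low plant has zero detectable
#'   7-epizingiberene.
#' @param density_mean,density_dispersion Negative-binomial mean and size
#'   for summed per-disc type-VI counts.
#' @param active_gland_ng,lazy_gland_ng Per-gland terpene totals of the two
#'   latent activity classes (must satisfy active > lazy).
#' @param gland_cv Within-class CV of per-gland content.
#' @param p_active Marginal probability of the active class.
#' @param activity_link In [0, 1]: probability that a plant's activity class
#'   copies its terpene phenotype class instead of being drawn
#'   independently (0 = fully independent, the default, reflecting that
#'   density/productivity and the high-terpene loci segregate
#'   independently).
#' @param leaf_scale Constant linking density x gland content to the
#'   leaf-level total (ng/mg per (count x ng/gland)).
#' @param cavity_pl_per_ng Storage-cavity volume per ng of gland content
#'   (default 25/17.7, the parental 25 pl at 17.7 ng/gland).
#' @param parental_n Number of parental reference replicates.
#' @return Object of class `"sim_config"`.
#' @export
simulation_config <- function(model = parse_model("a-b-C-D"),
                              n_plants = 392,
                              seed = 1L,
                              high_level_mean = 70, high_cv = 0.3,
                              low_level_mean = 1.1, low_cv = 0.8,
                              zero_fraction_low = 0.8,
                              density_mean = 50, density_dispersion = 5,
                              active_gland_ng = 17.7,
                              lazy_gland_ng = 17.7 / 150,
                              gland_cv = 0.3,
                              p_active = 0.5,
                              activity_link = 0,
                              leaf_scale = 0.2,
                              cavity_pl_per_ng = 25 / 17.7,
                              parental_n = 4L) {
  if (is.character(model)) model <- parse_model(model)
  stopifnot(inherits(model, "genetic_model"))
  cfg <- list(model = model, n_plants = as.integer(n_plants),
              seed = as.integer(seed),
              high_level_mean = high_level_mean, high_cv = high_cv,
              low_level_mean = low_level_mean, low_cv = low_cv,
              zero_fraction_low = zero_fraction_low,
              density_mean = density_mean,
              density_dispersion = density_dispersion,
              active_gland_ng = active_gland_ng,
              lazy_gland_ng = lazy_gland_ng,
              gland_cv = gland_cv, p_active = p_active,
              activity_link = activity_link,
              leaf_scale = leaf_scale,
              cavity_pl_per_ng = cavity_pl_per_ng,
              parental_n = as.integer(parental_n))
  with(cfg, {
    stopifnot(n_plants >= 1,
              high_level_mean > 0, low_level_mean > 0,
              high_cv >= 0, low_cv >= 0, gland_cv >= 0,
              zero_fraction_low >= 0, zero_fraction_low <= 1,
              density_mean > 0, density_dispersion > 0,
              active_gland_ng > lazy_gland_ng, lazy_gland_ng > 0,
              p_active >= 0, p_active <= 1,
              activity_link >= 0, activity_link <= 1,
              leaf_scale > 0, cavity_pl_per_ng > 0, parental_n >= 2)
  })
  structure(cfg, class = "sim_config")
}

# lognormal parameterized by arithmetic mean and CV
rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate F2 genotypes from a selfed heterozygous F1
#'
#' Each locus receives two alleles drawn independently and uniformly from
#' {wild, cultivar}; loci assort independently, so wild-allele dosage per
#' locus is Binomial(2, 1/2) with the Mendelian 1:2:1 genotype classes.
#' Uses the current RNG state (seed upstream).
#'
#' @param model A [genetic_model()].
#' @param n Number of plants.
#' @return Integer matrix, `n` rows, one column per locus label, entries in
#'   0..2 (wild-allele dosage).
#' @export
simulate_genotypes <- function(model, n) {
  stopifnot(inherits(model, "genetic_model"), n >= 1)
  L <- length(model$loci)
  g <- matrix(stats::rbinom(n * L, size = 2L, prob = 0.5), nrow = n,
              dimnames = list(NULL, locus_labels(model)))
  storage.mode(g) <- "integer"
  g
}

#' Simulate a complete synthetic F2 population
#'
#' Generates one plant-level table with the statistical structure the
#' analysis stages assume: genotype by selfed-F1 Mendelian segregation,
#' phenotype class by [classify_phenotype()], class-conditional right-skewed
#' 7-epizingiberene level with a zero-inflated low class, negative-binomial
#' trichome density independent of the phenotype, per-gland content from an
#' independent active/lazy latent class, leaf-level total terpene as
#' density x gland content x constant, and cavity volume proportional to
#' gland content. Deterministic given `cfg$seed`.
#'
#' @param cfg A [simulation_config()].
#' @return Data frame of class `"f2_population"`: one row per plant with
#'   genotype dosage columns (prefixed `geno_`), `phenotype_class`,
#'   `terpene_ng_per_mg`, `density_per_disc`, `latent_activity`, `gland_ng`,
#'   `total_ng_per_mg`, `cavity_pl`. The parental replicate levels are in
#'   attribute `"parental_levels"`, the configuration in `"config"`.
#' @export
simulate_f2_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_plants
  geno <- simulate_genotypes(cfg$model, n)
  high <- classify_phenotype(geno, cfg$model)

  level <- numeric(n)
  nh <- sum(high)
  level[high] <- rlnorm_mean_cv(nh, cfg$high_level_mean, cfg$high_cv)
  nl <- n - nh
  lowlev <- rlnorm_mean_cv(nl, cfg$low_level_mean, cfg$low_cv)
  zero <- stats::runif(nl) < cfg$zero_fraction_low
  lowlev[zero] <- 0
  level[!high] <- lowlev

  density <- stats::rnbinom(n, size = cfg$density_dispersion,
                            mu = cfg$density_mean)
  copy <- stats::runif(n) < cfg$activity_link
  indep <- stats::runif(n) < cfg$p_active
  active <- ifelse(copy, high, indep)
  gland_mean <- ifelse(active, cfg$active_gland_ng, cfg$lazy_gland_ng)
  gland_ng <- rlnorm_mean_cv(n, 1, cfg$gland_cv) * gland_mean
  total <- density * gland_ng * cfg$leaf_scale
  cavity <- gland_ng * cfg$cavity_pl_per_ng

  pop <- data.frame(plant_id = sprintf("F2-%03d", seq_len(n)),
                    as.data.frame(geno), phenotype_class = ifelse(high, "high", "low"),
                    terpene_ng_per_mg = level,
                    density_per_disc = density,
                    latent_activity = ifelse(active, "active", "lazy"),
                    gland_ng = gland_ng,
                    total_ng_per_mg = total,
                    cavity_pl = cavity,
                    stringsAsFactors = FALSE)
  names(pop)[seq_len(ncol(geno)) + 1L] <- paste0("geno_", colnames(geno))
  attr(pop, "parental_levels") <-
    rlnorm_mean_cv(cfg$parental_n, cfg$high_level_mean, cfg$high_cv)
  attr(pop, "config") <- cfg
  class(pop) <- c("f2_population", "data.frame")
  pop
}

#' Fast count-level segregation simulator
#'
#' Draws high-plant counts for replicate F2 populations directly from the
#' binomial implied by the model's exact expected fraction — the count-level
#' marginal of [simulate_f2_population()], used for calibration studies
#' where the per-plant tables are not needed.
#'
#' @param model A [genetic_model()].
#' @param n Population size per replicate.
#' @param reps Number of replicate populations.
#' @return Integer vector of `reps` high counts.
#' @export
simulate_segregation_counts <- function(model, n, reps) {
  f <- expected_high_fraction(model)
  stats::rbinom(reps, n, f)
}

#' Write the measurement tables a synthetic population implies
#'
#' Emits the CSVs consumed by the quantification and phenotype stages plus a
#' ground-truth table: an integrated GC-MS peak table (`peaks.csv`, with a
#' fixed internal-standard area and peak areas back-calculated so that the
#' standard normalization recovers `terpene_ng_per_mg`), sample metadata
#' (`metadata.csv`), response factors (`response_factors.csv`), trichome
#' counts (`counts.csv`; the summed per-disc density split over the two leaf
#' surfaces), cavity measurements (`cavities.csv`; width/height of a
#' prolate spheroid of the plant's cavity volume with aspect ratio
#' height = 0.8 x width), parental replicates (`parental.csv`) and
#' `ground_truth.csv`. Every file carries the seed in a comment header.
#'
#' @param pop An `"f2_population"` from [simulate_f2_population()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_population_tables <- function(pop, dir) {
  stopifnot(inherits(pop, "f2_population"))
  cfg <- attr(pop, "config")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  hdr <- sprintf("# terpseg synthetic population; seed=%d", cfg$seed)
  is_area <- 5e4
  fw_mg <- 100
  ext_ul <- 1000
  inj_ul <- 1
  dilution <- 1
  # invert the normalization so the pipeline recovers terpene_ng_per_mg
  peak_area <- pop$terpene_ng_per_mg * fw_mg / (dilution * ext_ul / inj_ul) * is_area
  peaks <- data.frame(sample_id = pop$plant_id,
                      compound = "7-epizingiberene",
                      peak_area = peak_area, is_area = is_area)
  meta <- data.frame(sample_id = pop$plant_id, basis = "fresh_weight",
                     fresh_weight_mg = fw_mg, n_glands = NA,
                     extraction_volume_ul = ext_ul,
                     injection_volume_ul = inj_ul, dilution = dilution)
  rf <- data.frame(compound = "7-epizingiberene",
                   standard_compound = "beta-caryophyllene",
                   ng_per_unit_area = 1)
  ab <- ceiling(pop$density_per_disc / 2)
  ad <- pop$density_per_disc - ab
  counts <- data.frame(plant_id = rep(pop$plant_id, 2L),
                       side = rep(c("abaxial", "adaxial"),
                                  each = nrow(pop)),
                       disc_radius_mm = 2,
                       trichome_type = "typeVI",
                       count = c(ab, ad))
  v_um3 <- picolitre_to_um3(pop$cavity_pl)
  # printed-formula spheroid v = (4/3) a^2 b with b = 0.8 a
  a <- (v_um3 / ((4 / 3) * 0.8))^(1 / 3)
  cav <- data.frame(plant_id = pop$plant_id,
                    trichome_id = paste0(pop$plant_id, "-t1"),
                    width_um = 2 * a, height_um = 2 * 0.8 * a)
  parental <- data.frame(replicate = seq_along(attr(pop, "parental_levels")),
                         terpene_ng_per_mg = attr(pop, "parental_levels"))
  truth <- data.frame(plant_id = pop$plant_id,
                      genotype = apply(pop[, grep("^geno_", names(pop)),
                                           drop = FALSE], 1L, paste,
                                       collapse = "/"),
                      phenotype_class = pop$phenotype_class,
                      latent_activity = pop$latent_activity)
  tabs <- list(peaks = peaks, metadata = meta, response_factors = rf,
               counts = counts, cavities = cav, parental = parental,
               ground_truth = truth)
  paths <- vapply(names(tabs), function(nm) {
    p <- file.path(dir, paste0(nm, ".csv"))
    con <- file(p, "w")
    writeLines(hdr, con)
    utils::write.csv(tabs[[nm]], con, row.names = FALSE)
    close(con)
    p
  }, character(1))
  invisible(paths)
}

#' Model-recovery experiment on synthetic populations
#'
#' For each replicate: simulate an F2 population under `cfg`, build a
#' parental reference from the simulated parental replicates, classify
#' plants high/low against it, fit the candidate models with
#' [fit_segregation()] (exact basis), and record whether the true model is
#' rejected at `alpha` and which model ranks first.
#'
#' @param cfg A [simulation_config()]; `cfg$model` is the true model.
#' @param models Candidate model list (default [table1_models()]).
#' @param reps Number of replicates (>= 1; use >= 100 for stable rates).
#' @param alpha Rejection level.
#' @return Data frame with one row per candidate model: `model`,
#'   `rejection_rate` (fraction of reps with p < alpha) and `best_fraction`
#'   (fraction of reps ranked first); the true model's label is in
#'   attribute `"true_model"`.
#' @export
recovery_experiment <- function(cfg, models = table1_models(), reps = 100,
                                alpha = 0.05) {
  stopifnot(inherits(cfg, "sim_config"), reps >= 1)
  labels <- vapply(models, model_label, character(1))
  rejected <- matrix(FALSE, reps, length(labels),
                     dimnames = list(NULL, labels))
  best <- character(reps)
  for (r in seq_len(reps)) {
    cfg_r <- cfg
    cfg_r$seed <- cfg$seed + r - 1L
    pop <- simulate_f2_population(cfg_r)
    ref <- parental_reference(attr(pop, "parental_levels"))
    cls <- classify_high_low(pop$terpene_ng_per_mg, ref)
    fit <- fit_segregation(sum(cls == "high"), sum(cls == "low"),
                           models, basis = "exact")
    rejected[r, fit$fits$model] <- fit$fits$p < alpha
    best[r] <- fit$fits$model[1L]
  }
  out <- data.frame(model = labels,
                    rejection_rate = colMeans(rejected)[labels],
                    best_fraction = vapply(labels, function(l)
                      mean(best == l), numeric(1)),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "true_model") <- model_label(cfg$model)
  out
}
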