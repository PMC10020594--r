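test_that("simulated genotypes have Mendelian 1:2:1 marginals", {
  set.seed(71)
  g <- simulate_genotypes(parse_model("a-b-C"), 100000)
  for (lab in c("a", "b", "c")) {
    freq <- tabulate(g[, lab] + 1L, nbins = 3L) / nrow(g)
    se <- sqrt(c(1, 2, 1) / 4 * (1 - c(1, 2, 1) / 4) / nrow(g))
    expect_true(all(abs(freq - c(1, 2, 1) / 4) < 3 * se))
  }
})

test_that("high-phenotype frequency converges to the expected fraction", {
  set.seed(72)
  n <- 100000
  for (spec in c("a", "a-b-c-d")) {
    m <- parse_model(spec)
    g <- simulate_genotypes(m, n)
    f <- expected_high_fraction(m)
    obs <- mean(classify_phenotype(g, m))
    expect_lt(abs(obs - f), 3 * sqrt(f * (1 - f) / n))
  }
})

test_that("population simulation is deterministic given the seed", {
  cfg <- simulation_config(seed = 123, n_plants = 200)
  p1 <- simulate_f2_population(cfg)
  p2 <- simulate_f2_population(cfg)
  expect_identical(p1, p2)
  p3 <- simulate_f2_population(simulation_config(seed = 124, n_plants = 200))
  expect_false(identical(p1$terpene_ng_per_mg, p3$terpene_ng_per_mg))
  # written tables are bit-identical across runs too
  d1 <- tempfile(); d2 <- tempfile()
  write_population_tables(p1, d1)
  write_population_tables(p2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("population structure matches the configured study conditions", {
  cfg <- simulation_config(model = parse_model("a-b-C-D"), n_plants = 392,
                           seed = 77)
  pop <- simulate_f2_population(cfg)
  expect_equal(nrow(pop), 392)
  # phenotype class is the classification of the stored genotype
  geno <- as.matrix(pop[, paste0("geno_", c("a", "b", "c", "d"))])
  colnames(geno) <- c("a", "b", "c", "d")
  expect_identical(pop$phenotype_class == "high",
                   classify_phenotype(geno, cfg$model))
  # high count within binomial 95% bounds of n * 9/256
  nh <- sum(pop$phenotype_class == "high")
  bounds <- qbinom(c(0.025, 0.975), 392, 9 / 256)
  expect_gte(nh, bounds[1]); expect_lte(nh, bounds[2])
  # zero inflation confined to the low class
  expect_true(all(pop$terpene_ng_per_mg[pop$phenotype_class == "high"] > 0))
  lows <- pop$terpene_ng_per_mg[pop$phenotype_class == "low"]
  expect_gt(mean(lows == 0), 0.6)
  # ~150-fold spread between latent activity classes
  expect_equal(cfg$active_gland_ng / cfg$lazy_gland_ng, 150)
  expect_gt(mean(pop$gland_ng[pop$latent_activity == "active"]) /
            mean(pop$gland_ng[pop$latent_activity == "lazy"]), 50)
  # parental replicates come with the population
  expect_length(attr(pop, "parental_levels"), 4L)
})

test_that("trichome density is independent of the terpene phenotype by default", {
  cfg <- simulation_config(n_plants = 5000, seed = 78)
  pop <- simulate_f2_population(cfg)
  hi <- pop$density_per_disc[pop$phenotype_class == "high"]
  lo <- pop$density_per_disc[pop$phenotype_class == "low"]
  expect_gt(t.test(hi, lo)$p.value, 0.01)
})

test_that("gland-content spread controls the density-total correlation", {
  # constant per-gland content: leaf total is proportional to density
  cfg_const <- simulation_config(n_plants = 84, seed = 79, gland_cv = 0,
                                 active_gland_ng = 10, lazy_gland_ng = 9.999,
                                 p_active = 1)
  pop_c <- simulate_f2_population(cfg_const)
  r2_c <- suppressWarnings(density_terpene_correlation(
    pop_c$density_per_disc, pop_c$total_ng_per_mg)$r_squared)
  expect_gt(r2_c, 0.99)
  # 150-fold active/lazy spread collapses it
  cfg_spread <- simulation_config(n_plants = 84, seed = 79)
  pop_s <- simulate_f2_population(cfg_spread)
  r2_s <- density_terpene_correlation(pop_s$density_per_disc,
                                      pop_s$total_ng_per_mg)$r_squared
  expect_lt(r2_s, 0.2)
})

test_that("written tables validate against the consuming modules (round trip)", {
  cfg <- simulation_config(n_plants = 60, seed = 80)
  pop <- simulate_f2_population(cfg)
  dir <- tempfile()
  paths <- write_population_tables(pop, dir)
  peaks <- read.csv(paths[["peaks"]], comment.char = "#")
  meta <- read.csv(paths[["metadata"]], comment.char = "#")
  rf <- read.csv(paths[["response_factors"]], comment.char = "#")
  q <- quantify_peaks(normalize_peaks(peaks, meta), rf)
  # pipeline arithmetic inverts the generator's back-calculation
  expect_equal(q$quantity[match(pop$plant_id, q$sample_id)],
               pop$terpene_ng_per_mg, tolerance = 1e-9)
  counts <- read.csv(paths[["counts"]], comment.char = "#")
  dens <- summed_density(counts)
  expect_equal(dens$summed_per_disc[match(pop$plant_id, dens$plant_id)],
               as.numeric(pop$density_per_disc))
  cav <- read.csv(paths[["cavities"]], comment.char = "#")
  vol <- um3_to_picolitre(cavity_volume(cav$width_um, cav$height_um))
  expect_equal(vol[match(pop$plant_id, cav$plant_id)], pop$cavity_pl,
               tolerance = 1e-9)
  truth <- read.csv(paths[["ground_truth"]], comment.char = "#")
  expect_identical(truth$phenotype_class,
                   pop$phenotype_class[match(truth$plant_id, pop$plant_id)])
  # seed recorded in every header
  for (p in paths) expect_match(readLines(p, n = 1), "seed=80")
  unlink(dir, recursive = TRUE)
})

test_that("count-level simulator matches the population marginal", {
  m <- parse_model("a-b")
  set.seed(81)
  counts <- simulate_segregation_counts(m, 392, 2000)
  expect_equal(mean(counts), 392 / 16, tolerance = 0.1)
  expect_true(all(counts >= 0 & counts <= 392))
})

test_that("recovery experiment reports calibrated rejection and ranking", {
  cfg <- simulation_config(model = parse_model("a-b-C-D"), n_plants = 392,
                           seed = 90)
  res <- recovery_experiment(cfg, reps = 60)
  expect_identical(attr(res, "true_model"), "a - b - C - D")
  expect_equal(sum(res$best_fraction), 1)
  # the true model is rarely rejected, the most distant model usually is
  expect_lt(res$rejection_rate[res$model == "a - b - C - D"], 0.3)
  expect_gt(res$rejection_rate[res$model == "a - b - c - d"],
            res$rejection_rate[res$model == "a - b - C - D"])
  # single replicate still yields a complete table
  one <- recovery_experiment(cfg, reps = 1)
  expect_equal(nrow(one), 6)
})

test_that("wrong models are rejected with near certainty at large n", {
  true <- parse_model("a-b-C-D")
  set.seed(91)
  hits <- replicate(25, {
    nh <- simulate_segregation_counts(true, 50000, 1)
    fit <- fit_segregation(nh, 50000 - nh,
                           list(parse_model("a-b"), parse_model("a-b-c-d"),
                                true), basis = "exact")
    c(fit$fits$p[fit$fits$model == "a - b"] < 0.05,
      fit$fits$p[fit$fits$model == "a - b - c - d"] < 0.05)
  })
  expect_gt(mean(hits), 0.99)
})

test_that("simulation config validates its invariants", {
  expect_error(simulation_config(active_gland_ng = 1, lazy_gland_ng = 2))
  expect_error(simulation_config(zero_fraction_low = 1.5))
  expect_error(simulation_config(n_plants = 0))
  expect_error(simulation_config(parental_n = 1))
})
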