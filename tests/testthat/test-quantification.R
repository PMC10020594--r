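test_that("normalization matches the hand-computed oracle and is linear", {
  norm <- normalize_peaks(toy_peaks(), toy_meta())
  expect_equal(norm$norm_area, toy_expected_norm())
  expect_identical(norm$basis, c("fresh_weight", "glands", "fresh_weight"))
  # linearity in peak area
  scaled <- toy_peaks()
  scaled$peak_area <- scaled$peak_area * 3
  expect_equal(normalize_peaks(scaled, toy_meta())$norm_area,
               3 * norm$norm_area)
  # doubling dilution doubles, doubling IS area halves
  m2 <- toy_meta(); m2$dilution <- m2$dilution * 2
  expect_equal(normalize_peaks(toy_peaks(), m2)$norm_area, 2 * norm$norm_area)
  p2 <- toy_peaks(); p2$is_area <- p2$is_area * 2
  expect_equal(normalize_peaks(p2, toy_meta())$norm_area, norm$norm_area / 2)
  # IS-equivalent ng output is a constant rescaling
  expect_equal(normalize_peaks(toy_peaks(), toy_meta(),
                               is_ng_per_ul = 0.5)$norm_area,
               0.5 * norm$norm_area)
})

test_that("normalization rejects invalid inputs", {
  expect_error(normalize_peaks(toy_peaks(), toy_meta()[-1, ]), "no metadata")
  bad <- toy_peaks(); bad$is_area[1] <- 0
  expect_error(normalize_peaks(bad, toy_meta()), "is_area")
  neg <- toy_peaks(); neg$peak_area[1] <- -1
  expect_error(normalize_peaks(neg, toy_meta()), "peak_area")
})

test_that("quantification applies response factors and flags missing ones", {
  norm <- normalize_peaks(toy_peaks(), toy_meta())
  rf <- data.frame(compound = "7-epizingiberene",
                   standard_compound = "beta-caryophyllene",
                   ng_per_unit_area = 2.5)
  q <- suppressWarnings(quantify_peaks(norm, rf))
  expect_equal(q$quantity[1:2], 2.5 * norm$norm_area[1:2])
  expect_false(any(q$semi_quantitative[1:2]))
  expect_true(q$semi_quantitative[3])         # no rf: kept, not dropped
  expect_equal(q$quantity[3], norm$norm_area[3])
  expect_warning(quantify_peaks(norm, rf), "beta-caryophyllene")
  rf$ng_per_unit_area <- 1
  expect_equal(suppressWarnings(quantify_peaks(norm, rf))$quantity[1:2],
               norm$norm_area[1:2])            # unit slope is the identity
})

test_that("per-gland quantities recover a configured parental-like total", {
  # synthetic high-producer fixture: 150 glands, configured 17.7 ng/gland
  target <- 17.7
  n_glands <- 150
  peaks <- data.frame(sample_id = "pi_like",
                      compound = c("7-epizingiberene", "beta-caryophyllene"),
                      peak_area = c(0.7, 0.3) * target * n_glands / 300 * 1000,
                      is_area = 1000)
  meta <- data.frame(sample_id = "pi_like", basis = "glands",
                     fresh_weight_mg = NA, n_glands = n_glands,
                     extraction_volume_ul = 300, injection_volume_ul = 1,
                     dilution = 1)
  rf <- data.frame(compound = c("7-epizingiberene", "beta-caryophyllene"),
                   standard_compound = "beta-caryophyllene",
                   ng_per_unit_area = 1)
  q <- quantify_peaks(normalize_peaks(peaks, meta), rf)
  expect_equal(sum(q$quantity), target, tolerance = 1e-9)
})

test_that("parental reference matches the 1.96 SE interval formula", {
  ref <- parental_reference(c(1, 2, 3, 4))
  expect_equal(ref$mean, 2.5)
  expect_equal(ref$sd, sd(c(1, 2, 3, 4)))        # 1.2910
  expect_equal(ref$ci_high - ref$mean, 1.96 * ref$sd / 2)
  expect_equal(ref$ci_high - ref$mean, 1.2652, tolerance = 1e-4)
  cst <- parental_reference(rep(7, 4))
  expect_equal(cst$sd, 0)
  expect_equal(cst$ci_low, cst$mean)
  expect_equal(cst$ci_high, cst$mean)
  expect_error(parental_reference(5), "n >= 2")
})

test_that("high/low classification is monotone and respects the rule", {
  ref <- parental_reference(c(60, 70, 75, 80))
  expect_identical(classify_high_low(ref$mean, ref), "high")
  expect_identical(classify_high_low(0, ref), "low")
  v <- seq(0, 120, by = 5)
  cls <- classify_high_low(v, ref)
  expect_true(all(diff(cls == "high") >= 0))  # monotone in value
  # mean rule is stricter than ci_low rule
  between <- (ref$ci_low + ref$mean) / 2
  expect_identical(classify_high_low(between, ref), "high")
  expect_identical(classify_high_low(between, ref, rule = "mean"), "low")
})

test_that("classification recovers a ~3% true-high fraction within binomial bounds", {
  # two recessive + two dominant loci: f = 9/256, about 3.5% true-high
  # plants; the mean recovered count over replicate populations must sit
  # inside the single-population binomial 95% bounds of n * f (the n = 4
  # parental interval makes the ci_low rule mildly conservative, so a
  # replicate mean is the stable statistic for this check)
  model <- parse_model("a-b-C-D")
  f <- expected_high_fraction(model)
  recovered <- vapply(101:140, function(seed) {
    pop <- simulate_f2_population(
      simulation_config(model = model, n_plants = 392, seed = seed))
    ref <- parental_reference(attr(pop, "parental_levels"))
    sum(classify_high_low(pop$terpene_ng_per_mg, ref) == "high")
  }, numeric(1))
  bounds <- qbinom(c(0.025, 0.975), 392, f)
  expect_gte(mean(recovered), bounds[1])
  expect_lte(mean(recovered), bounds[2])
})

test_that("SD-width binning isolates zeros and matches a loop oracle", {
  sd_p <- 2
  h <- bin_levels(c(0, 0, 1, 3, 4.1), sd_p)
  expect_equal(h$count[h$bin == 0], 2)
  expect_equal(h$count[h$bin == 1], 1)   # 1 in (0, 2]
  expect_equal(h$count[h$bin == 2], 1)   # 3 in (2, 4]
  expect_equal(h$count[h$bin == 3], 1)   # 4.1 in (4, 6]
  expect_equal(sum(h$count), 5)
  # boundary values are right-closed
  expect_equal(bin_levels(c(0.5, 1.5) * sd_p, sd_p)$count[-1], c(1, 1))
  expect_equal(bin_levels(sd_p, sd_p)$count[2], 1)  # exactly 1 sd -> bin 1
  # all zeros
  z <- bin_levels(rep(0, 7), sd_p)
  expect_equal(z$count[z$bin == 0], 7)
  # brute-force loop oracle on random values
  set.seed(5)
  v <- c(rep(0, 10), rexp(200, rate = 0.5))
  h2 <- bin_levels(v, sd_p)
  oracle <- integer(max(h2$bin) + 1L)
  for (x in v) {
    b <- if (x == 0) 0L else {
      k <- 0L
      while (x > (k + 1) * sd_p) k <- k + 1L
      k + 1L
    }
    oracle[b + 1L] <- oracle[b + 1L] + 1L
  }
  expect_equal(h2$count, oracle)
  expect_equal(sum(h2$count), length(v))
  # detection limit zeroes small values first
  dl <- bin_levels(c(0.01, 5), sd_p, detection_limit = 0.1)
  expect_equal(dl$count[dl$bin == 0], 1)
  expect_error(bin_levels(c(-1, 2), sd_p), "non-negative")
  expect_error(bin_levels(c(1, 2), 0), "parental_sd")
})

test_that("fold changes and percent reductions reproduce the printed report values", {
  expect_identical(format_fold(fold_change(17.7, 0.51)), "~35")
  expect_identical(format_fold(fold_change(0.9, 0.51)), "~1.8")
  expect_equal(fold_change(3, 3), 1)
  expect_error(fold_change(1, 0), "> 0")
  expect_equal(percent_reduction(12.3, 0.21, round_report = TRUE), 98)
  expect_equal(percent_reduction(25.0, 1.2, round_report = TRUE), 95)
  expect_equal(percent_reduction(5.2, 0.065, round_report = TRUE), 99)
  expect_equal(percent_reduction(0.13, 0.083, round_report = TRUE), 36)
  expect_equal(percent_reduction(0.16, 0.060, round_report = TRUE), 63)
  expect_equal(percent_reduction(4, 4), 0)
  expect_warning(percent_reduction(1, 2), "negative")
  expect_error(percent_reduction(0, 1), "control")
})

test_that("percent reduction and fold change are mutually consistent", {
  set.seed(9)
  a <- runif(30, 1, 100)
  b <- runif(30, 0.01, 1) * a
  expect_equal(percent_reduction(a, b),
               100 * (1 - 1 / fold_change(a, b)), tolerance = 1e-12)
})

test_that("localization sums split plastidial and cytosolic compounds", {
  q <- data.frame(sample_id = c("s1", "s1", "s1", "s2"),
                  compound = c("7-epizingiberene", "beta-caryophyllene",
                               "alpha-humulene", "7-epizingiberene"),
                  quantity = c(10, 2, 1, 4))
  tot <- sum_by_localization(q)
  expect_equal(tot$plastidial[tot$sample_id == "s1"], 10)
  expect_equal(tot$cytosolic[tot$sample_id == "s1"], 3)
  expect_equal(tot$cytosolic[tot$sample_id == "s2"], 0)
  # permutation invariance
  tot2 <- sum_by_localization(q[sample(nrow(q)), ])
  expect_equal(tot2[order(tot2$sample_id), ], tot[order(tot$sample_id), ],
               ignore_attr = TRUE)
  # unmapped compounds reported, never silently included
  q$compound[3] <- "mystery-terpene"
  expect_warning(tot3 <- sum_by_localization(q), "mystery-terpene")
  expect_identical(attr(tot3, "unmapped"), "mystery-terpene")
  expect_equal(tot3$cytosolic[tot3$sample_id == "s1"], 2)
})

test_that("quantified values survive a CSV round trip at full precision", {
  norm <- normalize_peaks(toy_peaks(), toy_meta())
  rf <- data.frame(compound = unique(norm$compound),
                   standard_compound = "beta-caryophyllene",
                   ng_per_unit_area = pi / 3)
  q <- quantify_peaks(norm, rf)
  path <- tempfile(fileext = ".csv")
  write_csv_full(q, path)
  back <- utils::read.csv(path)
  expect_identical(back$quantity, q$quantity)
  unlink(path)
})
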