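# Shared in-code fixtures for the test suite.

# all 2^L mode assignments over L loci, as genetic_model objects
all_mode_models <- function(L) {
  combos <- expand.grid(rep(list(c("recessive", "dominant")), L),
                        stringsAsFactors = FALSE)
  lapply(seq_len(nrow(combos)), function(i) {
    genetic_model(lapply(seq_len(L), function(j)
      locus(letters[j], combos[i, j])))
  })
}

# three-record toy GC-MS peak table with matching metadata, values chosen so
# the normalization can be recomputed by hand
toy_peaks <- function() {
  data.frame(sample_id = c("s1", "s2", "s3"),
             compound = c("7-epizingiberene", "7-epizingiberene",
                          "beta-caryophyllene"),
             peak_area = c(1000, 500, 0),
             is_area = c(200, 100, 400),
             stringsAsFactors = FALSE)
}

toy_meta <- function() {
  data.frame(sample_id = c("s1", "s2", "s3"),
             basis = c("fresh_weight", "glands", "fresh_weight"),
             fresh_weight_mg = c(50, NA, 20),
             n_glands = c(NA, 150, NA),
             extraction_volume_ul = c(1000, 300, 1000),
             injection_volume_ul = c(2, 1, 1),
             dilution = c(1, 2, 1),
             stringsAsFactors = FALSE)
}

# hand-computed spreadsheet-style oracle for the toy table:
# (peak/is) * dilution * (ext/inj) / denom
toy_expected_norm <- function() {
  c((1000 / 200) * 1 * (1000 / 2) / 50,  # s1 = 50
    (500 / 100) * 2 * (300 / 1) / 150,   # s2 = 20
    0)                                   # s3
}

toy_counts <- function() {
  data.frame(plant_id = rep(c("p1", "p2"), each = 4),
             side = rep(c("abaxial", "abaxial", "adaxial", "adaxial"), 2),
             disc_radius_mm = 2,
             trichome_type = "typeVI",
             count = c(24, 26, 25, 25,   # p1: means 25 + 25 = 50
                       10, 14, 8, 8),    # p2: means 12 + 8  = 20
             stringsAsFactors = FALSE)
}

expect_seed_stable <- function(expr, seed = 42) {
  set.seed(seed)
  a <- eval.parent(substitute(expr))
  set.seed(seed)
  b <- eval.parent(substitute(expr))
  expect_identical(a, b)
}
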