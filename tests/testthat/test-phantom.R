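small_spec <- function(n_patients = 4, ...) {
  phantom_spec(n_patients = n_patients, seed = 42, ...)
}

test_that("cohort generation is deterministic given the seed", {
  c1 <- generate_cohort(small_spec())
  c2 <- generate_cohort(small_spec())
  expect_identical(c1$table, c2$table)
  expect_identical(as.numeric(c1$patients[[2]]$image),
                   as.numeric(c2$patients[[2]]$image))
  expect_equal(length(c1$patients), 4)
  # masks respect the containment conventions
  p <- c1$patients[[1]]
  expect_false(any(p$tumor_mask & p$lung_mask))
  expect_true(all(c1$table$time > 0))
  expect_true(all(c1$table$event %in% 0:1))
})

test_that("cohort splits half/half into training and validation", {
  co <- generate_cohort(phantom_spec(n_patients = 10, seed = 3))
  expect_equal(sum(co$table$split == "A"), 5)
  expect_equal(sum(co$table$split == "B"), 5)
})

test_that("a grid too small for tumor plus margin is rejected", {
  expect_error(phantom_spec(grid_shape = c(20, 20, 10),
                            tumor_radius_range_mm = c(8, 11)),
               "9 mm margin")
})

test_that("zero rim effect decouples rim heterogeneity from the latent score", {
  spec <- phantom_spec(n_patients = 100, rim_effect_size = 0,
                       tumor_effect_size = 0, exterior_effect_size = 0,
                       seed = 7)
  co <- generate_cohort(spec)
  summ <- vapply(co$patients, function(p) {
    d_out <- distance_to_mask(p$tumor_mask)
    d_in <- distance_to_mask(!p$tumor_mask)
    shell <- (p$tumor_mask & d_in <= 3) | (!p$tumor_mask & d_out <= 3)
    sd(as.numeric(p$image)[shell])
  }, numeric(1))
  r <- cor(co$table$latent_score, summ)
  expect_lt(abs(r), 2 / sqrt(100))
})

test_that("rim-only signal places the strongest latent correlate in the rim", {
  spec <- phantom_spec(n_patients = 40, rim_effect_size = 1,
                       tumor_effect_size = 0, exterior_effect_size = 0,
                       seed = 8)
  co <- generate_cohort(spec)
  stat <- vapply(co$patients, function(p) {
    d_out <- distance_to_mask(p$tumor_mask)
    d_in <- distance_to_mask(!p$tumor_mask)
    rim <- (p$tumor_mask & d_in <= 3) | (!p$tumor_mask & d_out <= 3 & p$lung_mask)
    ext <- !p$tumor_mask & d_out > 3 & d_out <= 9 & p$lung_mask
    c(rim = sd(as.numeric(p$image)[rim]), ext = sd(as.numeric(p$image)[ext]))
  }, numeric(2))
  r_rim <- cor(co$table$latent_score, stat["rim", ], method = "spearman")
  r_ext <- cor(co$table$latent_score, stat["ext", ], method = "spearman")
  expect_gt(abs(r_rim), abs(r_ext))
  expect_gt(abs(r_rim), 0.5)
})

test_that("simulated outcomes follow the proportional-hazards model", {
  spec <- small_spec()
  # vanishing censoring horizon: everyone censored
  spec0 <- phantom_spec(n_patients = 4, seed = 1, censor_admin_months = 1e-4)
  set.seed(9)
  oc0 <- simulate_outcomes(rnorm(200), sample_clinical_table(200), spec0)
  expect_equal(sum(oc0$event), 0)

  # parameter recovery for the latent log-hazard
  set.seed(10)
  lat <- rnorm(500)
  oc <- simulate_outcomes(lat, sample_clinical_table(500), spec)
  m <- fit_cox(data.frame(latent = lat), oc)
  expect_lt(abs(m$coefficients[["latent"]] - 0.7), 0.1)
})

test_that("retest pairs are faithful replicates", {
  spec <- small_spec(retest_noise_sd = 0, retest_shift_mm = 0)
  co <- generate_cohort(spec)
  set.seed(11)
  pair <- generate_retest_pair(co$patients[[1]], spec)
  expect_identical(as.numeric(pair$test$image), as.numeric(pair$retest$image))
  expect_identical(pair$test$outcome, pair$retest$outcome)

  spec2 <- small_spec()
  set.seed(12)
  pair2 <- generate_retest_pair(co$patients[[1]], spec2)
  expect_false(identical(as.numeric(pair2$test$image),
                         as.numeric(pair2$retest$image)))
  expect_equal(pair2$test$latent_score, pair2$retest$latent_score)
})

test_that("identical replicates give ICC 1 for every feature, noisy ones fail the cut", {
  spec <- small_spec(n_patients = 6, retest_noise_sd = 0, retest_shift_mm = 0)
  co <- generate_cohort(spec)
  filters <- list(filter_spec("original"), filter_spec("log", sigma_mm = 3))
  set.seed(13)
  feat_of <- function(p) {
    regs <- region_set(p$tumor_mask, p$lung_mask)
    ft <- extract_region_features(p$image, regs, filters,
                                  which_regions = "rim")
    out <- ft[, setdiff(names(ft), "region")]
    out$patient_id <- p$patient_id
    out
  }
  pairs <- lapply(co$patients, generate_retest_pair, spec = spec)
  tf <- dplyr::bind_rows(lapply(pairs, function(pr) feat_of(pr$test)))
  rf <- dplyr::bind_rows(lapply(pairs, function(pr) feat_of(pr$retest)))
  tf$patient_id <- sub("_test$", "", tf$patient_id)
  rf$patient_id <- sub("_retest$", "", rf$patient_id)
  res <- stability_filter(tf, rf, threshold = 0.85)
  ok <- res$report[!res$report$degenerate, ]
  expect_true(all(abs(ok$icc - 1) < 1e-8))
  expect_gt(nrow(ok), 10)
})

test_that("cohorts round-trip through NIfTI and CSV", {
  co <- generate_cohort(small_spec(n_patients = 2))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "P001_image.nii.gz")))
  img <- read_volume(file.path(dir, "P001_image.nii.gz"))
  expect_equal(as.numeric(img), as.numeric(co$patients[[1]]$image),
               tolerance = 1e-6)
  expect_equal(vol_spacing(img), vol_spacing(co$patients[[1]]$image),
               tolerance = 1e-6)
  csv <- read.csv(file.path(dir, "clinical.csv"))
  expect_equal(nrow(csv), 2)
  expect_true(all(c("patient_id", "time_months", "event", "split",
                    "tumor_size_mm") %in% names(csv)))
})
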