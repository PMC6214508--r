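#' Synthetic CT phantom cohort specification
#'
#' Defines the generating conditions for a seeded phantom cohort: a thoracic
#' patch (body cylinder at soft-tissue HU holding two lung half-ellipsoids
#' at parenchymal HU) with one ellipsoidal tumor abutting the lateral lung
#' wall, spatially correlated texture fields whose amplitude in the rim /
#' tumor / exterior shells scales with a latent aggressiveness score, and
#' exponential proportional-hazards outcomes driven by that score and the
#' clinical covariates.
#'
#' The texture amplitude in a shell is
#' `texture_sd_hu * exp(effect_size * latent)`, so an effect size of 0
#' makes that shell's heterogeneity exactly independent of the latent
#' score.
#'
#' @param n_patients cohort size (default 200, split half/half into
#'   training "A" and validation "B").
#' @param grid_shape voxels per axis.
#' @param spacing_mm per-axis voxel size (mm).
#' @param lung_hu_mean,lung_hu_sd lung parenchyma mean HU and white-noise sd.
#' @param tumor_hu_mean,tumor_hu_sd tumor mean HU and white-noise sd.
#' @param body_hu_mean,body_hu_sd soft-tissue values outside the lungs.
#' @param tumor_radius_range_mm min/max tumor radius (mm).
#' @param rim_effect_size,tumor_effect_size,exterior_effect_size
#'   dimensionless couplings of the latent score to the texture amplitude of
#'   each shell.
#' @param texture_sd_hu base amplitude (HU) of the correlated texture
#'   fields.
#' @param texture_corr_mm correlation length (Gaussian smoothing scale) of
#'   the texture fields.
#' @param psf_sigma_mm scanner point-spread-function sigma (mm); the
#'   noiseless anatomy is blurred by this kernel so tissue interfaces show
#'   realistic partial-volume softening instead of infinite-resolution
#'   steps.
#' @param baseline_hazard events/month for an average patient.
#' @param beta_latent log-hazard per unit latent score.
#' @param beta_clinical named log-hazard vector for the clinical covariates
#'   (applied to mean-centred covariates).
#' @param censor_admin_months administrative censoring horizon; independent
#'   censoring times are uniform on (0, horizon).
#' @param retest_noise_sd white-noise sd (HU) of the replicate scans.
#' @param retest_shift_mm rigid shift magnitude between replicate scans.
#' @param seed integer seed.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(n_patients = 200,
                         grid_shape = c(72, 48, 24),
                         spacing_mm = c(1.25, 1.25, 2.5),
                         lung_hu_mean = -800, lung_hu_sd = 30,
                         tumor_hu_mean = 0, tumor_hu_sd = 20,
                         body_hu_mean = 30, body_hu_sd = 20,
                         tumor_radius_range_mm = c(5, 11),
                         rim_effect_size = 1,
                         tumor_effect_size = 0.4,
                         exterior_effect_size = 0,
                         texture_sd_hu = 60,
                         texture_corr_mm = 2,
                         psf_sigma_mm = 1,
                         baseline_hazard = 0.05,
                         beta_latent = 0.7,
                         beta_clinical = c(age = 0.01, gender = 0,
                                           overall_stage = 0.15,
                                           t_stage = 0.05, n_stage = 0.1,
                                           performance_status = 0.1,
                                           tumor_size_mm = 0.005),
                         censor_admin_months = 72,
                         retest_noise_sd = 10,
                         retest_shift_mm = 1.25,
                         seed = 1L) {
  spec <- list(
    n_patients = as.integer(n_patients), grid_shape = as.integer(grid_shape),
    spacing_mm = as.numeric(spacing_mm), lung_hu_mean = lung_hu_mean,
    lung_hu_sd = lung_hu_sd, tumor_hu_mean = tumor_hu_mean,
    tumor_hu_sd = tumor_hu_sd, body_hu_mean = body_hu_mean,
    body_hu_sd = body_hu_sd,
    tumor_radius_range_mm = as.numeric(tumor_radius_range_mm),
    rim_effect_size = rim_effect_size, tumor_effect_size = tumor_effect_size,
    exterior_effect_size = exterior_effect_size,
    texture_sd_hu = texture_sd_hu, texture_corr_mm = texture_corr_mm,
    psf_sigma_mm = psf_sigma_mm,
    baseline_hazard = baseline_hazard, beta_latent = beta_latent,
    beta_clinical = beta_clinical,
    censor_admin_months = censor_admin_months,
    retest_noise_sd = retest_noise_sd, retest_shift_mm = retest_shift_mm,
    seed = as.integer(seed)
  )
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (n_patients < 1) stop("need n_patients >= 1")
    if (any(c(lung_hu_sd, tumor_hu_sd, body_hu_sd, retest_noise_sd,
              texture_sd_hu) < 0)) {
      stop("all HU standard deviations must be >= 0")
    }
    rr <- tumor_radius_range_mm
    if (length(rr) != 2 || any(rr <= 0) || rr[1] > rr[2]) {
      stop("tumor_radius_range_mm must be a positive interval")
    }
    extent <- grid_shape * spacing_mm
    if (2 * (rr[2] + 9) > min(extent)) {
      stop("grid too small to contain the tumor plus a 9 mm margin")
    }
    if (baseline_hazard <= 0) stop("baseline_hazard must be positive")
    if (censor_admin_months <= 0) stop("censor_admin_months must be positive")
  })
  invisible(spec)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> %d patients, grid %s @ %s mm, effects rim/tumor/ext = %g/%g/%g, seed %d\n",
    x$n_patients, paste(x$grid_shape, collapse = "x"),
    paste(signif(x$spacing_mm, 3), collapse = "x"),
    x$rim_effect_size, x$tumor_effect_size, x$exterior_effect_size, x$seed))
  invisible(x)
}

# marginal distributions of the clinical covariates (ordinal codes follow the
# category order of the covariate definitions)
sample_clinical <- function(n) {
  age <- rnorm(n, 64, 10)
  while (any(bad <- age < 35 | age > 93)) {
    age[bad] <- rnorm(sum(bad), 64, 10)
  }
  tibble::tibble(
    age = age,
    gender = rbinom(n, 1, 0.635),  # 1 = female
    overall_stage = sample(1:4, n, TRUE, prob = c(2.5, 3, 55, 39.5)),
    t_stage = sample(1:7, n, TRUE,
                     prob = c(10.5, 13.5, 29, 9.5, 20, 17, 0.5)),
    n_stage = sample(0:3, n, TRUE, prob = c(7, 8, 54, 31)),
    performance_status = sample(0:3, n, TRUE, prob = c(47.5, 47.5, 4, 1))
  )
}

#' Clinical covariate names of the phantom cohorts
#' @return Character vector of the seven covariates used by the clinical
#'   model.
#' @export
clinical_covariates <- function() {
  c("age", "gender", "overall_stage", "t_stage", "n_stage",
    "performance_status", "tumor_size_mm")
}

# correlated unit-variance Gaussian field on the grid
correlated_field <- function(d, spacing_mm, corr_mm) {
  w <- array(rnorm(prod(d)), dim = d)
  sv <- pmax(corr_mm / spacing_mm, 1e-6)
  k <- lapply(sv, gauss_kernel)
  f <- conv_sep(w, k[[1]], k[[2]], k[[3]])
  f / sd(f)
}

phantom_geometry <- function(spec) {
  d <- spec$grid_shape
  sp <- spec$spacing_mm
  ext <- d * sp
  # voxel centre coordinates (mm)
  cx <- (seq_len(d[1]) - 0.5) * sp[1]
  cy <- (seq_len(d[2]) - 0.5) * sp[2]
  cz <- (seq_len(d[3]) - 0.5) * sp[3]
  list(d = d, sp = sp, ext = ext, cx = cx, cy = cy, cz = cz,
       body_c = ext * c(0.5, 0.5, 0.5), body_ax = ext * c(0.47, 0.45, 1),
       lung_c = list(ext * c(0.27, 0.5, 0.5), ext * c(0.73, 0.5, 0.5)),
       lung_ax = ext * c(0.17, 0.36, 0.48))
}

ellipsoid_mask <- function(geo, centre, ax) {
  ex <- ((geo$cx - centre[1]) / ax[1])^2
  ey <- ((geo$cy - centre[2]) / ax[2])^2
  ez <- ((geo$cz - centre[3]) / ax[3])^2
  outer(outer(ex, ey, `+`), ez, `+`) <= 1
}

# one patient's geometry, template image and masks
build_phantom_case <- function(spec, geo, latent) {
  r <- runif(1, spec$tumor_radius_range_mm[1], spec$tumor_radius_range_mm[2])
  ax <- r * runif(3, 0.85, 1.15)
  lc <- geo$lung_c[[2]]
  centre <- c(lc[1] + max(0, geo$lung_ax[1] - ax[1] - 2),
              lc[2] + runif(1, -3, 3),
              lc[3] + runif(1, -3, 3))
  tumor <- ellipsoid_mask(geo, centre, ax)
  if (!any(tumor)) stop("tumor mask empty: grid/radius mismatch")
  check_margin(tumor, geo$sp, margin_mm = 9)
  lungs <- ellipsoid_mask(geo, geo$lung_c[[1]], geo$lung_ax) |
    ellipsoid_mask(geo, geo$lung_c[[2]], geo$lung_ax)
  body <- ellipsoid_mask(geo, c(geo$body_c[1], geo$body_c[2], geo$ext[3] / 2),
                         c(geo$body_ax[1], geo$body_ax[2], 1e9))
  lung_mask <- lungs & !tumor

  template <- array(-1000, dim = geo$d)
  template[body] <- spec$body_hu_mean
  template[lung_mask] <- spec$lung_hu_mean
  template[tumor] <- spec$tumor_hu_mean

  d_out <- distance_to_mask(tumor, geo$sp)
  d_in <- distance_to_mask(!tumor, geo$sp)
  shells <- list(
    rim = (tumor & d_in <= 3) | (!tumor & d_out <= 3),
    tumor = tumor & d_in > 3,
    exterior = !tumor & d_out > 3 & d_out <= 9
  )
  effects <- c(rim = spec$rim_effect_size, tumor = spec$tumor_effect_size,
               exterior = spec$exterior_effect_size)
  for (nm in names(shells)) {
    amp <- spec$texture_sd_hu * exp(effects[[nm]] * latent)
    f <- correlated_field(geo$d, geo$sp, spec$texture_corr_mm)
    template[shells[[nm]]] <- template[shells[[nm]]] + amp * f[shells[[nm]]]
  }

  # finite scanner resolution: blur the noiseless anatomy with the system PSF
  if (spec$psf_sigma_mm > 0) {
    sv <- spec$psf_sigma_mm / geo$sp
    k <- lapply(sv, gauss_kernel)
    template <- conv_sep(template, k[[1]], k[[2]], k[[3]])
  }

  noise_sd <- array(spec$body_hu_sd, dim = geo$d)
  noise_sd[lung_mask] <- spec$lung_hu_sd
  noise_sd[tumor] <- spec$tumor_hu_sd
  image <- template + array(rnorm(prod(geo$d)), dim = geo$d) * noise_sd

  list(template = image_volume(template, geo$sp),
       image = image_volume(image, geo$sp),
       tumor_mask = as_mask(tumor, geo$sp),
       lung_mask = as_mask(lung_mask, geo$sp),
       noise_sd = noise_sd)
}

check_margin <- function(tumor, spacing_mm, margin_mm = 9) {
  d <- dim(tumor)
  idx <- which(tumor, arr.ind = TRUE)
  m_vox <- ceiling(margin_mm / spacing_mm)
  lo <- apply(idx, 2, min) - m_vox
  hi <- apply(idx, 2, max) + m_vox
  if (any(lo < 1) || any(hi > d)) {
    stop("grid too small to contain the tumor plus a ", margin_mm,
         " mm margin")
  }
  invisible(TRUE)
}

#' Simulate censored time-to-DM outcomes
#'
#' Event times are exponential with rate
#' `baseline_hazard * exp(beta_latent * latent + beta_clinical . clinical)`
#' (clinical covariates mean-centred so the baseline describes an average
#' patient); censoring times are uniform on (0, `censor_admin_months`);
#' the event is observed iff it precedes the censoring time.
#'
#' @param latent numeric latent aggressiveness scores.
#' @param clinical tibble of clinical covariates (columns matching
#'   `names(spec$beta_clinical)`).
#' @param spec a [phantom_spec()].
#' @return Outcome tibble (see [survival_records()]).
#' @export
simulate_outcomes <- function(latent, clinical, spec) {
  if (spec$baseline_hazard <= 0) stop("baseline_hazard must be positive")
  bc <- spec$beta_clinical
  lp <- spec$beta_latent * latent
  if (length(bc)) {
    miss <- setdiff(names(bc), names(clinical))
    if (length(miss)) stop("clinical covariates missing: ",
                           paste(miss, collapse = ", "))
    xc <- scale(as.matrix(clinical[, names(bc)]), center = TRUE,
                scale = FALSE)
    lp <- lp + as.numeric(xc %*% bc)
  }
  n <- length(latent)
  t_event <- rexp(n, rate = spec$baseline_hazard * exp(lp))
  t_cens <- runif(n, 0, spec$censor_admin_months)
  survival_records(time = pmin(t_event, t_cens),
                   event = as.integer(t_event <= t_cens))
}

#' Generate a phantom cohort
#'
#' Draws `n_patients` phantom cases with latent scores, images, masks,
#' clinical covariates and censored outcomes, deterministically for a given
#' spec and seed. The cohort is split half/half into training split "A" and
#' validation split "B" (in generation order, mimicking a temporal split).
#'
#' @param spec a [phantom_spec()].
#' @return A `phantom_cohort`: list with `patients` (list of
#'   `phantom_patient`s), `table` (patient-level tibble: id, split, latent
#'   score, clinical covariates, time, event) and `spec`.
#' @export
generate_cohort <- function(spec) {
  validate_phantom_spec(spec)
  set.seed(spec$seed)
  geo <- phantom_geometry(spec)
  n <- spec$n_patients
  latent <- rnorm(n)
  clinical <- sample_clinical(n)
  patients <- vector("list", n)
  tumor_size <- numeric(n)
  for (i in seq_len(n)) {
    case <- build_phantom_case(spec, geo, latent[i])
    tumor_size[i] <- shape_features(case$tumor_mask)$max_3d_diameter_mm
    patients[[i]] <- structure(
      c(list(patient_id = sprintf("P%03d", i), latent_score = latent[i]),
        case),
      class = "phantom_patient"
    )
  }
  clinical$tumor_size_mm <- tumor_size
  outcomes <- simulate_outcomes(latent, clinical, spec)
  split <- rep(c("A", "B"), c(ceiling(n / 2), floor(n / 2)))
  tab <- dplyr::bind_cols(
    tibble::tibble(patient_id = vapply(patients, `[[`, "", "patient_id"),
                   split = split, latent_score = latent),
    clinical, outcomes
  )
  for (i in seq_len(n)) {
    patients[[i]]$clinical <- clinical[i, ]
    patients[[i]]$outcome <- outcomes[i, ]
    patients[[i]]$split <- split[i]
  }
  structure(list(patients = patients, table = tab, spec = spec),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("<phantom_cohort> %d patients (%d events), split %d A / %d B\n",
              nrow(x$table), sum(x$table$event), sum(x$table$split == "A"),
              sum(x$table$split == "B")))
  invisible(x)
}

#' Generate a test/retest replicate pair
#'
#' Both members are rebuilt from the patient's noiseless template: the test
#' scan adds fresh white noise of sd `retest_noise_sd`; the retest scan is
#' the template rigidly shifted by `retest_shift_mm` along a random
#' direction (masks shifted consistently by nearest neighbour) plus fresh
#' noise. Latent score, clinical covariates and outcome are unchanged. With
#' zero noise and zero shift the two scans are identical. Uses the current
#' RNG state; seed externally for reproducibility.
#'
#' @param patient a `phantom_patient`.
#' @param spec the cohort's [phantom_spec()].
#' @return List with elements `test` and `retest` (both
#'   `phantom_patient`s).
#' @export
generate_retest_pair <- function(patient, spec) {
  if (spec$retest_noise_sd < 0) stop("retest_noise_sd must be >= 0")
  sp <- vol_spacing(patient$template)
  d <- dim(patient$template)
  dir <- rnorm(3)
  dir <- dir / sqrt(sum(dir^2))
  shift <- dir * spec$retest_shift_mm

  fresh <- function(template) {
    template + array(rnorm(prod(d), sd = spec$retest_noise_sd), dim = d)
  }
  test <- patient
  test$image <- image_volume(fresh(as_bare_array(patient$template)), sp)
  test$patient_id <- paste0(patient$patient_id, "_test")

  shifted <- function(a, nn) {
    array(.resample3d(as.numeric(a), d, sp, d, sp, shift, nn), dim = d)
  }
  tmpl2 <- shifted(as_bare_array(patient$template), FALSE)
  tumor2 <- shifted(as.numeric(patient$tumor_mask), TRUE) > 0.5
  lung2 <- shifted(as.numeric(patient$lung_mask), TRUE) > 0.5
  if (!any(tumor2)) stop("shift pushed the tumor outside the grid")
  check_margin(tumor2, sp, margin_mm = 9)
  retest <- patient
  retest$template <- image_volume(tmpl2, sp)
  retest$image <- image_volume(fresh(tmpl2), sp)
  retest$tumor_mask <- as_mask(tumor2, sp)
  retest$lung_mask <- as_mask(lung2, sp)
  retest$patient_id <- paste0(patient$patient_id, "_retest")
  list(test = test, retest = retest)
}

#' Write a phantom cohort to disk
#'
#' Per-patient NIfTI volumes (`<id>_image.nii.gz`, `<id>_tumor.nii.gz`,
#' `<id>_lung.nii.gz`) plus a cohort-level `clinical.csv` with columns
#' patient_id, time_months, event, age, gender, overall_stage, t_stage,
#' n_stage, performance_status, tumor_size_mm, split.
#'
#' @param cohort a `phantom_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (p in cohort$patients) {
    write_volume(p$image, file.path(dir, paste0(p$patient_id, "_image.nii.gz")))
    write_volume(p$tumor_mask,
                 file.path(dir, paste0(p$patient_id, "_tumor.nii.gz")))
    write_volume(p$lung_mask,
                 file.path(dir, paste0(p$patient_id, "_lung.nii.gz")))
  }
  tab <- cohort$table
  out <- tibble::tibble(
    patient_id = tab$patient_id, time_months = tab$time, event = tab$event,
    age = tab$age, gender = tab$gender, overall_stage = tab$overall_stage,
    t_stage = tab$t_stage, n_stage = tab$n_stage,
    performance_status = tab$performance_status,
    tumor_size_mm = tab$tumor_size_mm, split = tab$split
  )
  write.csv(out, file.path(dir, "clinical.csv"), row.names = FALSE)
  invisible(dir)
}
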