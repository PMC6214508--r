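# per-stage seed derivation from one root seed (kept below 2^31)
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 1009) %% 2147483629)
}

#' Study configuration
#'
#' Collects every tunable of the end-to-end study: the phantom generating
#' conditions, the region geometry, the filter bank and discretization, the
#' selection thresholds and the model-building settings. `regions` controls
#' which tissue regions are analysed.
#'
#' @param phantom a [phantom_spec()].
#' @param regions subset of `c("tumor", "rim", "exterior")`.
#' @param filters list of [filter_spec()]s.
#' @param bin_width_hu discretization bin width (HU).
#' @param resample_mm isotropic resampling target (mm).
#' @param rim_inner_mm,rim_outer_mm,ext_from_mm,ext_to_mm region geometry
#'   (mm).
#' @param icc_threshold test-retest stability cutoff.
#' @param icc_type ICC form, see [icc()].
#' @param mrmr_k number of mRMR-selected features per region.
#' @param mrmr_criterion `"mid"` or `"miq"`.
#' @param cv_reps,cv_ratio cross-validation repetitions and fit fraction.
#' @param alpha significance level for the univariable screen.
#' @param seed root seed; every stage derives its own stream from it.
#' @return A `study_config` list.
#' @export
study_config <- function(phantom = phantom_spec(),
                         regions = c("tumor", "rim", "exterior"),
                         filters = default_filters(),
                         bin_width_hu = 25, resample_mm = 3,
                         rim_inner_mm = 3, rim_outer_mm = 3,
                         ext_from_mm = 3, ext_to_mm = 9,
                         icc_threshold = 0.85, icc_type = "icc2_1",
                         mrmr_k = 15, mrmr_criterion = "mid",
                         cv_reps = 1000, cv_ratio = 0.7,
                         alpha = 0.05, seed = 1L) {
  regions <- match.arg(regions, c("tumor", "rim", "exterior"),
                       several.ok = TRUE)
  structure(
    list(phantom = phantom, regions = regions, filters = filters,
         bin_width_hu = bin_width_hu, resample_mm = resample_mm,
         rim_inner_mm = rim_inner_mm, rim_outer_mm = rim_outer_mm,
         ext_from_mm = ext_from_mm, ext_to_mm = ext_to_mm,
         icc_threshold = icc_threshold, icc_type = icc_type,
         mrmr_k = mrmr_k, mrmr_criterion = mrmr_criterion,
         cv_reps = cv_reps, cv_ratio = cv_ratio, alpha = alpha,
         seed = as.integer(seed)),
    class = "study_config"
  )
}

#' @rdname study_config
#' @param path YAML file whose top-level keys override [study_config()]
#'   defaults; a `phantom` mapping overrides [phantom_spec()] defaults.
#' @export
study_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  ph <- do.call(phantom_spec, as.list(y$phantom %||% list()))
  y$phantom <- NULL
  do.call(study_config, c(list(phantom = ph), y))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# feature table for a list of patients: patient_id + region-prefixed columns
extract_cohort_features <- function(patients, cfg) {
  # surface the under-resolved-sigma warning once, not once per scan
  for (f in cfg$filters) {
    if (f$kind == "log" && f$sigma_mm < cfg$resample_mm / 2) {
      warning("LoG sigma ", f$sigma_mm, " mm is under-resolved on the ",
              cfg$resample_mm, " mm analysis grid", call. = FALSE)
    }
  }
  rows <- purrr::map(patients, function(p) {
    regs <- region_set(p$tumor_mask, p$lung_mask,
                       inner_mm = cfg$rim_inner_mm,
                       outer_mm = cfg$rim_outer_mm,
                       from_mm = cfg$ext_from_mm, to_mm = cfg$ext_to_mm)
    ft <- suppressWarnings(
      extract_region_features(p$image, regs, cfg$filters, cfg$bin_width_hu,
                              cfg$resample_mm, which_regions = cfg$regions))
    wide <- purrr::map(seq_len(nrow(ft)), function(i) {
      vals <- ft[i, setdiff(names(ft), "region"), drop = FALSE]
      names(vals) <- paste(ft$region[i], names(vals), sep = "_")
      vals
    })
    dplyr::bind_cols(tibble::tibble(patient_id = p$patient_id), wide)
  })
  dplyr::bind_rows(rows)
}

region_columns <- function(feature_table, region) {
  grep(paste0("^", region, "_"), names(feature_table), value = TRUE)
}

#' Run the full peritumoral radiomics study
#'
#' Executes the complete analysis on a seeded phantom cohort: cohort
#' generation, region construction, filtered feature extraction, stability
#' filtering on training-split test/retest replicates, mRMR reduction,
#' univariable screening, forward cross-validated signature construction
#' per region, a clinical Cox model, linear-predictor model combinations,
#' pairwise concordance comparisons, and median-risk Kaplan-Meier
#' stratification. Every validation statistic uses only the held-out
#' split "B"; all randomness derives from the config's root seed.
#'
#' @param config a [study_config()] or the path of a YAML config file.
#' @return A `periomics_study` list: cohort table, feature table,
#'   per-region selection reports, univariable table, signatures, models,
#'   validation tibble, pairwise comparisons and stratification results.
#' @export
run_study <- function(config = study_config()) {
  cfg <- if (is.character(config)) study_config_yaml(config) else config
  spec <- cfg$phantom
  spec$seed <- derive_seed(cfg$seed, 1)

  message("[1/7] generating phantom cohort (n = ", spec$n_patients, ")")
  cohort <- generate_cohort(spec)
  tab <- cohort$table
  is_a <- tab$split == "A"

  message("[2/7] extracting features (", length(cfg$filters), " filters x ",
          length(cfg$regions), " regions)")
  features <- extract_cohort_features(cohort$patients, cfg)

  message("[3/7] test/retest replicates and stability filtering")
  set.seed(derive_seed(cfg$seed, 2))
  a_patients <- cohort$patients[is_a]
  pairs <- purrr::map(a_patients, generate_retest_pair, spec = spec)
  test_feat <- extract_cohort_features(purrr::map(pairs, "test"), cfg)
  retest_feat <- extract_cohort_features(purrr::map(pairs, "retest"), cfg)
  test_feat$patient_id <- sub("_test$", "", test_feat$patient_id)
  retest_feat$patient_id <- sub("_retest$", "", retest_feat$patient_id)

  outcomes_a <- tab[is_a, c("time", "event")]
  outcomes_b <- tab[!is_a, c("time", "event")]
  feat_a <- features[is_a, , drop = FALSE]
  feat_b <- features[!is_a, , drop = FALSE]

  selection <- list()
  signatures <- list()
  univariable <- list()
  models <- list()
  for (rg in cfg$regions) {
    cols <- region_columns(features, rg)
    stab <- stability_filter(
      test_feat[, c("patient_id", cols)], retest_feat[, c("patient_id", cols)],
      threshold = cfg$icc_threshold, type = cfg$icc_type
    )
    usable <- stab$kept[vapply(stab$kept, function(f) !anyNA(features[[f]]),
                               logical(1))]
    k_eff <- min(cfg$mrmr_k, length(usable))
    if (k_eff < cfg$mrmr_k) {
      message("  [", rg, "] only ", length(usable),
              " stable features; ranking k = ", k_eff)
    }
    ranking <- mrmr_rank(feat_a[, usable, drop = FALSE],
                         labels = outcomes_a$event, k = k_eff,
                         criterion = cfg$mrmr_criterion)
    selection[[rg]] <- list(icc_report = stab$report, kept = stab$kept,
                            ranking = ranking)
    message("[4/7] univariable screen: ", rg)
    univariable[[rg]] <- dplyr::mutate(
      univariable_screen(feat_a[, c("patient_id", ranking$feature)],
                         outcomes_a, alpha = cfg$alpha),
      region = rg, .before = 1
    )
    message("[5/7] signature construction: ", rg)
    signatures[[rg]] <- build_signature(
      ranking, feat_a, outcomes_a, n_reps = cfg$cv_reps,
      split_ratio = cfg$cv_ratio, seed = derive_seed(cfg$seed, 100 + match(rg, cfg$regions)),
      region = rg
    )
    models[[rg]] <- signatures[[rg]]
  }

  message("[6/7] clinical and combined models")
  master_a <- dplyr::left_join(feat_a,
                               dplyr::bind_cols(tibble::tibble(patient_id = tab$patient_id[is_a]),
                                                tab[is_a, clinical_covariates()]),
                               by = "patient_id")
  master_b <- dplyr::left_join(feat_b,
                               dplyr::bind_cols(tibble::tibble(patient_id = tab$patient_id[!is_a]),
                                                tab[!is_a, clinical_covariates()]),
                               by = "patient_id")
  models$clinical <- build_clinical_model(tab[is_a, ], outcomes_a)

  for (rg in cfg$regions) {
    models[[paste0("clinical+", rg)]] <-
      combine_models(models$clinical, models[[rg]], master_a, outcomes_a)
  }
  if (length(cfg$regions) > 1) {
    comp <- models[[cfg$regions[1]]]
    for (rg in cfg$regions[-1]) {
      comp <- combine_models(comp, models[[rg]], master_a, outcomes_a)
    }
    models$composite_radiomics <- comp
  }

  message("[7/7] validation, comparisons, stratification")
  risks_b <- purrr::map(models, risk_score, data = master_b)
  validation <- purrr::imap(risks_b, function(r, nm) {
    cr <- concordance_index(r, outcomes_b)
    tibble::tibble(model = nm, ci = cr$ci, se = cr$se, p = cr$p,
                   n = nrow(master_b))
  })
  validation <- dplyr::bind_rows(validation)

  pair_names <- utils::combn(names(models), 2, simplify = FALSE)
  comparisons <- purrr::map(pair_names, function(pr) {
    cc <- compare_cindex(risks_b[[pr[1]]], risks_b[[pr[2]]], outcomes_b)
    tibble::tibble(model_a = pr[1], model_b = pr[2], ci_a = cc$ci_a,
                   ci_b = cc$ci_b, delta = cc$delta,
                   p_a_greater = cc$p)
  })
  comparisons <- dplyr::bind_rows(comparisons)

  strat_models <- intersect(
    c("clinical", paste0("clinical+", intersect(c("tumor", "rim"),
                                                cfg$regions))),
    names(models)
  )
  stratification <- purrr::map(
    setNames(strat_models, strat_models),
    function(nm) {
      tryCatch(
        stratify(models[[nm]], master_a, outcomes_a, master_b, outcomes_b),
        error = function(e) structure(list(error = conditionMessage(e)),
                                      class = "stratification_result")
      )
    }
  )

  structure(
    list(config = cfg, cohort = tab, features = features,
         selection = selection,
         univariable = dplyr::bind_rows(univariable),
         signatures = signatures, models = models,
         validation = validation, comparisons = comparisons,
         stratification = stratification),
    class = "periomics_study"
  )
}

#' @export
print.periomics_study <- function(x, ...) {
  cat("<periomics_study>\n")
  cat("Validation concordance (split B):\n")
  print(as.data.frame(x$validation), row.names = FALSE)
  invisible(x)
}

#' Write a study report to disk
#'
#' Writes `report.json` (validation, comparisons, stratification and
#' signature summaries), `univariable.csv`, `validation.csv` and one
#' `km_<model>.csv` step table per stratified model.
#'
#' @param study a `periomics_study`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(study, dir) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("jsonlite is required to write study reports")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(study$univariable, file.path(dir, "univariable.csv"),
            row.names = FALSE)
  write.csv(study$validation, file.path(dir, "validation.csv"),
            row.names = FALSE)
  strat <- purrr::imap(study$stratification, function(s, nm) {
    if (!is.null(s$error)) return(list(error = s$error))
    write.csv(s$km, file.path(dir, paste0("km_", gsub("[^a-z+]", "_", nm),
                                          ".csv")), row.names = FALSE)
    list(cutoff = s$cutoff, n_low = s$n_low, n_high = s$n_high,
         logrank_p = s$logrank_p,
         hazard_ratio_low_vs_high = s$hazard_ratio_low_vs_high)
  })
  report <- list(
    seed = study$config$seed,
    validation = study$validation,
    comparisons = study$comparisons,
    signatures = purrr::map(study$signatures, function(s)
      list(features = s$features, coefficients = as.list(s$cox$coefficients),
           risk_median = s$risk_median)),
    stratification = strat
  )
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
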