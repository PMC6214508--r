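#' Univariable prognostic screen
#'
#' Evaluates every feature column as a univariable risk score with the
#' concordance index, tests each against CI = 0.5 (Noether-type test) and
#' adjusts the p-values by Benjamini-Hochberg. `ci_oriented` folds the index
#' to be >= 0.5 with the direction recorded separately ("Prop." = higher
#' value, higher hazard; "Inv." = inversely proportional).
#'
#' @param features tibble with `patient_id` plus feature columns.
#' @param outcomes outcome tibble matched by row.
#' @param alpha significance level on the adjusted p-values.
#' @return Tibble: feature, ci, ci_oriented, direction, se, p, p_adj,
#'   significant.
#' @export
univariable_screen <- function(features, outcomes, alpha = 0.05) {
  check_outcomes(outcomes)
  feats <- setdiff(names(features), "patient_id")
  rows <- purrr::map(feats, function(f) {
    x <- features[[f]]
    if (anyNA(x) || sd(x) == 0) {
      return(tibble::tibble(feature = f, ci = NA_real_,
                            ci_oriented = NA_real_,
                            direction = NA_character_, se = NA_real_,
                            p = NA_real_))
    }
    cr <- concordance_index(x, outcomes)
    tibble::tibble(feature = f, ci = cr$ci,
                   ci_oriented = max(cr$ci, 1 - cr$ci),
                   direction = if (cr$ci >= 0.5) "Prop." else "Inv.",
                   se = cr$se, p = cr$p)
  })
  out <- dplyr::bind_rows(rows)
  out$p_adj <- bh_adjust(out$p)
  out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  dplyr::arrange(out, .data$p_adj)
}

#' Cross-validated mean concordance of a feature set
#'
#' Repeated random 70:30 subset validation on the training data, stratified
#' so the event fraction is balanced between the fit and evaluation parts:
#' a Cox model is fitted on the 70% part and its concordance measured on
#' the held-out 30%. Splits where the fit or the concordance is degenerate
#' (e.g. no comparable pairs) are redrawn and counted.
#'
#' @param features training feature tibble.
#' @param outcomes training outcome tibble.
#' @param feature_names columns to include in the model.
#' @param n_reps number of random splits (default 1000).
#' @param split_ratio fraction used for fitting (default 0.7).
#' @param seed optional seed.
#' @return List with `mean_ci`, `sd_ci`, `cis`, `n_reps`, `redraws`.
#' @export
cv_mean_ci <- function(features, outcomes,
                       feature_names = setdiff(names(features), "patient_id"),
                       n_reps = 1000, split_ratio = 0.7, seed = NULL) {
  check_outcomes(outcomes)
  if (length(feature_names) == 0) stop("empty feature prefix")
  if (!is.null(seed)) set.seed(seed)
  X <- as.data.frame(features[, feature_names, drop = FALSE])
  ev <- which(outcomes$event == 1)
  ce <- which(outcomes$event == 0)
  if (length(ev) < 2) stop("training data needs at least two events")
  n_fit_ev <- max(1L, round(split_ratio * length(ev)))
  n_fit_ce <- round(split_ratio * length(ce))
  cis <- numeric(n_reps)
  redraws <- 0L
  for (r in seq_len(n_reps)) {
    repeat {
      fit_idx <- c(sample(ev, n_fit_ev), sample(ce, n_fit_ce))
      eval_idx <- setdiff(seq_len(nrow(X)), fit_idx)
      ci <- tryCatch({
        m <- fit_cox(X[fit_idx, , drop = FALSE], outcomes[fit_idx, ])
        concordance_index(risk_score(m, X[eval_idx, , drop = FALSE]),
                          outcomes[eval_idx, ])$ci
      }, error = function(e) NA_real_)
      if (!is.na(ci)) break
      redraws <- redraws + 1L
      if (redraws > 50L * n_reps) stop("too many degenerate CV splits")
    }
    cis[r] <- ci
  }
  list(mean_ci = mean(cis), sd_ci = sd(cis), cis = cis, n_reps = n_reps,
       redraws = redraws)
}

# forward-selection stop rule: grow the prefix while the mean CV CI strictly
# increases; the signature is the prefix before the first non-increase
select_prefix_size <- function(mean_cis) {
  size <- 1L
  for (k in seq_along(mean_cis)[-1]) {
    if (mean_cis[k] > mean_cis[k - 1]) size <- k else break
  }
  size
}

#' Build a radiomic signature by forward cross-validation
#'
#' Features are added to the Cox model in mRMR rank order; each prefix is
#' scored by [cv_mean_ci()] and growth stops at the first prefix whose mean
#' CV concordance does not exceed its predecessor's (ties prefer the
#' smaller prefix). The chosen signature is refitted on the full training
#' data and the training risk-score median is recorded for later
#' stratification.
#'
#' @param ranking an [mrmr_rank()] result or a character vector of feature
#'   names in rank order.
#' @param features training feature tibble.
#' @param outcomes training outcome tibble.
#' @param n_reps,split_ratio cross-validation settings (defaults 1000 and
#'   0.7).
#' @param seed optional base seed (each prefix derives its own stream).
#' @param region optional region label carried in the result.
#' @return A `signature_model`: selected features, fitted `cox_model`,
#'   per-prefix CV table and the training risk median.
#' @export
build_signature <- function(ranking, features, outcomes, n_reps = 1000,
                            split_ratio = 0.7, seed = NULL, region = NULL) {
  feats <- if (inherits(ranking, "mrmr_ranking")) ranking$feature else ranking
  if (length(feats) < 1) stop("empty ranking")
  cv <- vector("list", length(feats))
  mean_cis <- numeric(0)
  for (k in seq_along(feats)) {
    res <- cv_mean_ci(features, outcomes, feats[seq_len(k)], n_reps,
                      split_ratio,
                      seed = if (is.null(seed)) NULL else derive_seed(seed, k))
    cv[[k]] <- tibble::tibble(prefix_size = k, mean_ci = res$mean_ci,
                              sd_ci = res$sd_ci, redraws = res$redraws)
    mean_cis <- c(mean_cis, res$mean_ci)
    if (k > 1 && mean_cis[k] <= mean_cis[k - 1]) break
  }
  size <- select_prefix_size(mean_cis)
  selected <- feats[seq_len(size)]
  cox <- fit_cox(features[, selected, drop = FALSE], outcomes)
  risk <- risk_score(cox, features)
  structure(
    list(region = region, features = selected, cox = cox,
         cv = dplyr::bind_rows(cv), risk_median = median(risk)),
    class = "signature_model"
  )
}

#' @export
print.signature_model <- function(x, ...) {
  cat(sprintf("<signature_model>%s %d feature(s), training risk median %.4f\n",
              if (is.null(x$region)) "" else paste0(" [", x$region, "]"),
              length(x$features), x$risk_median))
  cat(paste0("  ", x$features, collapse = "\n"), "\n")
  invisible(x)
}

#' @export
risk_score.signature_model <- function(model, data) {
  risk_score(model$cox, data)
}

#' Multivariable clinical Cox model
#'
#' Cox fit on the seven clinical covariates (gender, age, overall stage,
#' T stage, N stage, performance status, tumor size), with ordinal stages
#' encoded as integer scores in category order.
#'
#' @param clinical tibble containing the columns of
#'   [clinical_covariates()].
#' @param outcomes outcome tibble.
#' @return A `cox_model`.
#' @export
build_clinical_model <- function(clinical, outcomes) {
  cols <- clinical_covariates()
  miss <- setdiff(cols, names(clinical))
  if (length(miss)) stop("missing clinical covariates: ",
                         paste(miss, collapse = ", "))
  fit_cox(clinical[, cols], outcomes)
}

#' Combine two fitted models through their linear predictors
#'
#' Fits a Cox model whose only covariates are the two models' risk scores
#' on the training data; the combined risk is the resulting linear
#' predictor. Collinear predictors (correlation above 0.999, or a constant
#' predictor) are flagged and the better single model (by training
#' concordance) is used as a fallback.
#'
#' @param model_a,model_b fitted models supporting [risk_score()].
#' @param data training data holding both models' covariates.
#' @param outcomes training outcome tibble.
#' @return A `combined_model`.
#' @export
combine_models <- function(model_a, model_b, data, outcomes) {
  lp_a <- risk_score(model_a, data)
  lp_b <- risk_score(model_b, data)
  collinear <- sd(lp_a) == 0 || sd(lp_b) == 0 ||
    abs(stats::cor(lp_a, lp_b)) > 0.999
  if (collinear) {
    ci_a <- tryCatch(concordance_index(lp_a, outcomes)$ci, error = function(e) 0.5)
    ci_b <- tryCatch(concordance_index(lp_b, outcomes)$ci, error = function(e) 0.5)
    fallback <- if (ci_a >= ci_b) "a" else "b"
    return(structure(list(model_a = model_a, model_b = model_b, cox = NULL,
                          collinear = TRUE, fallback = fallback),
                     class = "combined_model"))
  }
  cox <- fit_cox(data.frame(lp_a = lp_a, lp_b = lp_b), outcomes)
  structure(list(model_a = model_a, model_b = model_b, cox = cox,
                 collinear = FALSE, fallback = NULL),
            class = "combined_model")
}

#' @export
risk_score.combined_model <- function(model, data) {
  lp_a <- risk_score(model$model_a, data)
  lp_b <- risk_score(model$model_b, data)
  if (model$collinear) {
    return(if (model$fallback == "a") lp_a else lp_b)
  }
  risk_score(model$cox, data.frame(lp_a = lp_a, lp_b = lp_b))
}

#' Median-risk patient stratification
#'
#' Splits the validation patients at the median training risk score of the
#' model, then compares the low- and high-risk arms by Kaplan-Meier
#' curves, the log-rank test and the hazard ratio of the low-risk arm
#' relative to the high-risk arm.
#'
#' @param model fitted model supporting [risk_score()] (fitted on training
#'   data only).
#' @param train_data,train_outcomes training covariates and outcomes.
#' @param valid_data,valid_outcomes validation covariates and outcomes.
#' @return A `stratification_result`: cutoff, arm sizes, log-rank
#'   chi-square and p, hazard ratio (low vs high), and the two KM step
#'   tables bound with a `group` column.
#' @export
stratify <- function(model, train_data, train_outcomes, valid_data,
                     valid_outcomes) {
  cutoff <- median(risk_score(model, train_data))
  v_risk <- risk_score(model, valid_data)
  high <- v_risk > cutoff
  if (all(high) || all(!high)) {
    stop("degenerate stratification: all ", nrow(valid_data),
         " validation patients fall on one side of the training median (",
         signif(cutoff, 4), ")")
  }
  lr <- logrank_test(high, valid_outcomes)
  hr <- hazard_ratio(!high, valid_outcomes)
  km <- dplyr::bind_rows(
    dplyr::mutate(km_curve(valid_outcomes[!high, ]), group = "low"),
    dplyr::mutate(km_curve(valid_outcomes[high, ]), group = "high")
  )
  structure(
    list(cutoff = cutoff, n_low = sum(!high), n_high = sum(high),
         groups = ifelse(high, "high", "low"), logrank_chi2 = lr$chi2,
         logrank_p = lr$p, hazard_ratio_low_vs_high = hr, km = km),
    class = "stratification_result"
  )
}

#' @export
print.stratification_result <- function(x, ...) {
  cat(sprintf(
    "<stratification> %d low / %d high; log-rank chi2 %.3f (p = %.3g); HR(low vs high) %.3f\n",
    x$n_low, x$n_high, x$logrank_chi2, x$logrank_p,
    x$hazard_ratio_low_vs_high))
  invisible(x)
}
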