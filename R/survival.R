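#' Outcome table helpers
#'
#' Outcomes are tibbles with `time` (months, > 0) and `event` (0/1, 1 =
#' distant metastasis observed) columns; any other columns are carried as
#' covariates.
#'
#' @param time positive event/censoring times (months).
#' @param event 0/1 event indicators.
#' @param ... further per-patient columns.
#' @return A tibble of survival records.
#' @export
survival_records <- function(time, event, ...) {
  if (any(!is.finite(time)) || any(time <= 0)) {
    stop("`time` must be finite and positive")
  }
  if (!all(event %in% c(0, 1))) stop("`event` must be 0/1")
  tibble::tibble(time = as.numeric(time), event = as.integer(event), ...)
}

check_outcomes <- function(outcomes) {
  if (!all(c("time", "event") %in% names(outcomes))) {
    stop("outcomes need `time` and `event` columns")
  }
  invisible(outcomes)
}

#' Harrell concordance index with Noether-type inference
#'
#' A pair is comparable iff the earlier time is an event (an event tied in
#' time with a censored observation counts as earlier; two events at the
#' same time are not comparable). A comparable pair is concordant when the
#' earlier-event patient has strictly higher risk; tied risks count 0.5.
#' The standard error is the leave-one-subject-out jackknife of the
#' concordance U-statistic, and `p` is the two-sided normal test of
#' CI = 0.5.
#'
#' @param risk numeric risk scores (higher = higher hazard).
#' @param outcomes outcome tibble (see [survival_records()]).
#' @return A `concordance_result`: list with `ci`, `n_comparable`,
#'   `n_concordant`, `n_tied`, `se`, `p` and the per-subject leave-one-out
#'   concordances (`loo`).
#' @export
concordance_index <- function(risk, outcomes) {
  check_outcomes(outcomes)
  if (length(risk) != nrow(outcomes)) stop("length mismatch")
  st <- .concordance_pairs(as.numeric(risk), as.numeric(outcomes$time),
                           as.integer(outcomes$event))
  if (st$n_comparable == 0) stop("no comparable pairs")
  ci <- st$score / st$n_comparable
  loo <- ifelse(st$n_comparable - st$W > 0,
                (st$score - st$S) / (st$n_comparable - st$W), ci)
  n <- length(risk)
  se <- sqrt((n - 1) / n * sum((loo - mean(loo))^2))
  p <- if (se > 0) {
    2 * pnorm(-abs(ci - 0.5) / se)
  } else if (ci == 0.5) 1 else 0
  structure(
    list(ci = ci, n_comparable = st$n_comparable,
         n_concordant = st$n_concordant, n_tied = st$n_tied,
         se = se, p = p, loo = loo),
    class = "concordance_result"
  )
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("Concordance index %.4f (se %.4f), p = %.3g vs CI = 0.5\n",
              x$ci, x$se, x$p))
  cat(sprintf("  %d comparable pairs: %d concordant, %d risk-tied\n",
              as.integer(x$n_comparable), as.integer(x$n_concordant),
              as.integer(x$n_tied)))
  invisible(x)
}

#' Paired one-sided comparison of two concordance indices
#'
#' Tests whether `risk_a` is more concordant than `risk_b` on the same
#' patients, using the difference of the per-patient leave-one-out
#' (jackknife) concordance contributions as the paired statistic. Returns
#' the one-sided p-value for the alternative CI(a) > CI(b); identical risk
#' vectors give p = 0.5.
#'
#' @param risk_a,risk_b risk scores on the same patients.
#' @param outcomes outcome tibble.
#' @return List with `ci_a`, `ci_b`, `delta`, `se`, `p`.
#' @export
compare_cindex <- function(risk_a, risk_b, outcomes) {
  ca <- concordance_index(risk_a, outcomes)
  cb <- concordance_index(risk_b, outcomes)
  d <- ca$loo - cb$loo
  n <- length(d)
  se <- sqrt((n - 1) / n * sum((d - mean(d))^2))
  delta <- ca$ci - cb$ci
  p <- if (se > 0) {
    pnorm(delta / se, lower.tail = FALSE)
  } else if (delta == 0) 0.5 else if (delta > 0) 0 else 1
  list(ci_a = ca$ci, ci_b = cb$ci, delta = delta, se = se, p = p)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (wrapper over
#' `stats::p.adjust(method = "BH")`).
#'
#' @param p_values numeric vector in \[0, 1\].
#' @return Adjusted p-values, monotone and capped at 1.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Cox proportional-hazards fit
#'
#' Multivariable Cox regression with Breslow tie handling (Efron available
#' via `ties`), fitted with `survival::coxph` behind a stable interface.
#' Singular/unconverged fits are flagged rather than raised; singular
#' coefficients are set to 0 in the risk score.
#'
#' @param x data frame or matrix of covariates (no constant columns).
#' @param outcomes outcome tibble.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return A `cox_model`: list with `coefficients`, `loglik` (at the
#'   solution), `converged`, `ties` and the underlying `fit`.
#' @export
fit_cox <- function(x, outcomes, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  check_outcomes(outcomes)
  x <- as.data.frame(x)
  if (nrow(x) != nrow(outcomes)) stop("row mismatch")
  if (sum(outcomes$event) < 1) stop("need at least one event")
  csd <- vapply(x, function(v) sd(as.numeric(v)), numeric(1))
  if (any(csd == 0)) {
    stop("constant covariate(s): ", paste(names(x)[csd == 0], collapse = ", "))
  }
  xm <- as.matrix(x)
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(outcomes$time, outcomes$event) ~ xm,
                    ties = ties),
    warning = function(w) {
      converged <<- FALSE
      invokeRestart("muffleWarning")
    }
  )
  beta <- coef(fit)
  names(beta) <- colnames(xm)
  if (anyNA(beta)) {
    converged <- FALSE
    beta[is.na(beta)] <- 0
  }
  structure(
    list(coefficients = beta, loglik = fit$loglik[2], converged = converged,
         ties = ties, fit = fit),
    class = "cox_model"
  )
}

#' @export
print.cox_model <- function(x, ...) {
  cat("<cox_model>", if (x$converged) "converged" else "NOT converged",
      sprintf("(log partial likelihood %.4f, %s ties)\n", x$loglik, x$ties))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Risk score (linear predictor) of a fitted model
#'
#' @param model a `cox_model`, `signature_model` or `combined_model`.
#' @param data data frame holding the model's covariate columns.
#' @return Numeric linear predictor (higher = higher hazard).
#' @export
risk_score <- function(model, data) UseMethod("risk_score")

#' @export
risk_score.cox_model <- function(model, data) {
  nm <- names(model$coefficients)
  missing <- setdiff(nm, colnames(data))
  if (length(missing)) stop("missing covariates: ",
                            paste(missing, collapse = ", "))
  as.numeric(as.matrix(as.data.frame(data)[, nm, drop = FALSE]) %*%
               model$coefficients)
}

#' Two-group log-rank test
#'
#' @param groups binary group labels (0/1, logical, or 2-level factor).
#' @param outcomes outcome tibble.
#' @return List with `chi2` and `p` (1 df).
#' @export
logrank_test <- function(groups, outcomes) {
  check_outcomes(outcomes)
  g <- as.integer(as.factor(groups))
  if (length(unique(g)) != 2) stop("need exactly two nonempty groups")
  if (sum(outcomes$event) < 1) stop("need at least one event")
  sd_ <- survival::survdiff(
    survival::Surv(outcomes$time, outcomes$event) ~ g)
  chi2 <- sd_$chisq
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Kaplan-Meier survivor curve
#'
#' Product-limit estimate as a right-continuous step table starting at
#' S(0) = 1.
#'
#' @param outcomes outcome tibble.
#' @return Tibble with `time`, `n_risk`, `n_event`, `n_censor`, `survival`.
#' @export
km_curve <- function(outcomes) {
  check_outcomes(outcomes)
  sf <- survival::survfit(survival::Surv(outcomes$time, outcomes$event) ~ 1)
  tibble::tibble(
    time = c(0, sf$time),
    n_risk = c(nrow(outcomes), sf$n.risk),
    n_event = c(0, sf$n.event),
    n_censor = c(0, sf$n.censor),
    survival = c(1, sf$surv)
  )
}

#' Hazard ratio between two groups
#'
#' `exp(coefficient)` from a univariable Cox fit on the group indicator:
#' the hazard in the `groups == 1` (or `TRUE`) arm relative to the other.
#'
#' @inheritParams logrank_test
#' @return Scalar hazard ratio.
#' @export
hazard_ratio <- function(groups, outcomes) {
  check_outcomes(outcomes)
  g <- as.numeric(groups)
  if (length(unique(g)) != 2) stop("need exactly two nonempty groups")
  g <- as.numeric(g == max(g))
  m <- fit_cox(data.frame(group = g), outcomes)
  unname(exp(m$coefficients["group"]))
}
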