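#' Tidy methods for fitted objects
#'
#' `tidy()` returns one row per model term; `glance()` returns a one-row
#' model summary.
#'
#' @param x a fitted object.
#' @param ... unused.
#' @return A tibble.
#' @name periomics-tidiers
NULL

#' @rdname periomics-tidiers
#' @export
tidy.cox_model <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(s[, "se(coef)"]),
    statistic = unname(s[, "z"]),
    p.value = unname(s[, "Pr(>|z|)"]),
    hazard.ratio = exp(unname(x$coefficients))
  )
}

#' @rdname periomics-tidiers
#' @export
glance.cox_model <- function(x, ...) {
  tibble::tibble(
    n = x$fit$n, n_event = x$fit$nevent,
    log_partial_likelihood = x$loglik,
    converged = x$converged, ties = x$ties
  )
}

#' @rdname periomics-tidiers
#' @export
tidy.signature_model <- function(x, ...) {
  dplyr::mutate(tidy(x$cox), region = x$region %||% NA_character_,
                .before = 1)
}

#' @rdname periomics-tidiers
#' @export
glance.signature_model <- function(x, ...) {
  tibble::tibble(
    region = x$region %||% NA_character_,
    n_features = length(x$features),
    peak_cv_mean_ci = max(x$cv$mean_ci),
    risk_median = x$risk_median
  )
}

#' @rdname periomics-tidiers
#' @export
tidy.concordance_result <- function(x, ...) {
  tibble::tibble(
    ci = x$ci, se = x$se, p.value = x$p,
    n_comparable = x$n_comparable, n_concordant = x$n_concordant,
    n_tied = x$n_tied
  )
}

#' @rdname periomics-tidiers
#' @export
tidy.mrmr_ranking <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}
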