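#' Intraclass correlation coefficient for test-retest agreement
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC(2,1)
#' computed from the ANOVA decomposition of the subjects x 2 table. The
#' consistency form ICC(3,1) is available via `type`.
#'
#' @param test,retest paired numeric vectors (one value per subject).
#' @param type `"icc2_1"` (absolute agreement, default) or `"icc3_1"`
#'   (consistency).
#' @return A scalar ICC in (-Inf, 1] with attribute `degenerate` set to
#'   `TRUE` when there is no between-subject variance (value then <= 0).
#' @export
icc <- function(test, retest, type = c("icc2_1", "icc3_1")) {
  type <- match.arg(type)
  if (length(test) != length(retest)) stop("unpaired inputs")
  n <- length(test)
  if (n < 3) stop("need >= 3 subjects")
  x <- cbind(test, retest)
  k <- 2
  grand <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  resid <- x - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + grand
  mse <- sum(resid^2) / ((n - 1) * (k - 1))
  degenerate <- msr <= .Machine$double.eps * max(1, mse, msc)
  denom <- if (type == "icc2_1") {
    msr + (k - 1) * mse + k * (msc - mse) / n
  } else {
    msr + (k - 1) * mse
  }
  val <- if (denom == 0) 1 else (msr - mse) / denom
  structure(val, degenerate = degenerate)
}

#' Filter features by test-retest stability
#'
#' Computes the ICC of every shared feature column between matched test and
#' retest feature tables and keeps the features with `icc > threshold`.
#' Features with missing values or degenerate (no between-subject variance)
#' ICCs are never kept.
#'
#' @param test,retest tibbles with a `patient_id` column and one column per
#'   feature; rows are matched by `patient_id`.
#' @param threshold stability cutoff (default 0.85).
#' @param type ICC form, see [icc()].
#' @return List with `kept` (character vector of stable feature names) and
#'   `report` (tibble: feature, icc, n_subjects, stable, degenerate).
#' @export
stability_filter <- function(test, retest, threshold = 0.85,
                             type = "icc2_1") {
  if (!"patient_id" %in% names(test) || !"patient_id" %in% names(retest)) {
    stop("both tables need a `patient_id` column")
  }
  ids <- intersect(test$patient_id, retest$patient_id)
  if (length(ids) < 3) stop("need >= 3 matched subjects")
  test <- test[match(ids, test$patient_id), , drop = FALSE]
  retest <- retest[match(ids, retest$patient_id), , drop = FALSE]
  feats <- setdiff(intersect(names(test), names(retest)), "patient_id")
  rows <- purrr::map(feats, function(f) {
    a <- test[[f]]
    b <- retest[[f]]
    if (anyNA(a) || anyNA(b)) {
      return(tibble::tibble(feature = f, icc = NA_real_,
                            n_subjects = length(ids), stable = FALSE,
                            degenerate = TRUE))
    }
    v <- icc(a, b, type = type)
    tibble::tibble(feature = f, icc = as.numeric(v),
                   n_subjects = length(ids),
                   stable = !attr(v, "degenerate") & as.numeric(v) > threshold,
                   degenerate = attr(v, "degenerate"))
  })
  report <- dplyr::bind_rows(rows)
  kept <- report$feature[report$stable]
  if (length(kept) == 0) {
    stop("no feature passed the stability filter; review the ICC threshold (",
         threshold, ") or the retest acquisition")
  }
  list(kept = kept, report = report)
}

#' Plug-in mutual information
#'
#' Mutual information in bits between two discrete vectors, estimated from
#' the joint contingency table.
#'
#' @param x discrete (integer/factor/character) vector.
#' @param y discrete vector of the same length (typically binary labels).
#' @return MI in bits (0 for a constant `x`).
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  tab <- table(x, y)
  p <- tab / sum(tab)
  px <- rowSums(p)
  py <- colSums(p)
  e <- outer(px, py)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / e[nz]))
}

# equal-frequency quartile discretization for continuous features
discretize_quartiles <- function(x, bins = 4) {
  br <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1),
                        na.rm = TRUE))
  if (length(br) < 2) return(rep(1L, length(x)))
  as.integer(cut(x, breaks = br, include.lowest = TRUE))
}

#' Minimum-redundancy maximum-relevance feature ranking
#'
#' Greedy mRMR with the difference (MID) criterion: the first feature
#' maximizes MI with the labels; each subsequent step maximizes
#' `MI(f; y) - mean over selected s of MI(f; s)`. Continuous features are
#' discretized by equal-frequency quartiles for MI estimation. Exact score
#' ties break lexicographically on the feature name, making the ranking
#' deterministic.
#'
#' @param features tibble of candidate feature columns (an optional
#'   `patient_id` column is ignored).
#' @param labels binary vector (e.g. event status), one per row.
#' @param k number of features to rank (default 15).
#' @param criterion `"mid"` (difference, default) or `"miq"` (quotient).
#' @param bins number of equal-frequency bins for MI estimation.
#' @return An `mrmr_ranking` tibble: rank, feature, relevance, redundancy,
#'   score.
#' @export
mrmr_rank <- function(features, labels, k = 15, criterion = c("mid", "miq"),
                      bins = 4) {
  criterion <- match.arg(criterion)
  features <- features[, setdiff(names(features), "patient_id"), drop = FALSE]
  if (length(unique(labels)) < 2) stop("labels must take >= 2 values")
  if (nrow(features) != length(labels)) stop("row/label mismatch")
  cand <- sort(names(features))
  if (k > length(cand)) {
    stop("k = ", k, " exceeds the ", length(cand), " candidate features")
  }
  disc <- lapply(features[cand], discretize_quartiles, bins = bins)
  rel <- vapply(disc, mutual_information, numeric(1), y = labels)

  selected <- character(0)
  out <- vector("list", k)
  red_cache <- matrix(NA_real_, nrow = length(cand), ncol = k,
                      dimnames = list(cand, NULL))
  for (step in seq_len(k)) {
    avail <- setdiff(cand, selected)
    if (step == 1) {
      red <- setNames(rep(0, length(avail)), avail)
    } else {
      last <- selected[step - 1]
      red_cache[avail, step - 1] <- vapply(
        avail, function(f) mutual_information(disc[[f]], disc[[last]]),
        numeric(1))
      red <- rowMeans(red_cache[avail, seq_len(step - 1), drop = FALSE])
    }
    score <- if (criterion == "mid") {
      rel[avail] - red
    } else {
      rel[avail] / (red + .Machine$double.eps)
    }
    best <- avail[which.max(score)]  # avail is sorted: first max wins ties
    selected <- c(selected, best)
    out[[step]] <- tibble::tibble(rank = step, feature = best,
                                  relevance = unname(rel[best]),
                                  redundancy = unname(red[best]),
                                  score = unname(score[best]))
  }
  structure(dplyr::bind_rows(out), class = c("mrmr_ranking",
                                             class(dplyr::bind_rows(out))))
}
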