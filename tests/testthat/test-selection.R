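test_that("ICC handles perfect, degenerate and noisy agreement", {
  x <- c(1.2, 3.4, 2.2, 5.1, 0.3)
  expect_equal(as.numeric(icc(x, x)), 1)
  v <- icc(c(0, 0, 0), c(1, 1, 1))
  expect_true(attr(v, "degenerate"))
  expect_lte(as.numeric(v), 0)
  # variance components 4 (subject) : 1 (noise) -> ICC(2,1) = 0.8
  set.seed(21)
  subj <- rnorm(500, sd = 2)
  v2 <- icc(subj + rnorm(500), subj + rnorm(500))
  expect_lt(abs(as.numeric(v2) - 0.8), 0.05)
})

test_that("ICC is invariant to a common affine rescaling", {
  set.seed(22)
  a <- rnorm(50); b <- a + rnorm(50, sd = 0.5)
  expect_equal(as.numeric(icc(3 * a + 7, 3 * b + 7)),
               as.numeric(icc(a, b)), tolerance = 1e-12)
})

test_that("stability filter keeps clean features and drops noisy ones", {
  set.seed(23)
  n <- 40
  base <- tibble::tibble(patient_id = sprintf("P%02d", 1:n),
                         clean = rnorm(n), noisy = rnorm(n))
  test <- base
  retest <- base
  retest$noisy <- rnorm(n)  # retest of the noisy feature is uncorrelated
  res <- stability_filter(test, retest, threshold = 0.85)
  expect_true("clean" %in% res$kept)
  expect_false("noisy" %in% res$kept)
  expect_equal(res$report$icc[res$report$feature == "clean"], 1)
  # all-noise table -> explicit error
  allnoise <- base
  allnoise$clean <- rnorm(n)
  allnoise$noisy <- rnorm(n)
  expect_error(stability_filter(test, allnoise, threshold = 0.85),
               "threshold")
})

test_that("mutual information matches direct formula evaluation", {
  y <- rep(c(0, 1), each = 4)
  expect_equal(mutual_information(y, y), 1)
  expect_equal(mutual_information(rep(1, 8), y), 0)
  # joint counts [[2,1],[1,2]]
  x <- c(1, 1, 2, 1, 2, 2)
  y2 <- c(0, 0, 0, 1, 1, 1)
  p <- matrix(c(2, 1, 1, 2), 2) / 6
  expected <- sum(p * log2(p / (rowSums(p) %o% colSums(p))))
  expect_equal(mutual_information(x, y2), expected, tolerance = 1e-12)
})

test_that("mRMR ranking equals an exhaustive greedy oracle", {
  set.seed(24)
  n <- 80
  labels <- rep(c(0, 1), each = n / 2)
  feats <- tibble::as_tibble(setNames(
    lapply(1:8, function(i) rnorm(n) + labels * runif(1, 0, 1.5)),
    paste0("f", 1:8)))
  rk <- mrmr_rank(feats, labels, k = 3)

  # oracle: recompute the greedy MID selection from scratch
  disc <- lapply(feats, function(x) {
    br <- unique(quantile(x, seq(0, 1, 0.25)))
    as.integer(cut(x, br, include.lowest = TRUE))
  })
  mi <- function(a, b) {
    tab <- table(a, b); p <- tab / sum(tab)
    px <- rowSums(p); py <- colSums(p)
    sum(ifelse(p > 0, p * log2(p / (px %o% py)), 0))
  }
  rel <- vapply(disc, mi, numeric(1), b = labels)
  sel <- character(0)
  for (step in 1:3) {
    avail <- sort(setdiff(names(disc), sel))
    score <- vapply(avail, function(f) {
      red <- if (length(sel)) mean(vapply(sel, function(s)
        mi(disc[[f]], disc[[s]]), numeric(1))) else 0
      rel[f] - red
    }, numeric(1))
    sel <- c(sel, avail[which.max(score)])
  }
  expect_identical(rk$feature, sel)
  expect_equal(rk$relevance[1], max(rel))
})

test_that("mRMR demotes duplicated copies of an informative feature", {
  set.seed(25)
  n <- 120
  labels <- rep(c(0, 1), each = n / 2)
  strong <- rnorm(n) + 2 * labels
  weak <- rnorm(n) + 0.8 * labels
  feats <- tibble::tibble(a_strong = strong, b_copy1 = strong,
                          c_copy2 = strong, d_weak = weak)
  rk <- mrmr_rank(feats, labels, k = 2)
  expect_equal(rk$feature[1], "a_strong")
  expect_equal(rk$feature[2], "d_weak")  # redundancy beats raw relevance
  expect_error(mrmr_rank(feats, labels, k = 10), "exceeds")
})
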