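line_volume <- function(levels) {
  array(as.integer(levels), dim = c(length(levels), 1, 1))
}

test_that("first-order statistics match their definitions", {
  fo <- first_order(c(1, 1, 5, 5))
  expect_equal(fo$kurtosis, 1)  # symmetric two-point law: m4 = m2^2
  fo2 <- first_order(c(0, 10))
  expect_equal(fo2$median, 5)
  expect_equal(fo2$minimum, 0)
  expect_equal(fo2$range, 10)
  expect_equal(fo2$energy, 100)
  set.seed(4)
  fo3 <- first_order(rnorm(1e4))
  expect_lt(abs(fo3$kurtosis - 3), 0.2)
  expect_true(is.na(first_order(rep(3, 5))$kurtosis))
  # entropy of a two-bin half/half histogram is one bit
  expect_equal(first_order(c(10, 10, 40, 40), bin_width = 25)$entropy, 1)
})

test_that("texture features reproduce hand-enumerated 1D cases", {
  expect_equal(glcm_features(line_volume(c(1, 1, 2)))$difference_entropy, 1)
  expect_equal(glcm_features(line_volume(c(3, 3, 3)))$difference_entropy, 0)
  # single-offset hand enumeration along the line direction
  expect_equal(glrlm_features(line_volume(c(5, 5, 5) - 4L),
                              directions = 1)$run_entropy, 0)
  expect_equal(glrlm_features(line_volume(c(1, 1, 2)),
                              directions = 1)$run_entropy, 1)
  nt <- ngtdm_features(line_volume(c(1, 2, 1)))
  # n = (2,1), p = (2/3,1/3), s = (2,1)
  o <- oracle_ngtdm(line_volume(c(1, 2, 1)))
  expect_equal(nt$complexity, o$complexity)
  expect_equal(nt$strength, o$strength)
  ct <- ngtdm_features(line_volume(c(2, 2, 2) - 1L))
  expect_equal(ct$complexity, 0)
  expect_equal(ct$strength, 0)
})

test_that("texture features equal brute-force enumeration on random volumes", {
  set.seed(11)
  for (i in 1:6) {
    g <- random_gray_volume(d = c(5, 4, 4), ng = 4)
    expect_equal(glcm_features(g)$difference_entropy, oracle_glcm_de(g),
                 tolerance = 1e-12)
    expect_equal(glrlm_features(g)$run_entropy, oracle_glrlm_re(g),
                 tolerance = 1e-12)
    nt <- ngtdm_features(g)
    o <- oracle_ngtdm(g)
    expect_equal(nt$complexity, o$complexity, tolerance = 1e-12)
    expect_equal(nt$strength, o$strength, tolerance = 1e-12)
  }
})

test_that("texture matrices satisfy their accounting invariants", {
  set.seed(12)
  g <- random_gray_volume(d = c(6, 5, 4), ng = 5)
  ng <- max(g)
  cc <- periomics:::.glcm_counts(as.integer(g), dim(g), ng)
  expect_true(isSymmetric(cc$counts))
  expect_equal(sum(cc$counts / sum(cc$counts)), 1)
  rl <- periomics:::.glrlm_counts(as.integer(g), dim(g), ng, 1:13)
  # per 13-direction set, total weighted run length = 13 * in-region voxels
  expect_equal(sum(rl %*% seq_len(ncol(rl))), 13 * sum(g > 0))
  st <- periomics:::.ngtdm_stats(as.integer(g), dim(g), ng)
  expect_equal(sum(st$n / sum(st$n)), 1)
})

test_that("texture features are invariant to gray shifts and axis permutation", {
  set.seed(13)
  d <- c(6, 6, 6)
  vals <- array(rnorm(prod(d), sd = 60), dim = d)
  mask <- array(runif(prod(d)) < 0.8, dim = d)
  img1 <- image_volume(vals, c(1, 1, 1))
  img2 <- image_volume(vals + 4 * 25, c(1, 1, 1))
  f1 <- extract_features(img1, mask, list(filter_spec("original")))
  f2 <- extract_features(img2, mask, list(filter_spec("original")))
  tex <- grep("glcm|glrlm|ngtdm", names(f1), value = TRUE)
  expect_equal(as.numeric(f1[tex]), as.numeric(f2[tex]), tolerance = 1e-10)

  perm <- aperm(vals, c(3, 1, 2))
  pmask <- aperm(mask, c(3, 1, 2))
  f3 <- extract_features(image_volume(perm, c(1, 1, 1)), pmask,
                         list(filter_spec("original")))
  expect_equal(as.numeric(f1[tex]), as.numeric(f3[tex]), tolerance = 1e-10)
})

test_that("extraction is deterministic with a fixed schema and flags degenerate masks", {
  set.seed(14)
  img <- image_volume(array(rnorm(8^3, sd = 100), c(8, 8, 8)), c(3, 3, 3))
  mask <- array(FALSE, c(8, 8, 8)); mask[3:6, 3:6, 3:6] <- TRUE
  filters <- list(filter_spec("original"), filter_spec("log", sigma_mm = 3),
                  filter_spec("wavelet", subband = "LHL"))
  f1 <- extract_features(img, mask, filters)
  f2 <- extract_features(img, mask, filters)
  expect_identical(f1, f2)
  expect_equal(ncol(f1), length(filters) * 15)  # 8 first-order + 7 texture
  single <- array(FALSE, c(8, 8, 8)); single[4, 4, 4] <- TRUE
  fd <- extract_features(img, single, filters)
  expect_true(all(is.na(as.numeric(fd))))
})
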