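test_that("discretization follows the edge-anchored floor rule", {
  expect_identical(discretize(c(0, 24, 25, 50), 25), c(1L, 1L, 2L, 3L))
  expect_identical(discretize(rep(7.3, 5), 25), rep(1L, 5))
  # translation by an exact bin multiple leaves the levels unchanged
  set.seed(1)
  v <- rnorm(100, sd = 200)
  expect_identical(discretize(v, 25), discretize(v + 4 * 25, 25))
  expect_identical(discretize(v, 25), discretize(v - 11 * 25, 25))
  expect_error(discretize(numeric(0), 25), "empty")
  expect_error(discretize(1:3, 0), "positive")
})

test_that("resampling is the identity on an already-isotropic grid", {
  set.seed(2)
  img <- image_volume(array(rnorm(6 * 6 * 6), c(6, 6, 6)), c(3, 3, 3))
  m <- array(TRUE, c(6, 6, 6))
  rs <- resample_isotropic(img, m, target_mm = 3)
  expect_equal(dim(rs$image), c(6L, 6L, 6L))
  expect_equal(as_vec <- as.numeric(rs$image), as.numeric(img),
               tolerance = 1e-12)
})

test_that("resampling a constant image stays constant and preserves masks", {
  img <- image_volume(array(42, c(10, 10, 8)), c(1, 1, 2.5))
  m <- array(FALSE, c(10, 10, 8)); m[3:8, 3:8, 2:6] <- TRUE
  rs <- resample_isotropic(img, list(roi = m), target_mm = 3)
  expect_true(all(abs(as.numeric(rs$image) - 42) < 1e-12))
  # mask volume preserved within one voxel shell
  vol_in <- sum(m) * 1 * 1 * 2.5
  vol_out <- sum(rs$masks$roi) * 27
  surface <- sum(periomics:::surface_voxels(rs$masks$roi))
  expect_lt(abs(vol_out - vol_in), (surface + 1) * 27)
  # a mask too thin for the grid errors
  thin <- array(FALSE, c(10, 10, 8)); thin[1, 1, 1] <- TRUE
  expect_error(resample_isotropic(img, thin, target_mm = 9), "empty")
})

test_that("LoG responds zero to constants and is antisymmetric", {
  img <- image_volume(array(100, c(8, 8, 8)), c(2, 2, 2))
  expect_lt(max(abs(log_filter(img, 2))), 1e-10)
  set.seed(3)
  a <- array(rnorm(8^3), c(8, 8, 8))
  f1 <- log_filter(image_volume(a, c(2, 2, 2)), 2)
  f2 <- log_filter(image_volume(-a, c(2, 2, 2)), 2)
  expect_equal(as.numeric(f1), -as.numeric(f2), tolerance = 1e-12)
  expect_warning(log_filter(image_volume(a, c(2, 2, 2)), 0.5),
                 "under-resolved")
})

test_that("LoG magnitude peaks near the blob scale", {
  d <- c(21, 21, 21)
  ctr <- 11
  blob_sigma <- 2
  g <- expand.grid(x = 1:21, y = 1:21, z = 1:21)
  a <- array(exp(-((g$x - ctr)^2 + (g$y - ctr)^2 + (g$z - ctr)^2) /
                   (2 * blob_sigma^2)), dim = d)
  img <- image_volume(a, c(1, 1, 1))
  sweep_sigmas <- c(0.75, 1.5, 2, 3, 4.5)
  resp <- vapply(sweep_sigmas, function(s)
    abs(as.numeric(log_filter(img, s))[ctr + 21 * (ctr - 1) +
                                         441 * (ctr - 1)]),
    numeric(1))
  # analytic optimum for a Gaussian blob is sigma = sqrt(2/3) * blob scale
  expect_true(sweep_sigmas[which.max(resp)] %in% c(1.5, 2))
  expect_gt(max(resp), resp[1])
  expect_gt(max(resp), resp[length(resp)])
})

test_that("wavelet decomposition has 8 sub-bands and kills constants", {
  img <- image_volume(array(7, c(6, 6, 6)), c(3, 3, 3))
  wb <- wavelet_subbands(img)
  expect_setequal(names(wb),
                  c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH"))
  for (nm in names(wb)) {
    if (grepl("H", nm)) {
      expect_lt(max(abs(wb[[nm]])), 1e-10)
    } else {
      expect_equal(as.numeric(wb[[nm]])[1], 7 * sqrt(2)^3, tolerance = 1e-6)
    }
  }
})

test_that("impulse responses factor into the 1D analysis taps", {
  d <- c(9, 9, 9)
  a <- array(0, d); a[5, 5, 5] <- 1
  img <- image_volume(a, c(1, 1, 1))
  wb <- wavelet_subbands(img)
  taps <- periomics:::coif1_taps()
  # direct correlation oracle: out[i] = sum_t k[t] x[i + t - c]
  resp1d <- function(k) {
    cshift <- (length(k) - 1) %/% 2
    vapply(1:9, function(i) {
      s <- 0
      for (t in seq_along(k)) {
        j <- i + (t - 1) - cshift
        if (j >= 1 && j <= 9) s <- s + k[t] * (j == 5)
      }
      s
    }, numeric(1))
  }
  for (code in c("HLL", "LHH")) {
    ltr <- strsplit(code, "")[[1]]
    kx <- resp1d(if (ltr[1] == "L") taps$lo else taps$hi)
    ky <- resp1d(if (ltr[2] == "L") taps$lo else taps$hi)
    kz <- resp1d(if (ltr[3] == "L") taps$lo else taps$hi)
    expected <- outer(outer(kx, ky), kz)
    expect_equal(as.numeric(wb[[code]]), as.numeric(expected),
                 tolerance = 1e-12)
  }
})
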