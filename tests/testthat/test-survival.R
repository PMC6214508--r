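test_that("concordance handles perfect ranking, censoring and ties", {
  oc <- survival_records(c(1, 2, 3), c(1, 1, 1))
  expect_equal(concordance_index(c(3, 2, 1), oc)$ci, 1)
  expect_equal(concordance_index(c(1, 2, 3), oc)$ci, 0)
  # censored middle observation: comparable pairs are (1,2) and (1,3)
  oc2 <- survival_records(c(1, 2, 3), c(1, 0, 1))
  cr <- concordance_index(c(3, 1, 2), oc2)
  expect_equal(cr$n_comparable, 2)  # (1,2) and (1,3); pair (2,3) has the
  expect_equal(cr$ci, 1)            # censored observation earlier

  expect_error(concordance_index(c(1, 2), survival_records(c(1, 2), c(0, 0))),
               "comparable")
})

test_that("concordance equals the exhaustive pair oracle and survival::concordance", {
  set.seed(31)
  for (i in 1:25) {
    dat <- random_censored_data(n = sample(10:60, 1))
    oc <- survival_records(dat$time, dat$event)
    ci <- concordance_index(dat$risk, oc)$ci
    expect_equal(ci, oracle_ci(dat$risk, dat$time, dat$event))
  }
  # independent implementation cross-check (no tied risks/times edge cases)
  set.seed(32)
  tm <- rexp(80); ev <- rbinom(80, 1, 0.6); rk <- rnorm(80)
  expect_equal(
    concordance_index(rk, survival_records(tm, ev))$ci,
    unname(survival::concordance(survival::Surv(tm, ev) ~ rk,
                                 reverse = TRUE)$concordance))
})

test_that("concordance is invariant under strictly increasing risk transforms", {
  set.seed(33)
  dat <- random_censored_data(50, tie_prob = 0)
  oc <- survival_records(dat$time, dat$event)
  c1 <- concordance_index(dat$risk, oc)
  c2 <- concordance_index(exp(2 * dat$risk) + 5, oc)
  expect_equal(c1$ci, c2$ci)
  expect_equal(c1$se, c2$se)
})

test_that("cindex comparison is symmetric and detects real differences", {
  set.seed(34)
  tm <- rexp(100, 0.1); ev <- rbinom(100, 1, 0.7)
  oc <- survival_records(tm, ev)
  r <- rnorm(100)
  expect_equal(compare_cindex(r, r, oc)$p, 0.5)
  a <- -tm + rnorm(100, sd = 0.01)  # near-perfect ranking
  b <- rnorm(100)
  p_ab <- compare_cindex(a, b, oc)$p
  expect_lt(p_ab, 0.05)
  expect_equal(compare_cindex(b, a, oc)$p, 1 - p_ab, tolerance = 1e-12)
})

test_that("BH adjustment reproduces the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5))
  expect_equal(bh_adjust(0.031), 0.031)
  expect_equal(bh_adjust(rep(0.2, 4)), rep(0.2, 4))
  set.seed(35)
  p <- runif(30)
  adj <- bh_adjust(p)
  # independent step-up oracle
  o <- order(p)
  stepped <- rev(cummin(rev(p[o] * 30 / seq_len(30))))
  oracle <- pmin(1, stepped)[order(o)]
  expect_equal(adj, oracle)
  expect_true(all(adj >= p - 1e-12) && all(adj <= 1))
})

test_that("Cox fitting recovers parameters and maximizes the partial likelihood", {
  set.seed(36)
  n <- 500
  x <- rnorm(n)
  tm <- rexp(n, rate = 0.1 * exp(0.7 * x))
  cens <- rexp(n, rate = 0.1 * exp(0.7 * x) / 3)  # ~25% censoring
  oc <- survival_records(pmin(tm, cens), as.integer(tm <= cens))
  m <- fit_cox(data.frame(x = x), oc)
  expect_true(m$converged)
  expect_lt(abs(m$coefficients[["x"]] - 0.7), 0.1)

  # grid-search oracle on the directly evaluated Breslow partial likelihood
  set.seed(37)
  ns <- 60
  xs <- rnorm(ns)
  tms <- rexp(ns, rate = 0.1 * exp(0.5 * xs))
  evs <- rbinom(ns, 1, 0.8)
  ocs <- survival_records(tms, evs)
  pl <- function(beta) {
    lp <- beta * xs
    sum(vapply(which(evs == 1), function(i) {
      lp[i] - log(sum(exp(lp[tms >= tms[i]])))
    }, numeric(1)))
  }
  grid <- seq(-2, 2, by = 1e-4)
  beta_grid <- grid[which.max(vapply(grid, pl, numeric(1)))]
  ms <- fit_cox(data.frame(x = xs), ocs)
  expect_lt(abs(ms$coefficients[["x"]] - beta_grid), 1e-4 + 1e-4)

  expect_error(fit_cox(data.frame(x = rep(1, 10)),
                       survival_records(1:10, rep(1, 10))), "constant")
})

test_that("Cox fit on symmetric paired groups gives a null coefficient", {
  tm <- rep(c(1, 2, 3, 4, 6, 9), 2)
  ev <- rep(c(1, 1, 0, 1, 1, 0), 2)
  g <- rep(c(0, 1), each = 6)
  m <- fit_cox(data.frame(g = g), survival_records(tm, ev))
  expect_lt(abs(m$coefficients[["g"]]), 1e-8)
})

test_that("log-rank, KM and hazard ratio behave on identical and separated groups", {
  tm <- rep(c(2, 4, 7, 11, 15), 2)
  ev <- rep(c(1, 0, 1, 1, 0), 2)
  oc <- survival_records(tm, ev)
  g <- rep(c(0, 1), each = 5)
  lr <- logrank_test(g, oc)
  expect_lt(lr$chi2, 1e-10)
  expect_equal(lr$p, 1, tolerance = 1e-6)
  expect_equal(hazard_ratio(g, oc), 1, tolerance = 1e-6)

  set.seed(38)
  t1 <- rexp(100, 0.05); t2 <- rexp(100, 0.15)
  oc2 <- survival_records(c(t1, t2), rep(1, 200))
  g2 <- rep(0:1, each = 100)
  expect_lt(logrank_test(g2, oc2)$p, 0.001)
  hr <- hazard_ratio(g2, oc2)
  expect_gt(hr, 2)
  expect_equal(hazard_ratio(1 - g2, oc2), 1 / hr, tolerance = 1e-8)

  km <- km_curve(survival_records(c(1, 2, 3), c(1, 1, 1)))
  expect_equal(km$survival, c(1, 2 / 3, 1 / 3, 0))
  km2 <- km_curve(survival_records(c(1, 2, 3), c(0, 0, 0)))
  expect_true(all(km2$survival == 1))
})

test_that("KM matches the closed-form exponential survivor curve", {
  set.seed(39)
  spec <- phantom_spec(n_patients = 10, beta_latent = 0, seed = 5,
                       beta_clinical = numeric(0))
  oc <- simulate_outcomes(rep(0, 1000), tibble::tibble(), spec)
  km <- km_curve(oc)
  mid <- km$time > 1 & km$time < 30
  expect_lt(max(abs(km$survival[mid] - exp(-0.05 * km$time[mid]))), 0.06)
})
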