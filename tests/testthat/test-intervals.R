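crit95 <- qchisq(0.95, 1)

test_that("interval endpoints satisfy the likelihood-ratio equation", {
  y <- c(0, 0, 1, 3)
  iv <- ci_m(y)
  fit <- fit_m(y)
  expect_lte(iv$lower, fit$estimate)
  expect_gte(iv$upper, fit$estimate)
  for (endpoint in c(iv$lower, iv$upper)) {
    resid <- 2 * (fit$loglik - loglik(fa_model("LD", m = endpoint), y)) -
      crit95
    expect_lt(abs(resid), 1e-6)
  }
  # brute-force scan oracle at step 1e-5
  grid <- seq(1e-5, 3, by = 1e-5)
  ok <- 2 * (fit$loglik - vapply(grid, function(m)
    loglik(fa_model("LD", m = m), y), numeric(1))) <= crit95
  expect_lt(abs(iv$lower - min(grid[ok])), 1.5e-5)   # scan step is 1e-5
  expect_lt(abs(iv$upper - max(grid[ok])), 1.5e-5)
})

test_that("intervals are nested across confidence levels", {
  y <- c(0, 2, 0, 5, 1, 0, 0, 3)
  iv90 <- ci_m(y, level = 0.90)
  iv95 <- ci_m(y, level = 0.95)
  iv99 <- ci_m(y, level = 0.99)
  expect_lt(iv99$lower, iv95$lower)
  expect_lt(iv95$lower, iv90$lower)
  expect_gt(iv99$upper, iv95$upper)
  expect_gt(iv95$upper, iv90$upper)
})

test_that("published experiments reproduce the printed rate intervals", {
  # measured fitness w1 = 1.47, w2 = 1.45; default 95% level reproduces the
  # printed endpoints (the published calls pass no level argument)
  fx <- fluctuation_fixtures()
  iv1 <- rate_interval(ci_m(fx$krasovec_expt1), Nt = 2.27e8)
  expect_equal(iv1$lower, 1.798407e-9, tolerance = 1e-6)
  expect_equal(iv1$upper, 5.244954e-9, tolerance = 1e-6)
  iv2 <- rate_interval(ci_m(fx$krasovec_expt2), Nt = 5.15e8)
  expect_equal(iv2$lower, 2.155918e-9, tolerance = 1e-6)
  expect_equal(iv2$upper, 6.105526e-9, tolerance = 1e-6)
})

test_that("all-zero data give a one-sided interval from zero", {
  y <- rep(0L, 5)
  iv <- ci_m(y)
  expect_identical(iv$lower, 0)
  # l(m) = -n m, so the upper limit solves 2 n m = crit
  expect_equal(iv$upper, crit95 / (2 * 5), tolerance = 1e-6)
})

test_that("profiling the nuisance widens the interval and covers the truth", {
  y <- as.vector(simulate_counts(fa_model("LD", m = 2), cultures = 400,
                                 seed = 5))
  joint <- fit_mw(y)
  prof <- ci_profile(y, "m")
  fixed <- ci_m(y, family = "MK", w = joint$estimate[["w"]])
  expect_lte(prof$lower, fixed$lower + 1e-6)
  expect_gte(prof$upper, fixed$upper - 1e-6)
  # the profile interval for w covers the simulating value 1
  ivw <- ci_profile(y, "w")
  expect_lt(ivw$lower, 1)
  expect_gt(ivw$upper, 1)
})

test_that("rate conversion rescales endpoints by the divisions", {
  iv <- structure(list(lower = 1, upper = 2, level = 0.95, parameter = "m",
                       method = "likelihood-ratio", estimate = 1.5),
                  class = "fa_interval")
  r <- rate_interval(iv, Nt = 1e8)
  expect_equal(c(r$lower, r$upper), c(1e-8, 2e-8))
  expect_identical(r$parameter, "rate")
  expect_equal(rate_interval(iv, Nt = 1)$upper, 2)
  expect_error(rate_interval(iv, Nt = NA), "Nt")
  expect_error(rate_interval(iv, Nt = 10, N0 = 10), "N0")
})

test_that("the iteration trace is streamed on request", {
  expect_message(ci_m(c(0, 1, 2), show_iter = TRUE), "bisect")
})
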