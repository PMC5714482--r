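test_that("log-likelihood has closed-form values and is additive", {
  expect_equal(loglik(fa_model("LD", m = 3), c(0)), -3)
  expect_equal(loglik(fa_model("LD", m = 1), c(0, 1)), -2 + log(1 / 2))
  model <- fa_model("MK", m = 2, w = 0.9)
  y <- as.vector(simulate_counts(model, cultures = 40, seed = 11))
  expect_equal(loglik(model, y),
               sum(vapply(y, function(yi) loglik(model, yi), numeric(1))))
})

test_that("all-zero data give a boundary estimate of zero", {
  for (fit in list(fit_m(rep(0L, 5)),
                   fit_m(rep(0L, 5), family = "MK", w = 0.8),
                   fit_m(rep(0L, 5), family = "PLATING", epsilon = 0.4),
                   fit_m(rep(0L, 5), family = "B0", cv = 0.2))) {
    expect_identical(fit$estimate, 0)
    expect_true(fit$boundary)
    expect_true(fit$converged)
    expect_lt(fit$score, 0)     # likelihood decreasing in m at the boundary
  }
})

test_that("Newton estimate equals the independent grid/golden-section argmax", {
  # the worked small dataset, against a coarse grid refined by optimize()
  y <- c(0, 0, 1, 3)
  grid <- seq(0.001, 3, by = 0.001)
  ll <- vapply(grid, function(m) loglik(fa_model("LD", m = m), y), numeric(1))
  i <- which.max(ll)
  refined <- optimize(function(m) loglik(fa_model("LD", m = m), y),
                      interval = grid[c(i - 1, i + 1)], maximum = TRUE,
                      tol = 1e-9)$maximum
  fit <- fit_m(y)
  expect_equal(fit$estimate, refined, tolerance = 1e-6)
  expect_lt(abs(fit$score), 1e-6)
  expect_gt(fit$obs_info, 0)
})

test_that("the estimator recovers the simulating m at large sample size", {
  y <- as.vector(simulate_counts(fa_model("LD", m = 4), cultures = 1e4,
                                 seed = 2604))
  fit <- fit_m(y)
  expect_gt(fit$estimate, 3.8)
  expect_lt(fit$estimate, 4.2)
})

test_that("duplicating every culture preserves m and doubles the information", {
  y <- c(0, 1, 0, 5, 2, 0, 9)
  f1 <- fit_m(y, family = "MK", w = 1.2)
  f2 <- fit_m(rep(y, 2), family = "MK", w = 1.2)
  expect_equal(f1$estimate, f2$estimate, tolerance = 1e-6)
  expect_equal(f2$obs_info / f1$obs_info, 2, tolerance = 1e-6)
  expect_equal(f2$loglik, 2 * f1$loglik, tolerance = 1e-9)
})

test_that("starting values follow the zero-fraction and median heuristics", {
  y <- c(rep(0L, 11), rep(3L, 9))    # 11 zeros of 20
  expect_equal(init_guess(y), -log(0.55))
  expect_equal(init_guess(rep(0L, 4)), 1e-4)    # clamp at the lower bound
  # no zeros: root of med/m - log(m) = 1.24
  root <- uniroot(function(m) 5 / m - log(m) - 1.24, c(1e-4, 1e3),
                  tol = 1e-12)$root
  expect_equal(init_guess(c(5, 5, 5, 5)), root, tolerance = 1e-6)
})

test_that("joint (m, w) fit recovers neutral fitness and is stationary", {
  y <- as.vector(simulate_counts(fa_model("LD", m = 2), cultures = 5000,
                                 seed = 99))
  fit <- fit_mw(y)
  expect_gt(fit$estimate[["w"]], 0.9)
  expect_lt(fit$estimate[["w"]], 1.1)
  expect_lt(max(abs(fit$score)), 1e-6)
  info <- fit$obs_info
  expect_true(all(eigen(info, only.values = TRUE)$values > 0))
  # freezing w at 1 reduces the model to Lea-Coulson
  expect_equal(fit_m(y, family = "MK", w = 1)$estimate,
               fit_m(y, family = "LD")$estimate, tolerance = 1e-8)
})

test_that("degenerate inputs are rejected with clear messages", {
  expect_error(fit_m(integer(0)), "nonempty")
  expect_error(fit_m(c(0, -1)), "nonnegative")
  expect_error(fit_m(c(0.5, 1)), "integers")
  expect_error(fit_mw(rep(0L, 6)), "boundary")
})
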