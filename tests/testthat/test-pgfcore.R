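test_that("unit coefficient sequences match their closed forms", {
  # hand expansion of (1/z - 1) log(1 - z)
  expect_equal(unit_coeffs("LD", 3), c(-1, 1/2, 1/6, 1/12))
  # general phi: q_j = phi^(j-1) (1/j - phi/(j+1))
  phi <- 0.9
  j <- 1:6
  expect_equal(unit_coeffs("LD", 6, phi = phi),
               c(-1, phi^(j - 1) * (1 / j - phi / (j + 1))))
  # rho = 1 collapses the beta function to 1/(j(j+1))
  expect_equal(unit_coeffs("MK", 100, w = 1), unit_coeffs("LD", 100),
               tolerance = 1e-15)
  # closed-form constant term of the plating series
  q <- unit_coeffs("PLATING", 0, epsilon = 0.4)
  expect_equal(q[1], (0.4 / 0.6) * log(0.4))
  # epsilon = 1 dispatches to the Lea-Coulson series
  expect_identical(unit_coeffs("PLATING", 10, epsilon = 1),
                   unit_coeffs("LD", 10))
})

test_that("invalid nuisance parameters are rejected", {
  expect_error(unit_coeffs("MK", 5, w = 0), "'w'")
  expect_error(unit_coeffs("MK", 5, w = -1), "'w'")
  expect_error(unit_coeffs("PLATING", 5, epsilon = 0), "'epsilon'")
  expect_error(unit_coeffs("PLATING", 5, epsilon = 1.2), "'epsilon'")
  expect_error(unit_coeffs("LD", 5, phi = 0), "'phi'")
  expect_error(fa_model("LD", m = -1), "'m'")
  expect_error(unit_coeffs("LD", -1), "order")
  expect_error(unit_coeffs("LD", 2e5), "cap")
})

test_that("log-PGF coefficients are m-linear with vanishing partial sums", {
  expect_equal(logpgf_coeffs(fa_model("LD", m = 0), 5), rep(0, 6))
  # c = m q for the log-linear families
  m <- 3.7
  expect_equal(logpgf_coeffs(fa_model("MK", m = m, w = 0.75), 40),
               m * unit_coeffs("MK", 40, w = 0.75))
  # G(1) = 1: partial sums of c tend to zero
  for (model in list(fa_model("LD", m = 1), fa_model("MK", m = 1, w = 1.2),
                     fa_model("PLATING", m = 1, epsilon = 0.4))) {
    expect_lt(abs(sum(logpgf_coeffs(model, 1e4))), 1e-3)
  }
  # signs: q_0 < 0 and q_j > 0
  for (fam in c("LD", "MK", "PLATING")) {
    q <- unit_coeffs(fam, 50, w = 0.6, epsilon = 0.3)
    expect_lt(q[1], 0)
    expect_true(all(q[-1] > 0))
  }
})

test_that("B0 log-PGF follows the series-log construction", {
  # hand series of -k log(1 - A u), A = 1, k = 2  (so m0 = A k = 2,
  # cv^2 = A / m0 = 1/2): c_0 = -2 log 2, c_1 = 2 * (1/2) / 2 = 1/2
  cf <- logpgf_coeffs(fa_model("B0", m = 2, cv = sqrt(0.5)), 1)
  expect_equal(cf[1], -2 * log(2))
  expect_equal(cf[2], 0.5)
  # gamma mixture degenerates to Lea-Coulson as cv -> 0
  cf_b0 <- logpgf_coeffs(fa_model("B0", m = 11, cv = 1e-4), 50)
  cf_ld <- logpgf_coeffs(fa_model("LD", m = 11), 50)
  expect_equal(cf_b0, cf_ld, tolerance = 1e-4)
  # cv = 0 is normalised to LD at construction and rejected downstream
  expect_identical(fa_model("B0", m = 2, cv = 0)$family, "LD")
  degenerate <- structure(list(family = "B0", m = 2, cv = 0),
                          class = "fa_model")
  expect_error(logpgf_coeffs(degenerate, 5), "cv = 0")
})

test_that("pmf recursion reproduces closed-form heads and is prefix-stable", {
  p <- mutant_pmf(fa_model("LD", m = 1), 1)
  expect_equal(p, c(exp(-1), exp(-1) / 2))
  # p_0 = exp(c_0) for every family
  expect_equal(mutant_pmf(fa_model("PLATING", m = 0.9786801,
                                   epsilon = 0.4), 0),
               exp(0.9786801 * (0.4 / 0.6) * log(0.4)))
  # extending the order never changes earlier entries
  short <- mutant_pmf(fa_model("MK", m = 2, w = 1.3), 20)
  long <- mutant_pmf(fa_model("MK", m = 2, w = 1.3), 200)
  expect_identical(short, long[1:21])
})

test_that("pmf mass is monotone in the order and approaches 1", {
  for (m in c(0.5, 2)) {
    sums <- sapply(c(100, 1000, 5000), function(N)
      sum(mutant_pmf(fa_model("LD", m = m), N)))
    expect_true(all(diff(sums) > 0))
    expect_true(all(sums < 1))
  }
  # small m reaches 1 - 1e-6 within a modest truncation
  expect_gt(sum(mutant_pmf(fa_model("LD", m = 0.01), 2e4)), 1 - 1e-6)
})

test_that("pmf derivatives agree with closed forms and finite differences", {
  d <- mutant_pmf_derivs(fa_model("LD", m = 2), 0)
  expect_equal(d$d1[1], -exp(-2))    # p_0 = exp(-m)
  expect_equal(d$d2[1], exp(-2))
  # MK derivative in w against a central finite difference
  m <- 1.5; w <- 0.8; h <- 1e-6
  dw <- mutant_pmf_derivs(fa_model("MK", m = m, w = w), 30, wrt = "w")
  fd <- (mutant_pmf(fa_model("MK", m = m, w = w + h), 30) -
         mutant_pmf(fa_model("MK", m = m, w = w - h), 30)) / (2 * h)
  expect_equal(dw$d1, fd, tolerance = 1e-5)
  # second derivative in m against a central finite difference (B0 too)
  for (model in list(fa_model("LD", m = 2), fa_model("B0", m = 2, cv = 0.3))) {
    hm <- 1e-5
    up <- model; up$m <- model$m + hm
    dn <- model; dn$m <- model$m - hm
    fd2 <- (mutant_pmf(up, 20) - 2 * mutant_pmf(model, 20) +
            mutant_pmf(dn, 20)) / hm^2
    # absolute comparison: the difference quotient carries ~4*eps*p/h^2
    # roundoff and some exact-zero entries defeat a relative tolerance
    expect_lt(max(abs(mutant_pmf_derivs(model, 20)$d2 - fd2)), 1e-5)
  }
  expect_error(mutant_pmf_derivs(fa_model("LD", m = 1), 5, wrt = "w"),
               "MK")
})
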