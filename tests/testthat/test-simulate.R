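test_that("the simulator is seed-deterministic and respects m = 0", {
  cfg <- fa_model("LD", m = 2)
  a <- simulate_counts(cfg, cultures = 25, replicates = 4, seed = 77)
  b <- simulate_counts(cfg, cultures = 25, replicates = 4, seed = 77)
  expect_identical(a, b)
  expect_identical(dim(a), c(4L, 25L))
  zero <- simulate_counts(fa_model("LD", m = 0), cultures = 30, seed = 1)
  expect_true(all(zero == 0L))
})

test_that("zero-count frequency matches exp(-m) within sampling error", {
  n <- 1e5
  y <- simulate_counts(fa_model("LD", m = 2), cultures = n, seed = 123)
  f0 <- mean(y == 0L)
  se <- sqrt(exp(-2) * (1 - exp(-2)) / n)
  expect_lt(abs(f0 - exp(-2)), 3 * se)
})

test_that("thinned Lea-Coulson draws follow the plating pmf", {
  n <- 1e5
  y <- as.vector(simulate_counts(fa_model("PLATING", m = 2, epsilon = 0.4),
                                 cultures = n, seed = 321))
  kmax <- 20
  obs <- tabulate(factor(pmin(y, kmax + 1), levels = 0:(kmax + 1)),
                  nbins = kmax + 2)
  p <- mutant_pmf(fa_model("PLATING", m = 2, epsilon = 0.4), kmax)
  probs <- c(p, 1 - sum(p))      # counts 0..kmax plus the tail bin
  gof <- suppressWarnings(chisq.test(obs, p = probs))
  expect_gt(gof$p.value, 0.01)
})

test_that("heterogeneous-Nt simulation matches the gamma-mixture pmf", {
  n <- 5e4
  y <- as.vector(simulate_counts(fa_model("B0", m = 2, cv = 0.4),
                                 cultures = n, seed = 555))
  kmax <- 15
  obs <- tabulate(factor(pmin(y, kmax + 1), levels = 0:(kmax + 1)),
                  nbins = kmax + 2)
  p <- mutant_pmf(fa_model("B0", m = 2, cv = 0.4), kmax)
  gof <- suppressWarnings(chisq.test(obs, p = c(p, 1 - sum(p))))
  expect_gt(gof$p.value, 0.01)
})

test_that("estimation closes the loop on simulated experiments", {
  # the ML estimate should fall inside its own 95% interval nearly always,
  # and the interval should cover the simulating m in most seeded runs
  runs <- 100
  covered <- 0L
  for (s in seq_len(runs)) {
    y <- as.vector(simulate_counts(fa_model("LD", m = 4), cultures = 100,
                                   seed = 1000 + s))
    iv <- ci_m(y)
    expect_lte(iv$lower, iv$estimate)
    expect_gte(iv$upper, iv$estimate)
    if (iv$lower <= 4 && 4 <= iv$upper) covered <- covered + 1L
  }
  expect_gte(covered, 90L)
})

test_that("bundled experiments match their published summaries", {
  fx <- fluctuation_fixtures()
  expect_length(fx$krasovec_expt1$counts, 24)
  expect_identical(sum(fx$krasovec_expt1$counts), 67L)
  expect_identical(fx$krasovec_expt1$Nt, 2.27e8)
  expect_identical(fx$krasovec_expt1$w, 1.47)
  expect_length(fx$krasovec_expt2$counts, 12)
  expect_identical(max(fx$krasovec_expt2$counts), 13L)
  expect_identical(fx$krasovec_expt2$Nt, 5.15e8)
  expect_equal(fx$luria16$zeros / fx$luria16$cultures, 0.55)
  expect_identical(fx$luria16$epsilon, 0.4)
})

test_that("invalid simulation configurations are rejected", {
  expect_error(simulate_counts(fa_model("LD", m = 1), cultures = 0), ">= 1")
  expect_error(simulate_counts(list(m = 1), cultures = 5), "fa_model")
})
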