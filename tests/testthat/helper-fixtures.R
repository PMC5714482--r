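# Shared fixtures and independent oracles used across test files.

# the two published experiments (also available via fluctuation_fixtures())
expt1 <- c(0, 2, 0, 3, 0, 15, 21, 0, 1, 0, 0,
           4, 4, 1, 3, 2, 1, 0, 0, 0, 1, 0, 9, 0)
expt2 <- c(8, 2, 4, 3, 6, 11, 2, 2, 0, 13, 6, 8)

# binomial-thinning oracle for the plating pmf: a culture with j mutants
# contributes dbinom(n, j, eps) to the probability of observing n colonies.
# Independent of the plating series construction.
thinned_pmf_oracle <- function(m, eps, n_max, j_max = 5000) {
  p_ld <- mutant_pmf(fa_model("LD", m = m), j_max)
  sapply(0:n_max, function(n) sum(p_ld * dbinom(n, size = 0:j_max, prob = eps)))
}

# golden-section / parabolic maximiser of the log-likelihood, independent of
# the Newton path under test
optimize_m <- function(counts, family = "LD", w = 1, epsilon = 1, cv = 0,
                       upper = 30) {
  f <- function(m) loglik(fa_model(family, m = m, w = w, epsilon = epsilon,
                                   cv = cv), counts)
  optimize(f, interval = c(1e-4, upper), maximum = TRUE, tol = 1e-9)$maximum
}

# random small datasets for estimator cross-checks
random_counts <- function(model, cultures = 10) {
  as.vector(simulate_counts(model, cultures = cultures))
}
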