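#' Simulate fluctuation experiments
#'
#' Draws mutant counts from a mutant-count model by its compound-Poisson
#' construction: each culture receives \eqn{M \sim Poisson(m)} mutations and
#' every mutation founds a clone whose final size is drawn from the model's
#' clone-size distribution (the normalised unit coefficients \eqn{q_j},
#' \eqn{j \ge 1}).  For the Lea-Coulson model the clone size has the exact
#' inverse-CDF form \eqn{K = \lfloor 1/U \rfloor} (valid because
#' \eqn{P(K \ge k) = 1/k}); the Mandelbrot-Koch clone size is drawn from a
#' cached cumulative table up to `clone_cap` with the residual tail mass
#' assigned to `clone_cap`.  Partial plating thins the per-culture total by
#' a Binomial(\eqn{\cdot, \epsilon}) draw.  For the `B0` family the
#' per-culture mean is scaled by a Gamma multiplier with unit mean and the
#' requested coefficient of variation, emulating culture-to-culture
#' variability of the final population size.
#'
#' Clone sizes are capped at `clone_cap`, which truncates the heavy
#' clone-size tail; this keeps downstream pmf recursions bounded and has a
#' negligible effect at moderate m (the probability of any clone reaching
#' the default cap is about \eqn{m \times 10^{-4}} per culture).
#'
#' @param model An [fa_model()] giving the family, `m` and nuisance
#'   parameters.
#' @param cultures Number of parallel cultures per experiment.
#' @param replicates Number of replicate experiments.
#' @param seed Optional integer; when supplied, `set.seed(seed)` is called
#'   so the matrix is reproducible.  One root seed drives the whole draw in
#'   a fixed order, so identical configurations give identical output.
#' @param clone_cap Maximum clone size (default `1e4`).
#' @return An integer matrix of dim `replicates x cultures`.
#' @examples
#' simulate_counts(fa_model("LD", m = 2), cultures = 10, replicates = 2,
#'                 seed = 1)
#' @export
simulate_counts <- function(model, cultures, replicates = 1L, seed = NULL,
                            clone_cap = 1e4L) {
  stopifnot(inherits(model, "fa_model"))
  if (cultures < 1 || replicates < 1 || clone_cap < 1)
    stop("'cultures', 'replicates' and 'clone_cap' must all be >= 1")
  if (!is.null(seed)) set.seed(seed)
  nc <- as.integer(cultures) * as.integer(replicates)
  m <- model$m

  lambda <- if (model$family == "B0" && model$cv > 0) {
    shape <- model$cv^-2
    m * rgamma(nc, shape = shape, rate = shape)
  } else rep.int(m, nc)

  M <- rpois(nc, lambda)
  total <- numeric(nc)
  Ttot <- sum(M)
  if (Ttot > 0) {
    sizes <- draw_clone_sizes(model, Ttot, clone_cap)
    agg <- rowsum(sizes, group = rep.int(seq_len(nc), M))
    total[as.integer(rownames(agg))] <- agg[, 1L]
  }
  counts <- if (model$family == "PLATING")
    rbinom(nc, size = total, prob = model$epsilon)
  else total
  matrix(as.integer(counts), nrow = replicates, ncol = cultures,
         byrow = TRUE)
}

# clone-size sampler; plating uses the underlying Lea-Coulson clones
draw_clone_sizes <- function(model, n, clone_cap) {
  family <- model$family
  phi <- model$phi %||% 1
  if (family == "MK" || (family == "LD" && phi < 1)) {
    q <- if (family == "MK") unit_coeffs("MK", clone_cap, w = model$w)
         else unit_coeffs("LD", clone_cap, phi = phi)
    cum <- cumsum(q[-1L])
    cum[length(cum)] <- 1          # residual tail mass lands on the cap
    findInterval(runif(n), cum) + 1L
  } else {
    # LD at phi = 1 (also the clone law under plating and B0):
    # P(K >= k) = 1/k  <=>  K = floor(1/U)
    pmin(floor(1 / runif(n)), clone_cap)
  }
}

#' Monte-Carlo power of mutation-rate comparisons
#'
#' Reproduces the paired-experiment power pipeline: a baseline group of
#' Lea-Coulson experiments (final population `baseline_Nt`, mutation rate
#' `baseline_rate`, so \eqn{m = rate (N_t - N_0)}) is compared against
#' alternative groups with final population `alt_Nt` and rates
#' `k * baseline_rate`.  Experiment pairs share a serial number; each pair
#' is tested for rate equality by the likelihood-ratio test (with
#' \eqn{R = alt\_Nt / baseline\_Nt}) and/or by disjointness of the two 84%
#' likelihood-ratio rate intervals.  Power is the percentage of pairs
#' declared significant at `alpha`.
#'
#' @param k Rate multipliers of the alternative groups.
#' @param replicates Replicate pairs per multiplier.
#' @param cultures Cultures per experiment.
#' @param baseline_rate,baseline_Nt Baseline mutation rate and final
#'   population size.
#' @param alt_Nt Final population size of the alternative groups.
#' @param N0 Inoculum size.
#' @param methods Subset of `c("lrt", "ci_overlap")`.
#' @param alpha Significance level for the LRT.
#' @param overlap_level Confidence level of the overlap intervals.
#' @param seed Optional root seed; per-group substreams are derived from it
#'   deterministically.
#' @param clone_cap Passed to [simulate_counts()].
#' @return A data frame with one row per `k`: the alternative rate, the
#'   power (in percent) of each requested method, and the replicate count.
#' @examples
#' power_study(k = 2, replicates = 20, seed = 1)
#' @export
power_study <- function(k = c(1.25, 1.5, 1.75, 2, 2.5, 3),
                        replicates = 10000L, cultures = 20L,
                        baseline_rate = 1e-8, baseline_Nt = 2e8,
                        alt_Nt = 1e8, N0 = 50,
                        methods = c("lrt", "ci_overlap"), alpha = 0.05,
                        overlap_level = 0.84, seed = NULL,
                        clone_cap = 1e4L) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, length(k))
  m_base <- baseline_rate * (baseline_Nt - N0)
  R <- alt_Nt / baseline_Nt
  rows <- lapply(seq_along(k), function(i) {
    m_alt <- k[i] * baseline_rate * (alt_Nt - N0)
    set.seed(sub_seeds[i])
    base_mat <- simulate_counts(fa_model("LD", m = m_base), cultures,
                                replicates, clone_cap = clone_cap)
    alt_mat <- simulate_counts(fa_model("LD", m = m_alt), cultures,
                               replicates, clone_cap = clone_cap)
    hits <- compare_pairs(base_mat, alt_mat, R, baseline_Nt, alt_Nt,
                          methods, alpha, overlap_level)
    data.frame(k = k[i], alt_rate = k[i] * baseline_rate,
               power_lrt = if ("lrt" %in% methods)
                 100 * mean(hits$lrt) else NA_real_,
               power_ci_overlap = if ("ci_overlap" %in% methods)
                 100 * mean(hits$overlap) else NA_real_,
               replicates = replicates)
  })
  do.call(rbind, rows)
}

# run both comparison methods over paired rows of two count matrices
compare_pairs <- function(base_mat, alt_mat, R, Nt1, Nt2, methods, alpha,
                          overlap_level) {
  nrep <- nrow(base_mat)
  q_full <- unit_coeffs("LD", max(base_mat, alt_mat, 1L))
  crit <- qchisq(overlap_level, df = 1)
  lrt_hit <- logical(nrep)
  ov_hit <- logical(nrep)
  for (r in seq_len(nrep)) {
    y1 <- base_mat[r, ]
    y2 <- alt_mat[r, ]
    q1 <- q_full[seq_len(max(max(y1), 1L) + 1L)]
    q2 <- q_full[seq_len(max(max(y2), 1L) + 1L)]
    fit1 <- newton_m_q(q1, y1)
    fit2 <- newton_m_q(q2, y2)
    if ("lrt" %in% methods) {
      if (all(y1 == 0L) && all(y2 == 0L)) {
        stat <- 0
      } else {
        m0 <- max((fit1$estimate + fit2$estimate / R) / 2, 1e-4)
        con <- constrained_newton(q1, y1, q2, y2, R, m0)
        stat <- max(0, 2 * (fit1$loglik + fit2$loglik - con$ll))
      }
      lrt_hit[r] <- pchisq(stat, df = 1, lower.tail = FALSE) < alpha
    }
    if ("ci_overlap" %in% methods) {
      ci1 <- lr_ci_q(q1, y1, fit1, crit) / Nt1
      ci2 <- lr_ci_q(q2, y2, fit2, crit) / Nt2
      ov_hit[r] <- (ci1[1] > ci2[2]) || (ci2[1] > ci1[2])
    }
  }
  list(lrt = lrt_hit, overlap = ov_hit)
}

# lean LR interval on m for a precomputed unit sequence (used in bulk runs)
lr_ci_q <- function(q, counts, fit, crit) {
  ll <- function(m) ll_q(q, counts, m)
  upper <- lr_endpoint(ll, max(fit$estimate, 0.05), fit$loglik, crit, +1)
  lower <- if (fit$boundary) 0
           else lr_endpoint(ll, fit$estimate, fit$loglik, crit, -1)
  c(lower, upper)
}

#' Bundled in-paper example experiments
#'
#' Returns the two published fluctuation experiments of Krasovec and
#' colleagues (mutant counts printed in full, with measured relative
#' fitness and final population sizes) and the summary of Luria and
#' Delbruck's experiment 16 (20 cultures of which 11 had no mutants,
#' plating efficiency 0.4, \eqn{N_t = 5.6\times 10^8}; the full counts are
#' not part of this bundle, only the zero-class summary needed by the
#' P0-method examples).
#'
#' @return A named list: `krasovec_expt1` and `krasovec_expt2` as
#'   [count_data()] objects, and `luria16` as a list with elements
#'   `cultures`, `zeros`, `epsilon`, `Nt`.
#' @examples
#' fluctuation_fixtures()$krasovec_expt2
#' @export
fluctuation_fixtures <- function() {
  list(
    krasovec_expt1 = count_data(
      c(0, 2, 0, 3, 0, 15, 21, 0, 1, 0, 0,
        4, 4, 1, 3, 2, 1, 0, 0, 0, 1, 0, 9, 0),
      Nt = 2.27e8, w = 1.47),
    krasovec_expt2 = count_data(
      c(8, 2, 4, 3, 6, 11, 2, 2, 0, 13, 6, 8),
      Nt = 5.15e8, w = 1.45),
    luria16 = list(cultures = 20L, zeros = 11L, epsilon = 0.4, Nt = 5.6e8)
  )
}
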