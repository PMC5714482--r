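# Experiment-design calculators: how large may m be before colonies become
# uncountable, and how many cultures are needed for a target precision.

#' Overflow index: probability of exceeding a countable threshold
#'
#' \eqn{\eta_{500} = P(Y > 500)}, the probability that a culture yields more
#' mutant colonies than can be counted on a plate.  A common rule of thumb
#' keeps this below 0.01 when planning an experiment; large anticipated m
#' can be brought back under the rule by partial plating.  The threshold is
#' a parameter (default 500).
#'
#' @param model An [fa_model()] with the anticipated `m`.
#' @param threshold Mutant-count cap (default 500).
#' @return The tail probability `1 - sum(p_0..p_threshold)`.
#' @examples
#' eta_index(fa_model("MK", m = 4, w = 0.75))          # 0.001243678
#' eta_index(fa_model("PLATING", m = 50, epsilon = 0.1))
#' @export
eta_index <- function(model, threshold = 500L) {
  threshold <- check_order(threshold)
  1 - sum(mutant_pmf(model, threshold))
}

#' Per-culture expected Fisher information for m
#'
#' \eqn{I(m) = \sum_n (\partial p_n/\partial m)^2 / p_n}, accumulated over a
#' pmf truncated at successively doubled orders.  Accumulation stops when
#' the remaining probability mass drops below `tail_tol`, or when the
#' information total changes by less than a relative `rel_tol` across an
#' order doubling — the information series converges far faster than the
#' probability mass for these heavy-tailed distributions, so the second
#' rule usually fires first.  If neither criterion is met by the order cap,
#' an error reports the mass accumulated so far.
#'
#' @param family `"LD"`, `"MK"`, `"PLATING"` or `"B0"`.
#' @param m Anticipated expected mutations per culture (> 0).
#' @param phi,w,epsilon,cv Nuisance parameters, as in [fa_model()].
#' @param tail_tol Target on the residual probability mass.
#' @param rel_tol Relative convergence target on the information total.
#' @param cap Maximum truncation order.
#' @param details If `TRUE`, also return the truncation order and residual
#'   mass at which accumulation stopped.
#' @return The per-culture expected information (a positive number), or,
#'   with `details = TRUE`, a list with elements `info`, `order`, `tail`.
#' @examples
#' expected_info("LD", m = 2)
#' @export
expected_info <- function(family = c("LD", "MK", "PLATING", "B0"), m,
                          phi = 1, w = 1, epsilon = 1, cv = 0,
                          tail_tol = 1e-8, rel_tol = 1e-4, cap = 1e5L,
                          details = FALSE) {
  family <- match.arg(family)
  if (m <= 0) stop("'m' must be positive")
  model <- fa_model(family, m = m, phi = phi, w = w, epsilon = epsilon,
                    cv = cv)
  N <- 1024L
  I_prev <- -Inf
  repeat {
    d <- mutant_pmf_derivs(model, N, wrt = "m", order = 1)
    I_cur <- sum(d$d1^2 / d$p)
    tail <- 1 - sum(d$p)
    if (tail < tail_tol || abs(I_cur - I_prev) <= rel_tol * I_cur)
      return(if (details) list(info = I_cur, order = N, tail = tail)
             else I_cur)
    if (N >= cap)
      stop(sprintf(paste0("expected information did not converge by order ",
                          "%d (accumulated probability mass %.10g)"),
                   N, 1 - tail), call. = FALSE)
    I_prev <- I_cur
    N <- min(2L * N, as.integer(cap))
  }
}

#' Precision-based sample size for a fluctuation experiment
#'
#' Smallest number of cultures `n` such that the anticipated half-width of
#' the 95% confidence interval for m is at most a fraction `psi` of m:
#' \deqn{z_{(1+level)/2} / \sqrt{n I(m)} \le \psi m,}
#' with \eqn{I(m)} the per-culture expected Fisher information from
#' [expected_info()].  `psi` is the target ratio of half-width to the
#' anticipated magnitude of m; the default 0.25 asks for an interval whose
#' half-width is a quarter of m.
#'
#' @inheritParams expected_info
#' @param psi Target precision ratio in (0, 1).
#' @param level Confidence level defining the half-width (default 0.95).
#' @return The required number of cultures (a positive integer).
#' @examples
#' sample_size("MK", m = 4, w = 0.75, psi = 0.25)              # 31
#' sample_size("PLATING", m = 50, epsilon = 0.1, psi = 0.25)   # 15
#' @export
sample_size <- function(family = c("LD", "MK", "PLATING", "B0"), m,
                        phi = 1, w = 1, epsilon = 1, cv = 0, psi = 0.25,
                        level = 0.95) {
  if (psi <= 0 || psi >= 1) stop("'psi' must lie in (0, 1)")
  I <- expected_info(family, m, phi = phi, w = w, epsilon = epsilon,
                     cv = cv)
  z <- qnorm((1 + level) / 2)
  max(1L, as.integer(ceiling(z^2 / (I * (psi * m)^2))))
}
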