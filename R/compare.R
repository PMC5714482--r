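# Comparing mutation rates between two fluctuation experiments.  A naive
# comparison of the two m values is misleading whenever the final population
# sizes differ: equality of the *rates* p1 = p2 corresponds to m2 = R m1
# with R = Nt2/Nt1, which is what the likelihood-ratio test encodes.

#' Likelihood-ratio test for equality of two mutation rates
#'
#' Tests \eqn{H_0: p_1 = p_2} between two fluctuation experiments whose
#' final population sizes differ by the ratio \eqn{R = N_{t,2}/N_{t,1}},
#' encoded as the constraint \eqn{m_2 = R m_1}.  The unconstrained optimum
#' is two independent [fit_m()] calls; the constrained optimum is a
#' one-dimensional Newton iteration on \eqn{m_1} with score
#' \eqn{U_1(m_1) + R U_2(R m_1)} and the corresponding observed information.
#' The statistic \eqn{2[\ell_1(\hat m_1) + \ell_2(\hat m_2) -
#' \ell_1(\tilde m_1) - \ell_2(R \tilde m_1)]} (floored at 0) is referred to
#' \eqn{\chi^2_1}.
#'
#' Per-experiment nuisance parameters are fixed: relative fitness `w1`/`w2`
#' (Mandelbrot-Koch variant) or plating efficiencies `epsilon1`/`epsilon2`
#' (plating variant); all defaults of 1 give the plain Lea-Coulson test.
#'
#' @param counts1,counts2 Count vectors (or [count_data()] objects, whose
#'   metadata supply the nuisance defaults).
#' @param R Ratio of final population sizes, \eqn{N_{t,2}/N_{t,1}} (> 0).
#' @param w1,w2 Relative fitness in experiments 1 and 2.
#' @param epsilon1,epsilon2 Plating efficiencies.
#' @return An `"fa_lrt"`: `statistic`, `p_value` (upper-tail
#'   \eqn{\chi^2_1}), `R`, unconstrained estimates `m1_hat`, `m2_hat` and
#'   the constrained `m1_constrained` (with \eqn{\tilde m_2 = R \tilde m_1}).
#' @examples
#' fx <- fluctuation_fixtures()
#' lrt_rate_equality(fx$krasovec_expt1, fx$krasovec_expt2, R = 2.29)
#' @export
lrt_rate_equality <- function(counts1, counts2, R, w1 = NULL, w2 = NULL,
                              epsilon1 = NULL, epsilon2 = NULL) {
  if (R <= 0) stop("'R' must be positive")
  cfg1 <- resolve_nuisance(counts1, NULL, NULL, w1, epsilon1, 0)
  cfg2 <- resolve_nuisance(counts2, NULL, NULL, w2, epsilon2, 0)
  y1 <- cfg1$counts
  y2 <- cfg2$counts
  q1 <- unit_for(cfg1$family, max(max(y1), 1L), 1, cfg1$w, cfg1$epsilon)
  q2 <- unit_for(cfg2$family, max(max(y2), 1L), 1, cfg2$w, cfg2$epsilon)

  fit1 <- newton_m_q(q1, y1)
  fit2 <- newton_m_q(q2, y2)

  if (all(y1 == 0L) && all(y2 == 0L)) {
    m_con <- 0
    ll_con <- 0
  } else {
    m0 <- max((fit1$estimate + fit2$estimate / R) / 2, 1e-4)
    con <- constrained_newton(q1, y1, q2, y2, R, m0)
    m_con <- con$m1
    ll_con <- con$ll
  }
  stat <- max(0, 2 * (fit1$loglik + fit2$loglik - ll_con))
  out <- list(statistic = stat,
              p_value = pchisq(stat, df = 1, lower.tail = FALSE),
              R = R,
              m1_hat = fit1$estimate, m2_hat = fit2$estimate,
              m1_constrained = m_con,
              fits = list(unconstrained = list(fit1, fit2),
                          constrained_loglik = ll_con))
  class(out) <- "fa_lrt"
  out
}

#' @export
print.fa_lrt <- function(x, ...) {
  cat(sprintf("LRT for equality of mutation rates (R = %g):\n", x$R))
  cat(sprintf("  statistic = %.7g, p-value = %.7g (chi-square, 1 df)\n",
              x$statistic, x$p_value))
  cat(sprintf("  unconstrained m: %.7g, %.7g; constrained m1 = %.7g\n",
              x$m1_hat, x$m2_hat, x$m1_constrained))
  invisible(x)
}

# constrained fit: maximize l1(m1) + l2(R m1) over m1 > 0
constrained_newton <- function(q1, y1, q2, y2, R, m0, tol = 1e-10,
                               max_iter = 100L) {
  eval_at <- function(m1) {
    s1 <- score_info_q(q1, y1, m1)
    s2 <- score_info_q(q2, y2, R * m1)
    list(ll = s1$ll + s2$ll, U = s1$U + R * s2$U,
         J = s1$J + R^2 * s2$J)
  }
  m <- m0
  st <- eval_at(m)
  step <- Inf
  for (iter in seq_len(max_iter)) {
    if (abs(st$U) <= 1e-6 && abs(step) <= tol * (1 + m))
      return(list(m1 = m, ll = st$ll))
    step <- if (is.finite(st$U / st$J) && st$J > 0) st$U / st$J
            else sign(st$U) * 0.5 * max(m, 0.1)
    repeat {
      m_new <- m + step
      if (m_new > 0) {
        st_new <- tryCatch(eval_at(m_new), error = function(e) NULL)
        if (!is.null(st_new) && st_new$ll >= st$ll - 1e-12 * (1 + abs(st$ll)))
          break
      }
      step <- step / 2
      if (abs(step) < 1e-14 * (1 + m)) { m_new <- m; st_new <- st; break }
    }
    m <- m_new
    st <- st_new
  }
  stop("constrained Newton iteration did not converge", call. = FALSE)
}

#' CI-overlap comparison of two mutation rates
#'
#' The empirical alternative to the likelihood-ratio test: build
#' likelihood-ratio confidence intervals for m in each experiment at the
#' given level (84% by default), convert them to mutation-rate intervals by
#' dividing by the respective \eqn{N_t}, and declare the difference
#' significant at the 5% level exactly when the two rate intervals are
#' disjoint.
#'
#' @inheritParams lrt_rate_equality
#' @param Nt1,Nt2 Final population sizes (default: taken from
#'   [count_data()] metadata).
#' @param level Confidence level of the two intervals (default 0.84).
#' @return A list with `significant` (logical), `interval1`, `interval2`
#'   (rate scale) and `level`.
#' @examples
#' fx <- fluctuation_fixtures()
#' ci_overlap_test(fx$krasovec_expt1, fx$krasovec_expt2)
#' @export
ci_overlap_test <- function(counts1, counts2, Nt1 = NULL, Nt2 = NULL,
                            w1 = NULL, w2 = NULL, epsilon1 = NULL,
                            epsilon2 = NULL, level = 0.84) {
  meta1 <- data_meta(counts1)
  meta2 <- data_meta(counts2)
  if (is.null(Nt1)) Nt1 <- meta1$Nt
  if (is.null(Nt2)) Nt2 <- meta2$Nt
  if (is.na(Nt1) || is.na(Nt2))
    stop("Nt is required for both experiments (argument or count_data ",
         "metadata)")
  i1 <- rate_interval(ci_m(counts1, w = w1, epsilon = epsilon1,
                           level = level), Nt1)
  i2 <- rate_interval(ci_m(counts2, w = w2, epsilon = epsilon2,
                           level = level), Nt2)
  disjoint <- (i1$lower > i2$upper) || (i2$lower > i1$upper)
  list(significant = disjoint,
       decision = if (disjoint) "significant" else "not-significant",
       interval1 = i1, interval2 = i2, level = level)
}
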