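# Likelihood-ratio (profile) confidence intervals.  Endpoints solve the
# defining equation 2[l(hat) - l(theta)] = chi^2_1(level); they are located
# by outward geometric bracketing from the ML estimate followed by bisection.
# Likelihood-ratio intervals are usually asymmetric about the ML estimate,
# unlike Wald intervals.

new_interval <- function(lower, upper, level, parameter, estimate) {
  structure(list(lower = lower, upper = upper, level = level,
                 parameter = parameter, method = "likelihood-ratio",
                 estimate = estimate),
            class = "fa_interval")
}

#' @export
print.fa_interval <- function(x, ...) {
  cat(sprintf("%g%% likelihood-ratio C.I. for %s: (%s, %s)\n",
              100 * x$level, x$parameter,
              format(x$lower, digits = 7), format(x$upper, digits = 7)))
  invisible(x)
}

# bisection with optional iteration trace; f must change sign on [lo, hi]
bisect_root <- function(f, lo, hi, flo, fhi, rel_tol = 1e-8,
                        show_iter = FALSE) {
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (show_iter)
      message(sprintf("  bisect %3d: [%.*g, %.*g] f(mid) = %.3g",
                      i, 10, lo, 10, hi, fm))
    if (sign(fm) == sign(flo)) {
      lo <- mid
      flo <- fm
    } else {
      hi <- mid
      fhi <- fm
    }
    if ((hi - lo) <= rel_tol * (1 + abs(mid))) break
  }
  (lo + hi) / 2
}

# Solve 2*(ll_hat - ll(m)) = crit on one side of m_hat.
# `ll` is a function of m; direction +1 searches upward, -1 downward.
# Bracketing is geometric (factor 1.5) outward from the estimate; the root
# inside the bracket is found by Brent's derivative-free iteration (plain
# traced bisection when show_iter is requested).
lr_endpoint <- function(ll, m_hat, ll_hat, crit, direction,
                        show_iter = FALSE) {
  f <- function(m) {
    val <- tryCatch(2 * (ll_hat - ll(m)) - crit, error = function(e) Inf)
    min(val, 1e12)          # keep underflow regions finite for the solver
  }
  grow <- 1.5
  a <- m_hat
  fa <- -crit        # f(m_hat) = -crit < 0
  b <- if (m_hat > 0) m_hat else 0.1
  repeat {
    b <- if (direction > 0) b * grow else b / grow
    fb <- f(b)
    if (show_iter)
      message(sprintf("  bracket: m = %.10g f = %.3g", b, fb))
    if (fb > 0) break
    a <- b
    fa <- fb
    if (b > 1e8 || b < 1e-12)
      stop("could not bracket the confidence limit", call. = FALSE)
  }
  lo <- min(a, b)
  hi <- max(a, b)
  if (show_iter) {
    if (direction > 0) bisect_root(f, a, b, fa, fb, show_iter = TRUE)
    else bisect_root(f, b, a, fb, fa, show_iter = TRUE)
  } else {
    uniroot(f, lower = lo, upper = hi,
            f.lower = if (direction > 0) fa else fb,
            f.upper = if (direction > 0) fb else fa,
            tol = 1e-10 * (1 + hi))$root
  }
}

#' Likelihood-ratio confidence interval for m
#'
#' Endpoints are the solutions of
#' \eqn{2[\ell(\hat m) - \ell(m)] = \chi^2_1(level)} (3.841459 at the 0.95
#' level), found by geometric bracketing outward from the ML estimate and
#' bisection.  For all-zero data the estimate sits on the boundary and a
#' one-sided interval \eqn{[0, u]} is returned, with `u` solving the same
#' equation.
#'
#' @inheritParams fit_m
#' @param level Confidence level in (0, 1).
#' @param show_iter If `TRUE`, stream the bracketing/bisection trace.
#' @return An `"fa_interval"` for parameter `m`.
#' @examples
#' ci_m(c(0, 0, 1, 3))
#' @export
ci_m <- function(counts, family = NULL, phi = NULL, w = NULL,
                 epsilon = NULL, cv = NULL, level = 0.95,
                 show_iter = FALSE) {
  stopifnot(level > 0, level < 1)
  cfg <- resolve_nuisance(counts, family, phi, w, epsilon, cv)
  fit <- fit_m(counts, family = cfg$family, phi = cfg$phi, w = cfg$w,
               epsilon = cfg$epsilon, cv = cfg$cv)
  crit <- qchisq(level, df = 1)
  ll <- if (cfg$family == "B0" && cfg$cv > 0) {
    function(m) loglik(fa_model("B0", m = m, cv = cfg$cv), cfg$counts)
  } else {
    q <- unit_for(cfg$family, max(max(cfg$counts), 1L), cfg$phi, cfg$w,
                  cfg$epsilon)
    function(m) ll_q(q, cfg$counts, m)
  }
  upper <- lr_endpoint(ll, max(fit$estimate, 0.05), fit$loglik, crit, +1,
                       show_iter = show_iter)
  lower <- if (fit$boundary) 0
           else lr_endpoint(ll, fit$estimate, fit$loglik, crit, -1,
                            show_iter = show_iter)
  new_interval(lower, upper, level, "m", fit$estimate)
}

#' Profile-likelihood confidence interval for m or w
#'
#' Starting from a joint Mandelbrot-Koch fit, profiles the log-likelihood
#' over the other parameter:
#' \eqn{\ell_p(\theta) = \max_{\eta} \ell(\theta, \eta)}, the inner
#' maximisation being a warm-started one-dimensional Newton iteration.
#' Endpoints solve \eqn{2[\ell(\hat m, \hat w) - \ell_p(\theta)] =
#' \chi^2_1(level)}.  A profile interval is at least as wide as the
#' corresponding fixed-nuisance interval because maximising over the
#' nuisance can only raise \eqn{\ell_p}.  Failure of the inner maximisation
#' is reported as practical nonidentifiability.
#'
#' @param counts Nonnegative integer vector or [count_data()].
#' @param target `"m"` or `"w"`.
#' @param level Confidence level.
#' @param show_iter If `TRUE`, stream the search trace.
#' @return An `"fa_interval"` for the target parameter.
#' @examples
#' x <- simulate_counts(fa_model("LD", m = 2), cultures = 60, seed = 7)
#' ci_profile(as.vector(x), "m")
#' @export
ci_profile <- function(counts, target = c("m", "w"), level = 0.95,
                       show_iter = FALSE) {
  target <- match.arg(target)
  stopifnot(level > 0, level < 1)
  counts <- check_counts(counts)
  joint <- fit_mw(counts)
  crit <- qchisq(level, df = 1)
  warm <- new.env()
  if (target == "m") {
    warm$w <- joint$estimate[["w"]]
    ll_p <- function(m) {
      f <- fit_w_given_m(counts, m, w_init = warm$w)
      warm$w <- f$w
      f$ll
    }
    hat <- joint$estimate[["m"]]
  } else {
    warm$m <- joint$estimate[["m"]]
    ll_p <- function(w) {
      f <- fit_m(counts, family = "MK", w = w, init = warm$m)
      warm$m <- f$estimate
      f$loglik
    }
    hat <- joint$estimate[["w"]]
  }
  upper <- lr_endpoint(ll_p, hat, joint$loglik, crit, +1,
                       show_iter = show_iter)
  lower <- lr_endpoint(ll_p, hat, joint$loglik, crit, -1,
                       show_iter = show_iter)
  new_interval(lower, upper, level, target, hat)
}

# inner maximisation over w at fixed m (Newton on log w with halving)
fit_w_given_m <- function(counts, m, w_init = 1, tol = 1e-9,
                          max_iter = 100L) {
  N <- max(counts)
  eval_at <- function(lw) {
    w <- exp(lw)
    d <- mk_joint_derivs(m, w, N)
    py <- d$p[counts + 1L]
    if (any(py <= 0)) stop("pmf underflow", call. = FALSE)
    rw <- d$pw[counts + 1L] / py
    gw <- sum(rw)
    Hww <- sum(d$pww[counts + 1L] / py - rw^2)
    list(ll = sum(log(py)), g = w * gw, H = w^2 * Hww + w * gw, w = w,
         gw = gw)
  }
  lw <- log(min(max(w_init, 1e-3), 1e3))
  st <- eval_at(lw)
  for (iter in seq_len(max_iter)) {
    if (abs(st$gw) <= 1e-8 * (1 + abs(st$ll))) break
    step <- if (is.finite(st$g / st$H) && st$H < 0) -st$g / st$H
            else sign(st$g) * 0.2
    accepted <- FALSE
    for (half in 1:40) {
      lw_new <- lw + step
      if (abs(lw_new) <= log(1e3)) {
        st_new <- tryCatch(eval_at(lw_new), error = function(e) NULL)
        if (!is.null(st_new) && st_new$ll >= st$ll - 1e-12 * (1 + abs(st$ll))) {
          accepted <- TRUE
          break
        }
      }
      step <- step / 2
    }
    if (!accepted) break
    if (abs(lw_new - lw) <= tol * (1 + abs(lw_new)) && iter > 1L) {
      lw <- lw_new
      st <- st_new
      break
    }
    lw <- lw_new
    st <- st_new
  }
  if (abs(st$gw) > 1e-3 * (1 + abs(st$ll)))
    stop("profile inner maximisation over w did not converge ",
         "(practical nonidentifiability)", call. = FALSE)
  list(ll = st$ll, w = st$w)
}

#' Convert an interval for m into an interval for the mutation rate
#'
#' Divides both endpoints by the number of cell divisions
#' \eqn{N_t - N_0 \approx N_t} and relabels the parameter `"rate"`.
#'
#' @param interval An `"fa_interval"` for `m`.
#' @param Nt Final number of cells per culture (> 0).
#' @param N0 Inoculum size (default 0).
#' @return An `"fa_interval"` for the mutation rate (per cell division).
#' @examples
#' rate_interval(ci_m(c(0, 0, 1, 3)), Nt = 1e8)
#' @export
rate_interval <- function(interval, Nt, N0 = 0) {
  stopifnot(inherits(interval, "fa_interval"))
  if (missing(Nt) || is.null(Nt) || is.na(Nt) || Nt <= 0)
    stop("'Nt' must be supplied and positive to convert m to a rate")
  if (N0 < 0 || Nt <= N0) stop("need Nt > N0 >= 0")
  div <- Nt - N0
  new_interval(interval$lower / div, interval$upper / div, interval$level,
               "rate", interval$estimate / div)
}
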