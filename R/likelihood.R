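#' Log-likelihood of mutant-count data
#'
#' Sum of \eqn{\log p_{y_i}} over cultures under a mutant-count model; the
#' pmf is truncated at the largest observed count.
#'
#' @param model An [fa_model()].
#' @param counts Nonnegative integer vector (or a [count_data()] object).
#' @return The log-likelihood (a single number).
#' @examples
#' loglik(fa_model("LD", m = 3), c(0, 0))   # -6
#' @export
loglik <- function(model, counts) {
  counts <- check_counts(counts)
  p <- mutant_pmf(model, max(counts))
  safe_log_p(p, counts)
}

# sum(log p[y]) with an informative error on underflow
safe_log_p <- function(p, counts) {
  py <- p[counts + 1L]
  if (any(py <= 0)) {
    n <- counts[which(py <= 0)[1L]]
    stop(sprintf("pmf underflow: p_%d is not representable in double precision",
                 n), call. = FALSE)
  }
  sum(log(py))
}

#' Starting value for the Newton iteration on m
#'
#' If any culture has a zero count, uses the zero-fraction (P0) heuristic
#' \eqn{m_0 = -\log(z/n)}.  Otherwise solves the Lea-Coulson median equation
#' \eqn{\tilde r/m - \log m = 1.24} for \eqn{m}, with \eqn{\tilde r} the
#' sample median.  The result is clamped to \eqn{[10^{-4}, 10^3]}.
#'
#' @param counts Nonnegative integer vector (or [count_data()]).
#' @return A positive starting value for `m`.
#' @examples
#' init_guess(c(0, 0, 1, 3))    # -log(0.5)
#' @export
init_guess <- function(counts) {
  counts <- check_counts(counts)
  z <- sum(counts == 0L)
  m0 <- if (z > 0L) {
    if (z == length(counts)) 0 else -log(z / length(counts))
  } else {
    med <- median(counts)
    f <- function(m) med / m - log(m) - 1.24
    if (f(1e-4) < 0) 1e-4
    else if (f(1e3) > 0) 1e3
    else uniroot(f, c(1e-4, 1e3), tol = 1e-10)$root
  }
  min(max(m0, 1e-4), 1e3)
}

# ---- internal Newton core on precomputed unit coefficients ------------------
# Log-linear families: log-pgf = m * q.  Returns score/information pieces at m.
score_info_q <- function(q, counts, m) {
  p <- series_exp_cpp(m * q)
  d1 <- conv_trunc(q, p)
  d2 <- conv_trunc(q, d1)
  py <- p[counts + 1L]
  if (any(py <= 0)) {
    n <- counts[which(py <= 0)[1L]]
    stop(sprintf("pmf underflow: p_%d is not representable in double precision",
                 n), call. = FALSE)
  }
  r <- d1[counts + 1L] / py
  list(ll = sum(log(py)), U = sum(r),
       J = sum(r^2 - d2[counts + 1L] / py))
}

ll_q <- function(q, counts, m) {
  p <- series_exp_cpp(m * q)
  safe_log_p(p, counts)
}

# Safeguarded 1-d Newton on m >= 0 for a log-linear family with unit
# coefficients q (truncated at max(counts)).  Backtracking halving keeps the
# log-likelihood nondecreasing across accepted steps.
newton_m_q <- function(q, counts, init = NULL, tol = 1e-9, max_iter = 100L) {
  n <- length(counts)
  if (all(counts == 0L)) {
    # likelihood exp(n m q_0) is decreasing in m: boundary optimum at 0
    return(list(estimate = 0, loglik = 0, score = n * q[1L], obs_info = 0,
                iterations = 0L, converged = TRUE, boundary = TRUE))
  }
  m <- if (is.null(init)) init_guess(counts) else init
  if (m <= 0) m <- 1e-4
  si <- score_info_q(q, counts, m)
  step <- Inf
  for (iter in seq_len(max_iter)) {
    if (abs(si$U) <= 1e-6 && abs(step) <= tol * (1 + m)) {
      return(list(estimate = m, loglik = si$ll, score = si$U,
                  obs_info = si$J, iterations = iter - 1L,
                  converged = TRUE, boundary = FALSE))
    }
    step <- if (is.finite(si$U / si$J) && si$J > 0) si$U / si$J
            else sign(si$U) * 0.5 * max(m, 0.1)
    # backtrack: stay positive and never decrease the log-likelihood
    repeat {
      m_new <- m + step
      if (m_new > 0) {
        si_new <- tryCatch(score_info_q(q, counts, m_new),
                           error = function(e) NULL)
        if (!is.null(si_new) && si_new$ll >= si$ll - 1e-12 * (1 + abs(si$ll)))
          break
      }
      step <- step / 2
      if (abs(step) < 1e-14 * (1 + m)) { m_new <- m; si_new <- si; break }
    }
    m <- m_new
    si <- si_new
  }
  stop(sprintf(paste0("Newton iteration did not converge after %d steps ",
                      "(last iterate m = %.8g, score = %.3g)"),
               max_iter, m, si$U), call. = FALSE)
}

# B0 family: Newton on the overall mean m0 with cv fixed
newton_m_b0 <- function(counts, cv, init = NULL, tol = 1e-9,
                        max_iter = 100L) {
  n <- length(counts)
  if (all(counts == 0L)) {
    return(list(estimate = 0, loglik = 0, score = -n, obs_info = 0,
                iterations = 0L, converged = TRUE, boundary = TRUE))
  }
  N <- max(counts)
  eval_b0 <- function(m) {
    d <- mutant_pmf_derivs(fa_model("B0", m = m, cv = cv), N)
    py <- d$p[counts + 1L]
    if (any(py <= 0)) stop("pmf underflow", call. = FALSE)
    r <- d$d1[counts + 1L] / py
    list(ll = sum(log(py)), U = sum(r),
         J = sum(r^2 - d$d2[counts + 1L] / py))
  }
  m <- if (is.null(init)) init_guess(counts) else init
  if (m <= 0) m <- 1e-4
  si <- eval_b0(m)
  step <- Inf
  for (iter in seq_len(max_iter)) {
    if (abs(si$U) <= 1e-6 && abs(step) <= tol * (1 + m)) {
      return(list(estimate = m, loglik = si$ll, score = si$U,
                  obs_info = si$J, iterations = iter - 1L,
                  converged = TRUE, boundary = FALSE))
    }
    step <- if (is.finite(si$U / si$J) && si$J > 0) si$U / si$J
            else sign(si$U) * 0.5 * max(m, 0.1)
    repeat {
      m_new <- m + step
      if (m_new > 0) {
        si_new <- tryCatch(eval_b0(m_new), error = function(e) NULL)
        if (!is.null(si_new) && si_new$ll >= si$ll - 1e-12 * (1 + abs(si$ll)))
          break
      }
      step <- step / 2
      if (abs(step) < 1e-14 * (1 + m)) { m_new <- m; si_new <- si; break }
    }
    m <- m_new
    si <- si_new
  }
  stop("Newton iteration for the B0 model did not converge", call. = FALSE)
}

# resolve nuisance defaults from a count_data object
resolve_nuisance <- function(data, family, phi, w, epsilon, cv) {
  meta <- data_meta(data)
  if (is.null(w)) w <- meta$w
  if (is.null(epsilon)) epsilon <- meta$epsilon
  if (is.null(cv)) cv <- meta$cv
  if (is.null(phi)) phi <- 1
  if (is.null(family)) {
    family <- if (cv > 0) "B0"
              else if (epsilon < 1) "PLATING"
              else if (w != 1) "MK"
              else "LD"
  }
  list(counts = meta$counts, family = family, phi = phi, w = w,
       epsilon = epsilon, cv = cv)
}

unit_for <- function(family, N, phi, w, epsilon) {
  unit_coeffs(if (family == "B0") "LD" else family, N,
              phi = phi, w = w, epsilon = epsilon)
}

#' Maximum-likelihood estimate of m
#'
#' Newton-Raphson estimation of the expected number of mutations per culture
#' under a chosen mutant-count family with fixed nuisance parameters, using
#' the observed Fisher information.  The update is
#' \eqn{m \leftarrow m + U/J} with score
#' \eqn{U = \sum_i \partial_m p_{y_i}/p_{y_i}} and observed information
#' \eqn{J = \sum_i [(\partial_m p/p)^2 - \partial_m^2 p/p]_{y_i}}, with
#' backtracking so the likelihood never decreases across accepted steps.
#' All-zero data sit on the boundary of the parameter space: the estimate 0
#' is returned with the `boundary` flag set.
#'
#' @param counts Nonnegative integer vector or [count_data()]; metadata of a
#'   `count_data` object supplies nuisance defaults.
#' @param family `"LD"`, `"MK"`, `"PLATING"` or `"B0"`; if `NULL`, inferred
#'   from the nuisance values (`cv > 0` selects B0, `epsilon < 1` plating,
#'   `w != 1` MK, otherwise LD).
#' @param phi,w,epsilon,cv Nuisance parameters (fixed, not estimated).
#' @param init Optional starting value; defaults to [init_guess()].
#' @param tol Convergence tolerance on the scale-free step,
#'   \eqn{|\Delta m| \le tol (1 + m)}; the score must also satisfy
#'   \eqn{|U| \le 10^{-6}}.
#' @param max_iter Iteration cap; exceeding it is an error.
#' @return An object of class `"fa_fit"` with elements `estimate`, `loglik`,
#'   `score`, `obs_info`, `iterations`, `converged`, `boundary`, plus the
#'   model description.
#' @examples
#' fit_m(c(0, 0, 1, 3))
#' fit_m(c(0, 2, 5, 1), family = "MK", w = 0.8)
#' @export
fit_m <- function(counts, family = NULL, phi = NULL, w = NULL,
                  epsilon = NULL, cv = NULL, init = NULL, tol = 1e-9,
                  max_iter = 100L) {
  cfg <- resolve_nuisance(counts, family, phi, w, epsilon, cv)
  fit <- if (cfg$family == "B0" && cfg$cv > 0) {
    newton_m_b0(cfg$counts, cfg$cv, init = init, tol = tol,
                max_iter = max_iter)
  } else {
    q <- unit_for(cfg$family, max(max(cfg$counts), 1L), cfg$phi, cfg$w,
                  cfg$epsilon)
    newton_m_q(q, cfg$counts, init = init, tol = tol, max_iter = max_iter)
  }
  fit$family <- cfg$family
  fit$nuisance <- cfg[c("phi", "w", "epsilon", "cv")]
  fit$counts <- cfg$counts
  fit$parameter <- "m"
  class(fit) <- "fa_fit"
  fit
}

#' @export
print.fa_fit <- function(x, ...) {
  lab <- if (length(x$estimate) == 2L) "(m, w)" else x$parameter
  cat(sprintf("ML fit [%s]: %s = %s\n", x$family, lab,
              paste(format(x$estimate, digits = 7), collapse = ", ")))
  cat(sprintf("  log-likelihood %.7g; %d iteration(s); converged: %s%s\n",
              x$loglik, x$iterations, x$converged,
              if (isTRUE(x$boundary)) "; estimate on boundary (m = 0)" else ""))
  invisible(x)
}

#' Joint maximum-likelihood estimation of (m, w)
#'
#' Two-parameter Newton-Raphson fit of the Mandelbrot-Koch model: the
#' expected number of mutations `m` and the mutant relative fitness `w` are
#' estimated simultaneously using the observed information matrix.  The
#' iteration runs on \eqn{(m, \log w)} so that `w` stays within
#' \eqn{(10^{-3}, 10^{3})}, with step-halving whenever a proposed step does
#' not increase the likelihood.  Fluctuation data carry little information
#' about `w` unless several distinct positive counts are present; on
#' failure (singular information or non-convergence) the error message
#' recommends fixing `w` from an attendant fitness assay and using
#' [fit_m()] — the practical-nonidentifiability situation.
#'
#' @param counts Nonnegative integer vector or [count_data()].
#' @param init Optional length-2 vector `c(m, w)`; defaults to
#'   `(init_guess(counts), 1)`.
#' @param tol Convergence tolerance (scale-free step size; both score
#'   components must additionally have magnitude below `1e-6`).
#' @param max_iter Iteration cap.
#' @return An `"fa_fit"` with `estimate = c(m, w)`, `score` of length 2 and
#'   a 2x2 observed information matrix `obs_info` (in the `(m, w)`
#'   parameterisation).
#' @examples
#' x <- simulate_counts(fa_model("LD", m = 2), cultures = 50, seed = 1)
#' fit_mw(as.vector(x))
#' @export
fit_mw <- function(counts, init = NULL, tol = 1e-9, max_iter = 200L) {
  counts <- check_counts(counts)
  if (all(counts == 0L))
    stop("all counts are zero: m lies on the boundary and w is ",
         "unidentifiable; use fit_m() with w fixed")
  N <- max(counts)
  eval_at <- function(m, lw) {
    w <- exp(lw)
    d <- mk_joint_derivs(m, w, N)
    py <- d$p[counts + 1L]
    if (any(py <= 0)) stop("pmf underflow", call. = FALSE)
    rm <- d$pm[counts + 1L] / py
    rw <- d$pw[counts + 1L] / py
    gm <- sum(rm)
    gw <- sum(rw)
    Hmm <- sum(d$pmm[counts + 1L] / py - rm^2)
    Hww <- sum(d$pww[counts + 1L] / py - rw^2)
    Hmw <- sum(d$pmw[counts + 1L] / py - rm * rw)
    list(ll = sum(log(py)), gm = gm, gw = gw,
         Hmm = Hmm, Hww = Hww, Hmw = Hmw, w = w)
  }
  if (is.null(init)) init <- c(init_guess(counts), 1)
  m <- max(init[1], 1e-4)
  lw <- log(min(max(init[2], 1e-3), 1e3))
  st <- eval_at(m, lw)
  fail <- function(why) {
    stop("joint (m, w) estimation failed (", why, "): the data are ",
         "practically nonidentifiable in w; fix w from a fitness assay ",
         "and use fit_m()", call. = FALSE)
  }
  for (iter in seq_len(max_iter)) {
    # chain rule to (m, log w)
    g <- c(st$gm, st$w * st$gw)
    H <- matrix(c(st$Hmm, st$w * st$Hmw,
                  st$w * st$Hmw, st$w^2 * st$Hww + st$w * st$gw), 2, 2)
    if (abs(st$gm) <= 1e-6 && abs(st$gw) <= 1e-6 && iter > 1L) {
      info <- -matrix(c(st$Hmm, st$Hmw, st$Hmw, st$Hww), 2, 2)
      if (any(!is.finite(info)) || det(info) <= 0) fail("singular information")
      fit <- list(estimate = c(m = m, w = st$w), loglik = st$ll,
                  score = c(m = st$gm, w = st$gw), obs_info = info,
                  iterations = iter - 1L, converged = TRUE,
                  boundary = FALSE, family = "MK",
                  nuisance = list(phi = 1, w = NULL, epsilon = 1, cv = 0),
                  counts = counts, parameter = c("m", "w"))
      class(fit) <- "fa_fit"
      return(fit)
    }
    step <- tryCatch(solve(-H, g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step)))
      step <- g / max(sum(abs(g)), 1)   # gradient fallback
    accepted <- FALSE
    for (half in 1:40) {
      m_new <- m + step[1]
      lw_new <- lw + step[2]
      if (m_new > 0 && abs(lw_new) <= log(1e3)) {
        st_new <- tryCatch(eval_at(m_new, lw_new), error = function(e) NULL)
        if (!is.null(st_new) &&
            st_new$ll >= st$ll - 1e-12 * (1 + abs(st$ll))) {
          accepted <- TRUE
          break
        }
      }
      step <- step / 2
    }
    if (!accepted) fail("no ascent step found")
    m <- m_new
    lw <- lw_new
    st <- st_new
  }
  fail(sprintf("no convergence after %d iterations", max_iter))
}
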