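#' Mutant-count probability mass function
#'
#' Expands the PGF of a mutant-count model into probabilities
#' \eqn{p_0, \ldots, p_N} by the exp-of-series (compound-Poisson) recursion
#' \eqn{p_0 = e^{c_0}}, \eqn{p_n = (1/n)\sum_{j=1}^n j c_j p_{n-j}}, where
#' \eqn{c} are the log-PGF coefficients from [logpgf_coeffs()].  The result
#' is deterministic and prefix-stable: extending `N` never changes earlier
#' entries.  The partial sums increase to 1 as `N` grows; the missing tail
#' mass `1 - sum(p)` is the overflow probability used by [eta_index()].
#'
#' @param model An [fa_model()].
#' @param N Truncation order: probabilities are returned for counts
#'   `0, ..., N`.
#' @return Numeric vector of length `N + 1` with `p[n + 1]` =
#'   \eqn{P(Y = n)}.
#' @examples
#' p <- mutant_pmf(fa_model("LD", m = 1), 5)
#' p[1]            # exp(-1)
#' p[2]            # exp(-1) / 2
#' @export
mutant_pmf <- function(model, N) {
  series_exp_cpp(logpgf_coeffs(model, N))
}

#' Parameter derivatives of the mutant-count pmf
#'
#' Computes \eqn{\partial p_n/\partial\theta} (and optionally
#' \eqn{\partial^2 p_n/\partial\theta^2}) for \eqn{\theta = m} (all
#' families) or \eqn{\theta = w} (Mandelbrot-Koch only).  Because
#' \eqn{p = \exp(c)} as a formal series, derivatives follow by Cauchy
#' convolution: \eqn{\partial p = (\partial c) * p} and
#' \eqn{\partial^2 p = (\partial^2 c) * p + (\partial c) * (\partial p)}.
#' These feed the score and observed Fisher information of the likelihood
#' machinery.
#'
#' For the log-linear families, \eqn{\partial c/\partial m = q} and
#' \eqn{\partial^2 c/\partial m^2 = 0}.  For `B0`,
#' \eqn{\partial c/\partial m} is obtained by series division.  For `MK` in
#' `w`, the first derivative of the unit coefficients is analytic (digamma
#' form); the second derivative uses a central difference with step
#' \eqn{h = 10^{-4}\max(1, w)}.
#'
#' @param model An [fa_model()].
#' @param N Truncation order.
#' @param wrt `"m"` or `"w"` (the latter only for family `"MK"`).
#' @param order 1 or 2 (order 2 also returns the first derivative).
#' @return A list with elements `p`, `d1` and (if `order == 2`) `d2`, each a
#'   numeric vector of length `N + 1`.
#' @examples
#' d <- mutant_pmf_derivs(fa_model("LD", m = 2), 0)
#' d$d1[1]   # -exp(-2), since p_0 = exp(-m)
#' @export
mutant_pmf_derivs <- function(model, N, wrt = c("m", "w"), order = 2) {
  stopifnot(inherits(model, "fa_model"), order %in% c(1, 2))
  wrt <- match.arg(wrt)
  N <- check_order(N)
  if (wrt == "w" && model$family != "MK")
    stop("derivatives in 'w' are defined only for the MK family")

  if (model$family == "B0") {
    A <- model$cv^2 * model$m
    k <- model$cv^-2
    u <- unit_coeffs("LD", N)
    v <- -A * u
    v[1] <- 1 - A * u[1]
    p <- series_exp_cpp(-k * series_log_cpp(v))
    dc1 <- k * model$cv^2 * series_div_cpp(u, v)
    d1 <- conv_trunc(dc1, p)
    if (order == 1) return(list(p = p, d1 = d1))
    dc2 <- series_mul_cpp(dc1, dc1) / k
    return(list(p = p, d1 = d1, d2 = conv_trunc(dc2, p) + conv_trunc(dc1, d1)))
  }

  if (wrt == "m") {
    q <- unit_coeffs(model$family, N, phi = model$phi %||% 1,
                     w = model$w %||% 1, epsilon = model$epsilon %||% 1)
    p <- series_exp_cpp(model$m * q)
    d1 <- conv_trunc(q, p)
    if (order == 1) return(list(p = p, d1 = d1))
    return(list(p = p, d1 = d1, d2 = conv_trunc(q, d1)))
  }

  # wrt = "w", family MK
  q <- unit_coeffs("MK", N, w = model$w)
  p <- series_exp_cpp(model$m * q)
  dc1 <- model$m * mk_unit_dw(q, model$w)
  d1 <- conv_trunc(dc1, p)
  if (order == 1) return(list(p = p, d1 = d1))
  dc2 <- model$m * mk_unit_dw2(model$w, N)
  list(p = p, d1 = d1, d2 = conv_trunc(dc2, p) + conv_trunc(dc1, d1))
}

# d q_j / d w for the MK unit sequence:
# q_j = rho B(j, rho + 1), d log q_j / d rho = 1/rho + psi(rho+1) - psi(j+rho+1),
# d rho / d w = -1/w^2.
mk_unit_dw <- function(q, w) {
  N <- length(q) - 1L
  rho <- 1 / w
  dq <- numeric(N + 1)
  if (N >= 1) {
    j <- seq_len(N)
    dq[-1] <- q[-1] * (1 / rho + digamma(rho + 1) - digamma(j + rho + 1)) *
      (-1 / w^2)
  }
  dq
}

# d^2 q / d w^2 by central differences; step scales with w
mk_unit_dw2 <- function(w, N) {
  h <- 1e-4 * max(1, w)
  (unit_coeffs("MK", N, w = w + h) - 2 * unit_coeffs("MK", N, w = w) +
     unit_coeffs("MK", N, w = w - h)) / h^2
}

# All mixed partial derivative series of the MK pmf in (m, w), used by the
# joint Newton fit: p, pm, pw, pmm, pmw, pww.
mk_joint_derivs <- function(m, w, N) {
  N <- check_order(N)
  q <- unit_coeffs("MK", N, w = w)
  qw <- mk_unit_dw(q, w)
  qww <- mk_unit_dw2(w, N)
  p <- series_exp_cpp(m * q)
  pm <- conv_trunc(q, p)
  pw <- conv_trunc(m * qw, p)
  list(p = p, pm = pm, pw = pw,
       pmm = conv_trunc(q, pm),
       pmw = conv_trunc(qw, p) + conv_trunc(q, pw),
       pww = conv_trunc(m * qww, p) + conv_trunc(m * qw, pw))
}
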