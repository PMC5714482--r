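# Truncation guard shared by every series routine.  Orders above the cap make
# the O(N^2) recursions impractical; callers should reduce m by partial
# plating instead of asking for million-term series.
N_CAP <- 1e5L

check_order <- function(N) {
  if (length(N) != 1L || is.na(N) || N < 0 || N != round(N))
    stop("truncation order 'N' must be a single nonnegative integer")
  if (N > N_CAP)
    stop(sprintf("truncation order %d exceeds the cap of %d; reduce the ",
                 as.integer(N), N_CAP),
         "required order (e.g. by partial plating)")
  as.integer(N)
}

#' Unit coefficients of a log-PGF
#'
#' Every mutant-count distribution family with a fixed nuisance parameter has
#' a log-PGF that is linear in `m`: \eqn{\log G(z) = m \sum_j q_j z^j}.  This
#' function returns the unit coefficient sequence \eqn{q_0, \ldots, q_N},
#' which doubles as the clone-size distribution (\eqn{q_j} for \eqn{j \ge 1}
#' sums to \eqn{-q_0 = 1}):
#'
#' * `LD`: \eqn{q_0 = -1}, \eqn{q_j = \phi^{j-1}(1/j - \phi/(j+1))};
#'   at \eqn{\phi = 1} this is \eqn{1/(j(j+1))}.
#' * `MK`: \eqn{q_0 = -1}, \eqn{q_j = \rho B(j, \rho + 1)} with
#'   \eqn{\rho = 1/w} and \eqn{B} the beta function (evaluated through
#'   log-gamma for stability).
#' * `PLATING`: the Taylor coefficients of
#'   \eqn{\xi (1-z) \log(\epsilon(1-z)) / (1 + \xi z)} with
#'   \eqn{\xi = \epsilon/(1-\epsilon)}, computed by formal series arithmetic;
#'   \eqn{q_0 = \xi \log \epsilon}.  `epsilon = 1` dispatches to `LD`.
#'
#' The `B0` family is not log-linear in `m`; see [logpgf_coeffs()].
#'
#' @param family `"LD"`, `"MK"` or `"PLATING"`.
#' @param N Truncation order (the sequence has `N + 1` entries).
#' @param phi,w,epsilon Nuisance parameters, as in [fa_model()].
#' @return Numeric vector \eqn{q_0, \ldots, q_N}.
#' @examples
#' unit_coeffs("LD", 3)            # -1, 1/2, 1/6, 1/12
#' unit_coeffs("MK", 3, w = 1)     # identical to the above
#' @export
unit_coeffs <- function(family = c("LD", "MK", "PLATING"), N,
                        phi = 1, w = 1, epsilon = 1) {
  family <- match.arg(family)
  N <- check_order(N)
  switch(family,
    LD = {
      if (phi <= 0 || phi > 1) stop("'phi' must lie in (0, 1]")
      q <- numeric(N + 1)
      q[1] <- -1
      if (N >= 1) {
        j <- seq_len(N)
        q[-1] <- phi^(j - 1) * (1 / j - phi / (j + 1))
      }
      q
    },
    MK = {
      if (w <= 0) stop("'w' must be positive")
      rho <- 1 / w
      q <- numeric(N + 1)
      q[1] <- -1
      if (N >= 1) {
        j <- seq_len(N)
        q[-1] <- exp(log(rho) + lbeta(j, rho + 1))
      }
      q
    },
    PLATING = {
      if (epsilon <= 0 || epsilon > 1) stop("'epsilon' must lie in (0, 1]")
      if (epsilon == 1) return(unit_coeffs("LD", N))
      xi <- epsilon / (1 - epsilon)
      if (xi <= 1) {
        # a(z) = log(eps (1 - z)); b = (1 - z) a; q = xi * b / (1 + xi z)
        a <- c(log(epsilon), if (N >= 1) -1 / seq_len(N))
        b <- a
        if (N >= 1) b[-1] <- a[-1] - a[-(N + 1)]
        xi * geom_div_cpp(b, xi)
      } else {
        # The geometric-division recursion amplifies rounding error by xi
        # per step and is unusable for xi > 1.  The series is analytic there
        # (the numerator vanishes exactly at the pole z = -1/xi), and the
        # same function is the log-PGF of binomially thinned Lea-Coulson
        # clones: q_k = sum_j u_j dbinom(k; j, eps), a cancellation-free
        # positive-term sum (q_0 = xi log eps in closed form).
        plating_unit_thinned(N, epsilon)
      }
    })
}

#' Log-PGF coefficient sequence of a mutant-count model
#'
#' Returns the truncated Taylor coefficients \eqn{c_0, \ldots, c_N} of
#' \eqn{\log G(z)} for a model.  For the log-linear families this is simply
#' `m * unit_coeffs(...)`.  For `B0` the PGF is
#' \eqn{G(z) = (1 - A u(z))^{-k}} where \eqn{u} is the Lea-Coulson unit
#' series, \eqn{A = cv^2 m} and \eqn{k = cv^{-2}}; its log is computed by the
#' standard series-log recursion.
#'
#' @param model An [fa_model()].
#' @param N Truncation order.
#' @return Numeric vector \eqn{c_0, \ldots, c_N}.  `sum(c)` tends to 0 as
#'   `N` grows (this is \eqn{G(1) = 1}).
#' @examples
#' logpgf_coeffs(fa_model("LD", m = 2), 5)
#' @export
logpgf_coeffs <- function(model, N) {
  stopifnot(inherits(model, "fa_model"))
  N <- check_order(N)
  if (model$family == "B0") {
    if (model$cv == 0)
      stop("B0 with cv = 0 degenerates to LD; construct the model through ",
           "fa_model(), which performs this dispatch")
    A <- model$cv^2 * model$m
    k <- model$cv^-2
    u <- unit_coeffs("LD", N)
    v <- -A * u
    v[1] <- 1 - A * u[1]
    -k * series_log_cpp(v)
  } else {
    model$m * unit_coeffs(model$family, N, phi = model$phi %||% 1,
                          w = model$w %||% 1,
                          epsilon = model$epsilon %||% 1)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Plating unit coefficients as thinned Lea-Coulson clones, used when
# xi = eps/(1-eps) > 1: q_k = sum_{j>=1} dbinom(k; j, eps) / (j(j+1)) for
# k >= 1, q_0 = xi log(eps) exactly.  Accumulates per clone size j over the
# +/-12-sigma window of Binomial(j, eps), leaving relative truncation error
# far below double precision.
plating_unit_thinned <- function(N, epsilon) {
  xi <- epsilon / (1 - epsilon)
  q <- numeric(N + 1)
  q[1] <- xi * log(epsilon)
  if (N >= 1) {
    j_max <- ceiling((N + 12 * sqrt(N + 9) + 25) / epsilon) + 50
    for (j in seq_len(j_max)) {
      mu <- j * epsilon
      half <- 12 * sqrt(j * epsilon * (1 - epsilon)) + 5
      k_lo <- max(1, floor(mu - half))
      if (k_lo > N) break
      k_hi <- min(N, ceiling(mu + half), j)
      if (k_hi < k_lo) next
      kk <- k_lo:k_hi
      q[kk + 1] <- q[kk + 1] + dbinom(kk, j, epsilon) / (j * (j + 1))
    }
  }
  q
}

# truncated Cauchy product; FFT above a size threshold, exact loop below
conv_trunc <- function(a, b) {
  n <- length(a)
  if (n == 1L) return(a * b)
  if (n <= 512L) series_mul_cpp(a, b)
  else convolve(a, rev(b), type = "open")[seq_len(n)]
}
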