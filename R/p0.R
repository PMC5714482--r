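#' P0-method estimate of m
#'
#' Classic zero-class estimator: with `z` cultures showing no mutants out of
#' `n`, \eqn{\hat m = -\log(z/n)}, from
#' \eqn{P(Y = 0) = e^{-m}} under perfect plating.  Either a full counts
#' vector or the pair `zeros`/`n` may be supplied.
#'
#' @param counts Nonnegative integer vector or [count_data()]; alternative
#'   to `zeros`/`n`.
#' @param zeros Number of cultures with zero mutants.
#' @param n Total number of cultures.
#' @return The estimate of `m`.  All-zero data return 0 (boundary), in line
#'   with [fit_m()].
#' @examples
#' p0_estimate(zeros = 11, n = 20)   # -log(0.55)
#' @export
p0_estimate <- function(counts = NULL, zeros = NULL, n = NULL) {
  zf <- zero_fraction(counts, zeros, n)
  if (zf == 0)
    stop("no zero counts: the P0 method is inapplicable; use fit_m()")
  if (zf == 1) return(0)
  -log(zf)
}

#' Plating-corrected P0 estimate of m
#'
#' Under partial plating a zero *count* need not come from a null culture: a
#' mutant present in the tube is missed with probability \eqn{1-\epsilon}.
#' The modified zero-class estimator inverts
#' \eqn{P(Y = 0) = \exp(m \xi \log\epsilon)}, \eqn{\xi = \epsilon/(1-\epsilon)}:
#' \deqn{\hat m = \log(z/n) / (\xi \log \epsilon).}
#' As \eqn{\epsilon \to 1} this tends to the classic estimator
#' \eqn{-\log(z/n)}.
#'
#' @inheritParams p0_estimate
#' @param epsilon Plating efficiency in (0, 1].
#' @return The estimate of `m`.
#' @examples
#' p0_estimate_plating(zeros = 11, n = 20, epsilon = 0.4)   # 0.9786801
#' @export
p0_estimate_plating <- function(counts = NULL, zeros = NULL, n = NULL,
                                epsilon) {
  if (epsilon <= 0 || epsilon > 1) stop("'epsilon' must lie in (0, 1]")
  if (epsilon == 1) return(p0_estimate(counts, zeros, n))
  zf <- zero_fraction(counts, zeros, n)
  if (zf == 0)
    stop("no zero counts: the P0 method is inapplicable; use fit_m()")
  if (zf == 1) return(0)
  xi <- epsilon / (1 - epsilon)
  log(zf) / (xi * log(epsilon))
}

zero_fraction <- function(counts, zeros, n) {
  if (!is.null(counts)) {
    counts <- check_counts(counts)
    zeros <- sum(counts == 0L)
    n <- length(counts)
  }
  if (is.null(zeros) || is.null(n))
    stop("supply either 'counts' or both 'zeros' and 'n'")
  if (n < 1 || zeros < 0 || zeros > n)
    stop("need 0 <= zeros <= n with n >= 1")
  zeros / n
}

#' Stewart adjustment factor for partial plating
#'
#' The historical multiplicative correction
#' \eqn{A(\epsilon) = (\epsilon - 1)/(\epsilon \log \epsilon)} applied to an
#' estimate of m obtained under the (false) assumption of perfect plating.
#' It is provided for reference: compared with the maximum-likelihood
#' estimate under the plating model it systematically understates m, and it
#' is not applicable when the mutant relative fitness differs from 1.
#'
#' @param epsilon Plating efficiency in (0, 1]; `epsilon = 1` returns 1 (the
#'   continuous limit).
#' @return The adjustment factor \eqn{A \ge 1}.
#' @examples
#' stewart_factor(0.01)    # about 21.50
#' @export
stewart_factor <- function(epsilon) {
  if (epsilon <= 0 || epsilon > 1) stop("'epsilon' must lie in (0, 1]")
  if (epsilon == 1) return(1)
  (epsilon - 1) / (epsilon * log(epsilon))
}

#' Mutation rate from m and the final population size
#'
#' \eqn{p = m / (N_t - N_0)}: mutations per cell division, since a culture
#' grown from \eqn{N_0} to \eqn{N_t} cells underwent \eqn{N_t - N_0} cell
#' divisions.
#'
#' @param m Expected mutations per culture.
#' @param Nt Final cells per culture.
#' @param N0 Inoculum (default 0).
#' @return The mutation rate per cell division.
#' @examples
#' mutation_rate(0.98, Nt = 5.6e8)   # 1.75e-9
#' @export
mutation_rate <- function(m, Nt, N0 = 0) {
  if (N0 < 0 || Nt <= N0) stop("need Nt > N0 >= 0")
  m / (Nt - N0)
}
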