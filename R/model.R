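#' Specify a mutant-count distribution
#'
#' A fluctuation-assay mutant-count distribution is identified by its
#' probability generating function (PGF).  Four families are supported:
#'
#' * `"LD"` — the Lea-Coulson model, optionally with finite inoculum through
#'   `phi` \eqn{= 1 - N_0/N_t} (the conventional choice is `phi = 1`);
#' * `"MK"` — the Mandelbrot-Koch model, in which mutants grow at relative
#'   fitness `w` (ratio of mutant to non-mutant growth rate);
#' * `"PLATING"` — the Lea-Coulson model observed after plating a fraction
#'   `epsilon` of each culture (partial plating / imperfect plating
#'   efficiency);
#' * `"B0"` — a gamma mixture of Lea-Coulson distributions absorbing
#'   culture-to-culture variability of the final population size with
#'   coefficient of variation `cv`; its focal parameter `m` is the overall
#'   mean number of mutations per culture.
#'
#' In every family `m` is the expected number of *mutations* (not mutants)
#' per culture, the fundamental inferential parameter.  A `"B0"` model with
#' `cv = 0` degenerates to `"LD"` and is normalised to it on construction.
#'
#' @param family Distribution family, one of `"LD"`, `"MK"`, `"PLATING"`,
#'   `"B0"`.
#' @param m Expected number of mutations per culture (\eqn{\ge 0}).
#' @param phi \eqn{1 - N_0/N_t \in (0, 1]}; used by `"LD"` only.
#' @param w Mutant relative fitness (> 0); used by `"MK"` only.
#' @param epsilon Plating efficiency \eqn{\in (0, 1]}; used by `"PLATING"`
#'   only. `epsilon = 1` reduces to `"LD"`.
#' @param cv Coefficient of variation of the final population size
#'   (\eqn{\ge 0}); used by `"B0"` only.
#'
#' @return An object of class `"fa_model"`: a list with elements `family`,
#'   `m` and the relevant nuisance parameter.  For `"B0"` the internal
#'   mixture parameters `A = cv^2 m` and `k = cv^-2` (so that `A k = m`)
#'   are derived on demand.
#'
#' @examples
#' fa_model("LD", m = 2)
#' fa_model("MK", m = 4, w = 0.75)
#' fa_model("PLATING", m = 50, epsilon = 0.1)
#' fa_model("B0", m = 11, cv = 0.15)
#' @export
fa_model <- function(family = c("LD", "MK", "PLATING", "B0"),
                     m, phi = 1, w = 1, epsilon = 1, cv = 0) {
  family <- match.arg(family)
  stopifnot(is.numeric(m), length(m) == 1L, is.finite(m))
  if (m < 0) stop("'m' must be nonnegative")
  if (family == "LD" && (phi <= 0 || phi > 1))
    stop("'phi' must lie in (0, 1]")
  if (family == "MK" && w <= 0)
    stop("'w' (relative fitness) must be positive")
  if (family == "PLATING" && (epsilon <= 0 || epsilon > 1))
    stop("'epsilon' (plating efficiency) must lie in (0, 1]")
  if (family == "B0" && cv < 0)
    stop("'cv' must be nonnegative")
  # degenerate reductions
  if (family == "B0" && cv == 0) return(fa_model("LD", m = m))
  if (family == "PLATING" && epsilon == 1) return(fa_model("LD", m = m))
  out <- switch(family,
    LD      = list(family = "LD", m = m, phi = phi),
    MK      = list(family = "MK", m = m, w = w),
    PLATING = list(family = "PLATING", m = m, epsilon = epsilon),
    B0      = list(family = "B0", m = m, cv = cv))
  class(out) <- "fa_model"
  out
}

#' @export
print.fa_model <- function(x, ...) {
  nuis <- switch(x$family,
    LD      = sprintf("phi = %g", x$phi),
    MK      = sprintf("w = %g", x$w),
    PLATING = sprintf("epsilon = %g", x$epsilon),
    B0      = sprintf("cv = %g", x$cv))
  cat(sprintf("Mutant-count model %s(m = %g, %s)\n", x$family, x$m, nuis))
  invisible(x)
}

#' Bundle one fluctuation experiment
#'
#' Couples a vector of mutant colony counts (one entry per parallel culture)
#' with the experiment metadata needed to turn an estimate of `m` into a
#' mutation rate: the final number of cells per culture `Nt`, the inoculum
#' `N0`, the plating efficiency `epsilon`, the mutant relative fitness `w`,
#' and the coefficient of variation `cv` of `Nt` across cultures.
#'
#' @param counts Nonnegative integer vector of mutant counts.
#' @param Nt Final cells per culture (> 0); `NA` if not measured.
#' @param N0 Inoculum size (\eqn{\ge 0}).
#' @param epsilon Plating efficiency \eqn{\in (0, 1]}.
#' @param w Mutant relative fitness (> 0).
#' @param cv Coefficient of variation of `Nt` (\eqn{\ge 0}).
#' @return A list of class `"count_data"`.
#' @examples
#' count_data(c(0, 2, 0, 3), Nt = 2.27e8, w = 1.47)
#' @export
count_data <- function(counts, Nt = NA_real_, N0 = 0, epsilon = 1, w = 1,
                       cv = 0) {
  counts <- check_counts(counts)
  if (!is.na(Nt) && Nt <= 0) stop("'Nt' must be positive")
  if (N0 < 0) stop("'N0' must be nonnegative")
  if (epsilon <= 0 || epsilon > 1) stop("'epsilon' must lie in (0, 1]")
  if (w <= 0) stop("'w' must be positive")
  if (cv < 0) stop("'cv' must be nonnegative")
  structure(list(counts = counts, Nt = Nt, N0 = N0, epsilon = epsilon,
                 w = w, cv = cv),
            class = "count_data")
}

#' @export
print.count_data <- function(x, ...) {
  cat(sprintf(
    "Fluctuation experiment: %d cultures, total mutants %d, max count %d\n",
    length(x$counts), sum(x$counts), max(x$counts)))
  meta <- c(Nt = x$Nt, N0 = x$N0, epsilon = x$epsilon, w = x$w, cv = x$cv)
  cat("  ", paste(names(meta), "=", format(meta, digits = 7),
                  collapse = ", "), "\n")
  invisible(x)
}

# validate and coerce a counts vector (count_data passes through)
check_counts <- function(counts) {
  if (inherits(counts, "count_data")) counts <- counts$counts
  if (length(counts) == 0L) stop("'counts' must be nonempty")
  if (anyNA(counts) || !is.numeric(counts))
    stop("'counts' must be numeric without missing values")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("'counts' must be nonnegative integers")
  as.integer(counts)
}

# pull metadata from a count_data object, else defaults
data_meta <- function(x) {
  if (inherits(x, "count_data")) x
  else list(counts = check_counts(x), Nt = NA_real_, N0 = 0, epsilon = 1,
            w = 1, cv = 0)
}
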