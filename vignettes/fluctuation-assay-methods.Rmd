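---
title: "Models and methods for fluctuation-assay inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for fluctuation-assay inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flucassay)
```

## The inferential problem

A fluctuation assay grows many parallel cultures from small inocula, plates
each culture on selective medium, and counts mutant colonies.  Mutations
arise during growth at rate $p$ per cell division; a mutation occurring
while the culture has $N$ cells founds a clone that keeps growing until
plating, so a single early mutation can produce a "jackpot" of thousands of
mutants.  The number of *mutants* per culture is therefore wildly
overdispersed and its mean is nearly useless; the inferential target is
$m$, the expected number of *mutations* per culture, from which the
mutation rate follows as
$$p = \frac{m}{N_t - N_0} \approx \frac{m}{N_t},$$
with $N_t$ the final and $N_0$ the initial number of cells.

No mutant-count distribution in this family has a closed-form pmf; each is
defined by its probability generating function (PGF).  Writing
$\log G(z) = \sum_j c_j z^j$, the probabilities follow from the truncated
coefficients by the exp-of-series recursion
$$p_0 = e^{c_0}, \qquad p_n = \frac1n \sum_{j=1}^n j\, c_j\, p_{n-j},$$
which is exact for the head $p_0,\dots,p_N$ of every distribution here (the
truncation never contaminates earlier entries).  All likelihood, interval,
testing and design machinery in this package is built on this recursion and
on formal power-series arithmetic (log, product, quotient), implemented in
C++ because the recursions are quadratic in the truncation order.

## The four model families

* **Lea-Coulson (`LD`)**: the classical model — exponential growth,
  neutral mutants, perfect plating.  Unit coefficients (per unit of $m$)
  are $q_0 = -1$, $q_j = \phi^{j-1}(1/j - \phi/(j+1))$, where
  $\phi = 1 - N_0/N_t$.  In practice $\phi > 0.999$; $\phi$ is exposed
  mainly for exploring the sensitivity to a finite inoculum, and the
  default is 1.  The exponent is normalised so that $p_0 = e^{-m}$ for
  every $\phi$ and the $\phi = 1$ limit is the textbook Lea-Coulson PGF;
  this normalisation also makes $q$ a probability distribution over clone
  sizes ($\sum_{j\ge1} q_j = 1$).
* **Mandelbrot-Koch (`MK`)**: mutants grow at relative fitness $w \neq 1$.
  Clone sizes follow $q_j = \rho B(j, \rho + 1)$ with $\rho = 1/w$ and $B$
  the beta function, evaluated through log-gamma.  This unit sequence is
  normalised so that $\sum_{j \ge 1} q_j = 1$, which is required for
  $G(1) = 1$ and makes $w = 1$ reduce exactly to Lea-Coulson; the
  published overflow-index values confirm this orientation of $w$
  empirically (fitter mutants, $w > 1$, give heavier tails).
* **Partial plating (`PLATING`)**: only a fraction $\epsilon$ of each
  culture is plated, so each mutant is observed independently with
  probability $\epsilon$.  The log-PGF is
  $m\,\xi(1-z)\log(\epsilon(1-z))/(1+\xi z)$ with
  $\xi = \epsilon/(1-\epsilon)$; its coefficients are computed by formal
  series arithmetic (series of $\log(1-z)$, multiplication by $1-z$,
  geometric division by $1+\xi z$).  The geometric-division recursion
  amplifies rounding error by a factor $\xi$ per coefficient, so for
  $\xi > 1$ (i.e. $\epsilon > 1/2$) the coefficients are instead evaluated
  through the cancellation-free thinning representation
  $q_k = \sum_j u_j \binom{j}{k}\epsilon^k(1-\epsilon)^{j-k}$ — the same
  distribution is a binomial thinning of Lea-Coulson, an identity the test
  suite also verifies directly at the pmf level.
* **Gamma mixture (`B0`)**: final population sizes vary between cultures
  with coefficient of variation $C$; conditional on $N_t$ the counts are
  Lea-Coulson with mean proportional to $N_t$.  Integrating a Gamma law
  for the mutation load gives the PGF $(1 - A u(z))^{-k}$ with
  $u$ the Lea-Coulson unit series, $A = C^2 m_0$, $k = C^{-2}$ (so
  $Ak = m_0$, the overall mean).  The log-PGF is obtained by the standard
  series-log recursion.  $C = 0$ is normalised to `LD` at model
  construction; `logpgf_coeffs()` refuses a degenerate `B0` object so the
  dispatch cannot be bypassed silently.

## Estimation

`fit_m()` maximises the likelihood by Newton-Raphson with the *observed*
Fisher information, using the series identities
$\partial p = (\partial c) \ast p$ and
$\partial^2 p = (\partial^2 c)\ast p + (\partial c)\ast(\partial p)$
(Cauchy convolutions; FFT-based above order 512).  Design choices:

* Convergence requires both a scale-free step,
  $|\Delta m| \le 10^{-9}(1+m)$, and a small score, $|U| \le 10^{-6}$ —
  strict enough to support the 7-digit outputs the field prints.
* Steps are backtracked (halving) so the log-likelihood never decreases;
  when the observed information is nonpositive the step falls back to a
  scaled score direction.
* All-zero data lie on the boundary: the likelihood $e^{-nm}$ is
  decreasing in $m$, so the estimate 0 is returned with a `boundary` flag
  instead of failing.
* Starting values come from the zero-fraction when zeros are present
  ($-\log(z/n)$, exact for the zero class), otherwise from the
  Lea-Coulson median heuristic $\tilde r/m - \log m = 1.24$, clamped to
  $[10^{-4}, 10^3]$.

`fit_mw()` estimates $(m, w)$ jointly with the 2x2 observed-information
Newton step, parameterised in $(m, \log w)$ to keep
$w \in (10^{-3}, 10^3)$.  The derivative of the clone-size coefficients in
$w$ is analytic (digamma form); second derivatives in $w$ use a central
difference with step $10^{-4}\max(1, w)$, which the finite-difference
invariant in the test suite shows is accurate far beyond what the Newton
iteration needs.  Fluctuation data often carry little information about
$w$ (practical nonidentifiability); the failure message of `fit_mw()`
recommends fixing $w$ from an attendant fitness assay, which is also the
better experimental practice.

## Confidence intervals and tests

All intervals are likelihood-ratio (profile) intervals: endpoints solve
$2[\ell(\hat m) - \ell(m)] = \chi^2_1(\text{level})$, located by outward
geometric bracketing (factor 1.5) and then a derivative-free root solve
(Brent; a plain traced bisection when `show_iter = TRUE`).
Bracket-then-solve was chosen over Newton on the profile because profile
curves flatten near nonidentifiability, where Newton steps are unstable.
Likelihood-ratio intervals are generally asymmetric about the estimate and
outperform Wald intervals at fluctuation-assay sample sizes, which is why
Wald intervals are not offered.  At the $m = 0$ boundary a one-sided
$[0, u]$ interval is returned using the same $\chi^2$ threshold.

`lrt_rate_equality()` tests equality of two mutation *rates*, not of the
two $m$ values: with final populations differing by $R = N_{t,2}/N_{t,1}$,
the null $p_1 = p_2$ is the constraint $m_2 = R\,m_1$.  The constrained
optimum is a one-dimensional Newton iteration on $m_1$ with score
$U_1(m_1) + R\,U_2(R m_1)$, warm-started at the pooled heuristic
$(\hat m_1 + \hat m_2/R)/2$; the statistic is referred to $\chi^2_1$
(two-sided, as the published p-values are; no boundary mixture correction
is applied, and the bundled worked example is consistent with the plain
$\chi^2_1$ reference).  `ci_overlap_test()` implements the empirical
alternative: two 84% rate intervals, significance at the 5% level iff
they are disjoint.

On the interval level: the published comparison of the two bundled
experiments quotes "84% C.I.s" in prose, but the printed interval commands
use the package default level.  Reproducing the printed endpoints requires
level 0.95, so 0.95 is the default of `ci_m()` while
`ci_overlap_test()` uses 0.84 where the overlap heuristic calls for it.

## The simulator

`simulate_counts()` draws from the exact compound-Poisson structure:
$M \sim \text{Poisson}(m)$ mutations per culture, i.i.d. clone sizes from
the unit coefficients.  For Lea-Coulson the clone size has the exact
inverse-CDF form $K = \lfloor 1/U \rfloor$ (since $P(K \ge k) = 1/k$);
Mandelbrot-Koch clones come from a cumulative table truncated at
`clone_cap` with the residual tail mass assigned to the cap; plating thins
per-culture totals binomially; Nt variability scales the per-culture mean
by a unit-mean Gamma multiplier with the requested CV.  The Gamma law is a
convention — only the CV is specified by the mixture argument — and it is
exactly the mixing law under which the `B0` family is the marginal
distribution, which the simulator's goodness-of-fit test exploits.

The clone-size cap (default $10^4$) truncates the heavy tail so that
downstream pmf recursions stay bounded at $O(\text{cap}^2)$; a clone
reaches the cap with probability $\sim m \times 10^{-4}$ per culture, below
Monte-Carlo noise at the $m \le 6$ used in the power pipeline.

What the simulator does *not* emulate: phenotypic delay, cell death,
post-plating mutation, non-exponential cell lifetimes, or correlated
$N_t$ across cultures.  Tests passing against it therefore validate the
inference machinery under the model's own assumptions, not the adequacy of
those assumptions for any particular organism or protocol.

`power_study()` reproduces the paired-experiment power pipeline: baseline
20-culture experiments at rate $10^{-8}$ with $N_t = 2\times10^8$
($m = 2$) against alternatives at $k\times10^{-8}$ with $N_t = 10^8$
($R = 1/2$, $N_0 = 50$), comparing with the LRT and/or the 84%-overlap
rule at the 5% level.  The acceptance script runs 2,000 replicate pairs
per setting — enough for a Monte-Carlo standard error of about 1.1
percentage points at 60% power — and the reference values at $k = 2$ are
62.8% (LRT) and 62.4% (overlap) from a 10,000-pair run.

## Experiment design

`eta_index()` is the overflow probability $P(Y > 500)$ (the threshold is a
parameter; the "keep it below 0.01" rule is a documented guideline, not a
constant baked into the code).  `sample_size()` returns the smallest $n$
with
$$z_{(1+\text{level})/2} \big/ \sqrt{n\, I(m)} \;\le\; \psi\, m,$$
i.e. the anticipated Wald half-width on the $m$ scale at most a fraction
$\psi$ of the anticipated $m$; this criterion reproduces both published
worked examples (31 cultures for MK $m=4, w=0.75, \psi=0.25$; 15 cultures
for plating $m=50, \epsilon=0.1$).

The per-culture expected information
$I(m) = \sum_n (\partial_m p_n)^2/p_n$ is accumulated over order-doubled
truncations.  The probability mass of these distributions decays only like
$m/N$, so a pure mass-based stopping rule ($10^{-8}$) is unreachable at
practical orders, while the information increments decay like $1/N^2$ per
term.  Accumulation therefore also stops when the total changes by less
than a relative $10^{-4}$ across a doubling (the default), which leaves
the reported sample sizes several percent clear of their rounding
boundaries; the mass rule and a hard order cap of $10^5$ (with an
informative error) remain as safeguards.

## Numerical choices, degenerate inputs, limitations

* Truncation: every likelihood truncates at the largest observed count;
  design calculators truncate at the threshold (500).  Orders above
  $10^5$ are refused with an informative error.
* All recursions run in double precision in linear space (all quantities
  after $p_0$ are positive); log-likelihoods are sums of $\log p_n$.  If
  $p_n$ underflows for an observed count, a numeric-range error names the
  count rather than returning `-Inf` silently.  A frozen 50-digit
  reference head ($p_0\dots p_{20}$ per family) guards the recursion at
  $10^{-12}$ relative accuracy.
* The zero-class (P0) estimators return 0 for all-zero data (consistent
  with the ML boundary) and refuse data with no zeros at all.
* The Stewart plating correction $(\epsilon-1)/(\epsilon\log\epsilon)$ is
  included for reference only; it understates $m$ relative to the plating
  ML estimate and is inapplicable when $w \ne 1$.
* Out of scope: the synchronous-growth (Haldane) model, generating-
  function estimators, Wald and bootstrap intervals, and joint estimation
  of $(m, \epsilon)$ or $(m, C)$.

## Problem sizes used by the automated checks

The test suite and the acceptance script choose simulation sizes as a
compromise between Monte-Carlo resolution and turnaround: 2,000 replicate
pairs for power and type-I error (binomial SE about 0.5-1.1 points), 500
experiments for interval coverage (SE about 1 point), $10^5$ draws for
distributional goodness-of-fit, and $10^6$ draws for the Monte-Carlo check
of the expected information.  Worked-example quantities (overflow indices,
sample sizes, the two-experiment LRT) are deterministic and reproduce the
published 7-significant-digit values exactly at these settings.
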