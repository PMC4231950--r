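---
title: "Modelling inter-site heterogeneity in binned ChIP-seq counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling inter-site heterogeneity in binned ChIP-seq counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipmix)
```

## The model

ChIP-seq input (untreated control) libraries are summarised as read
counts $x_i$ over fixed-width genomic bins.  Counts from a single site
sequenced repeatedly are Poisson, but across sites the rate varies:
mappability artifacts, copy-number changes and library-preparation
effects make some bins systematically hot.  chipmix therefore models the
counts as a Poisson mixture,

$$X_i \mid \Lambda_i \sim \mathrm{Pois}(\Lambda_i), \qquad
  \Lambda_i \sim f(\lambda),$$

and centres the analysis on the mixing density $f$.  Four parametric
choices of $f$ are supported, each fit by maximum likelihood (or a
Bayesian approximation where the likelihood is intractable):

| count model | mixing distribution | parameters | fit |
|---|---|---|---|
| Poisson | point mass | $\mu$ | closed form ($\hat\mu = \bar x$) |
| negative binomial | gamma | $\mu, r$ | profile likelihood over $\log r$ |
| log-normal Poisson | log-normal | $\mu, \sigma^2$ | Metropolis–Hastings |
| NB-NB mixture | gamma–gamma mixture | $\tau, \mu_1, r_1, \mu_2, r_2$ | EM + SQUAREM |

The NB is parametrised by mean and dispersion with variance
$\mu + \mu^2/r$, equivalently a gamma-mixed Poisson with mixing
$\Gamma(\text{shape}=r,\ \text{rate}=r/\mu)$.  This choice is forced by
the mixing-distribution viewpoint: it makes the NB's gamma mixing
distribution, and the NB-NB's gamma–gamma mixture, explicit.

The NB-NB mixture encodes two latent bin populations — a bulk background
component and a rarer high-count (artifact) component selected with
probability $\tau$.  Components are always reported with
$\mu_1 \le \mu_2$.

## The nonparametric MLE and the constrained Newton method

Rather than committing to a parametric $f$, the NPMLE of the mixing
distribution is computed with the constrained Newton method (CNM).  For
Poisson mixtures the NPMLE is discrete, with at most as many support
points as there are distinct observed counts.  Each CNM iteration:

1. evaluates the gradient function
   $d(\theta^*; G) = \sum_j \left[ f_P(x_j;\theta^*)/f_G(x_j) - 1 \right]$,
   the directional derivative of the log-likelihood as mass moves from
   the current mixture $G$ towards a point mass at $\theta^*$, over a
   candidate grid (the distinct counts, a geometric grid, and midpoints
   of the current support), and inserts every polished local maximiser
   with $d > 0$;
2. recomputes the weight MLE for the enlarged support by iterating the
   constrained least-squares problem
   $\min_{\pi} \lVert S\pi - 2\cdot\mathbf 1 \rVert^2$ on the probability
   simplex ($S_{ij} = \partial \ell_j / \partial \pi_i$), interleaved
   with a multiplicative (EM) weight step and safeguarded by a monotone
   line search;
3. deletes support points whose weight has fallen to zero
   (below $10^{-10}$, the floating-point surrogate for exact zero).

Iteration stops when $\sup_{\theta^*} d(\theta^*;G) \le$ `grad_tol`,
whose default $10^{-6}\,n$ is scale-free because the gradient grows
linearly with sample size.  Non-convergence at `max_iter` is a
reportable outcome, not an error: the partial fit is still useful for
the diagnostics below.

Numerical notes, in the order they bit during development:

* The constrained least-squares subproblem is solved as
  column-equilibrated non-negative least squares with a penalty row for
  the sum-to-one constraint (at the scale of $\lVert b\rVert$, not
  larger: an over-weighted penalty destroys the conditioning), followed
  by exact renormalisation.  The unconstrained problem is degenerate —
  $2\pi_{\text{current}}$ solves it with zero residual — so the
  constraint cannot be dropped.
* A multiplicative weight step precedes each least-squares step.  It is
  what activates a freshly inserted support point whose density
  contribution is still orders of magnitude below the rest; the
  least-squares step alone stalls in that regime.
* A single initial support point at the sample mean can underflow to
  zero probability at extreme observed counts; such counts are seeded
  into the initial support.
* Support points closer than $10^{-4}(1+\theta)$ are merged (weights
  summed) to remove numerically duplicated atoms.

## Diagnostics

**Distribution recovery.**  The count pmf implied by the NPMLE,
$\hat f(x) = \sum_i \pi_i f_P(x;\theta_i)$, is compared with the
empirical pmf; closeness means the discrete NPMLE retains the key
features of the data.

**CDF bounds.**  A continuous mixing distribution consistent with the
NPMLE must satisfy
$\sum_{j<i}\pi_j \le F(\theta_i) < \sum_{j\le i}\pi_j$ at every support
point (with $F(\theta_1) \ge 0$; the derivation assumes no
zero-inflation of $\Lambda$).  `check_mixing_fit()` applies the bound
with the strict half-open convention: equality at the upper end is a
violation.  One subtlety is deliberate: the numerically exact NPMLE can
carry a pair of atoms a small fraction of a Poisson standard deviation
apart that share the mass of one effective atom — coalescing such a pair
costs a likelihood change of order $10^{-7}$ while leaving the gradient
criterion intact, so these splits are genuine features of the NPMLE, not
convergence failures.  Since the bound derivation assigns each atom its
own cell of a partition of $[0,\infty)$, atoms that are statistically
indistinguishable at Poisson resolution belong in one cell, and
`cdf_bounds()` therefore collapses atoms closer than
$\sqrt{1+\theta}$ — one Poisson standard deviation, the resolution scale of the Poisson kernel — by default (`collapse = 0` restores the verbatim
support).  Without this the bound intervals pinch to widths no
continuous CDF can thread, and the diagnostic loses its meaning.

**Total variation.**  Model fit is scored by
$d_{TV}(f,g) = \tfrac12\sum_x |f(x)-g(x)|$, computed over
$0..\max(x)$ with all remaining model mass lumped into one tail cell.

**Zero-inflation scan.**  For a grid of fractions $\rho$, `zero_scan()`
deletes (or, for $\rho<0$, adds) $\rho \cdot n_{\text{zeros}}$
zero-valued bins, refits each model and records $d_{TV}$.  Genuinely
zero-inflated data produces a fit optimum at the $\rho$ matching the
inflation fraction; a model that merely cannot accommodate the heavy
tail of large counts shows a spurious optimum at large $\rho$.  Zeros
are exchangeable, so deletion is deterministic; the grid row at
$\rho = 0$ reproduces the unadjusted fit exactly.  Zero addition is
parameterised relative to the existing zero count, keeping $\rho$
dimensionless and symmetric about zero.

**De novo blacklist.**  Under a fitted NB-NB model the posterior
probability that bin $i$ came from the high-count component is
$\tau f_2(x_i) / (\tau f_2(x_i) + (1-\tau) f_1(x_i))$.  Bins at or above
a threshold (default 0.5) are flagged and adjacent flagged bins merge
into BED-style regions — a blacklist constructed from the sample itself
rather than from an external catalogue.

## Fitting choices

**Log-normal Poisson.**  Each likelihood term is an intractable
integral, evaluated by mode-adapted Gauss–Hermite quadrature (nodes
centred at the mode of the integrand's exponent, scaled by its
curvature), with the node count doubled until two successive
evaluations agree to $10^{-8}$ relative; failure to reach the target is
an error reporting the achieved accuracy.  The fit is Bayesian with
weak priors $\mu \sim N(0, 10)$ (read as variance 10) and
$\sigma^{-2} \sim \Gamma(\text{shape}=1, \text{rate}=0.1)$, sampled by a
joint Gaussian random walk on $(\mu, \log \sigma^{-2})$ whose scale
adapts towards ~0.3 acceptance during burn-in and is frozen afterwards.
The point estimate is the post-burn-in posterior mean of each sampled
parameter; with $n$ in the tens of thousands the priors are
negligible, making this an approximation to the MAP.  Defaults
(`n_iter = 20000`, `burn_in = 5000`) are implementation choices; the
sampler details are not pinned down by any external reference.

**NB-NB EM.**  The E-step computes responsibilities of the high-mean
component; the M-step refits $\tau$ as the mean responsibility and each
NB component by weighted profile likelihood (dispersion bounded in
$[10^{-6}, 10^6]$ against overflow; data that are not overdispersed hit
the upper cap, which is flagged rather than diverging).  Acceleration
uses the first-order squared extrapolation of SQUAREM on the
unconstrained scale $(\operatorname{logit}\tau, \log\mu_k, \log r_k)$,
with the step length safeguarded at $\alpha \le -1$ and a fallback to
the plain double-EM step whenever the extrapolated point fails to
increase the log-likelihood — so the recorded trace is non-decreasing by
construction.  `"auto"` initialisation splits the counts at the 0.90
empirical quantile and moment-matches an NB to each part, reflecting the
expected structure of a bulk plus a heavy tail.  Component collapse
($\tau \to 0$ or $1$) is reported as `degenerate_to_single_NB`, a
legitimate answer when the data are a single NB.

**Binning.**  Coordinates are 0-based half-open (BED) throughout.  Reads
are points (start positions); a bin overlapping an excluded region by
one bp is dropped entirely, keeping all bins equal width, and a final
partial bin is dropped for the same reason.  Duplicate positions are
retained.

## The synthetic-data generator

`simulate_counts()` draws from the generative model directly: an
optional Bernoulli($\nu$) zero mask first (masked bins skip the rate
draw entirely), then $\Lambda_i$ from the requested mixing distribution
and $x_i \sim \mathrm{Pois}(\Lambda_i)$.  Every stochastic function in
the package takes an explicit seed and restores the caller's RNG state;
there is no hidden global state.

The generator emulates exactly what the models assume: independent
bins, a common mixing distribution, no spatial structure.  Real input
libraries have autocorrelation along the genome, mappability structure
and inter-chromosome differences that the generator does not produce,
so passing tests show correctness of the inference machinery under the
stated model, not robustness to those violations.  Simulated study
conditions used in the tests and the acceptance script — e.g. NB-NB
truth $(\tau, \mu_1, r_1, \mu_2, r_2) = (0.05, 2, 10, 30, 0.8)$ at
$n = 10^5$, gamma mixing with mean 10 and dispersion 2 at $n = 10^5$,
zero-inflation $\nu = 0.3$ over NB$(5, 2)$ at $n = 5\times10^4$, and a
13-point $\rho$ grid from $-0.3$ to $0.9$ — are fixed generative
settings chosen to resemble a sparse input library (mean counts of a
few reads per 100 bp bin with a rare hot component), and NPMLE checks
run at $n = 5000$, sizes at which every check completes in seconds to a
few minutes on one core.

## Known limitations

* The CDF bounds assume $\Lambda$ is not zero-inflated; a zero-inflated
  CNM variant would need its own $\nu$ update and extra identifiability
  constraints, and is not implemented.
* Mixtures of log-normal Poissons are excluded for computational cost;
  mixtures of pure Poissons are exactly what the CNM already provides.
* No regression on genomic covariates (GC, copy number, mappability):
  the approach is deliberately unsupervised.
* Inter-chromosome normalisation and peak calling are out of scope;
  analyses are per chromosome.

## A worked example

```{r example, eval = FALSE}
x <- simulate_counts(
  mix_gamma_gamma(0.05, shape1 = 10, rate1 = 5, shape2 = 0.8, rate2 = 0.8 / 30),
  n = 20000, seed = 1
)

glance(fit_nb(x))
fit <- fit_nbnb(x)
tidy(fit)

np <- cnm_fit(x)
glance(np)
check_mixing_fit(fit, cdf_bounds(np))

autoplot(np, x)
autoplot(zero_scan(x, seq(-0.3, 0.9, 0.1), models = c("nb", "nbnb")))
```
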