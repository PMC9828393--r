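---
title: "Modelling species' responses along environmental gradients with gradresp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling species' responses along environmental gradients with gradresp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

A species' abundance along a broad-scale gradient (depth, latitude,
temperature, ...) is typically unimodal: it rises to a realised optimum and
falls away, often asymmetrically, often with far more zeros than a textbook
count distribution would produce. `gradresp` models one species along one
gradient as

$$ y_i \sim P(\mu_i, \theta_E), \qquad \mu_i = f(x_i \mid \theta_M), $$

with the observations drawn independently.  The two components are chosen
separately: a parametric mean curve $f$ whose parameters are directly
interpretable (modal position $m$, maximum height $H$, spread, asymmetry,
peakedness), and an error distribution $P$ suited to how abundance was
actually measured (counts, biomass/density, percent cover, or
presence/absence).  The identity link is used throughout: the mean curve *is*
the distribution mean, so $H$ is read in the data's own units.  For
zero-inflated families, $\mu_i$ always denotes the mean of the non-excess-zero
component, and $E[Y_i] = (1 - \pi_i)\,\mu_i$.

## Mean curves

Seven families are available (`mean_families()`): `constant`, `uniform`,
`gaussian`, `mixgaussian` (two-component Gaussian mixture for bimodal
responses), `beta` (bounded support $(a, b)$ with hard edges), `hof`
(product of two logistic flanks), and `sech`, the workhorse:

$$ f(x) = \frac{H}{H_m}\, e^{\,r p u}\ \mathrm{sech}(u)^p, \qquad
   u = \frac{x - m}{s} + \operatorname{artanh} r. $$

with $H_m = e^{\,r p \operatorname{artanh} r} (1 - r^2)^{p/2}$.  The
anchoring constants are not free parameters; they exist so that the free
parameters mean exactly what a field ecologist wants them to mean.  Setting
$\partial_x \log f = \frac{p}{s}(r - \tanh u) = 0$ gives $\tanh u = r$, i.e.
a unique stationary point at $u^\ast = \operatorname{artanh} r$, which the
shifted argument places exactly at $x = m$; since
$\mathrm{sech}(\operatorname{artanh} r) = \sqrt{1 - r^2}$, the normaliser
makes $f(m) = H$ exactly.  The sign convention of the offset is therefore
*derived* from these two invariants rather than assumed, and a property test
checks both against a brute-force maximiser over thousands of random
parameter draws.  For $r > 0$ the right tail decays at rate $p(1-r)/s$
against $p(1+r)/s$ on the left — a broader right-hand tail — and $p$
controls peaked ($p < 1$ is flatter near the mode for fixed tails) versus
flattened shapes.  Simpler nested models fix $p = 1$ and/or $r = 0$ a
priori: `sech_p1`, `sech_r0`, `sech_p1_r0` are separate families with
correspondingly fewer free parameters (and smaller AICc penalties).

Two parameterisations are deliberately our own design, since only the shape
class is standard:

* **beta**: $f(x) = H \left(\frac{x-a}{m-a}\right)^{\alpha}
  \left(\frac{b-x}{b-m}\right)^{\gamma}$ on $(a, b)$, zero outside (boundary
  ties resolve to 0), with the mode $m = (\alpha b + \gamma a)/(\alpha +
  \gamma)$ derived and the height at the mode anchored at $H$.
* **hof**: $f(x) = H\, g(x) / \max_{[x_{\min}, x_{\max}]} g$ with
  $g(x) = \mathrm{logit}^{-1}(b_1 (x - a_1)) \cdot
  \mathrm{logit}^{-1}(-b_2 (x - a_2))$, rates $b_1, b_2 > 0$.  The maximum
  is located numerically (dense grid plus golden-section refinement) on the
  data's x-range, so the reported $H$ equals the realised maximum there;
  monotone and plateaued shapes arise when one flank is effectively flat
  inside the range.

## Error distributions

Twenty families (`err_families()`), organised by data type:

* **count**: Poisson; negative binomial with $\mathrm{Var} = \mu + \mu^2/\phi$
  (so $\phi \to \infty$ recovers Poisson — the direction in which "less
  over-dispersed" should point); zero-inflated versions of both.
* **biomass/density**: gamma (shape $\alpha$), inverse Gaussian (shape
  $\lambda$) within zero-inflated wrappers, and Tweedie with power
  $\rho \in (1, 2)$ — a compound Poisson–gamma with an exact atom at zero,
  evaluated by series summation over the Poisson event count with adaptive
  truncation (the truncation window is sized from the dominant index
  $j^\ast \approx y^{2-\rho} / (\phi(2-\rho))$ so dropped terms are
  negligible at double precision).  Correctness is guarded by quadrature
  (atom + density integrates to 1) and Monte-Carlo moment oracles rather
  than a closed form, which the family does not have.
* **cover**: binomial (requires a declared trials count per observation,
  e.g. points per quadrat — a configuration field, since nothing in the data
  itself reveals it), and the tail-adjusted beta (TAB): a Beta distribution
  with mean $\mu$ and precision $\psi$ whose mass below $\delta$ and above
  $1 - \delta$ is spread uniformly over those bands, so cover recorded as
  exactly 0 or 1 has positive density.  $\delta$ models instrument rounding
  and is a fixed constant (default 0.01), not an estimated parameter; a
  sensible value is half the smallest positive increment the recording
  method can produce.
* **binary**: Bernoulli.

Zero-inflation comes in three flavours.  A constant excess-zero probability
$\pi$; a *linked* probability
$\operatorname{logit} \pi_i = \gamma_0 + \gamma_1 \log \mu_i$ reflecting the
occupancy–abundance relationship (more zeros where the species is scarce, so
$\gamma_1$ is expected negative); and a directly linked variant
$\operatorname{logit} \pi_i = \gamma_0 + \gamma_1 \mu_i$ (`.mu` families).
The degeneracy ladder is exact by construction: $\pi = 0$ reproduces the
base family's log-density identically, and $\gamma_1 = 0$ reproduces the
constant-$\pi$ family at $\pi = \mathrm{logit}^{-1}(\gamma_0)$.

One subtlety: for ZITAB the recorded value 0 is both the zero atom and a
point with positive band density.  The likelihood contribution at $y = 0$
is the mixed form $\log(\pi + (1-\pi) f_{TAB}(0))$, which keeps the
$\pi = 0$ ladder exact and the total mass 1 (the band density at the single
point 0 carries no mass).

A second subtlety: $\mu = 0$ (which bounded mean curves produce outside
their support) is treated as the degenerate all-mass-at-zero limit for
every family — contribution 0 when $y = 0$, $-\infty$ otherwise.  Without
this convention the beta and uniform mean functions could never be fitted
to data whose x-range exceeds their support.

## Fitting

Estimation is maximum likelihood on an unconstrained scale: log for
strictly positive parameters, artanh for $r$, logit for $\pi$,
$\operatorname{logit}(\rho - 1)$ for the Tweedie power, and interval bounds
encoded as $(a, \log(b - a))$ so $a < b$ can never be violated.  Round
trips are the identity to $10^{-12}$.

Starting values come from the method of moments applied to a smoothed
curve: a smoothing spline (df capped at 8; a binned running mean when there
are fewer than 8 distinct x values) approximates the mean response, its
maximum seeds $H_0$ and $m_0$, and the second moment of the normalised
positive part seeds $s_0$; $r_0 = 0$ and $p_0 = 1$ start at their neutral
values.  The zero-inflation probability starts from the zero fraction where
the smoothed mean is below its median; NB dispersion from moment matching
of the residual variance; link coefficients from a logistic regression of
the zero indicator on the (log) smoothed mean.  Any smoother passing the
initialisation sanity checks would do; the spline was chosen because it
needs no tuning by the user.

Optimisation is two-stage: simulated annealing (`optim`, method `"SANN"`,
default budget 300 objective evaluations, temperature 2, parameter scales
from the starting point) to escape poor basins, then quasi-Newton
refinement (BFGS, relative tolerance $10^{-8}$), with `nlminb` as a bounded
Newton-variant fallback when BFGS fails or does not converge.  Infeasible
parameter vectors (non-finite values, means outside the family's support)
receive a large penalty ($10^{10}$) instead of raising errors, so the
stochastic stage can traverse them.  The refined solution never reports a
worse objective than the annealing solution, and total failure of all
stages returns the best point seen flagged `converged = FALSE` rather than
erroring.  Because the choice of optimiser and starting values can matter,
a multi-start option jitters the initial values on the unconstrained scale
(`restarts`); the default is a single start, which the stability tests
(independent optimiser seeds agreeing to 0.01 log-likelihood units) support
for these problem sizes.  All randomness in a fit flows from one integer
seed.  Gaussian-mixture fits are reported with components ordered by
location to remove label switching.

Very sparse species are flagged before fitting: the rare-species gate warns
(but does not refuse) when fewer than 1% of responses are non-zero — a rule
of thumb; the threshold is configurable down to zero because the decision
properly belongs to the analyst.

## Model selection

`fit_grid()` fits every requested mean-by-error combination compatible with
the data type, computes AIC, AICc and BIC, and ranks converged fits by
AICc.  Ties break by smaller parameter count, then lexicographic family
names — an arbitrary but deterministic order.  Non-converged fits are kept
in the table, flagged, and excluded from ranking.  `delta_aicc_profile()`
fixes the error family at the best model's and tabulates how much each mean
shape loses; `grid_tally()` cross-tabulates best pairs across many species.
Fixed-parameter sech variants count as distinct families only when
explicitly listed in the grid.

## Uncertainty

Three routes, one contract (`gradresp_uncertainty`):

* **Observed information**: numerical Hessian of the negative
  log-likelihood at the optimum on the unconstrained scale; its inverse is
  the covariance.  Natural-scale SEs use the delta method; confidence
  intervals are computed on the unconstrained scale and *endpoints* are
  mapped back, which keeps them inside parameter domains (an SE-symmetric
  interval on $\log H$ maps to an asymmetric, strictly positive interval
  for $H$).  A singular or indefinite Hessian flags the result unusable
  with a diagnostic instead of crashing.
* **Jackknife**: repeated fractional subsampling, not leave-one-out — 50
  replicates of a random quarter of the data by default, drawn
  proportionally within equal-width gradient strata so each replicate spans
  the full range.  The delete-d scaling convention used is
  $SE = sd(\hat\theta_{(r)}) \sqrt{f/(1-f)}$ with kept fraction $f$; with
  $f = 1/4$ this is $sd/\sqrt{3}$.  The convention is a choice; the
  coverage experiment is the arbiter of whether it is calibrated, and the
  method-agreement test (jackknife within a factor 2 of the information SE)
  guards it.
* **Bootstrap**: nonparametric pair resampling with percentile intervals.

Replicates failing the rare-species gate or the refit are dropped and the
effective replicate count reported.

## Simulation experiments

`sim_scenario()` + `generate_dataset()` realise the model exactly: x from a
uniform or equally spaced design, $\mu = f(x)$, $y$ sampled from the error
family (zero-inflation by Bernoulli gating).  Every experiment is a pure
function of (scenario, seed).

The generator emulates the study conditions the framework targets — a
unimodal (optionally asymmetric, optionally zero-inflated) mean response
sampled at independent stations along one gradient, with i.i.d. errors from
the declared family.  It does not emulate spatial or temporal
autocorrelation, measurement error in x, varying sampling effort,
inter-species interactions, or dispersion varying along the gradient; tests
passing on generated data therefore validate the estimation machinery, not
the adequacy of the model class for any particular field dataset.

The reference scenario throughout is sech($H = 50$, $m = 100$, $s = 20$,
$r = 0$, $p = 1$) on $x \in [0, 200]$ with NB($\phi = 2$) errors — a
strongly over-dispersed count response with a well-interior mode —
switching to $r = 0.5$ for asymmetry experiments and adding ZI($\pi = 0.4$)
for zero-inflation arms.  Desk-scale budgets are used: 500 replicates at
$n = 500$ for the headline coverage experiment (Monte-Carlo SE just under
one percentage point at 95% nominal), 200 replicates for bias contrasts,
50 for model-selection majorities, with smaller pilot sizes inside the
routine unit tests.  These sizes are the package's own choice of
experiment scale; they are smaller than a publication-grade study and the
test tolerances are set accordingly.

The bias experiment reproduces the qualitative contrast that motivates the
flexible curve: under asymmetric truth a symmetric Gaussian fit drags
$\hat m$ towards the heavier tail and under-estimates $H$, while the sech
fit stays unbiased (and stays unbiased when zero-inflation is added and
modelled).

## Numerical choices and limitations

* The sech curve is evaluated on the log scale
  ($\log \mathrm{sech}(u) = \log 2 - |u| - \log(1 + e^{-2|u|})$), stable for
  $|u|$ in the hundreds.
* AICc is undefined at $n \le k + 1$ and reported `NA` with a warning.
* The base family of a ZI pair sits at the $\pi = 0$ boundary of the
  interior logit parameterisation, so a ZI fit to zero-inflation-free data
  approaches but cannot exactly attain the base fit's likelihood; nesting
  holds to optimizer tolerance.
* Uniform and beta bounds are free parameters; initial values clip them
  just outside the observed x-range (padded 2–5%), since data carry no
  information about bounds beyond the range.
* Estimates from $n \le 20$ observations are highly variable, particularly
  for asymmetric responses — the tiny-sample test shows an order-of-
  magnitude inflation of $sd(\hat m)$ at $n = 10$ versus $n = 200$.
* With all five sech parameters free, $H$, $s$ and $p$ are correlated at
  moderate $n$; $\hat H$ has noticeably larger sampling variance than under
  the $p = 1$ sub-model.  When peakedness is not itself of interest,
  `sech_p1` is the more efficient choice — the same reasoning that
  motivates fixing parameters a priori in the family definitions.
* Out of scope by design: multi-gradient (niche surface) models, mixtures
  of sech/HOF/beta curves, more than two Gaussian components, hurdle and
  truncated/under-dispersed families, dispersion varying along the
  gradient, and Bayesian estimation.

## A worked example

```{r example}
library(gradresp)

scenario <- sim_scenario("sech", c(H = 50, m = 100, s = 20, r = 0.4, p = 1),
                         "zinbl", c(phi = 2, g0 = 2, g1 = -1),
                         n = 800, xlim = c(0, 200))
d <- generate_dataset(scenario, seed = 1)

fit <- fit_response(d, "sech", "zinbl", control = fit_control(seed = 1))
fit
information_se(fit)

grid <- fit_grid(d, c("gaussian", "sech", "hof"),
                 c("nb", "zinb", "zinbl"), control = fit_control(seed = 1))
grid
delta_aicc_profile(grid)
```
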