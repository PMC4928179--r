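---
title: "The Rg-distribution model: methods, parameters and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Rg-distribution model: methods, parameters and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rgdflex)
```

## The model

A solution SAXS measurement averages the scattering of every conformation
present. Recovering the full conformational distribution from a
one-dimensional curve is hopelessly underdetermined, so the model retains a
single structural coordinate — the radius of gyration $R_g$ — and asks only
for the distribution of sizes the molecule samples.

Two ingredients define the forward model:

* **Single-conformation scattering.** A conformation with radius of
  gyration $R_g$ scatters like a sphere of homogeneous density with the
  same $R_g$:
  $$I_S(q, R_g) = \left[\frac{3(\sin x - x\cos x)}{x^3}\right]^2,
  \qquad x = qR,\; R^2 = \tfrac{5}{3}R_g^2,$$
  normalized so $I_S(0, R_g) = 1$. The $R$–$R_g$ relation is the unique
  one consistent with a uniform solid sphere. Any constant contrast factor
  is absorbed by the fitted intensity scale, never by the form factor.

* **Size distribution.** $R_g$ follows a log-normal density
  $$P_{\mu,\sigma}(R_g) = \frac{1}{R_g\,\sigma\sqrt{2\pi}}
  \exp\!\left(-\frac{(\ln R_g - \mu)^2}{2\sigma^2}\right),$$
  supported on positive sizes, with $P(0) = 0$ by convention. $\mu$ is the
  log of the median $R_g$ (in Å) and $\sigma$ the log-scale spread.

The model intensity is the ensemble average
$I_{\mu,\sigma}(q) = \int P_{\mu,\sigma}(R_g)\, I_S(q, R_g)\, dR_g$,
and the flexibility metric is the differential entropy of the fitted
density,
$$S = -\int P \ln P \, dR_g = \mu + \tfrac12 + \ln(\sigma\sqrt{2\pi})
\quad \text{(nats)}.$$

The closed form is the standard log-normal differential entropy; the
package's tests verify it against adaptive quadrature of $-\int P\ln P$ to
$10^{-8}$ across the working parameter range rather than trusting the
algebra. Because $S$ is differential it is unbounded below:
$S \to -\infty$ as $\sigma \to 0$, a delta-like rigid ensemble. $\partial
S/\partial\mu = 1$ and $\partial S/\partial\sigma = 1/\sigma > 0$: entropy
grows with both the median size and, much faster at small spreads, with
the relative width of the distribution.

## The fit

`rgd()` minimizes a misfit over $(\mu, \sigma)$ with the overall scale
profiled out in closed form, leaving a two-dimensional search over the
same objective surface.

**Fit window.** The sphere reduction is credible only where intensity is
dominated by overall size: the low-$q$ region over which $I(q)$ falls by
about one order of magnitude. The default window therefore runs from
$q_{\min}$ to the first $q$ at which the lightly smoothed intensity drops
to $I(0)/10$ ($I(0)$ from Guinier analysis), capped at 0.3 Å⁻¹, and is
fully overridable via `q_window`. Fitting far beyond this decade would ask
the sphere model to explain internal-structure scattering it cannot
represent.

**Objective.** The default is log-intensity least squares,
$\frac1n\sum[\ln(c\,I_{\mu,\sigma}(q_i)) - \ln I_{\exp}(q_i)]^2$, which
weights the fitted decade of dynamic range evenly. An error-weighted
$\chi^2$ (`objective = "chi2"`) is available when the profile carries
per-point uncertainties. On well-behaved data the two agree; the log form
is the default because deposited error columns are of very uneven quality.

**Optimizer and starts.** The objective is multimodal in $\sigma$ (the
sphere form factor oscillates), so a deterministic multi-start is used:
bounded quasi-Newton (`L-BFGS-B`) from the lattice
$\mu \in \{\ln R_g^{\text{Guinier}} \pm 1\} \times
\sigma \in \{0.05, 0.2, 0.5, 1.0\}$, with bounds
$\mu \in [\ln 2, \ln 500]$ (median sizes 2–500 Å spans everything from
peptides to the largest depositable assemblies) and
$\sigma \in [10^{-3}, 2]$. The lower $\sigma$ bound keeps the entropy
finite; the upper keeps the quadrature mass on a representable grid. Since
the objective is non-negative, the start loop exits early if a start
reaches an essentially exact fit ($< 10^{-12}$), which cannot be improved.

**Quadrature.** The ensemble average uses trapezoid quadrature on 400
log-spaced nodes spanning the $[10^{-6}, 1-10^{-6}]$ quantiles of the
*current* $(\mu,\sigma)$, so the grid follows the distribution wherever the
optimizer moves. An explicitly supplied grid must carry at least 99.99% of
the mass or a coverage error is raised. The $10^6$-draw Monte-Carlo
cross-check in the test suite bounds the quadrature error well inside the
sampling error of real data; normalization at $q = 0$ is exact to about
$10^{-4}$ for the broadest distributions fitted.

**Numerical details.** The sphere amplitude switches to the series
$1 - x^2/10 + x^4/280$ below $x = 10^{-2}$: the direct expression's
$O(x^3)$ numerator suffers catastrophic cancellation at small $x$ (enough
to push intensities above 1 by $10^{-8}$ near $10^{-4}$), while at the
chosen switch the truncated series is exact to better than $10^{-16}$.
Model intensities are floored at `1e-300` before logs. Guinier $R_g$ is
found by fixed-point iteration of fit-window selection ($qR_g \le 1.3$)
and regression, to $10^{-6}$ relative tolerance, max 50 iterations;
measured $q = 0$ points are dropped rather than read as $I(0)$.

**Error estimate.** `entropy_error()` propagates the reported per-point
intensity errors by resampling: additive Gaussian perturbations with the
reported standard deviations, independent across $q$, followed by a refit.
Refits start from the original optimum with bracketing $\sigma$ starts
(half and double), not the full start lattice — the perturbations are
small, so the basin of attraction does not move; the full lattice remains
available through `rgd()`'s arguments. Correlated noise models are out of
scope. With 1% relative errors the entropy spread is a fraction of a
percent of $S$ (the acceptance script recomputes this with 200 resamples).

## Synthetic data: what it emulates and what it does not

`ensemble_spec()` / `generate_profile()` build profiles from known
ground-truth ensembles: delta components (single conformations, exact
sphere curves), log-normal components (the model's own assumption), and
finite mixtures (two-state open/closed systems). Defaults are chosen to
resemble deposited protein data: a 400-point linear grid on
$q \in [0.005, 0.35]$ Å⁻¹ — extending past the 0.3 Å⁻¹ coverage usually
demanded for a meaningful Kratky analysis — and multiplicative Gaussian
noise with per-point sd equal to `noise_level` × intensity (1% by
default), the crude counting-statistics model that matches how deposited
error columns behave at low-to-mid $q$.

`generate_suite()` writes a three-member demonstration set with increasing
median size and increasing relative spread:

| member     | $\mu$      | $\sigma$ | true $S$ |
|------------|------------|----------|----------|
| folded     | $\ln 16$   | 0.06     | 1.38     |
| partial    | $\ln 22$   | 0.20     | 2.90     |
| disordered | $\ln 35$   | 0.45     | 4.18     |

The sizes are typical of a small folded domain, a partially disordered
two-domain protein, and an expanded IDP; the spreads give clearly
separated entropies whose *ordering* (folded < partial < disordered) is
the property the tests assert. The absolute entropies of real proteins in
these classes depend on the actual conformational ensembles and are not
reproduced by construction here.

What passing these tests shows: the estimator recovers known log-normal
truths essentially exactly without noise, degrades gracefully at realistic
noise, and orders heterogeneity correctly. What it does not show: that
real molecules are log-normal in $R_g$, that the sphere reduction is
adequate at wide angles (it is not — hence the low-$q$ window), or that
instrument effects (smearing, buffer mismatch, inter-particle
interference) are handled; none of those are modelled.

## Diagnostics

The transforms are pointwise and never smooth the data: Kratky
($q^2I$ vs $q$), dimensionless Kratky ($(qR_g)^2I/I(0)$ vs $qR_g$, with
the folded-state landmark at $(\sqrt3, 3e^{-1} = 1.104)$), Porod
($q^4I$ vs $q$) and Porod-Debye ($q^4I/I(0)$ vs $q^4$, exponent 3
available for diagnosing $q^{-3}$ decays). The $R_g$ and $I(0)$ used for
normalization default to Guinier estimates — which $R_g$ convention to use
is genuinely open (pair-distance-derived values are a common alternative),
so both are accepted as explicit arguments.

Plateau detection is a stated heuristic for an inherently visual
judgement: the onset is the first local maximum of the Porod ordinate
(median-smoothed for peak finding only), and the curve beyond the onset is
scanned for any window spanning 25% of the x-range whose fitted relative
change is within `slope_tol = 0.1`; the flattest window is reported. The
scan (rather than testing only the window at the onset) is deliberate: for
sphere-like curves the first Porod peak overshoots the plateau and relaxes
onto it, so the flat region sits beyond the first oscillation, not at it.
Both thresholds are exposed, and borderline calls should be inspected by
eye.

Entropy classification uses the empirical quartile cut-points 3.37 / 3.86
/ 4.26 nats with left-inclusive boundaries. The middle boundary is
reported slightly inconsistently in the survey this scheme derives from
(3.86–4.26 vs 4.27); 4.26 is adopted because it is the explicitly stated
upper-quartile rule.

## Problem sizes

The package's own test suite and acceptance script run noiseless recovery
on a 5×5 $(\mu, \sigma)$ grid, a $10^6$-draw Monte-Carlo forward-model
check, a 200-resample error propagation at 1% noise, and three-profile
suite fits on 400-point curves — sizes chosen so each individual check
completes in seconds to a few minutes on a single core while leaving the
Monte-Carlo standard errors far below the tolerances being asserted.

## Known limitations

* The sphere reduction ignores shape: two ensembles with identical $R_g$
  distributions but different anisotropy are indistinguishable.
* Entropies are point estimates with resampling errors; there is no
  posterior over $(\mu, \sigma)$, and no ensemble reconstruction.
* The default window logic assumes a monotone-decaying low-$q$ decade;
  aggregated or interference-affected data violate that and should be
  cleaned upstream.
* Deposited error columns are trusted as-is by `entropy_error()`;
  over- or under-stated errors propagate directly into the entropy error.
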