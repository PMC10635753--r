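---
title: "Methods: BYM smoothing and spatial cluster detection in bymap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: BYM smoothing and spatial cluster detection in bymap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bymap)
```

This vignette is the package's own account of its statistical machinery:
the model and its assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, the numerical choices
made where the design was genuinely open, and the known limitations.

## The smoothing model

Registry counts are modelled per area as

$$O_i \sim \mathrm{Poisson}(E_i\,\theta_i), \qquad
  \log\theta_i = \alpha + u_i + v_i,$$

where $E_i$ is the expected count under internal standardization, $u$ is
a spatially structured random effect with an intrinsic conditional
autoregressive (ICAR) prior on the rook-contiguity graph, and $v_i$ is
independent Gaussian heterogeneity. The ICAR prior is used in its
pairwise-difference form with binary weights,

$$p(u \mid \tau_u) \propto \tau_u^{r/2}
  \exp\Big(-\tfrac{\tau_u}{2}\sum_{i\sim j}(u_i-u_j)^2\Big),$$

with $r$ the rank of the graph Laplacian (number of areas minus number of
connected components). No graph-structure rescaling of the kernel is
applied; this is the classical Besag–York–Mollié formulation rather than
one of its rescaled successors. Assumptions worth stating plainly:

* **Counts are conditionally Poisson.** Overdispersion beyond what $u$
  and $v$ absorb is not modelled separately.
* **Contiguity is adjacency, not distance.** Two areas interact iff their
  boundaries share a segment of positive length; corner contact does not
  count (rook definition). Planar coordinates are assumed throughout —
  contiguity is topology, so no geodesic computation is needed or done.
* **The ICAR kernel is improper.** Identifiability comes from recentring
  $u$ to sum to zero every sweep, with $\alpha$ absorbing the mean.
* **Internal standardization.** $E_i = r\,\mathrm{pop}_i$ with
  $r = \sum O / \sum \mathrm{pop}$ over populated areas, so the state
  aggregate has ratio exactly 1 and smoothed risks are relative to the
  state average, not to an external reference population. Age–sex
  stratified expecteds are deliberately not the default: the workflow this
  package supports standardizes on the 15+ population base only.

### Parameters and defaults

| parameter | meaning | default | why |
|---|---|---|---|
| `n_iter` | total MCMC iterations | 500,000 | long single-chain schedule customary in registry mapping |
| `burn_in_fraction` | discarded share | 0.6 | conservative burn-in; leaves 200,000 sampling iterations |
| `thin` | keep every k-th draw | 20 | 10,000 kept draws; manageable storage, low autocorrelation |
| `n_chains` | independent chains | 1 | single-chain workflow, convergence judged by Geweke + plots |
| `shape, rate` | Gamma hyperpriors on $\tau_u,\tau_v$ | 0.5, 0.0005 | conventional vague disease-mapping prior; configurable |
| `min_age` | cohort inclusion (years) | 15 | adult oral-cancer registries exclude under-15s |
| `n_perm` | Moran/LISA permutations | 99,999 | minimum attainable pseudo p of $10^{-5}$ |
| `alpha` | LISA significance level | 0.05 | raw, uncorrected across areas (see limitations) |
| `snap` | boundary snapping grid (coordinate units) | 1e-9 | absorbs sub-tolerance slivers in digitized borders |

The kept-sample count `floor(n_iter * (1 - burn_in_fraction) / thin)`
must be at least 100; the default schedule keeps exactly 10,000.

## The sampler

Updates per sweep, in order:

1. each $u_i$ by univariate random-walk Metropolis against its full
   conditional (ICAR prior mean = neighbour average, prior precision
   $\tau_u m_i$); then sum-to-zero recentring with $\alpha$ absorbing the
   mean;
2. each $v_i$ by random-walk Metropolis;
3. $\alpha$ by random-walk Metropolis (flat prior);
4. a **reallocation pass**: each $u_i$ is redrawn exactly from its
   Gaussian full conditional holding $\eta_i = u_i + v_i$ fixed,
   $u_i \mid \cdot \sim N\!\big((\tau_u \sum_{j\sim i} u_j + \tau_v\eta_i)
   /(\tau_u m_i + \tau_v),\, (\tau_u m_i + \tau_v)^{-1}\big)$, with
   $v_i = \eta_i - u_i$. The likelihood depends on $u_i + v_i$ only, so
   this is an exact Gibbs step in a reparametrized coordinate. It exists
   because single-site random walks move the structured/unstructured
   split extremely slowly, which starves $\tau_u$ and $\tau_v$ of mixing —
   without it, precision chains show kept-scale lag-1 autocorrelations
   around 0.9 and fail Geweke on schedules that are otherwise ample;
5. $\tau_u, \tau_v$ by conjugate Gamma full conditionals (the ICAR shape
   uses the Laplacian rank $r$, not $n$).

Proposal step sizes adapt multiplicatively every 100 sweeps during
burn-in toward roughly 40% acceptance and are frozen afterwards, so the
post-burn-in kernel satisfies detailed balance. All randomness flows
through R's RNG: a fixed seed gives bit-identical kept draws.

Initialization: $\alpha_0 = \log(\sum O/\sum E)$ (zero under internal
standardization), $u = v = 0$, $\tau_u = \tau_v = 1$, step sizes 0.1.

### Validation against an exact posterior

The sampler is checked (tests and `scripts/acceptance.R`) against a
deterministic quadrature oracle on a 3-area chain graph with fixed
precisions: with $\alpha$ flat, the prior on $\eta = \alpha 1 + u + v$ is
flat along the constant direction and Gaussian on the sum-to-zero
complement with covariance $(\tau_u L)^{+} + I/\tau_v$, so the posterior
of $\eta$ is a 3-dimensional integral evaluated on a fine grid. Posterior
medians of $\theta$ must agree within 0.05; observed discrepancies are an
order of magnitude smaller. Further property checks: recovery of a known
log-risk surface on a 10×10 lattice with $E = 50$, $\sigma_u = 0.5$,
$\sigma_v = 0.1$ (correlation above 0.8 required); credible-interval
coverage of a flat truth across 50 seeded 4×4 replicates (at least 85%
required); and variance of smoothed medians never exceeding the variance
of raw ratios. These sizes keep the whole suite to a few minutes while
leaving wide margins to the thresholds.

## Significance, bands, and the "low-risk" rule

An area is **high** when the 2.5th percentile of its kept $\theta_i$
draws exceeds 1 and **low** when the 97.5th percentile is below 1
(equal-tailed credible interval). Published workflows sometimes describe
selecting both high- and low-risk areas "by the lower limit"; a lower
limit alone cannot identify low risk, so this package uses the upper
limit for the low class and documents the choice rather than guessing an
alternative rule. Choropleth bands split at medians of 1 and 2: at or
below the state average, up to 100% above it, and more than 100% above
it.

## Moran statistics

Global Moran's I uses row-standardized weights, so the spatial lag is the
neighbour mean and the expectation under no autocorrelation is
$-1/(n-1)$. The pseudo p-value is one-sided *toward the observed
deviation* from that expectation: $(\#\{I^* \text{ at least as extreme}\}
+ 1)/(n_{\mathrm{perm}} + 1)$. A consequence worth knowing: under a null
field, rejection at $p \le \alpha$ occurs in either tail, so the
realized type-I rate of this convention is approximately $2\alpha$ — the
test suite asserts the null rejection rate inside a band derived from
that fact, not around $\alpha$ itself.

Local statistics use $I_i = (z_i/m_2)\,\mathrm{lag}_i$ with
$m_2 = \sum z^2/n$, under which the average of the $I_i$ equals the
global $I$ on fully connected graphs (asserted to $10^{-12}$ in tests).
Significance is by conditional permutation — area $i$'s value held fixed,
the others permuted, one stream in fixed area order for reproducibility.
Ties at $z_i = 0$ or zero lag are classified by treating the zero as
positive, a measure-zero rule that only matters for constructed inputs.
Islands have zero lag and an undefined local statistic; they are always
`not_significant` and never propagate NaN. By default islands are
included in the mean/variance used for $z$, because the intended workflow
repairs all islands before analysis.

## Islands and manual repair

Automatic contiguity never links an island to anything. The pipeline
refuses to fit while islands remain, naming them and pointing to
`apply_manual_links()` — mirroring how registry studies connect offshore
or detached units to their nearest neighbour by hand, and keeping the
repair auditable (`manual_links` is carried in the weights object and its
GAL export). An explicit `allow_islands = TRUE` escape hatch instead
gives island areas an independent $N(0, 1/\tau_u)$ structured prior
(degree treated as 1, mean 0); it is a documented fallback, not a
recommendation.

## The synthetic-data generator

`simulate_geography()` builds an nx×ny unit-square lattice plus optional
detached island cells, assigns a deterministic seeded fraction of areas
zero population (emulating census localities without residents), and
jitters the rest ±20% around `base_population`. `simulate_icar_field()`
draws the structured surface *exactly* — eigendecomposition of the graph
Laplacian, covariance $\sigma_u^2 (D - W)^{+}$, sum-to-zero imposed — so
the generator and the MCMC fitter share no code path and a generator bug
cannot mask a fitter bug. `simulate_counts()` adds the Poisson layer.
`simulate_registry()` draws patient rows with the marginal structure of a
large oral/oropharyngeal cancer cohort: 71.5% male, age bands
2.9/40.8/56.3% (plus a tiny under-15 mass to exercise the exclusion
rule), site classes 52.1/46.3/1.6%, 59.3% deceased, survival months
geometric with rate 0.024 truncated at 478 so roughly 60% of deaths fall
within 36 months.

What the generator does **not** emulate: realistic coastline geography or
area-size heterogeneity, calibrated incidence rates, spatiotemporal
trends, covariate gradients (socioeconomics, remoteness), and any
patient-level spatial signal — survival is independent of area by design,
because the mapping model consumes area counts only; spatial mortality
structure belongs in the $\theta$ surface. Passing tests on synthetic
data therefore demonstrate correctness of the machinery, not fidelity of
any particular real-world risk surface.

## Numerical choices and degenerate inputs

* **Boundary comparison.** Coordinates are snapped to a 1e-9 grid;
  segments are compared by collinearity plus overlap length, so shared
  borders digitized with different vertex sets still register. Overlap
  must exceed the snap tolerance — corner contact yields exactly zero.
* **Uninformative expecteds.** Areas with zero population get
  $E_i = r \cdot 1$ (the state rate applied to a notional single person):
  positive, so the Poisson model stays defined; negligible, so it injects
  (almost) no information; flagged, so it is auditable. These areas are
  excluded from the conservation identity
  $\sum E_i = \sum O$ (populated areas), which holds to $10^{-9}$.
* **Month thresholds.** "Within 3/5 years" is operationalized as
  survival ≤ 36 / ≤ 60 months, because registry survival is
  month-granular; the strata partition deaths exactly.
* **Percentage rounding** is half-up to one decimal, matching how
  registry tables print shares (base R's `round()` half-to-even would
  disagree on exact .05 boundaries).
* **Geweke diagnostic.** $z = (\bar x_{first} - \bar x_{last}) /
  \sqrt{\hat s^2_{first} + \hat s^2_{last}}$ on the first 10% and last
  50% of a kept chain, with each $\hat s^2$ a Bartlett-windowed
  autocovariance estimate of the spectral density at zero (window width
  $\lfloor\sqrt{n}\rfloor$), guarded against degenerate (constant or
  too-short) chains. |z| < 1.96 is reported as "converged" for $\alpha$,
  $\tau_u$, $\tau_v$ and three randomly chosen area risks.
* **Empty and malformed inputs** fail loudly with the offending
  identifier: duplicate area codes, unknown registry area ids, dead
  records without survival time, dangling GAL neighbour ids (with line
  numbers), zero-variance fields in Moran tests, schedules keeping fewer
  than 100 draws.

## Known limitations

* Only the classical BYM prior: no Leroux/BYM2/proper-CAR alternatives,
  no covariates, no space–time interaction.
* Crude internal standardization by default; age–sex stratified expected
  counts are out of scope.
* LISA p-values are raw at $\alpha = 0.05$ across areas — deliberately
  uncorrected to match standard practice in the field; `alpha` is exposed
  rather than silently FDR-corrected.
* Queen or higher-order contiguity, distance-band weights and geodetic
  coordinate handling are out of scope; supply planar geometry.
* The Metropolis-within-Gibbs sampler targets the exact posterior but is
  a different kernel from BUGS-style slice/adaptive-rejection samplers;
  agreement is established distributionally (quadrature oracle), not
  draw-by-draw.
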