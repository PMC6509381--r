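---
title: "Methods: niche modelling, sensitivity analysis and change attribution in coastniche"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: niche modelling, sensitivity analysis and change attribution in coastniche}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`coastniche` estimates where a coastal species can live, how sensitive that
estimate is to each environmental predictor, and how much of the projected
habitat change under warming and sea-level rise is attributable to each
driver alone, to both, or only to their combination. This vignette documents
the statistical machinery, the tunable parameters, the numerical choices,
and the limits of what the synthetic test bed can demonstrate.

## The maximum-entropy niche model

Presence-only data tell us where a species was seen, not where it was absent.
The maximum-entropy approach models the distribution of presences across the
landscape as the Gibbs distribution over background cells

$$P_\lambda(x) = \frac{\exp(\lambda \cdot f(x))}{Z_\lambda},\qquad
Z_\lambda = \sum_{x \in \text{background}} \exp(\lambda \cdot f(x)),$$

where $f(x)$ is a vector of features of the environment at cell $x$. The
coefficients minimize the penalized log loss

$$\ell(\lambda) = -\frac{1}{n}\sum_{i=1}^{n} \lambda \cdot f(x_i)
  + \log Z_\lambda + \sum_j \beta_j |\lambda_j|,$$

the convex dual of entropy maximization subject to relaxed moment
constraints. The L1 penalty both regularizes and selects: unneeded features
get exactly zero weight.

**Features.** Continuous predictors are min–max scaled to $[0,1]$ on the
training background and contribute linear ($z$), quadratic ($z^2$) and hinge
features — forward $\max(0,(x-k)/(\max-k))$ and reverse
$\max(0,(k-x)/(k-\min))$ at `n_hinge_knots` knots per direction placed
evenly and strictly inside the training range. Categorical predictors
(`Drainage`, `Tclass` in the canonical layer set) always contribute one
indicator per observed level, whatever the feature-class setting. At
projection time feature inputs are clamped to the training range, the
standard convention that keeps extrapolated features inside $[0,1]$.

**Penalties.** $\beta_j = \mathrm{rm}\cdot\sqrt{s^2_j/n}$ with $s^2_j$ the
feature's variance over the presences and $n$ the presence count — variance
shrinks the penalty as evidence accumulates, and the regularization
multiplier `rm` scales all of it. A variance floor of $10^{-4}$ keeps
near-constant features from escaping the penalty entirely. The exact penalty
schedule of any particular MaxEnt release is version-dependent, so the
formula is deliberately simple and `rm` is the tuned quantity.

**Optimization.** Accelerated proximal gradient (FISTA) with backtracking
line search and a momentum restart whenever a step would increase the
objective, so the objective sequence is monotone. Iteration stops when the
objective decrease falls below `convergence` (default $10^{-5}$) or at
`max_iter` (default 1000); non-convergence is flagged on the returned
object, not an error. Convexity means restarts land on the same objective
value — a property the test suite asserts to $10^{-6}$.

**Outputs.** `raw` is $P_\lambda$ itself (summing to 1 over the training
background); `cloglog`, the scale used for thresholding, is
$1 - \exp(-e^{H}\cdot \mathrm{raw})$ with $H$ the entropy of the fitted raw
distribution; the optional `logistic` output uses the prevalence parameter
`tau` (default 0.5). cloglog is a monotone transform of raw, so rankings —
and therefore AUC — agree between the two.

**Defaults** (all in `maxent_config()`): 10,000 background points sampled
uniformly without replacement from unmasked cells, 1,000 iterations,
convergence $10^{-5}$, prevalence 0.5, 50 hinge knots per direction.

## Tuning, evaluation and thresholds

`tune_maxent()` fits every combination of a regularization-multiplier list
and a feature-class list and scores each by
$\mathrm{AICc} = 2k - 2\ln L + 2k(k+1)/(n-k-1)$, with $k$ the number of
nonzero coefficients and $\ln L$ the sum of log raw scores over the
presences. The combination with the smallest AICc wins; ties break toward
fewer parameters, then smaller `rm`, then feature-class order, so the
selection is deterministic. AICc is undefined (reported infinite, excluded)
when $n - k - 1 \le 0$.

Evaluation uses the rank-based AUC (ties count one half) and the true skill
statistic $\mathrm{TSS} = \text{sensitivity} + \text{specificity} - 1$,
with sensitivity the fraction of presence scores at or above the threshold
and specificity the fraction of background scores below it. Three cloglog
threshold rules are computed on training scores:

* **MTSS** — the observed score maximizing sensitivity + specificity
  (smallest maximizer on ties);
* **PTSS** — the 10th percentile of presence scores, linearly interpolated
  (the variant that omits the lowest 10% of presences is identical up to
  interpolation; the interpolated percentile was chosen);
* **ETSS** — the observed score minimizing |sensitivity − specificity|
  (smallest on ties).

The three are combined into a single binarization threshold by TSS-weighted
averaging, $\sum_r t_r \mathrm{TSS}_r / \sum_r \mathrm{TSS}_r$. The
weighting itself is a design choice: "based on the TSS evaluation" admits
several readings, and weights proportional to each rule's TSS is the most
direct one. An unweighted mean is available by configuration and is also the
automatic fallback (flagged) if every rule's TSS is non-positive. The
combined threshold always lies within the range of the three rules.

Two screening steps precede tuning. A Spearman collinearity screen
iterates: among retained variables, find the pair with the largest
$|\rho|$ exceeding both thresholds (defaults $|\rho| > 0.8$,
$p < 0.001$), drop the member with the larger mean absolute correlation to
everything else (standard practice; which member to drop is otherwise
unspecified), repeat. A shadow-feature screen — a simplified Boruta — then
appends a permuted copy of every column, fits a random forest
(presence vs background, via `ranger`), counts rounds in which a real
column beats the best shadow, and confirms variables whose hit count beats
a fair coin at $\alpha = 0.01$ (one-sided binomial). Full Boruta
tentative-resolution is out of scope; the binomial shadow-max scheme keeps
the decision deterministic under a seed.

## Extended-FAST sensitivity analysis

The fitted model is treated as a deterministic function of its inputs and
decomposed by variance. For factor $i$, all inputs move along sinusoidal
search curves

$$x_j(s) = F_j^{-1}\!\left(\tfrac12 + \tfrac{1}{\pi}
  \arcsin \sin(\omega_j s + \varphi_j)\right),\qquad
  s_k \in (-\pi, \pi],\; k = 1,\dots,N_s$$

with the factor of interest at the peak frequency $\omega_i = \omega_{\max}$
and the complementary factors at distinct low frequencies
$\le \omega_{\max}/2M$. With $N_s = 2M\omega_{\max} + 1$ curve points per
factor and $m$ factors, the design costs $(2M\omega_{\max}+1)\,m$ model runs
(`efast_sample_size()`); at the full-scale setting $M = 4$,
$\omega_{\max} = 416$, $m = 15$ that is 49,935 evaluations. The first-order
index $S_F$ is the spectral mass at harmonics $p\,\omega_{\max}$,
$p = 1..M$, over the total variance; the total index is
$S_T = 1 - V_{\sim i}/V$ with $V_{\sim i}$ the mass at all frequencies up to
$\omega_{\max}/2$. $S_T - S_F$ is the share a variable contributes only
through interactions. Spectra come from one FFT per block; $N_s$ odd makes
$M\omega_{\max}$ exactly the Nyquist index.

**Complementary frequencies** are spread evenly over $1..\lfloor
\omega_{\max}/2M\rfloor$. Both extremes of that band fail: clustering them
at $1, 2, \dots$ makes pairs of complementary factors trace closed
low-order Lissajous curves whose cross moments no longer match the product
measure (visible as a collapsed variance estimate), while pushing them to
the top of the band leaks their higher harmonics past the
$\omega_{\max}/2$ cutoff into the factor's share. If the band cannot hold
$m-1$ distinct integers the design is rejected with the minimum required
$\omega_{\max}$; setting `allow_cycling = TRUE` reuses frequencies instead,
with a warning, at the cost of conflating the cycled factors'
complementary contributions. The random phases $\varphi_j$ are seeded;
repeats with different phase seeds (default 5) give the spread reported
next to each index.

**Input distributions.** Each layer's marginal is fitted by closed-form
maximum likelihood over the candidate families uniform, normal and — for
positive data — lognormal, and checked by a chi-square test on 20
equiprobable bins; the best-fitting family is kept if it passes at `alpha`,
otherwise the empirical quantile function is used. Categorical layers use
observed level frequencies; constant layers are flagged degenerate and
carry zero sensitivity. The default `alpha` is 0.01; the workflow this
mirrors quotes both a "1% level" and a $p < 0.005$ pass criterion, so the
level is configurable rather than hard-coded. Factors are sampled
independently from their marginals — the standard FAST workflow — which
ignores the spatial correlation between layers; indices are therefore
sensitivities of the model, not of the geographically realizable
environment. That caveat applies equally to the workflow this package
re-implements.

The estimators are validated against the Ishigami function's closed-form
Sobol indices, a Monte Carlo pick-freeze oracle, additive no-interaction
models, and single-factor identities; the acceptance suite requires
agreement within ±0.05 at full scale and ±0.03 for the additive check.

## Scenario projection and Venn attribution

Three futures modify the current stack: **CLC** applies per-layer
offsets/scales to climate layers only; **SLR** lowers elevation by the rise
(default 1 m) and masks cells dropping below 0 m as inundated; **CCS**
applies both. The two operators commute (disjoint layer support), and masks
only grow. Each scenario's cloglog map is binarized at the combined
threshold. A cell masked under some but not all scenarios — inundated under
SLR/CCS — counts as *unsuitable* there, not as missing data: inundation is
habitat loss. Only cells masked under every scenario are nodata.

With habitat sets $H_{CUR}, H_{CLC}, H_{SLR}, H_{CCS}$, the change between
current and combined futures splits as unchanged
$= H_{CCS}\cap H_{CUR}$, gain $= H_{CCS}\setminus H_{CUR}$, loss
$= H_{CUR}\setminus H_{CCS}$. Within the gain, a cell also gained under
both single-driver scenarios is **shared**; under exactly one, that
driver's **pure** effect; under neither, **coupling** — change that
materializes only when the drivers act together.

For losses two conventions are implemented, and the difference deserves
attention. The literal reading of the published set equations classifies a
lost cell by its *membership* in the single-scenario habitat sets: retained
under both CLC and SLR is shared, retained under exactly one is that
driver's pure effect, retained under neither is coupling
(`convention = "as_printed"`, the default). The mirror of the gain logic
would instead classify by *loss under* the single scenarios: lost under
both is shared, lost under exactly one is that driver's pure effect, lost
under neither is coupling (`convention = "symmetric"`). The two label the
same four regions and are an exact permutation of each other — printed
shared ↔ symmetric coupling, printed pure-climate ↔ symmetric
pure-sea-level-rise — so totals per direction are identical and only the
labels move. The package defaults to the literal equations and exposes the
mirror because the verbal phrase "caused by pure effects of X" arguably
describes it; both are tested cellwise against hand-enumerated oracles over
all 16 membership combinations.

Areas are cell counts times cell area; percentages are of the changed total
per direction, rounded half-up to two decimals so that published-style
tables reproduce exactly; components always sum to the changed total by
construction.

## The synthetic landscape

The generator emulates the data geometry of a coastal niche study: 15
co-registered 1-km layers — seven bioclimatic, six soil (two categorical
with four levels), elevation — on a default 100 × 200 grid. Continuous
fields are Gaussian-smoothed white noise (the simplest controllable
autocorrelated field; `autocorr` is the kernel sd in cells) rescaled to
realistic ranges (e.g. diurnal range 4–14 °C, pH 4.5–9). Elevation is a
linear ramp from −2 m at the western sea edge to +20 m landward plus
smoothed noise; cells below 0 m are sea, coded as nodata mask rather than a
value, so inundation = masking = loss of terrestrial area. Presences are
drawn with probability proportional to a known *true* suitability surface:
the cloglog of a linear predictor on standardized Bio02 and Elevation with
coefficients (−4, −8) and intercept −11. Those values confine suitable
habitat to a thin low-elevation, cool-diurnal-range band of roughly a tenth
of the strip — the geometry of an intertidal specialist, and a regime in
which presences and background are well separated, so recovery tests have a
sharp target. The band fraction follows from the construction
($\approx \Phi(b_0/\lVert w\rVert)$ for standardized predictors), not from
trial and error against any particular metric.

What the generator does *not* emulate: real coastline geometry, map
projections, spatially varying sea-level rise, correlation structure copied
from real layers, sampling bias in occurrences, or dispersal. Passing tests
therefore demonstrate that the estimators are correct and the pipeline is
deterministic — not that the defaults are calibrated to any real coast.

## Pipeline, determinism and problem sizes

`run_pipeline()` executes synthesize/ingest → thin → (optional regional
split at a y-threshold, boundary records going north) → Spearman and shadow
screening → AICc tuning → final fit → cross-validation, thresholds → eFAST
→ scenario projection → decomposition → reports. One master seed is fanned
out (via one seeded `sample.int`) into named per-stage seeds, so any stage
can be re-run in isolation and the whole run is bit-reproducible; the run
manifest (YAML) records the full configuration, per-stage wall-clock and
output checksums, and the failure point if a stage stops the run.

Default pipeline sizes are chosen so a full run takes on the order of a
minute: 100 × 200 cells, 300 presences, RM ∈ {1..4} × FC ∈ {L, LQ, LQH},
10,000 background points, 10 hinge knots per direction, 10-fold
cross-validation, and a reduced eFAST with $\omega_{\max} = 32$
($N_s = 257$) and 5 phase repeats. At $\omega_{\max} = 32$ the
complementary band holds only 4 distinct frequencies, so the pipeline
enables frequency cycling (with its documented bias); full-scale runs at
$\omega_{\max} = 416$ need no cycling for 15 factors. The test suite uses
smaller grids still (down to 8 × 8 maps for the attribution oracles and a
30 × 50 pipeline), with every fixture generated in code.

Occurrence thinning defaults to one raster cell: a one-degree thinning cell
(~111 km) is implausible against a 1-km working grid with coastal records,
so the cell size is a configuration parameter with the conservative
default, and coarser thinning remains available.

## Known limitations

* The L1 penalty schedule is a simplification of any specific MaxEnt
  release; tuned `rm` absorbs the difference in practice, but coefficients
  are not numerically comparable to another implementation's lambdas file.
* eFAST indices inherit the method's truncation bias (harmonics beyond $M$
  are unassigned) and, when frequency cycling is enabled, conflate the
  cycled factors' complementary contributions.
* Marginal-independent sampling in the GSA ignores cross-layer correlation
  (see above).
* Raster I/O is plain-text ESRI ASCII grid plus a YAML manifest; no
  projected CRS handling.
* The synthetic coastline is a straight west-edge gradient; regional splits
  are horizontal y-thresholds, not polygons.
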