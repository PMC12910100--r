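---
title: "Simulating the allocation of sampling effort in gradient studies"
author: "gradsamp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating the allocation of sampling effort in gradient studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gradsamp)
```

## The question

Regression-type ("gradient") studies estimate how a response — photosynthetic
activity, species richness, a vital rate — changes along a continuous
environmental driver. With a fixed budget of `N` experimental units, the
designer faces a trade-off: place many distinct levels of the driver
("sampling locations") with little or no replication, or replicate heavily at
few locations. `gradsamp` simulates that trade-off end to end: it generates
data from known response curves, samples them under competing designs, fits
the kind of polynomial regression such studies typically use, and scores how
well the fitted curve recovers the truth. The simulation output is then
analyzed the way an empiricist would analyze a designed experiment on
design choices: mixed-effect models of accuracy, variance decomposition, and
per-case significance classification.

## The data-generating model

A **response shape** is a deterministic curve $y = f(x)$ on the driver domain
$[1, 100]$ (arbitrary units; the lower bound is strictly positive so
log-spaced designs are defined). Six shapes are built in, spanning the
spectrum from trivially estimable to strongly nonlinear, all scaled to span
roughly $[0, 100]$:

| id            | form                                  | character    |
|---------------|---------------------------------------|--------------|
| `linear`      | $f(x) = x$                            | simple       |
| `hump`        | centered parabola, apex 100 at 50.5   | simple       |
| `skewed_hump` | Ricker curve $a\,x\,e^{-x/20}$        | asymmetric   |
| `saturating`  | $100 \log(x)/\log(100)$               | concave      |
| `exponential` | scaled $e^{0.05x}$                    | accelerating |
| `logistic`    | $100/(1+e^{-0.15(x-50.5)})$           | sigmoid      |

The exact constants are package defaults (the shape classes, not the
constants, carry the scientific content); every form is overridable through
`shape_params` or `register_shape()`, and each shape carries its analytic
derivative because the preferential designs need the local slope.

**Observations** at a location $x$ are
$y = f(x) + \varepsilon$, $\varepsilon \sim N(0, \sigma(x))$ with
$\sigma(x) = \max(\nu\,|f(x)|,\ \nu \cdot 0.01 \cdot \text{range}(f))$:
proportional, heteroscedastic noise at level $\nu$ (0.2 is a
close-to-real-world level; 1.0 an extreme one), with a small floor so that
points where the curve crosses zero are not observed noise-free and turned
into artificial anchors. Draws are independent across locations and
replicates and are never truncated.

## Designs

A **sampling procedure** is a factorization $N = L \times r$ of the budget
into locations times replicates; `enumerate_procedures()` lists every exact
factorization with $L \ge 3$ and $r \le 32$ for budgets
$\{6, 12, 24, 48, 96\}$ — 30 procedures in all. A **sampling strategy**
decides where the $L$ locations go:

* `systematic` — equidistant, always spanning both ends of the gradient;
* `log_systematic` — equidistant in $\log x$ (for drivers that act
  multiplicatively), also spanning the ends;
* `random` — uniform draws without replacement from a 1000-point candidate
  grid;
* `pref_slope`, `pref_extreme`, `pref_combined` — weighted draws where the
  sampling probability of a candidate is its **criticality**: the absolute
  local slope $|f'(x)|$, the absolute deviation of $f(x)$ from the midpoint
  of its range, or the equal-weight mean of the two (each min–max
  standardized). Weights are floored at $10^{-3}$ of their maximum so no
  candidate is strictly unreachable (a slope-weighted hump design could
  otherwise never sample the apex), then normalized.

The **gradient-length scenario** (`extremes`) controls whether the two
domain endpoints are forced into the design. Without forcing, systematic
strategies still span the ends (that is what equidistant placement means),
but random and preferential draws usually do not — the sampled gradient is
then shorter than the domain, and predictions beyond it are extrapolations.
With forcing, the smallest and largest placed points are replaced by the
endpoints, keeping $L$ constant across scenarios.

## Fitting, the knowledge scenario, and scoring

In the **shape-unknown** scenario, polynomials of order 1 up to
$\min(4, L-1)$ are fitted by OLS (on a coordinate mapped to $[-1,1]$ for
conditioning; coefficients are reported raw) and the order with minimal
$\mathrm{AIC} = n\log(\mathrm{rss}/n) + 2(k+2)$ is kept, ties to the lower
order, with `rss` floored at $10^{-12}$ so perfect fits do not produce
$\log 0$. Replicates enter as repeated rows — no pre-averaging — which is
precisely why the design-matrix geometry makes the trade-off bite.

In the **shape-known** scenario the fitted model is the one that represents
the known shape: a two-parameter calibration $y \sim a + b\,f(x)$. This
choice was genuinely open (a fixed "nominal" polynomial order per shape is
the obvious alternative, and remains available via
`known_model = "nominal_order"` or `select_model(known_model =)`). The
calibration reading was adopted because it is the only one under which the
package's own factorial experiment shows the characteristic signature of
the published analyses this design reproduces: with a nominal-order
polynomial, known-scenario accuracy still collapses as locations are traded
for replicates, the known and unknown scenarios decline in parallel, and
the replicates-by-knowledge interaction explains almost nothing; with the
calibration, replication is harmless-to-beneficial when the shape is known
and harmful when it is not, so the interaction — not the main effects —
carries the signal. It also makes the known scenario well-defined for every
procedure (any design with two distinct response levels identifies $a, b$),
where a degree-4 polynomial is simply unfittable at 3 locations.

Accuracy is scored on a fixed grid of 1000 equidistant points spanning the
**full** domain — deliberately including extrapolated regions, since
failing to cover the gradient is exactly the design failure under study —
with three metrics:

* `multiple_r2` — squared correlation between predicted and true values:
  affine-invariant, rewards getting the *pattern* right;
* `chalcraft_ps` — $1 - \sum(\hat y - y)^2 / \sum(y - \bar y)^2$, the
  coefficient of determination of the fixed identity model (through the
  origin, slope one): penalizes bias and scale error, can go negative;
* `neg_rmse` — $-\sqrt{\text{mean}(\hat y - y)^2}$: on the response scale
  and linear in the noise magnitude where the other two saturate.

The centered normalizer in `chalcraft_ps` (rather than $\sum y^2$) makes 1
mean "exact match" and 0 mean "no better than predicting the true mean";
the raw-sum variant is kept behind `ps_normalizer = "true_raw"` for
sensitivity checks.

## The factorial experiment

`run_grid()` crosses shapes × strategies × procedures × noise levels ×
knowledge × extremes × repetitions and emits one tidy row per run. Every
(cell, repetition) pair receives its own child seed through a bijective map
on $\mathbb{Z}_{2^{31}-1}$, so single rows can be re-created in isolation
(there is a test that does exactly that) and results are independent of
execution order. Runs that fail numerically are flagged, never fatal, and
excluded listwise downstream. With `out_file` set, completed cells are
appended to disk as the grid runs and `resume = TRUE` skips them on
restart.

The default repetition count is 1000; the package's own acceptance analyses
run at 100 repetitions per cell (432,000 runs per noise level), which keeps
a full two-noise reproduction within minutes on one core while leaving
Monte-Carlo error in the per-cell means near ±0.03 accuracy units.

## Analyzing the accuracy surface

Four hypothesis models relate accuracy to replication, all REML linear
mixed models with `n_replicates` numeric and response shape as an extra
random intercept whenever it varies:

1. `accuracy ~ replicates + (1|total) + (1|extremes) + (1|knowledge)`
2. `accuracy ~ replicates * extremes + (1|total) + (1|knowledge)`
3. `accuracy ~ replicates * knowledge + (1|total) + (1|extremes)`
4. `accuracy ~ replicates * total + (1|knowledge) + (1|extremes)`

They are fitted per shape × strategy sub-table on the raw per-repetition
rows. Cell-mean aggregation was evaluated and rejected: it guts the Wald
tests' power asymmetry between metrics that the per-case classification
relies on (an `aggregate = TRUE` switch keeps the variant accessible).
Explained variance is summarized by Nakagawa's marginal and conditional
R² computed from the variance components; fixed effects are tested with
Wald z (at these row counts Satterthwaite corrections change nothing
visible).

`variation_partition()` decomposes a model's marginal R² into unique and
shared contributions of two predictors via nested fits. The joint model
includes the interaction by default: the known and unknown replication
slopes have opposite signs, so an additive joint model would let them
cancel and attribute nearly nothing to replication; with the interaction
included, "unique to replicates" means everything the knowledge-only model
cannot explain. The additive variant (`joint = "additive"`) satisfies the
same algebraic identity and is used in the orthogonality property tests.

`classify_replication_effects()` treats each shape × strategy combination
at one noise level as a **case** (36 cases), fits Model 3 within the case,
and classifies the replication coefficient as significantly negative,
significantly positive, or non-significant at $\alpha = 0.05$.
`compare_models()` wraps one-way ANOVA + Tukey HSD into a compact letter
display for comparing R² values across models or metrics.

## Numerical choices and degenerate inputs

* Polynomial bases are evaluated on a $[-1,1]$-scaled coordinate; raw-scale
  coefficients are recovered by binomial expansion.
* A constant prediction has undefined correlation: `multiple_r2` returns 0
  by convention; a constant *true* curve makes `chalcraft_ps` undefined
  (`NA`); `neg_rmse` is always defined.
* Criticality that is flat over the grid (the linear shape's slope) yields
  uniform sampling probabilities rather than 0/0.
* Mixed fits ignore singular-boundary warnings (flagged on the result
  instead); a case whose random intercept is unidentifiable falls back to
  OLS; `fit_lmm(robust = TRUE)` exposes an iterative Huber-weighted
  variant as a sensitivity check, not the reference analysis.
* AIC-minimal selection accepts a spurious extra order at roughly the
  $P(\chi^2_1 > 2) \approx 16\%$ rate; on the quadratic hump at noise 0.05
  this leaves ~89% exact-order recovery and ~100% recovery of at least the
  true order. This is a property of AIC itself, not of the implementation.

## What the generator does and does not emulate

The simulations cover deterministic smooth one-factor response curves with
independent, Gaussian, proportional noise. Real gradient data add
autocorrelated and non-Gaussian errors, measurement error in the driver,
multi-factor response surfaces, and uncertainty about the domain itself.
Passing tests therefore demonstrate correctness of the machinery and the
qualitative design conclusions *within this model of the world* — many
locations beat heavy replication when the shape is unknown or complex;
replication pays off only for known, well-specified shapes; systematic
placement is the safest default — not that the specific percentages carry
over to any particular field system.

## Known limitations

* The "known shape" scenario assumes the true curve family is known up to
  affine calibration; a practitioner with partial knowledge sits somewhere
  between the two scenarios.
* Splines/GAMs are deliberately out of scope as prediction models.
* Only balanced replication (equal $r$ at every location) is simulated.
* The per-case classification inherits the power of its sub-design; at few
  repetitions the non-significant share is inflated for the noisier
  metrics.

## Reproducing the analyses

```{r, eval = FALSE}
library(gradsamp)

# one noise level of the full factorial, scaled down to 100 reps/cell
res <- run_grid(default_config(noise_levels = 0.2, reps = 100L,
                               master_seed = 1L))

# Model 3 sub-fits + variation partitioning (one row per shape x strategy)
vp <- replication_varpart(res, "r2_multiple")
100 * mean(vp$unique_replicates)   # replication's % share of total variation
mean(vp$marginal_r2)               # Model 3 marginal R2, averaged

# per-case classification of replication effects
classify_replication_effects(res, "r2_multiple")$percentages
```

`scripts/acceptance.R` runs exactly this at both noise levels and writes
the headline numbers as JSON; the test suite asserts them with tolerances.
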