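---
title: "Mixture-design response surfaces for formulation optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixture-design response surfaces for formulation optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixrsm)
```

## The problem

A formulation scientist blending q ingredients — here the cumin, carvi and
coriander essential oils making up the lipid phase of an oil-in-water
nanoemulsion — works on the composition simplex: the fractions
$x_1, \dots, x_q$ are non-negative and sum to 1. Changing one fraction
necessarily changes the others, so ordinary factorial response-surface
machinery does not apply. `mixrsm` implements the standard mixture-design
workflow end to end: design construction on the simplex, Scheffé polynomial
fitting with response transforms, the mixture ANOVA with a lack-of-fit /
pure-error split, backward model reduction, and multi-response desirability
optimization.

## Scheffé mixture polynomials

Because $\sum_i x_i = 1$, an intercept is redundant and the canonical
polynomials are Scheffé's:

$$y = \sum_i \beta_i x_i
    + \sum_{i<j} \beta_{ij} x_i x_j
    + \sum_{i<j} \delta_{ij} x_i x_j (x_i - x_j),$$

the "reduced cubic" form; dropping the $\delta$ terms gives the quadratic
model and keeping only $\beta_i$ the linear one. The linear coefficient
$\beta_i$ is directly interpretable as the predicted response of the pure
component $i$. Terms are written in the usual shorthand with components
aliased `A, B, C`: `"AB"` is $x_A x_B$, `"AB(A-B)"` is
$x_A x_B (x_A - x_B)$, `"ABC"` the triple product. Some texts call the
$x_i x_j (x_i - x_j)$ terms "quartic"; here they are uniformly the cubic
difference terms of the reduced cubic model.

```{r}
model_matrix(rbind(c(1, 0, 0), c(1, 1, 1) / 3),
             c("A", "B", "C", "AB", "AB(A-B)"))
```

## Response transforms

Fits are optionally performed on a transformed response (`sqrt`, `ln`,
`inverse`, `inverse_sqrt`, or `power`); coefficients and the ANOVA live on
that scale, predictions are reported in original units through the inverse
map. For the bundled study the square-root scale is used for droplet size
and IC50, and the identity for the colony counts. The choice is not a
matter of taste: on the bundled data the corrected total sum of squares of
$\sqrt{d_{3.2}}$ is 2.06 and the pure-error sum of squares 0.0111, matching
the source study's ANOVA to its printed precision, while the raw scale
gives a corrected total of 16.6 — the published coefficient magnitudes
(e.g. a pure-cumin coefficient of 1.45869 against an observed pure-cumin
droplet size of 2.1 µm, $\sqrt{2.1} = 1.449$) only make sense on the square
root scale. The same check identifies the square-root scale for IC50 and
the identity for both colony counts.

A related caveat uncovered by this reproduction: the source study prints
$R^2 = 99.24\%$ for its nine-term droplet-size model, but its own printed
coefficients — which `scheffe_fit()` reproduces to four decimals — give
$R^2 = 98.49\%$ on the printed data, under every transform and term set we
tried. The package reports the internally consistent 98.49; the other three
published $R^2$ values (99.18, 98.34, 94.88) are reproduced within a tenth
of a point.

## The mixture ANOVA

`mixture_anova()` follows the conventions of the response-surface software
family formulation studies typically use:

* the **Linear Mixture** row carries the Type I (sequential) sum of squares
  of the q linear terms after the mean, on $q - 1$ df — the linear blending
  signal;
* each non-linear term carries its **partial (drop-one)** SS from the full
  model, verified in the test suite against explicit refits;
* the residual is split into **Lack of Fit** and **Pure Error**, the latter
  computed from replicate groups (runs with identical composition at
  tolerance $10^{-6}$ after renormalization): with 17 runs over 12 distinct
  blends the split has 4 and 5 df. The LOF F-statistic against the
  pure-error mean square is the standard check that the polynomial form is
  adequate relative to measurement repeatability.

```{r}
fx <- nanoemulsion_runs()
f8 <- scheffe_fit(fx$design, fx$responses$d32_um,
                  c("A","B","C","AB","AC","BC","AB(A-B)","BC(B-C)"), "sqrt")
mixture_anova(f8)
```

Fit statistics follow the same conventions: SD $=\sqrt{\mathrm{MSE}}$,
$R^2$, adjusted $R^2$, and predicted $R^2 = 1 - \mathrm{PRESS}/SS_{tot}$
with PRESS computed through the hat matrix (equal to explicit leave-one-out
refits, also test-verified). CV% is reported on the transformed (modeling)
scale: this convention exactly reproduces the source study's printed CVs
for the square-root-fitted responses (5.19 for the eight-term droplet-size
model, 1.35 for IC50), which validates it; the printed CVs for the two
colony-count models (3.05, 5.38) do not follow from their ANOVA mean
squares and response means on any scale we tried and are reported as
computed (23.1, 25.3) without forcing agreement.

`reduce_model()` performs backward elimination: the non-linear term with
the largest partial-F p-value above `alpha` is dropped and the ANOVA
recomputed, until all remaining non-linear terms are significant; linear
terms are never dropped. On the bundled droplet-size data this removes
exactly the `AC(A-C)` term, as in the source study. Backward elimination
inherits the usual selection caveat: under a purely linear truth the final
model retains some interaction with probability roughly
$\alpha \times (\text{number of candidate terms})$ (about 30% here, and
confirmed by simulation in the test suite) — substantially more than
$\alpha$, because the per-stage tests are correlated and conditioning on
earlier drops inflates apparent significance. Users wanting strict type-I
control should pre-specify the model.

## I-optimal design construction

The study's 17-run design is I-optimal: it minimizes the average scaled
prediction variance $\overline{f(x)^\top (X^\top X)^{-1} f(x)}$ over the
region, which for prediction-oriented formulation work is the natural
criterion (D-optimality, by contrast, targets coefficient estimation).
Since the criterion's defining integral has no convenient closed form over
the simplex, `i_criterion()` averages over a uniform barycentric grid
(default step 0.02, 1326 points for q = 3; the test suite checks ≤ 5%
sensitivity to grid refinement). `coordinate_exchange()` performs the
classical point-exchange search from random starts: swap one design run
for one unused candidate whenever the criterion strictly decreases. The
selected runs are distinct; `augment_replicates()` then adds replicate
runs (the centroid first, then high-leverage blends) to buy pure-error df
— the bundled study replicated its centroid four times and two binary
blends twice each, giving 5 pure-error df. The candidate set is the
lattice of stated fractions plus the centroid and, for $q \ge 3$, the
axial check blends (centroid shifted halfway toward each vertex); axial
points are a three-plus-component convention and are omitted for binary
mixtures.

## Desirability optimization

Each fitted response is mapped to $[0,1]$ by a Derringer–Suich ramp; for a
minimization goal $d = 1$ below the target $T$, $0$ above the upper bound
$U$, and $((U - \hat y)/(U - T))^w$ between. The overall desirability is
the importance-weighted geometric mean
$D = (\prod d_i^{r_i})^{1/\sum r_i}$, so any fully undesirable response
vetoes the blend. The source study does not state its goal parameterization;
the defaults here are the ones that software family uses — bounds $L, U$
equal to each response's observed minimum and maximum, $T = L$ for
minimization, $w = 1$, equal importances — and they reproduce the published
optimum's desirability (0.97–0.98). Predictions below the observed minimum
saturate at $d = 1$: extrapolation earns no bonus and $D \le 1$ always.

`optimize_desirability()` evaluates $D$ on a barycentric grid (default step
0.005, i.e. half-percent compositional resolution, matching the two-decimal
percentages formulation studies report) and polishes the ten best grid
points by Nelder–Mead in the $q-1$ free coordinates with projection onto
the simplex. Refining the grid or polishing never lowers $D$ (test-verified
monotonicity). On the bundled study the optimum lies on a flat ridge of the
desirability surface: $D$ is 0.976 at carvi fractions anywhere between
roughly 60% and 62%, which is why small numerical differences between
implementations move the reported argmax composition by a point or two
while leaving $D$ and the predicted responses essentially unchanged.

```{r}
fits <- nanoemulsion_fits()
goals <- lapply(stats::setNames(names(fits), names(fits)),
                function(n) desirability_goal("minimize"))
optimize_desirability(fits, goals, grid_step = 0.02)
```

## Formulation metrics

The closed-form metrics of nanoemulsion characterization are included:
`sauter_mean()` (the surface-weighted diameter
$d_{3.2} = \sum n_i d_i^3 / \sum n_i d_i^2$), `dpph_inhibition()` (the
absorbance ratio of the DPPH radical-scavenging assay), `ic50()`
(log-linear interpolation of the 50% inhibition dose — serial dilutions
are geometric, hence the log scale), `droplet_growth_ratio()` (relative
size change during storage), and `fici()` (the checkerboard fractional
inhibitory concentration index). FICI breakpoints default to the
conventional ≤ 0.5 / 1 / 4 rule but are configurable: laboratories differ,
and values like 0.52–0.53 are called synergy in parts of the literature
while the strict rule labels them additive.

## Synthetic data

`simulate_responses()` generates response tables from a known Scheffé
surface: transformed-scale mean plus Gaussian noise, back-transformed.
Noise is Gaussian on the *transformed* scale — matching the scale on which
the models are fit, and implying right-skewed original-scale noise under
the square-root transform. A negative square-root-scale draw is resampled
once, then clamped to zero with a warning. `nanoemulsion_sim_config()`
builds a generator whose true surfaces are the bundled-study fits and whose
noise SDs are the corresponding residual SDs, so simulated datasets match
the real study's signal-to-noise (simulated $R^2$ within a point of the
real fits, test-verified). The generator emulates the response-table level
only: it does not simulate droplet-size distributions, absorbance curves or
colony images, and it assumes independent homoscedastic errors on the
transformed scale — real assay errors may be correlated across responses
measured on the same emulsion, so passing recovery tests here says nothing
about such cross-response structure.

## Numerical choices and limitations

* Rank deficiency is an error (reciprocal condition number $< 10^{-10}$),
  never a silent pseudo-inverse.
* Compositions are accepted if they sum to 1 within $10^{-5}$ (printed
  tables round to six decimals) and are renormalized to sum to exactly 1;
  replicate grouping uses a $10^{-6}$ tolerance after renormalization.
* A perfect fit reports an infinite F with $p = 0$ rather than NaN.
* CSV composition columns are auto-detected as percentages when their
  maximum exceeds 1.5.
* Problem sizes throughout the examples and tests are those of the bundled
  study (17 runs, 3 components, up to 9 terms); all computations are
  closed-form or small dense linear algebra and complete in seconds.
* The desirability optimizer is exhaustive-plus-polish, which is robust for
  $q \le 4$; for many components a proper global optimizer would be needed.
* Only simplex-shaped regions are supported: no multi-component constraints,
  no process variables crossed with the mixture, and no uncertainty
  intervals on the optimum.
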