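---
title: "Models and methods for electrolyte-leakage cold hardiness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for electrolyte-leakage cold hardiness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryoleak)
library(dplyr)
```

## The measurement and its indices

Freezing damage destabilises plant cell membranes and lets symplastic ions
leak into the bathing solution, so solution conductivity after a freeze–thaw
cycle is a proxy for the fraction of cells killed. A leakage experiment
freezes replicate stem segments at a ladder of temperatures (here the
standard design: 4 °C unfrozen control, then −10 … −80 °C), reads the
conductivity $L_T$, applies a maximum-damage control (autoclaving or
liquid-nitrogen immersion) to the same tube, and reads $L_K$.

Three indices are in common use, and they form a gradient of standardization:

* **Relative leakage** $R_T = L_T / L_K$. No further adjustment; the
  "Anderson" analysis fits a curve to $R_T$ directly, with both asymptotes
  free.
* **Index of injury** $I_T = 100\,(R_T - R_o)/(1 - R_o)$, where $R_o$ is the
  unfrozen-control baseline, so handling damage (cut stem ends and the like)
  scores 0 %. The "Flint" analysis fits $I_T$ with the lower asymptote pinned
  at 0.
* **Adjusted index** $I_{adj} = 100\,(R_T - R_o)/(R_{max} - R_o)$, where
  $R_{max}$ is the maximum relative leakage reached within the genotype.
  Woody twigs typically plateau well below $R = 1$ (deep-frozen tissue leaks
  roughly 60 % of what autoclaved tissue does), so treating the observed
  plateau as 100 % damage — the "Lim" analysis, both asymptotes pinned — is
  what makes critical values comparable across species and studies.

`standardize_leakage()` computes any of the three per genotype. Two
estimation policies are deliberate:

* $R_o$ defaults to the **mean** of the unfrozen 4 °C replicates
  (least-variance choice; replicate aggregation is otherwise
  underdetermined). For designs without replicate tubes an alternative takes
  the lowest leakage at either 4 or −5 °C (`min_of_4C_or_minus5C`).
* $R_{max}$ defaults to the maximum over **per-temperature replicate means**
  (robust to one leaky tube); a literal per-tube maximum (`max_replicate`)
  is available.
* Values outside the nominal range ($R > 1$, $I < 0$) are **flagged, never
  silently clamped**: clamping before fitting would bias the fitted lower
  asymptote. An explicit `clamp = TRUE` exists for consumers that need
  bounded values.

The chain $I_{adj} = 100\, I / I_{max}$ with
$I_{max} = 100\,(R_{max} - R_o)/(1 - R_o)$ is an algebraic identity, and the
test suite asserts it to $10^{-12}$ on random inputs.

## Damage curves and critical temperatures

Damage accumulates sigmoidally as temperature falls. The work-horse model is
the four-parameter log-logistic

$$y(T) = c + \frac{d - c}{1 + e^{b (T - u)}}, \qquad b > 0,$$

fit by unweighted least squares on replicate-level points (not temperature
means — replicate scatter carries information the fit should see). Constraint
modes mirror the standardization: all parameters free for $R$
(`anderson_free`, with bounds $c \ge 0$ and $d \le 110$ — soft headroom so a
near-100 plateau does not stick to the boundary), $c = 0$ for $I$
(`flint_c0`), and $c = 0, d = 100$ for $I_{adj}$ and visual damage
(`lim_c0_d100`, `vd_c0_d100`).

Critical temperatures use the **relative-damage convention**: $LT_p$ solves
$(y - c)/(d - c) = p/100$, giving

$$LT_p = u + \ln\!\frac{100 - p}{p} \Big/ b, \qquad LT_{50} = u \text{ exactly.}$$

This convention is what makes the four approaches comparable — an absolute
threshold (e.g. $R = 50\%$) is often never reached by autoclave-referenced
woody-tissue data, which plateaus near 58 %. An absolute-threshold variant is
available behind `absolute = TRUE` and returns `NA` outside the fitted span.

The asymmetric alternative is the Gompertz curve on the percent scale,

$$y(T) = 100\, e^{-b e^{-kT}}, \qquad b > 0,\; k < 0,$$

whose steepest-slope temperature $LT_{max} = \ln(b)/k$ is decoupled from
$LT_{50} = (\ln b - \ln\ln 2)/k$; with $k < 0$, $LT_{max}$ is always warmer
than $LT_{50}$, reflecting damage that accelerates before its midpoint. Both
identities are verified in the tests against brute-force grid scans and
forward evaluation to $10^{-9}$.

### Numerical policy

Fitting uses bounded Levenberg–Marquardt (`minpack.lm::nls.lm`) with
deterministic, derivative-free starts: the logistic is linearised
($\mathrm{logit}$ of the range-scaled per-temperature means regressed on
temperature) to seed $b$ and $u$; asymptote starts are the extreme
per-temperature means. A deliberately non-shallow fallback slope start avoids
a rank-deficient Jacobian when the linearisation is unusable.

Two degenerate regimes are handled explicitly:

* **Flat series** (range below `flat_tol`) raise a classed error — there is
  nothing to fit.
* **Step-like series** — quantized responses such as quartile visual-damage
  scores with identical replicates — have their unconstrained least-squares
  optimum at an infinite slope, where the optimizer crawls a flat valley
  indefinitely. The slope is therefore bounded at `b_max = 5` (a 10–90 %
  transition width of about 1 °C, far steeper than any biological
  transition across a 10 °C treatment grid), and when the optimizer exhausts
  its iterations the slope is profiled at that bound; the boundary solution
  is accepted only if it fits at least as well.

Non-convergence is never silent: the fit is returned with
`converged = FALSE`, a warning is raised, and downstream critical-value
tables show the genotype as missing rather than wrong.

Species-level fits pool replicate-level points across the genotypes of a
species rather than fitting genotype means — pooling preserves the
replicate weighting that the genotype fits use.

## Control calibration

Autoclaving maximises leakage by heat-killing; liquid-nitrogen immersion
(−196 °C and below) maximises it by the same physical process being studied.
The two standards are linearly related, and the calibration is estimated by
**zero-intercept Deming regression**: with error on both axes (the same
conductivity probe reads both), the fit minimises

$$L(s) = \sum_i \frac{(y_i - s\,x_i)^2}{\delta + s^2},$$

whose origin-constrained minimiser has the closed form
$s = \big[(S_{yy} - \delta S_{xx}) + \sqrt{(S_{yy} - \delta S_{xx})^2 +
4\delta S_{xy}^2}\big] / (2 S_{xy})$ in uncentred moments. Policies, each of
which the data cannot decide and is therefore explicit and configurable:

* $\delta = 1$ (equal error variances): both axes come from the same
  instrument. With $\delta = 1$ the slope satisfies the orthogonal-regression
  reciprocity $s_{y\sim x} \cdot s_{x\sim y} = 1$, which the tests assert to
  $10^{-9}$. Note that orthogonal regression is not unit-invariant: rescaling
  $y$ by $a$ transforms the slope exactly only if $\delta$ is rescaled by
  $a^2$ alongside.
* **Outliers**: perpendicular residuals from an initial all-data fit, flagged
  beyond $3 \times 1.4826 \times \mathrm{MAD}$, removed in a single pass, fit
  recomputed. Because the initial fit is itself tilted by gross outliers, the
  single pass may also trim a few tail points; the flagged indices are
  reported, never hidden.
* **Confidence interval**: seeded nonparametric bootstrap (10,000 resamples
  by default) — cheap because the slope is closed-form.
* $r^2$ is ordinary least-squares $R^2$ computed with residuals taken in each
  direction ($y$ given $x$, and $x$ given $y$).

`convert_to_ln_standard()` divides autoclave-referenced relative leakage by
the slope, capping at 1 (converted leakage above 100 % of the liquid-nitrogen
maximum is physically meaningless; caps are counted in a warning). The
adjusted index is invariant to the control standard — the slope cancels in
$(R - R_o)/(R_{max} - R_o)$ — so the cap is applied only to converted $R$ and
$I$ series, and `refit_under_converted_control()` demonstrates the invariance
exactly (asserted to $10^{-12}$).

## Validation against other assays

* **Visual damage** is scored on a quartile scale (0/25/50/75/100 % browning).
  `threshold_grid()` compares leakage-derived $LT_p$ with damage-derived
  $LT_q$ over the full 10–90 % grid in across-genotype correlation, bias
  (leakage minus reference, °C) and RMSE, with boolean masks at the
  conventional cutoffs (correlation > 0.55, |bias| < 5 °C, RMSE < 7 °C).
* **Lowest survival temperature**: the coldest tested temperature at which no
  stem segment exceeds 50 % damage, applied per temperature independently
  (no monotonicity repair — the definition is taken literally), undefined
  with a warning when already violated at the warmest freezing temperature.
* **DTA exotherms**: freezing releases heat; extracellular water freezes at
  mild sub-zero temperatures (high-temperature exotherm, benign), while
  supercooled intracellular water freezes lethally much colder
  (low-temperature exotherm). `detect_exotherms()` replaces manual peak
  curation with a transparent rule: running-median baseline over a 5 °C
  window, peaks at least 6 robust-SDs above the residual noise floor,
  HTE/LTE split at −15 °C (configurable — the literature gives no canonical
  number), nearby candidates collapsed to the most prominent. Detection is
  invariant to additive voltage offsets and uniform time rescaling, and the
  seeded synthetic benchmark requires recall ≥ 0.95 with mean location error
  ≤ 0.5 °C.

Correlation matrices across approaches (`critical_value_correlations()`) use
Pearson by default (Spearman behind a flag) at genotype level, except that
pairs involving LTE — a species-level quantity, since DTA pools segments per
cell — are computed on species means.

## The synthetic-data generator

`simulate_leakage_experiment()` emulates the standard panel design: 12
species × 3 genotypes × 3 replicate tubes at
{4, −10, −20, −30, −40, −60, −80} °C. For a genotype with true damage curve
$D(T) = 1/(1 + e^{b^* (T - u^*)})$:

$$L_T = P\,\big(f_0 + (m - f_0)\,D(T)\big)(1 + \varepsilon), \quad
L_K^{auto} = P (1 + \varepsilon), \quad
L_K^{LN} = P\, m (1 + \varepsilon),$$

with $\varepsilon \sim N(0, \sigma)$ multiplicative (conductivity errors
scale with magnitude), total electrolyte pool $P$, handling-leakage fraction
$f_0$ and maximum freezing-induced leakage fraction $m$. Defaults, chosen
once as realistic study conditions: $\sigma = 0.03$, $f_0 = 0.1$,
$m = 0.58$ (deep-frozen woody tissue leaks ~58 % of the autoclave maximum),
species-level $u^*$ uniform on [−30, −12] °C with 1.5 °C genotype jitter
(the range critical values occupy in early-spring maples), $b^*$ uniform on
[0.25, 0.45]. At $\sigma = 0$ the relative leakage plateaus at $m$ and the
adjusted index at exactly 100.

Visual damage follows a curve shifted 3 °C colder (`vd_offset = -3`) and
1.5× steeper (`vd_slope_mult = 1.5`) — browning is accrued faster than
leakage and lags it slightly — then quartile-rounds, with exact midpoints
rounded toward the scale's centre, 50.

What the generator does **not** emulate: between-replicate tube effects
beyond multiplicative noise, sample-size (diameter) heteroscedasticity,
incubation-time drift, rater variability in visual scoring, and
non-sigmoidal damage. Passing tests therefore demonstrate correctness of the
estimators under the stated generative model, not robustness to every
real-data pathology.

### Recovery properties, measured

At the default conditions the full pipeline (simulate → standardize → Lim
fit → LT50) recovers the true inflection with mean absolute error ≈ 0.38 °C
and a small systematic cold bias ≈ −0.27 °C (measured over 2,010 simulated
genotypes). The bias is a property of the method, not a bug: $R_{max}$ is the
maximum of a handful of noisy plateau means and therefore slightly
overshoots $m$, so the adjusted index plateaus just below 100 and the
$d = 100$-pinned fit compensates by shifting the inflection a fraction of a
degree colder. The acceptance tests check mean |error| ≤ 1 °C and |bias| ≤
0.3 °C over three seeded 201-genotype batches — one batch's Monte-Carlo
standard error (~0.03 °C) is too close to the bias bound to resolve it.

Two precision limits are inherent and documented rather than hidden:

* Even noise-free pipeline recovery is exact only up to the tail mass the
  empirical baseline and maximum truncate — $D(4\,°C)$ and $1 - D(-80\,°C)$,
  a few millidegrees for typical slopes.
* A single genotype's visual-damage LT50 is only localised to about half the
  10 °C treatment spacing when quartile rounding collapses its transition
  into a step (identical replicates make this the rule at low noise); the
  −3 °C offset between the assays is recovered on average, not per genotype.

## Problem sizes

The test suite simulates what it needs at run time: 603 genotypes for the
recovery check, 100 seeded replicates of the 176-pair calibration design, 50
seeded DTA traces, and small fixtures everywhere else; the full suite runs in
well under a minute.
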