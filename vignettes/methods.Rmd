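---
title: "Methods: models, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
# This vignette documents methods; code chunks are illustrative and not
# evaluated at build time. Empirical numbers live in the test suite and in
# scripts/acceptance.R, not here.
knitr::opts_chunk$set(eval = FALSE)
```

```{r}
library(winephenols)
```

This vignette records the mathematical model behind each module, the
meaning of every tunable parameter, what the synthetic generator does and
does not attempt to capture, and the numerical conventions used throughout.
It makes no empirical claims; quantitative behaviour is asserted in
`tests/testthat/` and recomputed by `scripts/acceptance.R`.

## 1. Spectral representation

A spectrum is a row of absorbances on a shared wavelength grid. The default
grid runs 230–700 nm in 1 nm steps (471 points), constructed by
`wavelength_grid(230, 700, 1)`. `spectra_set()` wraps a matrix or tibble of
such rows with validation: unique non-missing sample ids, finite
absorbances, and columns named by integer wavelengths. Two windows matter:

- **UV window**: 230–429 nm (200 points), used for tannins and TIPs.
- **Visible window**: 430–700 nm (271 points), used for anthocyanins.

`restrict_spectra()` subsets to a window; `features_for(spectra, target,
standard =)` routes each phenolic target to its window, applying the
anthocyanin correction (below) for `"tannins"` and `"tips"` and returning
the raw visible window for `"anthocyanins"`.

`sum_normalize()` divides each spectrum by its sum over the full grid, so a
normalised spectrum is a shape: it integrates to 1 and is invariant to
concentration, path length, and dilution. Normalisation is idempotent and
errors on all-zero rows.

## 2. Anthocyanin UV isolation

Among the modelled phenolic classes, only anthocyanins (and polymeric
pigments, see §6) absorb near 520 nm. Given a sum-normalised anthocyanin
standard shape $s(\lambda)$ (normalised over the *full* 230–700 nm grid,
not the UV window alone), the anthocyanin contribution to sample $i$ at UV
wavelength $\lambda < 430$ is estimated by anchoring the standard to the
sample's 520 nm absorbance:

$$\hat A_i^{\text{anth}}(\lambda) \;=\; s(\lambda)\,\frac{A_i(520)}{s(520)},
\qquad \lambda \in [230, 429].$$

`isolate_uv()` returns the estimate, the corrected UV spectrum
$A_i(\lambda) - \hat A_i^{\text{anth}}(\lambda)$, and the per-sample scale
factor $A_i(520)/s(520)$. Negative corrected values are clipped to zero and
the result is flagged (`clipped`), since they indicate the standard's shape
over-predicts the sample's UV anthocyanin signal at some wavelengths.

The step is exact when (a) the standard's shape equals the true anthocyanin
shape, (b) nothing else absorbs at 520 nm, and (c) absorbance is linear
(no saturation, no noise). Each relaxation degrades it gracefully: a
shape-mismatched standard leaves a structured residual, pigments at 520 nm
cause over-subtraction, and noise propagates with the anchor ratio.
Preconditions are enforced: the standard must be sum-normalised (usage
error otherwise) and must cover the full grid (data error if UV-only).

## 3. Error metrics

- `rmse(predicted, observed)` $= \sqrt{\sum_i (P_i - O_i)^2 / N}$.
- `pearson(x, y)` is the sample Pearson correlation; it errors when either
  input is constant rather than returning `NA` silently.
- `r_squared(predicted, observed, method = c("pearson", "residual"))`
  defaults to the *squared Pearson correlation* between predicted and
  observed. This is the convention used in all reported R²C/R²P/R²CV
  statistics. The alternative `"residual"` method computes
  $1 - \mathrm{SS}_{\text{res}}/\mathrm{SS}_{\text{tot}}$, which also
  penalises bias and scale errors; it is the right choice when judging
  *accuracy* (e.g. after calibration transfer), whereas squared Pearson
  judges *ranking/linearity* and is invariant to affine transformations of
  the predictions.

## 4. Regression backends

`fit_phenolic_model(x, y, algorithm, weight)` exposes three kernel methods,
each with exactly one flexibility parameter ("weight"):

- **`svr`** — $\varepsilon$-support-vector regression via `e1071::svm`
  with an RBF kernel, $\gamma = 1/p$ ($p$ = number of features),
  $\varepsilon = 0.1$; the weight is the cost $C$. Larger cost fits the
  training data more tightly.
- **`krr`** — kernel ridge regression with a *linear* kernel, solved in
  the dual: $\alpha = (K + \lambda I)^{-1} y_c$ on centred data; the
  weight is the penalty $\lambda$. *Smaller* $\lambda$ is more flexible,
  so its default grid is ordered from large to small.
- **`kpls`** — kernel partial least squares with a linear kernel, using
  the Dayal–MacGregor cross-product recursion on $X'X$ and $X'y$; the
  weight is the number of latent components, capped at
  $\min(n - 1, p)$. With a linear kernel this is numerically identical to
  classical NIPALS PLS (the test suite pins agreement to $10^{-8}$ against
  a literal NIPALS implementation).

All backends centre $X$ and $y$ with *training* statistics only; no
scaling is applied (features share units, absorbance). `predict()` checks
that new data carry the training wavelengths.

## 5. Validation and the weight search

`repeated_validation(x, y, algorithm, weight, repeats = 10, seed)` draws
`repeats` independent random 90/10 train/test splits (`random_split`; for
$n = 323$ that is 290/33). It reports:

- **R²C / RMSEC** — resubstitution on each training set, averaged;
- **R²P / RMSEP** — held-out test performance, averaged over repeats;
- **R²CV / RMSECV** — computed on the *pooled* held-out predictions across
  all repeats (with `repeats = 1` these coincide with R²P/RMSEP).

`weight_search(x, y, algorithm, grid, repeats, seed, r2_floor = 0.5,
patience = 2, decline_tol = 1e-4)` walks the algorithm's grid in order of
increasing flexibility (`default_weight_grid`: SVR costs $2^{-5}\ldots
2^{15}$; KRR penalties $10^{3}\ldots10^{-6}$ descending; KPLS components
$1\ldots\min(30, n_{\text{train}} - 1)$), evaluating mean test R² at each
point. Rules:

- **Floor**: candidates start at the last leading grid point whose score is
  below `r2_floor`; weights in the clearly-underfitting prefix are never
  chosen.
- **Early stop**: the walk stops after `patience` consecutive *material*
  declines — a decline counts only if the score drops by more than
  `decline_tol` below the previous point, and the stop fires only if the
  running maximum exceeds the current score by more than `decline_tol`.
  The tolerance exists because flat stretches of the profile can differ
  only by floating-point jitter; without it, two successive $10^{-7}$-level
  dips would be mistaken for a genuine peak. Termination is reported as
  `"declined"` or `"grid exhausted"`.
- **Ties** resolve to the least flexible weight.

## 6. The synthetic generator

The generator exists to exercise the workflow with known ground truth, not
to reproduce any particular wine. Scope and parameters:

- **Component shapes** (`default_component_library()`): each component is a
  sum of Gaussian bands $h\exp\{-(\lambda-c)^2/(2w^2)\}$ in absorbance per
  (mg/L) units. Anthocyanin has UV (277 nm) and visible (520 nm) bands;
  tannin and TIP are UV-only (hard-zeroed at $\ge 430$ nm); polymeric
  pigment has a UV band plus a broad visible band centred at 500 nm. The
  standard defaults to the anthocyanin shape; `standard_shift_nm` shifts it
  to model an imperfect standard.
- **Mixtures** (`mixture_design()`): concentrations are drawn uniformly
  over per-component ranges (defaults: anthocyanin 50–900, tannin 100–1400,
  TIP 300–2800 mg/L, pigment 0), optionally correlated through a Gaussian
  copula (rank correlations mapped via $\rho = 2\sin(\pi r/6)$). Spectra
  follow Beer–Lambert additivity, divided by the dilution ratio
  (default 1:5).
- **Instrument** (`instrument_model()` / `instrument_preset()`):
  absorbance is transformed as `gain * A + offset + noise`, then clipped at
  a saturation `ceiling`. Preset `"A"` is ideal-ish (unit gain, ceiling
  2.0 AU, no noise by default); preset `"B"` has a wavelength-dependent
  gain, a small offset, additive noise, and a low 0.8 AU ceiling, so that
  higher dilutions genuinely match a reference instrument better.
- **Assays**: reference-method values are truth times multiplicative
  log-normal-free Gaussian noise with coefficient of variation `assay_cv`
  (default 0.05), floored at zero.
- **Aging** (`aging_model()`, `simulate_aging_series()`): each week a
  fraction of every wine's anthocyanin pool converts to polymeric pigment.
  With `tannin_rate_scaling = TRUE` (default) the per-wine conversion rate
  is `conversion * tannin0 / max(tannin0)` — tannin-rich wines polymerise
  faster — which is what drives initially-positive anthocyanin–tannin
  correlations negative over the weeks. Pigment contributes a fraction
  (`pigment_tip_weight`) of its anthocyanin-equivalent mass to the TIP
  assay and `tannin_incorporation` couples tannin loss to pigment
  formation. A truth ledger (`attr(series, "wp_truth")`) conserves
  anthocyanin equivalents exactly. The aging defaults were chosen so the
  *signs* of the week-by-week correlation drift match the documented
  qualitative pattern (positive initial cross-correlations turning
  negative, the peak anthocyanin-correlated wavelength leaving the
  500–550 nm region); the magnitudes are not calibrated to any dataset.

Deliberately out of scope: scattering/baseline drift, pH- and
SO₂-dependent anthocyanin equilibria, instrument wavelength
mis-registration, and non-Gaussian band shapes.

## 7. Calibration transfer

`match_dilution(reference, candidates)` sum-normalises the *mean* spectrum
of the reference set and of each candidate set and reports the
root-mean-square distance between shapes. Because both sides are
normalised, the comparison is invariant to dilution and overall gain and
responds only to shape distortions — chiefly saturation clipping and
wavelength-dependent gain. `augment_calibration(old, new)` row-binds
matched spectra/assay sets after grid and column checks, for retraining a
model with a few samples from the new instrument.

## 8. Numerical conventions

- Wavelength grids are integer-labelled columns; all window boundaries are
  half-open at 430 nm (UV is 230–429, visible 430–700).
- Random behaviour is seed-controlled everywhere; internal draws use
  isolated RNG state so that library calls do not perturb the caller's
  RNG stream, and derived seeds keep sub-simulations independent.
- KRR solves the dual system with a Cholesky-backed solver on
  $K + \lambda I$; KPLS guards against degenerate score variance and
  reports a numerical-error condition rather than returning garbage.
- Errors are classed (`wp_usage_error`, `wp_data_error`,
  `wp_numeric_error`) and the CLI maps them to exit codes 2, 3, and 4.
- CSV output is deterministic: identical seeds give byte-identical files.

## 9. Limitations

- The squared-Pearson R² convention rewards linear association and ignores
  bias; use `r_squared(..., method = "residual")` when absolute accuracy
  matters (§3).
- The isolation step assumes the standard's shape matches the wines'
  anthocyanin profile; polymeric pigments absorbing at 520 nm cause
  over-subtraction (§2, §6).
- The weight search is one-dimensional by design; SVR's $\gamma$ and
  $\varepsilon$ are fixed at their conventional defaults and are not tuned.
- Synthetic-data conclusions transfer to real wines only to the extent the
  generator's assumptions (§6) hold; the generator is a test harness, not a
  wine model.
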