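---
title: "Multi-group PLS-DA for hyperspectral heat-stress phenotyping: models, defaults and design notes"
author: "hsiStress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-group PLS-DA for hyperspectral heat-stress phenotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hsiStress)
```

# The problem

Heat stress changes the biochemistry of plant leaves — chlorophyll,
nitrogen, water, sugar and protein content — before any symptom is
visible to the eye. Those changes shift narrow absorption features of
the leaf reflectance spectrum in the visible/near-infrared
(Vis/NIR, 400–1000 nm) and short-wave infrared (SWIR, 1000–1800 nm)
regions. Given hyperspectral images of plants before stress (group
**BH**), of stress-resistant plants after stress (**AR**) and of
stress-susceptible plants after stress (**AS**), the task is threefold:

1. classify leaf-mean spectra into the three states,
2. reduce ~128 contiguous wavebands to a handful of informative ones so
   that a cheap multispectral instrument could do the same job, and
3. render the predicted stress state pixel by pixel across the leaf.

This vignette describes the models, every tunable that matters, the
synthetic-data generator used to validate the pipeline, and the design
choices made where more than one defensible option existed.

# From raw cubes to a labelled spectrum table

Push-broom cameras deliver cubes of raw counts. `calibrateReflectance()`
applies the standard two-point correction per pixel and band,

$$R = \frac{S - D}{W - D},$$

after averaging the white and dark reference cubes over their spatial
extent band-wise. The averaging is a deliberate choice: references are
acquired once per scan session, and spatial averaging suppresses
reference noise before it is amplified by the division. Values are
clamped to $[0, 2]$ (detector noise can push $S$ below $D$; values above
1 occur on specular highlights). `cropBands()` removes low-signal
spectral margins — SWIR sensors, for instance, are noisy beyond
1800 nm.

Leaves are segmented either by a normalized-difference vegetation index
$(R_{800} - R_{670})/(R_{800} + R_{670}) > 0.3$ (Vis/NIR) or by a plain
reflectance threshold at 1100 nm (SWIR, where both index bands are out
of range). Connected components are labelled with 8-connectivity and
components below `minPixels` (default 50, scaled for synthetic frames;
real leaves run to tens of thousands of pixels) are dropped.
`meanSpectra()` reduces every labelled leaf to one band-wise mean
spectrum — one sample.

`splitCalVal()` splits samples into calibration and validation sets
stratified by group, with `round(fraction * n)` per stratum going to
calibration. The default fraction of 2/3 turns the default group sizes
377/192/144 (BH/AR/AS, Vis/NIR) into a 251/128/96 versus 126/64/48
accounting, and the SWIR defaults 377/127/169 into 251/85/113 versus
126/42/56 — the sample bookkeeping this package is designed around.

# Continuous class codes for a three-group discriminant problem

PLS-DA regresses spectra on a numeric response. With two groups the
response is binary; with three or more, some scalar code per group must
be chosen, and the choice is consequential. Two encodings are
implemented.

**Best projection values (BPV).** `fitLDA()` solves the generalized
eigenproblem for between- versus within-class scatter,
$S_B a = \lambda S_W a$, with the within-class scatter regularized as
$(1 - s)\,S_W + s\,\mathrm{diag}(S_W)$. The shrinkage default
$s = 0.1$ exists because a hundred-plus strongly collinear bands make
$S_W$ ill-conditioned on a few hundred samples; $s = 0$ is available
when samples are plentiful, and the error message suggests shrinkage
when the unregularized scatter is singular. Samples are projected onto
the leading discriminant axis (`bestProjectionValues()`); each group's
histogram of projections is summarized by the centre of a Gaussian fit —
numerically the sample mean, since for a unimodal, symmetric histogram
the fitted centre and the mean coincide. `encodeGroupsBPV()` then maps
centres affinely so the reference group (BH) is 0 and the farthest group
100, rounding to integers. Which axis is "the" projection axis is
genuinely ambiguous for three groups (there are two); the package
defaults to the largest-eigenvalue axis and exposes `chosenAxis`.

**Sequential placement at regular intervals (SPRI).**
`encodeGroupsSPRI()` ignores the metric information and places the
groups at 0, 50, 100 — in the *data-derived* order of the BPV centres,
not a hard-coded one, so a region where the resistant group moves
farthest from baseline (as SWIR leaf water content does) yields the
order BH < AS < AR without configuration.

The package guarantees order-consistency between encodings and LDA
centres; where exactly an intermediate group lands on the BPV scale
(53 in the README example) is a property of the data, not of the
algorithm.

# PLS1, classification and the accuracy convention

`fitPLS1()` is classical NIPALS PLS1 on mean-centred $X$ and $y$:
$w_f = X'y/\|X'y\|$, $t_f = X w_f$, $p_f = X't_f/t_f't_f$,
$q_f = y't_f/t_f't_f$, followed by rank-one deflation of both. The
per-component explained response sum of squares is
$SSY_f = q_f^2\, t_f' t_f$. Predictions via the regression vector
$\beta = W (P'W)^{-1} q$ agree with the factorization path to numerical
precision, and at full rank $\beta$ equals the least-squares solution —
both are regression-tested against an independent Krylov-subspace
closed form and an external chemometrics library.

`chooseNLV()` picks the component count by k-fold cross-validation with
a one-sided parsimony rule: the smallest count whose RMSEP is within 2%
of the global minimum. Folds are assigned to unique sample *contents*
rather than row indices, which makes the choice invariant to duplicated
rows and reproducible under a seed.

`classifyScores()` assigns each predicted score to the nearest class
code, breaking ties toward the lower code (a fixed, documented rule
rather than an arbitrary one). `accuracyTable()` reports per-group
accuracies and an **overall = unweighted (macro) mean** of the per-group
accuracies. The macro convention is deliberate: with group totals
(126, 64, 48) and correct counts (110, 57, 22), the per-group accuracies
87.3/89.1/45.8 average to 74.1, whereas the pooled ratio would give
79.4; the macro figure is the one consistent with the accounting
convention this package follows, and display rounding is half-up to one
decimal.

# Ensemble waveband selection

The two-stage selector reflects a division of labour:

* **VIP filter.** For a fitted PLS1 model,
  $$VIP_j = \sqrt{\,J \sum_f w_{jf}^2\, SSY_f \Big/ \sum_f SSY_f\,},$$
  with unit-norm $w_f$ and $J$ bands. Under this normalization
  $\sum_j VIP_j^2 = J$ exactly, so the mean squared score is 1 and the
  threshold default of 1.0 ("keep the above-average bands", inclusive)
  is not arbitrary. The identity is asserted at $10^{-10}$ in the tests.
* **SPA.** The successive projections algorithm grows a chain from a
  start column by repeatedly appending the unselected column with the
  largest norm after projection onto the orthogonal complement of the
  selected span. Duplicated or collinear columns have zero projected
  norm and can never be selected; if all remaining norms vanish the
  chain is returned truncated with a flag.

`spaSelect()` evaluates every start column and every chain length in
`[mMin, mMax]` by fitting PLS1 on the chain's bands and scoring
*validation misclassification* under the active encoding — not RMSE,
because classification is the endpoint. Ties break toward fewer bands,
then the smaller start index, making the selection deterministic. The
cap is 20 bands (`mMax`), with `mMin = 8` as a sensible floor between
"too few to be robust" and "defeats the purpose"; both are clamped to
the candidate count. `ensembleSelect()` wires the stages together and
reports both the candidate set and the final chain.

# Pixel-wise chemical imaging

`predictMap()` applies a selected-band model to every leaf pixel,
$\hat y = (x_{sel} - \bar x)\beta + \bar y$, with selected wavelengths
mapped onto the cube grid by nearest-band lookup (no interpolation —
selection indices come from the same grid). Because the model is
linear, the mask-mean of the pixel map equals the prediction of the
leaf's mean spectrum exactly; the tests assert this at $10^{-10}$ with
clipping disabled. For display, predicted codes are clipped to
$[-20, 120]$ (so extreme noise pixels stay visible but bounded) and
rendered against a 0–100 colorbar; values outside render as endpoint
colors, background as neutral gray. Rendering is deterministic: equal
inputs give byte-identical PNGs.

# The synthetic-data generator

No public dataset accompanies this problem, so the generator is a
first-class, tested component, and its defaults define the conditions
under which the pipeline is validated.

**Archetypes.** `makeArchetypes()` builds smooth per-group mean spectra
on a uniform grid (default 128 bands per region): Vis/NIR has a green
reflectance peak near 550 nm, a chlorophyll absorption trough near
680 nm and a red-edge rise; SWIR has the 1450 nm water absorption
trough. Group differences of magnitude `effectSize` (default 0.10
reflectance) are planted at `nInformative` (default 12) seeded band
positions inside the biologically active window, as band-local offsets
ordered BH < AR < AS (Vis/NIR) or BH < AS < AR (SWIR — the resistant
group moves farthest there, and the direction is configurable through
`groupPositions` precisely because the two regions order differently).
Outside the planted bands the three archetypes are identical, which
gives the band-selection tests an exact ground truth.

**Sample noise.** Each simulated leaf-mean spectrum is
$$x_i = a_i\,(\mu_g + z_i\,\delta) + b_i + \varepsilon_i,$$
with multiplicative scatter slope $a_i \sim N(1, 0.02)$, additive offset
$b_i \sim N(0, 0.005)$, band-correlated noise $\varepsilon_i$ (white
noise smoothed by a Gaussian kernel of width 8 bands, marginal SD
0.008 — spectra are smooth, and white band noise would make band
selection unrealistically easy), and a biological-heterogeneity term:
$z_i \sim N(0, 0.2)$ displaces the sample along the stress direction
$\delta$ (the reference-to-farthest archetype difference). The jitter
term is the load-bearing one. Scatter and smooth noise live largely in
the orthogonal complement of the class signal, so a full-spectrum
linear model cancels them almost completely and classification would
saturate at 100%; within-group variability *along the stress axis* is
what genuinely limits accuracy in real screening populations (resistant
and susceptible individuals respond with different intensity), and no
linear model can remove it. With the defaults above, full-spectrum
validation accuracy on the default problem sizes lands in the low-to-mid
80s — inside the range this kind of three-group screening reports —
and the selected-band model tracks the full model to within a few
points. These magnitudes were chosen once, when the generator was
designed, and are exposed through `noiseConfig()`.

**Cubes.** `simulateCube()` paints an elliptical leaf (exact
rasterization, so mask recovery can be asserted pixel-for-pixel) with
the archetype spectrum plus independent per-pixel noise (SD 0.02) over
a flat 0.03 background.

**What the generator does not emulate.** Radiative-transfer realism
(no PROSPECT-style leaf optics), spatial gradients within a leaf (edge
chlorosis), specular highlights, wavelength-dependent detector noise,
and real morphology (masks are ellipses). Passing tests therefore
demonstrate the correctness and calibration of the *algorithms* under
controlled conditions, not field performance on real plants.

# Numerical choices and degenerate inputs

* Stratified split rounding: `round(fraction * n)` half-up, remainder to
  validation; strata below 2 samples are an error.
* LDA axes are unit-norm and sign-fixed so the reference group sits at
  the low end; encodings are invariant to affine rescaling of the axis.
* `encodeGroupsBPV()` refuses coincident group centres (within 1e-9) —
  a degenerate encoding has no consistent order.
* NIPALS stops early (trimming components) when the response is fully
  deflated; `fitPLS1()` refuses a constant response.
* SPA uses 1e-12 as the projected-norm floor for rank exhaustion.
* Calibration errors name the first offending band when
  $W - D \le 0$.
* Accuracy display rounding is half-up (base R rounds half-even), to
  match the tabulated-percentage convention.
* All randomness flows from explicit seeds; `runPipeline()` derives
  named substream seeds (simulation, split, cross-validation, cubes)
  from the single root seed, and two runs of one config are
  byte-identical.

# Problem sizes used by the test-suite

Unit tests run on 16–64-band grids with tens of samples per group;
recovery and calibration properties use the full default conditions
(128 bands, 377/192/144 samples) across 10–20 seeds; oracle
equivalences use random 12 × 8 to 50 × 20 matrices. The complete suite
runs in well under a minute on a single core, and the acceptance script
(two full pipelines plus a 10-run recovery study) in about two.

# Known limitations

* PLS-DA is single-response (PLS1) on scalar codes; one-hot
  multi-response PLS2 is out of scope by design.
* More than three groups are supported structurally (SPRI spaces G
  codes evenly; LDA yields G−1 axes) but defaults are tuned for three.
* The ENVI reader supports the common little-endian interleaves
  (bil/bip/bsq) and data types (u8/i16/i32/f32/f64/u16) only.
* Band selection evaluates candidate subsets on a single validation
  split; nested resampling of the whole selection path is not
  implemented.
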