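---
title: "Image-based growth analysis of wheat: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Image-based growth analysis of wheat: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenogrowth)
```

# The problem

Classical growth analysis of annual crops relies on destructive sampling:
measuring leaf area or dry weight ends the plant's life, so every time point
needs its own set of replicate plants, plant-to-plant variation contaminates
the growth signal, and the temporal resolution is limited by how many plants
one can afford to grow and harvest. Machine-vision phenotyping replaces the
destroyed measurement with an image-derived surrogate: the **side-projected
area (SPA)**, the silhouette area of the plant seen from the side, averaged
over rotational views. If SPA tracks the destructive traits faithfully, a
single plant imaged daily yields the whole growth curve.

`phenogrowth` implements this workflow end to end for controlled-environment
wheat: silhouette segmentation from fluorescence-style grayscale images,
trait extraction and physical calibration, interval relative growth rates and
exponential growth-law fits, and the validation statistics that decide
whether the surrogate is trustworthy. Because no public image archive
accompanies the reference study the package reproduces, a synthetic-data
generator supplies images with exact ground truth and destructive-design
trait tables with known generative parameters, so every stage is testable.

# Segmentation

A chlorophyll-fluorescence image shows the plant as a bright silhouette on a
dark background, which makes histogram thresholding appropriate:

1. **Otsu's method** (`otsu_threshold()`): the threshold `t` maximizes the
   between-class variance
   $\sigma_B^2(t) = \omega_0(t)\,\omega_1(t)\,\bigl(\mu_0(t)-\mu_1(t)\bigr)^2$
   over all `2^bit_depth` candidate levels, where class 0 collects gray
   levels below `t`. The scan is exhaustive, ties break toward the lowest
   maximizing level (deterministic and conventional), and a histogram with a
   single occupied level raises a degenerate-histogram error — there is no
   foreground/background split to find.
2. **Binarization** (`binarize()`): pixels *below* the threshold become
   background (0); pixels at or above it belong to the plant (1). Pixels
   exactly at the threshold are foreground.
3. **Cleanup** (`clean_mask()`): a morphological opening (removes isolated
   speckle) followed by a closing (fills pinholes), each with a disc-shaped
   structuring element. The reference workflow states that opening and
   closing follow binarization but not the element sizes; the default is
   radius 1 for both, the smallest cleanup that removes single-pixel noise
   without destroying thin wheat blades, and both radii are configurable
   (`morphology_config()`, radius 0 disables a pass). Morphology is
   delegated to EBImage.

An optional keep-largest-component filter exists (`keep_largest = TRUE`) but
is off by default, since the reference workflow does not mention connected
components.

Thresholding operates on the native gray-level range of the image (256 bins
for 8-bit input); higher bit depths are scanned on their own range rather
than rescaled. Masks use 1 = plant, matrices are row-major with the origin
at top left. Because Otsu's threshold depends only on the histogram,
`segment()` is invariant to adding a constant to every pixel (below
saturation) — the threshold shifts with the histogram.

# Traits and calibration

From a mask, `measure_geometry()` extracts:

* **SPA in pixels** — the sum of mask pixels;
* **height and width** — the inclusive row and column extent of the
  axis-aligned rectangle enclosing the foreground. Height is defined as the
  *vertical* extent of that rectangle (the plausible reading for plants on a
  turntable; the alternative — the rectangle's longest side — differs only
  for plants wider than tall).

Physical units come from a single scalar calibration, `scale` in mm/pixel:
lengths multiply by `scale`, areas by `scale²`. This is the simplest model
consistent with a fixed camera geometry; the reference workflow mentions
"pre-established calibration functions" without specifying them.

One plant at one time point is imaged at 12 azimuthal angles 30° apart, and
its SPA is the **arithmetic mean over views** (`aggregate_angles()`). Fewer
than 12 available views produce a warning, not an error; the mean over
available angles is still returned, which keeps the pipeline robust to
missing frames.

# Growth analysis

Two growth-rate conventions coexist in the literature and differ materially
at the growth rates wheat reaches between samplings:

* `interval_rgr()` — the **simple-ratio** form
  $\mathrm{RGR} = \dfrac{W_2 - W_1}{W_1\,(t_2 - t_1)}$,
  scaled by 1000 for mg g⁻¹ d⁻¹ (mass traits) or left as a bare fraction
  for mm² mm⁻² d⁻¹ (SPA). This is the convention of the reference study's
  interval tables — its published values recompute exactly from its
  published trait means under this formula, and *not* under the log form.
  It is the package default.
* `classical_rgr()` — the **log-difference** form
  $(\ln W_2 - \ln W_1)/(t_2 - t_1)$ implied by exponential growth, provided
  as an explicit alternative. The two agree to first order when the relative
  increment is small.

`rgr_table()` maps an ordered series of `n` time points to its `n − 1`
consecutive-interval rates. `fit_compound_interest()` fits the
compound-interest law $W(t) = W_0 e^{rt}$ by least squares of $\ln W$ on
$t$, which is exact on noise-free exponential data and unbiased in log
space under multiplicative noise; with exactly two points it reduces to the
closed form $r = \ln(W_2/W_1)/\Delta t$.

RGR is computed on per-genotype means by default because a destructive
design has no paired plants across time points. Per-plant RGR is available
for longitudinal (non-destructive) data, which `pipeline_growth()` detects
automatically when every plant spans the full schedule.

# Validation statistics

`ols_simple()` regresses each destructive trait on SPA and reports slope,
intercept, $R^2$, Pearson $r$ (with $r^2 \equiv R^2$ in simple regression,
asserted to $10^{-9}$ in the tests) and the slope's t-test p-value.
Regressions against the reference study's tables are fit on the 8
per-genotype time-point means — verified to reproduce the published rows —
not on per-plant records, which the published tables do not contain.

`two_way_anova()` decomposes a balanced genotype × time-point design with
replicates into sequential sums of squares (order-invariant under balance),
F-tests against the residual mean square, and a model $R^2$. Unbalanced
designs are rejected explicitly rather than silently approximated: the
study design is balanced, and sequential SS would become order-dependent
otherwise. A response with zero variance yields a zero table with a
warning instead of 0/0 F ratios.

`fit_exponential_predictor()` addresses the late-season breakdown of the
linear SPA→biomass model: after heading, spikes add mass without adding
silhouette, so biomass accelerates relative to SPA. The exponential model
$y = a e^{bx}$ is fit with closed-form log-linear starting values refined
by nonlinear least squares on the original scale. The refinement matters:
pure log-scale fitting down-weights the largest (heaviest) plants and can
produce a back-transformed fit *worse* than the linear competitor on the
original scale, which would contradict the very comparison the model
exists for; nonlinear refinement minimizes the same residual sum of squares
that the linear model's $R^2$ is computed from, making "pseudo-$R^2$ vs
$R^2$" a like-for-like comparison. On zero-residual (exactly exponential)
data, where the nonlinear step has nothing to improve and its convergence
test degenerates, the closed-form log-linear estimates are kept.

# The synthetic-data generator

The generator emulates two things: the imaging chain and the destructive
study design.

**Images** (`render_plant()`): a plant is a fan of thin, tapered blades —
quadratic centreline with linear taper, the cheapest geometry that produces
wheat-like elongated silhouettes and genuinely stresses the morphology
settings. Each blade lies in a vertical plane at its own azimuth; viewing
from angle $\theta$ projects the lateral sweep by $\cos(\phi - \theta)$, so
views 180° apart are mirror images with identical SPA. Foreground and
background intensities are drawn from normal distributions (defaults
180 ± 10 vs 30 ± 10 on an 8-bit scale, mimicking strong fluorescence
contrast), rounded and clipped. The rasterized silhouette *is* the ground
truth: exact pixel count, exact mask.

The default canvas is 200 × 200 px at 1 mm/px. This is a deliberately
reduced geometry chosen so that blade widths (5–8 mm) span at least ~5
pixels — wide enough that radius-1 morphology edits only silhouette
boundaries, as it does at production camera resolution where a plant spans
thousands of pixels. Even so, synthetic mini-plants carry at most ~8k
silhouette pixels, below the real study's smallest plants (~12.5k at this
scale); boundary effects are therefore *over*-represented, and the 2–4%
per-plant SPA recovery error measured in the acceptance run should be read
as a conservative bound on study-scale accuracy.

**Trait tables** (`simulate_destructive_study()`): the latent trajectory is
exponential growth whose instantaneous rate declines logistically,

$$\mathrm{SPA}(t) = \mathrm{SPA}_0 \exp\!\Bigl(r\bigl[(t - t_0) -
\tau\,\Delta\mathrm{softplus}\bigr]\Bigr),\qquad
r(t) = \frac{r_0}{1 + e^{(t - t_h)/\tau}},$$

so early intervals obey the compound-interest law and late intervals
flatten, as real wheat does between stem elongation and grain fill. Leaf
area and leaf dry weight are proportional to SPA; biomass is proportional
before heading and inflates by a factor $(1 + 0.08\,\mathrm{d}^{-1}\times
(t - t_\mathrm{head}))$ afterwards. The 0.08 d⁻¹ default matches the
~0.06–0.07 d⁻¹ post-heading excess of biomass RGR over SPA RGR visible in
the reference study's interval tables; it makes the late biomass–SPA
relation superlinear without letting late RGR exceed early-season values.

Default genotype parameters (`default_genotypes()`) give an early-heading
genotype (heading 39 DAP, rate halving at 34 DAP) and a late-heading one
(heading 51 DAP, halving at 36 DAP), with starting SPA near the reference
magnitudes (12.5k and 10.9k mm² at 21 DAP) and 6–10× growth by 53 DAP.

Noise is plant-to-plant, lognormal and **shared across the four traits of a
plant** (default log-sd 0.12, mean-one corrected), with smaller independent
per-trait scatter (0.04). The shared factor is not a nicety: in a
destructive design the same harvested plant supplies both its image-derived
SPA and its weighed biomass, and without that shared size variation the
interval RGRs of biomass and SPA would decorrelate under replication noise
and the study's central cross-validation result could not emerge from the
simulation at all. Destructive semantics are the default — fresh,
independent plants at every time point, no plant sampled twice; a
longitudinal mode draws each plant's factors once so the same plants
persist, enabling per-plant growth curves.

**What the generator does not emulate:** leaf occlusion and overlap,
spike/head geometry (only a scalar biomass inflation), diurnal movement,
senescence, color/texture variation, illumination gradients, camera
distortion. Passing tests therefore certify the computational pipeline —
thresholding, morphology, measurement, statistics — under a controlled,
favorable imaging model; they do not certify segmentation performance on
real images with shadows, reflections or overlapping organs.

# Numerical choices and degenerate inputs

* Otsu ties: lowest maximizing level. Candidate thresholds leaving an empty
  class are excluded.
* Rounding for comparison against published values: half-up (commercial)
  rounding at the published number of decimals (`round_half_up()`,
  `matches_printed()`), since 372.28 prints as 372.3; each published value's
  own precision is the comparison surface.
* `interval_rgr()` requires a positive baseline ($W_1 > 0$) and a positive
  interval; negative rates are allowed (a shrinking trait is data, not an
  error). The growth-law fit requires strictly positive values throughout.
* Empty masks: SPA is 0; the bounding extent errors (there is no rectangle
  to report); the pipeline records the zero-area row.
* All generators are seed-deterministic; identical spec + seed gives
  bit-identical images and tables. Seeded rendering restores the caller's
  RNG state.

# Problem sizes in tests and the acceptance run

The bundled checks run at desk scale: 100 random histograms against the
exhaustive Otsu oracle, three rendered plants × 12 views for segmentation
recovery, 500 simulated datasets for the interaction-test null, 100 noisy
series for growth-rate recovery, and a 2 × 8 × 5 design for the ANOVA
decomposition — sizes chosen so the whole suite completes in well under a
minute while keeping Monte-Carlo standard errors far below the asserted
margins.

# Known limitations

* The published interval-RGR table of the late-heading reference genotype
  does not recompute exactly from its published trait means (the
  early-heading genotype's does, to every printed digit); its published RGR
  values are therefore carried as a read-only reference table and the
  package does not "correct" either source.
* The reference study's per-plant ANOVA $R^2$ values require raw per-plant
  data that the published tables cannot reconstruct (means ± SE are not
  sufficient); the package validates its ANOVA against algebraic oracles
  and simulation instead.
* Height is the vertical extent of the enclosing rectangle (see above);
  leaning plants are measured as their vertical projection.
* The scalar mm/px calibration assumes a fixed camera distance; it does not
  model perspective or lens distortion.
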