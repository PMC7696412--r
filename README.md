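# phenogrowth

Machine-vision growth analysis for controlled-environment wheat phenotyping.

Classical growth analysis destroys every plant it measures: leaf area, leaf
dry weight and above-ground biomass each require a harvest, so a growth
curve over eight time points with five replicates consumes forty plants per
genotype and still inherits plant-to-plant variability. Image-based
phenotyping replaces the harvested measurement with a non-destructive
surrogate — the **side-projected area (SPA)**: the plant's silhouette area
seen from the side, averaged over 12 rotational views and calibrated to
mm². `phenogrowth` implements the full analysis chain that turns grayscale
fluorescence-style images into validated growth statistics, for
physiologists and phenotyping-facility engineers who need the computation
without the conveyor belt.

## What it computes

* **Segmentation** — Otsu's histogram threshold (exhaustive maximization of
  the between-class variance ω₀ω₁(μ₀−μ₁)²), binarization with
  below-threshold pixels as background, morphological opening + closing
  cleanup (`segment()`, `otsu_threshold()`, `clean_mask()`).
* **Traits** — SPA as the mask pixel sum, height/width as the enclosing
  rectangle, scalar mm/px calibration (lengths ×s, areas ×s²), 12-angle
  averaging (`measure_geometry()`, `aggregate_angles()`).
* **Growth** — interval relative growth rate in the simple-ratio form
  RGR = (W₂−W₁)/(W₁·Δt) (the convention of destructive interval tables;
  `interval_rgr()`, `rgr_table()`), the log-difference alternative
  (`classical_rgr()`), and the compound-interest growth law W(t) = W₀e^{rt}
  fit by log-linear least squares (`fit_compound_interest()`).
* **Validation** — OLS of each destructive trait on SPA, Pearson
  correlation of biomass-based vs SPA-based RGR, balanced two-way ANOVA
  (genotype × time point with interaction), and a linear-vs-exponential
  SPA→biomass model comparison (`ols_simple()`, `pearson()`,
  `two_way_anova()`, `fit_exponential_predictor()`).
* **Synthetic data** — fluorescence-style plant renders with exact
  ground-truth masks and a destructive growth-study simulator with known
  generative parameters (`render_plant()`, `simulate_destructive_study()`,
  `simulate_imaging_series()`), so every stage is testable without an image
  archive.
* **Reference tables** — the published per-genotype trait means, interval
  RGRs and regression rows of a two-genotype spring wheat growth study
  (8 time points, 21–53 days after planting, n = 5) are bundled as
  plain-text fixtures (`wheat_trait_means()` and friends), and
  `reproduce_reference_analysis()` recomputes every reproducible published
  quantity from them.

## Worked example

Simulate a destructive study with the default two genotypes (an early- and
a late-heading one), then run the growth and validation analyses:

```r
library(phenogrowth)

sim <- simulate_destructive_study(growth_sim_spec(seed = 7))
head(sim, 3)
#>        genotype              plant_id dap       LA       LDW      BIO      SPA
#> 1 early_heading early_heading_d21_p01  21 171.0956 1031.5459 1444.497 15695.46
#> 2 early_heading early_heading_d21_p02  21 125.4461  716.0601 1002.218 12081.24
#> 3 early_heading early_heading_d21_p03  21 158.7185  921.6931 1180.080 13962.98

v <- pipeline_validate(sim)
v$regressions[, c("genotype", "response", "slope", "r2", "pearson_r")]
#>        genotype response      slope        r2 pearson_r
#> 1 early_heading       LA 0.01113201 0.9967888 0.9983931
#> 2 early_heading      LDW 0.06606498 0.9980849 0.9990420
#> 3 early_heading      BIO 0.16905528 0.7849370 0.8859667
#> 4  late_heading       LA 0.01593614 0.9963591 0.9981779
#> 5  late_heading      LDW 0.09827824 0.9971128 0.9985553
#> 6  late_heading      BIO 0.08303910 0.9772112 0.9885399

v$rgr_correlations
#>        genotype pearson_r        r2 n
#> 1 early_heading 0.8545065 0.7301814 7
#> 2  late_heading 0.9811046 0.9625663 7
```

Leaf area and leaf dry weight regress on SPA almost perfectly (R² ≈ 0.997);
biomass is predicted worst for the *early*-heading genotype (R² 0.78) — its
spikes have been adding mass without adding silhouette for 14 simulated
days, exactly the post-heading breakdown of the linear surrogate seen in
real data. The interval RGRs of biomass and SPA correlate at 0.85–0.98
across the seven intervals, the cross-validation that justifies replacing
harvested growth rates with image-based ones.

The same machinery replays the published reference study from the bundled
tables:

```r
out <- reproduce_reference_analysis()
#> quantity                                          computed    printed  match
#> RGR_LDW Yecora-Rojo 21-25                              309        309    yes
#> ...
#> RGR_BIO~RGR_SPA r Seri-82                            0.912       0.91    yes
#> 30 / 30 quantities reproduce at printed precision
```

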