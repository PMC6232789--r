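---
title: "Parametric iron MRI mapping and localized deposit quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parametric iron MRI mapping and localized deposit quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(femri)
```

## The problem

Tumor-associated macrophages (TAMs) sequester iron — both endogenous iron and
injected ultrasmall superparamagnetic iron oxide (USPIO) nanoparticles — in
compact multicellular colonies near the vascularized tumor margin. Iron
shortens the effective transverse relaxation time T2\*, so a multi-gradient-echo
(MGE) MRI acquisition carries a per-pixel iron signal. The analytic question is
how to quantify that signal so that a biologically real change (more deposits
after USPIO injection, each deposit unchanged in size) shows up with maximal
statistical sensitivity in a small cohort.

`femri` implements two quantification routes over the same parametric iron
map and a simulation harness that contrasts them:

* **whole-ROI distribution statistics** — the conventional approach: pool all
  tumor pixels, bin cluster counts and sizes by concentration, and compare
  group medians;
* **localized cluster counting** — threshold the map at the high-iron
  stratum, label connected pixel clusters, and compare their count and areas
  between groups.

## Signal model and relaxometry

Each pixel of the MGE series decays monoexponentially,

$$S(\mathrm{TE}) = S_0 \, e^{-R_2^* \cdot \mathrm{TE}}, \qquad
  R_2^* = 1/T_2^*,$$

with sixteen echoes at 3 ms spacing (TE = 3–48 ms) in the default phantom.
`fit_monoexponential()` estimates $(S_0, R_2^*)$ per pixel by nonlinear least
squares. The fit is initialized from the log-linear regression of
$\ln S$ on TE, weighted by $S^2$ — the delta-method variance weighting that
keeps noise-dominated late echoes from destabilizing the line — and refined by
a damped Gauss–Newton iteration vectorized across all pixels (at most 20
iterations; the two-parameter problem converges in a handful). On noiseless
input the initialization is already exact, so the noiseless phantom is
recovered to machine precision. A log-linear-only estimator
(`method = "loglinear"`) is provided for comparison.

Pixels whose first-echo signal falls below `min_signal_fraction` (default
0.05) of the masked 99th-percentile first-echo signal are excluded
(`fit_ok = FALSE`): there the decay model is not identifiable. Negative fitted
rates are clamped to zero. Rates are carried in s⁻¹ with echo times in ms;
the unit conversion is explicit at the fit boundary.

## Calibration and stratification

Aqueous iron standards of known concentration give a linear relation
$R_2^* = m\,C + b$ (`fit_calibration()`, ordinary least squares; the fitted
line must have positive slope). Inverting the line per pixel yields the
parametric FeMRI map (`apply_calibration()`). Concentrations are clamped to
the calibrated range — the map saturates rather than discards, matching how
such maps are displayed — and rates below the intercept map to zero
(physical non-negativity).

`stratify()` splits the map at the midpoint of the calibrated range: for the
0.0–0.3 mg iron(III)/g range the high-iron stratum is **0.15–0.3 mg/g**. The
boundary is inclusive (a pixel at exactly 0.15 is high) so ties resolve
deterministically toward deposit sensitivity. The calibration constants
themselves are instrument-specific inputs; the phantom defaults
(m = 400 s⁻¹ per mg/g, b = 20 s⁻¹) are plausible 7 T values used only for
simulation.

## Cluster quantification

`label_clusters()` labels connected components of a binary mask with a
two-pass union-find, under 4- or 8-connectivity (default 8, the common
particle-analysis convention). Labels are ordered deterministically by each
component's topmost-then-leftmost pixel. Areas are always
`pixel_count × pixel_size²`. The implementation is oracle-tested against an
independent brute-force flood fill.

`cluster_distribution()` reproduces the whole-ROI route: 15 equal-width
concentration bins over the calibrated range (0.02 mg/g bins; the bin width
is a configuration knob), per-bin cluster counts and mean areas, and two
summary medians computed over the per-cluster mean concentrations —
`median_iron_freq` (each cluster weighted equally) and `median_iron_size`
(clusters weighted by area). Computing the medians from per-cluster
concentrations rather than from binned bin centers keeps them continuous;
a median snapped to a bin center collapses to identical values across
subjects and carries no between-group information. `high_iron_metrics()`
is the localized route: count and areas of connected high-stratum clusters
inside the tumor ROI.

## Histological deposit mapping

The matched histology pipeline mirrors the MRI analysis at full resolution:

1. `detect_iron_pixels()` — a pixel is iron-positive when its blue chromatic
   fraction $B/(R+G+B)$ is ≥ 0.5 and its luminance is below the white
   background cutoff (0.9); label rasters bypass the color rule.
2. `downsample_to_mri()` — block mean over `factor × factor` tiles (pixel
   averaging), with bilinear resampling only when dimensions are not exact
   multiples. The default 1:100 per-axis factor maps a ~1 µm/px scan onto the
   0.1 mm MRI grid; the value is the iron-positive area fraction per
   MRI-scale pixel and block means conserve total mass exactly.
3. `watershed_deposits()` — Gaussian smoothing (σ = 0.5 low-resolution
   pixels), threshold at `min_density` = 0.02, watershed splitting of touching
   colonies, regions below `min_area` = 1 px dropped. σ = 0.5 is the matched
   smoothing scale for colonies spanning roughly one MRI-scale pixel
   (~100 µm); a broader kernel dilutes small colonies below the density
   threshold and loses them.
4. `count_cells_per_deposit()` — each iron-positive cell centroid (µm
   coordinates at full resolution) is assigned to the deposit label under it;
   background-landing cells are counted as unassigned, out-of-raster cells as
   skipped. Assigned + unassigned always equals the iron-positive total.

In phantoms, ground-truth centroids are authoritative for counting; for real
RGB sections a user-supplied cell table (from any cell caller) plays the same
role — decoupling counting from segmentation quality.

## Polarization statistics

`polarization_frequencies()` computes the M1/M2 split
$f_{M1} = N(\mathrm{AIF1^+}) / (N(\mathrm{AIF1^+}) + N(\mathrm{CD206^+}))$
with $f_{M2} = 100\% - f_{M1}$ exactly. Double-positive AIF1⁺CD206⁺ cells
count toward both tallies by default (they are a separately reported
population; the alternative `double_positive = "exclude"` is provided).
`iron_subset_frequencies()` reports iron⁺X⁺/X⁺ for X ∈ {CD68, AIF1, CD206,
AIF1∩CD206} as percentages.

`two_tailed_t_test()` is the pooled-variance (Student, not Welch) unpaired
two-sample t-test with a two-tailed p on $n_1+n_2-2$ df, matching the study
design it serves. Zero pooled variance returns p = 1 for equal means and
p = 0 otherwise — a documented convention so simulations never crash on
degenerate draws. No multiple-testing correction is applied (none is applied
in the design being emulated); reports should state this.

## The synthetic phantoms

**MRI phantom** (`generate_mri_phantom()`): a tumor disc (default radius
50 px = 5 mm at 0.1 mm/px on a 256×256 grid, i.e. a ~1 cm-diameter cross
section) with a Gaussian baseline iron field (0.03 ± 0.01 mg/g, clamped to
[0, 0.12] so the bulk sits well inside the low stratum and distribution
maxima fall in the low range) plus `n_deposits` compact blobs grown by
seeded random walk to Poisson(4)-pixel target areas, each assigned a uniform
iron level in [0.15, 0.3] mg/g. Deposits are confined to the peripheral
margin band (default outer 50% of the radius) and placed by rejection
sampling with a per-pair center separation of $r_i + r_j + 2$ px, which
guarantees blobs are disjoint and non-adjacent under 8-connectivity — hence
the high-cluster count of a noiseless phantom equals the planted count
exactly. Noise is additive Gaussian on magnitude (the high-SNR approximation
of Rician noise; `rician = TRUE` switches to true magnitude noise), clamped
at zero.

**Histology phantom** (`generate_histo_phantom()`): a 2200×2200 px section at
2 µm/px (4.4 mm) with a tumor disc at 45% of the half-width; 20 colonies of
Poisson(14) iron⁺ cells (Gaussian scatter σ = 30 µm around centers ≥ 500 µm
apart in the outer 35% margin band) and 500 diffuse background macrophages,
iron⁺ with probability 0.004. Cells paint 8 µm-radius discs — iron-laden
macrophages are ~15–20 µm across — so a 14-cell colony spans roughly one
MRI-scale pixel, the regime the watershed defaults are matched to. Marker
flags follow the configured frequencies (defaults 42% AIF1⁺ / 58% CD206⁺, no
double positives).

What the phantoms deliberately do **not** model: TR/flip-angle/fat-suppression
effects, coil inhomogeneity, motion, slice profiles, photorealistic staining,
stain deconvolution, or histology-to-MRI registration. Passing tests show the
analysis chain is correct and sensitive under the stated statistical
structure; they do not certify performance on real scanners or slides.

## The power contrast simulation

`compare_roi_vs_localized()` simulates the cohort design: per replicate, 8
control tumors with Poisson(235/8) ≈ 29 deposits per cross section and 8
treated tumors with Poisson(748/8) ≈ 94, sharing one deposit size
distribution. Each section runs the full relaxometry → calibration →
stratification → cluster pipeline, and the four per-section metrics are
compared between groups by the pooled t-test. Sections use a 144×144 grid
with tumor radius 60 px and margin band 0.6 — the annulus must accommodate
the upper tail of Poisson(94) deposit draws without violating the separation
constraint. With a count-only effect, the localized cluster-count t-statistic
dominates the ROI median t-statistic, and cluster size stays non-significant
— the qualitative pattern the localized analysis is designed to expose.
`deposit_count_power()` and `deposit_size_null()` isolate the two
cohort-level statistics (deposit counts 235 vs 748 totals over 8 tumors;
areas from one shared lognormal with median 4 low-res pixels, σ = 0.5) as
fast direct simulations.

## Numerical choices and degenerate inputs

* Weighted median: smallest value at which cumulative weight reaches half
  the total; empty weights give `NA`.
* Constant signal fits rate 0; a tie at the stratification threshold is
  "high"; an empty density raster yields zero watershed labels; a cohort
  metric that is `NA` for a subject (no high cluster) is dropped from that
  t-test.
* All generators take integer seeds and are bit-reproducible; simulation
  replicates use `seed + r - 1`.
* Problem sizes in the shipped tests (256² noiseless phantom, 10⁴ noisy
  pixels, 50 histology seeds, 25 cohort replicates) were chosen as the
  smallest sizes at which the statistical assertions are stable.

## Known limitations

* The calibration constants of any particular scanner must be supplied; the
  shipped values are simulation stand-ins.
* Whole-slide pyramid formats (MRXS) and DICOM are out of scope; rasters are
  exchanged as NIfTI/TIFF/PNG plus CSV tables.
* Cluster analysis is strictly 2D per cross section; no multi-slice merging.
* Cell identity in real RGB sections relies on an external cell caller; the
  built-in color rule detects stained pixels, not cells.
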