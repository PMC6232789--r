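# femri

Quantification of endogenous and nanoparticle (USPIO) iron contrast in tumor
MRI, built around the observation that tumor-associated macrophages
concentrate iron in rare, compact deposits at the tumor margin. `femri` is
for imaging scientists who want to turn multi-gradient-echo (MGE) series
into parametric iron maps and then quantify them with *localized* cluster
statistics rather than whole-ROI averages — plus the matched histology
pipeline to validate the MRI observables against Prussian-blue-stained
sections.

## The method

1. **Relaxometry.** Each pixel of an MGE series decays as
   S(TE) = S₀·exp(−R₂\*·TE). Pixel-wise nonlinear least squares (log-linear
   initialized, Gauss–Newton refined) yields R₂\* = 1/T₂\* maps.
2. **Iron calibration.** Standards of known concentration give a linear
   relation R₂\* = m·C + b; inverting it per pixel produces the parametric
   FeMRI map, clamped to the calibrated range (default 0.0–0.3 mg iron/g).
3. **Stratification.** The high-iron stratum starts at the range midpoint
   (0.15 mg/g); deposits live there, tumor bulk does not.
4. **Cluster quantification.** Connected components of high-iron pixels
   (union-find labeling, 4/8-connectivity) give the localized observables —
   cluster count and per-cluster area (mm²) — alongside the conventional
   whole-ROI concentration-binned distribution and its medians.
5. **Histology.** Iron⁺ pixel detection (blue chromatic ratio), 1:100
   pixel-averaged downsampling to MRI resolution, watershed discretization
   into deposits, and per-deposit cell counts at full resolution; M1/M2
   polarization frequencies (AIF1/CD206) and iron⁺ subset frequencies from
   cell tables.
6. **Statistics.** Two-tailed pooled-variance Student's t-tests between
   groups, and a simulation harness showing that when a treatment changes
   deposit *count* but not *size*, counting localized clusters detects it
   far more sensitively than ROI distribution medians.

A synthetic phantom module (MGE series and histology sections with known
ground truth) makes every stage testable end to end.

## Worked example

```r
library(femri)

# a 256x256 tumor cross section, 0.1 mm pixels, 30 planted deposits
ph  <- generate_mri_phantom(mri_phantom_config(n_deposits = 30, seed = 1))
res <- analyze_mge_phantom(ph)   # fit -> calibrate -> stratify -> clusters
res$n_high_clusters
#> [1] 30
signif(res$median_iron_freq, 4)      # whole-ROI median iron, mg/g
#> [1] 0.04096
signif(res$mean_high_area_mm2, 4)    # mean high-iron cluster area, mm^2
#> [1] 0.041

# cohort comparison: per-tumor high-cluster counts, control vs treated
two_tailed_t_test(c(28, 31, 25, 33), c(90, 102, 95, 88))
#> t(6) = -18.03, two-tailed p = 1.87e-06
#>   group a: 29.25 +/- 1.75 SEM (n = 4)
#>   group b: 93.75 +/- 3.119 SEM (n = 4)

# matched histology: 20 colonies of ~14 iron+ macrophages each
hp   <- generate_histo_phantom(histo_phantom_config(seed = 1))
hres <- map_histology_deposits(hp$raster, hp$truth$cell_table)
nrow(hres$deposit_table)
#> [1] 20
signif(mean(hres$deposit_table$iron_cell_count), 4)
#> [1] 14.45

pol <- polarization_frequencies(hp$truth$cell_table)
c(M1 = signif(pol$f_m1_pct, 4), M2 = signif(pol$f_m2_pct, 4))   # percent
#>    M1    M2
#> 41.71 58.29
```

The phantom recovers exactly the planted 30 MRI deposits and 20 histology
colonies; the t-test shows the ~3-fold count difference between cohorts at
p < 0.001 while the whole-ROI median shifts only slightly (see the methods
vignette and `compare_roi_vs_localized()` for the full contrast).

An end-to-end run with all intermediate rasters, tables, a resolved
key=value config and a JSON report:

```r
run_pipeline(default_run_config())
```

or from a shell: `Rscript inst/cli/femri.R run-all --out femri-out --seed 1`.

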