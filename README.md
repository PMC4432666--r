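# tractwise

Longitudinal along-tract analysis of white-matter fractional anisotropy
(FA), built as a complete, desk-scale tractometry pipeline with a
synthetic-data generator in place of scanner data.

## The problem

Longitudinal diffusion-tensor imaging (DTI) studies of aging ask how the
microstructural integrity of specific white-matter fiber bundles — for
example the connections between subcortical nuclei (thalamus, caudate,
putamen, pallidum, accumbens) and frontal white-matter regions — changes
over years within the same individuals. The standard analysis chain is:

1. **Tensor reconstruction.** Per voxel, fit the diffusion tensor *D* to the
   DWI signal by ordinary least squares on the log signal,
   ln *S* = ln *S*₀ − *b* **g**ᵀ*D* **g**, and compute its eigensystem.
2. **FA.** FA = √(3/2) · ‖λ − λ̄‖ / ‖λ‖ from the eigenvalues λ₁ ≥ λ₂ ≥ λ₃.
3. **Tractography.** Deterministic whole-volume streamline tracking by
   fiber assignment by continuous tracking (FACT): bidirectional
   propagation along the principal eigenvector with FA and turning-angle
   stopping rules.
4. **Tract-of-interest extraction.** Keep streamlines intersecting both a
   subcortical seed label and a frontal target label; a bundle is
   recognized with ≥ 20 continuous fibers, and a connection enters group
   analysis when detected in ≥ 90 % of the cohort.
5. **Tractometry.** Tract mean FA is the grand average over the FA-map
   voxels intersected by the bundle; along-tract profiles resample every
   streamline to 100 equidistant points from seed (point 1) to target
   (point 100), with 2 × 100 segments for midline-crossing callosal-style
   bundles and a single-defining-ROI mode for corticospinal-style tracts.
6. **Longitudinal statistics.** Per-subject annual percentage FA change
   (100 · ΔFA / FA / years, averaged across the cohort), a 2.5-SD
   sample-wide outlier exclusion, paired *t*-tests between two study
   waves, one-way repeated-measures ANOVA for three waves, Pearson
   correlation of change with baseline age, and Bonferroni-corrected
   alphas (0.05/22 = 0.0023 for tract-mean tests, 0.05/100 = 0.0005 for
   segment-wise tests).

Raw cohort scans for such studies are typically not redistributable, so
the package ships a first-class phantom module: curved fiber bundles
(straight, arc, S-curve) rasterized into axially symmetric tensor fields
with known FA, Stejskal–Tanner DWI simulation with Rician noise, and
multi-wave cohorts with known per-subject annual FA decline — every stage
of the pipeline is testable against ground truth, including parameter
recovery of the decline rate.

## Worked example

Simulate a 10-subject, two-wave cohort in which the straight bundle truly
declines by 1.5 ± 0.5 %/year while the other two bundles are stable, run
the full pipeline, and test for longitudinal change:

```r
library(tractwise)
spec <- phantom_cohort_spec(n_subjects = 10, waves = 2,
                            annual_decline_pct = c(1.5, 0, 0),
                            annual_decline_sd = 0.5, snr = 25, rng_seed = 42)
st <- run_phantom_study(spec)
st$detection
#>      arc   scurve straight
#>       10       10       10
connection_change_table(st$cohort, m_comparisons = 22)
#> Longitudinal FA change, 3 connection(s); corrected alpha = 0.0023
#>  connection w1_mean   w1_sd w2_mean   w2_sd  p_value  n pct_change_per_year
#>    straight   0.439 0.00485   0.412 0.01195 9.92e-05 10             -1.7453
#>         arc   0.421 0.00883   0.420 0.00875 9.09e-01 10              0.0157
#>      scurve   0.424 0.00650   0.420 0.00840 2.87e-01 10             -0.3168
#>  m_excluded significant
#>           0        TRUE
#>           0       FALSE
#>           0       FALSE
```

All three bundles are detected in all 10 subjects; only the truly
declining connection is flagged at the corrected alpha, with an estimated
decline (−1.75 %/year here, at this small *n*) near the generative rate.
`segmentwise_longitudinal_test()` performs the same analysis per
along-tract segment, and `plot()` methods display profiles and
segment-wise change.

A disk-based, resumable variant with per-stage caching, NIfTI/.trk/TSV
outputs and a run manifest is available as `run_pipeline()`
(`pipeline_config()` / plain-text config files), with a thin command-line
wrapper in `inst/cli/tractwise.R` exposing the stages as subcommands
(`simulate`, `fit`, `track`, `extract`, `profile`, `stats`, `run-all`).

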