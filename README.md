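# nmrstress

An R package implementing the complete data-analysis chain of a two-group
¹H-NMR metabolomics study — 6 non-stressed control rats versus 7 acutely
restraint-stressed rats — together with the study's closed-form biochemical
calculations. It is aimed at metabolomics practitioners who want a
transparent, fully testable re-implementation of the classic
binning → exclusion → normalization → PCA → OPLS-DA → correlation-cutoff
workflow, and at methodologists who need a synthetic-spectrum testbed with
known ground truth.

## What it computes

**Spectral chain.** Spectra are referenced by rigid peak-position
calibration (lactate CH₃ at δ 1.33 for plasma, TSP at δ 0.00 otherwise),
segmented into 0.005-ppm half-open bins by exact trapezoid integration,
stripped of matrix-specific solvent/urea windows (plasma δ 5.40–5.90 and
δ 4.20–5.10; urine δ 5.35–5.90 and δ 4.14–5.25; tissue δ 4.67–5.22 and
δ 3.31–3.40), and normalized (total area to 100, or probabilistic
quotient). PCA provides unsupervised quality control. OPLS-DA with Pareto
scaling splits variation into one class-predictive component plus
orthogonal components:

    w ∝ X'y,   w_o ∝ p − (w'p)w,   X ← X − t_o p_o',   t_pred = X w

with R²X the modelled fraction of the scaled matrix's sum of squares and
Q² = 1 − PRESS/SS from 7-fold venetian-blind cross-validation (scaling
refit per fold). Per-bin correlation loadings r(t_pred, x_j) are thresholded
at the Pearson critical value

    r_c = t_{1−α/2, df} / sqrt(t² + df)  →  r_c(0.05, 5) = 0.7545 ≈ 0.755

to select discriminating metabolites (reported r = signed max-|r| over each
metabolite's annotated bins; positive r = elevated in the stressed group).

**Biochemistry.** Xanthine oxidoreductase activity from 290-nm absorbance
changes, `(ΔA_test − ΔA_blank)·V_total·10⁶/(ε·d·V_sample·T)` in U/mL;
xanthine dehydrogenase as XDH = XOR − XO; unpaired pooled-variance
Student's t-tests computed directly from group means/SDs/sizes (Welch
optional); and 2^−ΔΔCt relative gene expression.

**Synthetic cohorts.** `simulate_cohort()` builds 6-vs-7 cohorts of
Lorentzian-multiplet spectra from a shipped 14-metabolite template library,
with configurable fold changes, noise, chemical-shift jitter and baseline
drift, returning exact ground truth so the whole chain's recovery behaviour
is measurable.

## Worked example

```r
library(nmrstress)

## Serum enzyme activities (U/mL) from the shipped assay summaries
act <- xor_activity_summaries()
xdh_from_xor_xo(act$xor_mean, act$xo_mean)
#> [1] 0.246 0.171        # non-stressed vs stressed XDH

## Pooled t-test from the published uric acid group summaries
ua <- subset(serum_biochemistry(), analyte == "uric_acid")
pooled_t_test(group_summary(ua$mean_nonstressed, ua$sd_nonstressed, 6),
              group_summary(ua$mean_stressed,   ua$sd_stressed,   7))
#> t = 1.916, df = 11, p = 0.082

critical_r(0.05, 5)
#> [1] 0.7545

## End-to-end synthetic run: three 1.5-fold perturbed metabolites
cfg <- run_config(
  design = cohort_design(
    metabolite_effects = c(creatine = 1.5, succinate = 1.5, acetone = 1.5),
    noise_sd = 0.02, shift_jitter_sd = 2e-4, baseline_amplitude = 0.01,
    n_points = 8192),
  matrix_type = "tissue", seed = 1)
rep <- run_pipeline(cfg)
rep
#> <run_report> tissue matrix, 1872 bins retained; R2X = 0.451, Q2 = 0.921
#> discriminating metabolites: 36; TPR = 1, FP = 7
head(as.data.frame(rep$table), 3)
#>   metabolite comparison      r
#> 1    acetone     tissue  0.936
#> 2  allantoin     tissue -0.933
#> 3 alpha-glc.     tissue -0.899
```

All three perturbed metabolites are recovered with |r| > 0.9. The flagged
unperturbed metabolites carry *negative* r: with total-area normalization, a
net increase in a few metabolites depresses every other bin in the stressed
group (the closure effect) — a real and documented property of
area-normalized binning, discussed in the methods vignette
(`vignettes/nmrstress-methods.Rmd`) together with all modelling choices and
defaults.

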