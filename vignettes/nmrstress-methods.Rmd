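---
title: "Methods: simulated 1H-NMR cohorts, OPLS-DA and the correlation cutoff"
author: "nmrstress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated 1H-NMR cohorts, OPLS-DA and the correlation cutoff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrstress)
```

## The problem

`nmrstress` models the data-analysis chain of an untargeted ¹H-NMR
metabolomics comparison between two small groups of animals — 6 non-stressed
controls versus 7 acutely restraint-stressed rats — across several
biological matrices (plasma, urine, tissue extracts). The chain is: spectral
referencing, fixed-width binning, removal of solvent/urea regions,
normalization, unsupervised PCA for quality control, supervised OPLS-DA,
and selection of discriminating metabolites by a Pearson-correlation cutoff.
Alongside the spectral chain, the package implements the study's closed-form
biochemistry: the Beer–Lambert conversion of 290-nm absorbance changes into
xanthine oxidoreductase activity, XDH = XOR − XO subtraction, unpaired
pooled-variance t-tests computed from published group summaries, and 2^−ΔΔCt
relative gene expression.

Because no raw spectra are deposited for this design, the package ships a
synthetic cohort generator with known ground truth; every downstream stage
is exercised and validated against it.

## The synthetic cohort generator

Each metabolite is a template: a set of Lorentzian lines
$h\,\gamma^2/((\delta-\delta_0)^2+\gamma^2)$ with centres at standard
reference shifts (lactate CH₃ doublet at 1.326/1.340 ppm, α/β-glucose
anomeric signals at 5.23/4.65 ppm, creatine at 3.03/3.93 ppm, aromatic NAD⁺
and nicotinate singlets between 8.1 and 9.3 ppm, and so on — 14 metabolites
in `metabolite_templates()`). A sample spectrum is the
concentration-weighted sum of its templates plus

* a slow sinusoid of random phase (amplitude `baseline_amplitude`),
  mimicking imperfect baseline correction without modelling acquisition
  physics;
* i.i.d. Gaussian noise (`noise_sd`), homoscedastic across the axis — the
  simplest model consistent with a binned-intensity analysis;
* Gaussian chemical-shift jitter (`shift_jitter_sd`) on every line centre,
  emulating small pH/temperature-driven misalignment between samples.

Case-group concentrations are multiplied by per-metabolite fold changes;
the generator returns the exact list of non-unit fold changes as ground
truth. Defaults are the study conditions: 6 controls vs 7 cases, a 0–10 ppm
axis with 8192 points, `noise_sd = 0.01`, `shift_jitter_sd = 0.001` ppm
(one fifth of a bin width), `baseline_amplitude = 0.02` — values a
practitioner would call typical for well-processed 500-MHz biofluid
spectra, since the study itself reports none. Base concentrations are
per-template constants of order 1; only relative group effects matter
downstream.

What the generator does **not** emulate: FID-domain effects (phasing,
apodization, lineshape distortion), J-coupling fine structure beyond fixed
multiplet approximations, pH-dependent shift drift, peak overlap from the
hundreds of minor metabolites in real biofluids, and correlated
(heteroscedastic) noise. Passing tests on these cohorts therefore
demonstrate the correctness of the computational chain, not field
performance on real spectra.

## Preprocessing

* **Referencing** is rigid peak-position calibration: the axis is shifted so
  the tallest point in a search window lands on the reference shift
  (lactate CH₃ at δ 1.33 for plasma, TSP at δ 0.00 for urine/tissue). True
  lineshape ("reference") deconvolution needs the FID, which this package
  never models; for binned integrals a rigid shift is sufficient alignment.
* **Binning** uses half-open buckets `[low, low + 0.005)` anchored at the
  axis minimum — anchoring removes the edge double-counting ambiguity.
  Each bin integral is the exact integral of the trapezoid (piecewise
  linear) interpolant between the bin edges, so the bin sum telescopes to
  the total spectral integral to machine precision. Bins are integrals, not
  mean intensities; for equal-width bins the two differ only by a constant
  factor.
* **Exclusion windows** (urea and residual water for plasma δ 5.40–5.90 and
  δ 4.20–5.10; urine δ 5.35–5.90 and δ 4.14–5.25; tissue water/methanol
  δ 4.67–5.22 and δ 3.31–3.40) drop bins whose *centres* fall inside a
  half-open window. Membership by centre rather than overlap fraction is
  deterministic and order-independent.
* **Normalization** defaults to total-area scaling to 100 (the field's
  historical default for urine/tissue binning, and idempotent); probabilistic
  quotient normalization is available (`normalize_rows(..,
  "probabilistic_quotient")`) and is preferable when a few metabolites carry
  very large fold changes, because total-area scaling then induces
  anti-correlated "closure" artefacts in unchanged bins.

## PCA and OPLS-DA

PCA (`fit_pca()`) mean-centres and uses the singular value decomposition;
scores, orthonormal loadings and per-component explained-variance fractions
follow directly.

OPLS-DA (`fit_oplsda()`) encodes class as centred ±1 (`case` positive) and,
after Pareto scaling (centre, divide by √SD — damping intense peaks without
the noise inflation of unit-variance scaling), computes the PLS1 weight
$w \propto X^\top y$ and removes `n_orth` orthogonal components: each takes
the loading of the current predictive score, strips its component along
$w$, normalizes it into an orthogonal weight $w_o$, and deflates
$X \leftarrow X - t_o p_o^\top$. The predictive component is then extracted
from the deflated matrix. Defaults: one orthogonal component — the minimal
OPLS-DA, matching a 2-D score plot. R²X is the modelled fraction of the
scaled matrix's total sum of squares.

Two conventions matter for interpretation:

* **Correlation/covariance loadings** are computed against the scaled but
  *undeflated* matrix, so they remain interpretable as
  metabolite-versus-class-score correlations (the semantics of the
  published discriminating-metabolite tables).
* **Sign orientation**: the predictive score is flipped so the case-group
  mean is positive; a positive correlation loading then always reads
  "elevated in the stressed group".

Zero-variance columns receive a Pareto divisor of 1 (centred pass-through)
rather than causing division by zero; their correlation loadings are
reported as 0.

**Q²** (`cross_validated_q2()`) uses 7-fold venetian-blind cross-validation
(sample *i* to fold *(i−1) mod 7 + 1*) — deterministic, and the de-facto
default of the commercial software family used for this kind of analysis.
Scaling is refit inside every training fold to prevent leakage. Held-out
class values are predicted by the training-fold regression of y on the
predictive score. Q² = 1 − PRESS/SS(y) may be negative (worse than the
mean); a fold whose training split loses a class raises an error naming the
fold.

At n = 13, label-permutation nulls deserve a caveat: a random 6/7
permutation shares |r| ≥ 0.55 with the true labels about 10% of the time
and then retains genuine class information, so even a perfectly calibrated
Q² shows a small tail of positive values under permutation.

## The correlation cutoff and metabolite selection

For df = 5, the two-tailed p < 0.05 critical value of the Pearson
correlation is $t_{0.975,5}/\sqrt{t^2+5} = 0.7545$; the conventional
adopted cutoff is 0.755, and the package defaults to that fixed value
(`significance_rule()`), with a `computed` mode deriving the cutoff from
any (α, df). The df = 5 convention corresponds to n = 7 pairs and is taken
as given rather than re-derived from the 6-vs-7 group sizes. No
multiple-testing correction is applied beyond the fixed cutoff, matching
the original analysis.

A metabolite is reported when *any* of its annotated bins exceeds the
cutoff; the reported r is the signed value of maximal magnitude among its
bins — how multiple peaks of one metabolite collapse to one table entry is
this package's documented choice. Significant bins outside the annotation
map are kept as `unassigned d<ppm>` with a warning. The default
annotation map covers only the shipped template library (one
non-overlapping diagnostic window per metabolite); real studies must supply
their own assignment table.

## Biochemical calculations

* `enzyme_activity()`: net ΔA × V_total × 10⁶ / (ε·d·V_sample·T), with
  V_total = 2.6×10⁻⁴ L, ε = 1.22×10⁴ L·mol⁻¹·cm⁻¹, d = 0.6 cm,
  V_sample = 0.01 mL, T = 30 min. Activities are linear in net ΔA and
  inverse in T and V_sample; negative values are reported with a warning,
  not clipped, to preserve assay-QC visibility.
* `xdh_from_xor_xo()`: XDH = XOR − XO.
* `pooled_t_test()`: Student's pooled-variance test from summaries — the
  default because it reproduces the study's reported p-values (computed
  with mainstream commercial statistics software, whose default line is the
  equal-variance test); Welch is available via `welch = TRUE`. Note the
  shipped serum table is treated as mean ± SD per its own footnote, even
  though the surrounding text mentions SEM — the footnote is attached to
  the numbers and governs.
* `ddct_fold_change()`: 2^−ΔΔCt; swapping case/control roles returns the
  reciprocal.

## Numerical and design choices

* Bin integrals are differences of the exact cumulative integral of the
  piecewise-linear interpolant at bin edges: conservation of the total
  integral is exact up to floating rounding (tested at 10⁻⁹ relative).
* The master pipeline seed fans out to per-stage substreams by a stable
  string hash kept below 2³¹, so a stage rerun in isolation reproduces its
  output; the simulator saves and restores the caller's RNG state.
* Degenerate inputs fail loudly with the offending sample/fold named:
  zero-area rows in normalization, flat calibration windows, single-class
  training folds, more than two classes.
* Test and validation problem sizes: cohorts of 13 spectra with 8192
  points (4096 in fast unit tests), ~1870 retained tissue bins; recovery is
  assessed over 50 seeds at fold change 1.5 with effect-bin SNR ≥ 4
  (the regime in which the ≥ 80% recovery property is claimed — recovery
  degrades gracefully below it), the false-flag rate over 100 null
  cohorts, and the permutation null over 100 label permutations.

## Limitations

* OPLS-DA here is strictly two-class discrimination; no multi-class or
  continuous-response variant.
* The simulator's templates are a 14-metabolite subset; spectral crowding
  and peak overlap of real biofluids are under-represented, so selection
  specificity on real data will be lower than on these cohorts.
* With 13 samples, Q² and permutation nulls are coarse; the package reports
  them but no asymptotic guarantees apply.
* Total-area normalization induces closure artefacts under large single
  fold changes; PQN is provided for that regime.
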