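# clonereg

Multimodal image registration by clonal selection, with spectral-CT
effusion diagnostics.

`clonereg` is for researchers studying optimizer behaviour in
mutual-information image registration — specifically the clonal
selection algorithm (CSA), an artificial-immune-system optimizer —
and for reproducing the accompanying benign-vs-malignant serous cavity
effusion statistics from published group summaries. Everything runs on
synthetic inputs: no patient data are required or included.

## What it computes

**Registration.** Given a fixed (CT-like) and a moving (PET-like) image,
the package estimates the similarity transform (rotation θ, per-axis
scale s, per-axis translation t, acting about the image center)
maximizing normalized mutual information,

    NMI(A, B) = (H(A) + H(B)) / H(A, B)  ∈ [1, 2],

with entropies from an equal-width joint histogram over the overlapping
valid pixels. The optimizer is a CLONALG-family loop — evaluate → select
a memory set Pn → clone the top K proportionally to rank → arithmetic
crossover (probability Yi = 0.7) + hypermutation (per-gene probability
Yt = 0.02, Gaussian scale shrinking with affinity) → re-select →
extinction of the d weakest remainder antibodies — plus a matched-budget
real-coded genetic algorithm as the comparison arm, and a paired seeded
benchmark that counts gross mismatches (recovered transform off truth by
more than 2° / 0.05 scale / 2 px).

**Diagnostics.** Welch two-sample t-tests computed directly from
per-group `(n, mean, sd)` summaries of monoenergetic CT values
(40–140 keV) and base-material concentrations (lipid/water,
water/iodine, water/calcium); a seeded synthetic two-group cohort
generator (25 benign / 72 malignant) parameterized by those summaries;
and ROC analysis (trapezoidal AUC ≡ Mann–Whitney, Youden cutoff,
sensitivity/specificity under the "score > threshold ⇒ malignant"
convention).

## Worked example

```r
library(clonereg)

# a 64x64 phantom pair with a known ground-truth transform
ph <- generate_phantom(phantom_spec(size = 64, seed = 7))
ph$truth
#> <transform_params> rot -4.133 deg | scale 0.9131, 1.0254 | shift -0.095, 4.710 px

res <- run_csa(ph$fixed, ph$moving, csa_config(seed = 7))
res$best_params
#> <transform_params> rot -3.469 deg | scale 0.9352, 1.0435 | shift -0.024, 4.888 px
res$best_nmi
#> [1] 1.38741

classify_mismatch(res, ph$truth, mismatch_rule())
#> [1] FALSE
```

The recovered rotation is within 0.7°, scale within 0.023 and
translation within 0.2 px of the ground truth — inside the mismatch
tolerances (2°, 0.05, 2 px), so the trial counts as a correct
registration on this noisy, intensity-remapped pair.

Diagnostics from the published group summaries:

```r
ref <- effusion_reference_summaries()
row <- ref[ref$feature == "CT@40keV", ]
welch_from_summary(
  group_summary(row$n_benign, row$benign_mean, row$benign_sd, "benign", "CT@40keV"),
  group_summary(row$n_malignant, row$malignant_mean, row$malignant_sd, "malignant", "CT@40keV"))
#> <welch_result> CT@40keV: t = 9.2726, df = 43.89, p = 6.67e-12 (Welch)
```

At 40 keV the benign group's CT values (41.24 ± 18.45 HU) separate
sharply from the malignant group's (0.96 ± 19.45 HU): p ≪ 0.05.

A command-line interface wrapping the same functions is installed at
`system.file("cli", "clonereg", package = "clonereg")` with subcommands
`simulate`, `register`, `benchmark`, `diagnose`.

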