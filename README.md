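# qsarpipe

A quantitative structure–activity relationship (QSAR) pipeline for modelling
the potency (pIC50) of small-molecule receptor antagonists — the setting it
was built for is CXCR2 chemokine-receptor antagonists — from 2D topological
descriptors, with genetic-algorithm descriptor selection wrapped around
partial least squares (GA-PLS), a full external-validation battery, and
leverage-based applicability-domain filtering for in silico screening.

## What it does

Starting from SMILES structures (or a precomputed descriptor CSV) and IC50
activities, the pipeline:

1. **Molecular graphs** — hydrogen-depleted graphs with aromatic perception
   (OpenBabel via ChemmineR/ChemmineOB), topological distance matrices, and
   carbon-scaled atomic property weights (mass *m*, van der Waals volume
   *v*, Sanderson electronegativity *e*, polarizability *p*).
2. **Descriptors** — Broto–Moreau (`ATS<lag><w>`), Moran (`MATS<lag><w>`)
   and Geary (`GATS<lag><w>`) 2D autocorrelations, Burden-matrix eigenvalues
   (`BEH<w><rank>`, `BEL<w><rank>`) and constitutional counts; then a
   prefilter that drops near-constant columns and one of every pair with
   |r| > 0.95.
3. **Data set handling** — exact IC50 → pIC50 conversion
   (pIC50 = −log10 IC50[mol/L]), deterministic Kennard–Stone maximin
   train/test splitting, autoscaling with stored parameters, PCA
   homogeneity check.
4. **Models** — MLR (`qsar_mlr`), stepwise partial-F selection
   (`stepwise_select`), NIPALS PLS (`qsar_pls`) with RMSECV-based
   latent-variable selection (`select_lv`), and GA-PLS (`qsar_gapls`):
   binary chromosomes over descriptor columns, fitness
   100·[1 − (n−1)/n · SSE_cv/SS_y] from random-subset cross-validation,
   roulette selection, double crossover, per-bit mutation, elitism.
5. **Validation** — RMSEC/RMSECV/RMSEP, REP%, external
   Q² = 1 − Σ(y−ŷ)²/Σ(y−ȳ_tr)², the Tropsha criteria (Q² > 0.5, R² > 0.6,
   through-origin slopes k, k′ in (0.85, 1.15), (R²−R₀²)/R² ≤ 0.1),
   Y-randomization, and per-descriptor mean effects
   MF_j = β_jΣ_i d_ij / Σ_j β_jΣ_i d_ij.
6. **Applicability domain** — leverages h_i = x_iᵀ(XᵀX)⁻¹x_i in model space,
   warning leverage h* = 3(p+1)/n, ±3 standardized-residual cut-off,
   Williams plot.
7. **Screening** — substituent enumeration on a scaffold with numbered
   attachment points (`[*:1]`, `[*:2]`, …), prediction with any fitted
   model, AD filtering and ranking.

Synthetic generators (`gen_descriptor_data`, `gen_molecules`) produce
descriptor/activity matrices with planted sparse linear signal and
valence-respecting random molecules, so every stage is testable without
proprietary descriptor software. Transcripts of the published CXCR2
activity tables ship as plain-text fixtures (`cxcr2_activities()`,
`cxcr2_test_predictions()`).

## Worked example

```r
library(qsarpipe)
set.seed(7)

mols <- gen_molecules(n = 40, size_range = c(8, 20), seed = 7)
spec <- c(paste0("MATS", 1:4, "m"), paste0("GATS", 1:4, "p"),
          paste0("ATS", 1:4, "v"), "BEHm1", "BEHm2", "BEHp1", "BEHp2",
          "nAT", "MW", "nCIC")
X  <- compute_descriptor_matrix(mols$molecules, spec)
pf <- prefilter(X)                      # drops constant/collinear columns

# activity planted on two descriptors plus noise
y <- drop(scale(pf$X[, "MATS2m"]) * 0.8 + scale(pf$X[, "BEHp2"]) * 0.5) +
  6.5 + rnorm(40, 0, 0.15)
names(y) <- rownames(pf$X)

sp  <- kennard_stone(pf$X, 30)          # 30 train / 10 prediction
Xtr <- pf$X[sp$train, ]; Xte <- pf$X[sp$test, ]

fit <- qsar_gapls(Xtr, y[sp$train],
                  ga_control(pop_size = 32, max_generations = 30), seed = 7)
fit
#> GA-PLS model: selected 7 of 16 descriptors in 30 generation(s)
#>   best fitness = 97.44 | LVs = 7 | R2 = 0.9848
#>   selected: MATS1m, MATS2m, ATS1v, ATS4v, BEHm2, BEHp2, nCIC

validation_report(fit, Xtr, y[sp$train], Xte, y[sp$test])
#> Validation report
#>   training:   R2 = 0.985  RMSEC = 0.123  RMSECV = 0.168  Q2cv = 0.972
#>   prediction: R2 = 0.926  RMSEP = 0.188  REP% = 2.82  Q2ext = 0.929
#> Tropsha external validation:
#>   R2 = 0.926  Q2 = 0.929  k = 0.994  k' = 1.006
#>   R0^2 = 0.996  R0'^2 = 0.997  ratios = -0.075 / -0.076
#>   overall: PASS

ad <- williams(fit, Xtr, y[sp$train], X_probe = Xte, y_probe = y[sp$test])
```

The GA recovers both planted descriptors (`MATS2m`, `BEHp2`) plus a few
correlated passengers; the external set validates (Q²ext = 0.93, slopes
within (0.85, 1.15)), and the Williams analysis flags one prediction-set
compound above the warning leverage (h* = 0.8 here: 30 training compounds,
7 latent variables).

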