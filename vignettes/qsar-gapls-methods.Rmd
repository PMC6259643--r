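---
title: "Methods: GA-PLS QSAR modelling with topological descriptors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GA-PLS QSAR modelling with topological descriptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of its science: the models it fits,
the conventions it fixes where the field leaves room, and what its tests do
and do not establish.

## The modelling problem

A QSAR model relates a compound's structure to its potency, here expressed
as pIC50 = −log10(IC50 in mol/L), so that one log unit is a tenfold change
in inhibitory concentration. The pipeline assumes the relationship is
(approximately) linear in a set of numeric descriptors computed from the
hydrogen-depleted molecular graph, and that only a small subset of a large,
strongly collinear descriptor pool is informative. That assumption dictates
the architecture: PLS to cope with collinearity, and a genetic algorithm to
find the informative subset.

## Descriptors and their conventions

All 2D descriptors operate on the heavy-atom graph with topological
distances d(i,j) = minimum bond count between atoms (every bond counts as
one edge, aromatic included — topological distance is bond count by
definition). Atoms are weighted by one of four properties — atomic mass,
van der Waals volume (from Bondi radii), Sanderson electronegativity,
atomic polarizability — divided by the carbon value, so a pure-carbon
skeleton has unit weights. Carbon scaling is the documented behaviour of
the descriptor software whose output the published models used; it is
configurable (`atom_property_table(carbon_scaled = FALSE)`) because the
original computation did not state it.

The three autocorrelation families at lag d with weights w:

* Broto–Moreau: ATS(d) = Σ_{i<j, d(i,j)=d} w_i w_j
* Moran: I(d) = [Δ⁻¹ Σ_{d(i,j)=d} (w_i−w̄)(w_j−w̄)] / [A⁻¹ Σ_i (w_i−w̄)²]
* Geary: c(d) = [(2Δ)⁻¹ Σ_{d(i,j)=d} (w_i−w_j)²] / [(A−1)⁻¹ Σ_i (w_i−w̄)²]

with Δ the number of ordered pairs at distance d and A the atom count.
Two conventions are fixed deliberately: a lag with no pairs, or a constant
weight vector, yields 0 rather than NaN. This keeps matrix assembly total —
a constant-weight molecule still gets a full row — and defers removal of
uninformative columns to the prefilter, where it is logged.

Burden eigenvalue descriptors (`BEHp2` = second-highest eigenvalue under
polarizability weighting) use the modified connectivity matrix with
diagonal w_i, off-diagonal 0.1 × bond order for bonded pairs (aromatic
bonds count 1.5) and 0.001 for non-bonded pairs. The 0.1/0.001/1.5
constants are the standard Burden-matrix convention and are frozen here
because the source publications name the descriptors without printing the
formulas. A descriptor name with `u` weighting (unweighted) uses all-ones
weights. One naming caveat inherited from the source material: the
descriptor `GATS8p` is occasionally glossed as a Moran autocorrelation in
published tables; the G prefix denotes Geary and it is computed as Geary
here.

The prefilter drops columns with raw-scale SD ≤ 1e−8, then scans column
pairs in fixed name order and drops the later member of any pair with
|Pearson r| > 0.95 (the cutoff the modelled analysis used; configurable).
"Later column loses" is an arbitrary but deterministic and logged
tie-break; the original analysis did not state one.

## Data handling

IC50 → pIC50 conversion is exact; rounding happens only at display (the
published tables print 2 decimals). The packaged transcriptions of those
tables carry a `self_consistent` flag because several printed rows disagree
with their own IC50 column by 0.01–0.08 log units; only self-consistent
rows serve as numeric anchors (see `inst/extdata/cxcr2_fixtures_NOTES.md`).

Kennard–Stone splitting is the classic maximin procedure on Euclidean
distances over autoscaled descriptors: seed with the two mutually farthest
compounds, then repeatedly add the compound maximizing the minimum distance
to the selected set; ties break to the lowest row index. The distance
metric and preprocessing are not stated in the source analysis; Euclidean
on autoscaled columns is the algorithm's standard form. Autoscaling uses
the sample SD (n−1) throughout, and stored training parameters are the only
thing ever applied to new rows.

## Regression models

`qsar_mlr` is ordinary least squares (base `lm`), refusing rank-deficient
designs. `stepwise_select` is classic forward selection with backward
elimination on partial-F p-values; the entry/removal thresholds default to
0.05/0.10 (conventional; the source analysis stated none).

`qsar_pls` is single-response NIPALS with mandatory centring and default
autoscaling; the regression vector is folded back so prediction is affine
in raw descriptor values, and with as many latent variables as the rank of
X the fit coincides with OLS (tested to 1e−8 against the normal equations
— the property that pins down the implementation regardless of algorithm
choice; NIPALS was chosen for transparency). Latent-variable count is the
argmin of cross-validated RMSECV with ties to fewer LVs (parsimony).

The residual and prediction convention everywhere is
**residual = predicted − experimental**, matching the sign of the published
prediction tables.

## GA-PLS

Chromosomes are binary inclusion vectors over descriptor columns. Fitness
is the cross-validated PLS score

100 − {[Σ(y_i−ŷ_i)²/n] / [Σ(y_i−ȳ)²/k]} × 100,  k = n − 1,

equivalently 100·[1 − (n−1)/n · SSE_cv/SS_y]: a perfect cross-validated
predictor scores 100, the constant mean predictor 100/n, worse-than-mean
prediction goes negative. The ŷ are out-of-fold predictions under
random-subset cross-validation with 4 subsets, re-randomized every
generation; the latent-variable count inside an evaluation is chosen by the
inner RMSECV minimum, capped at min(10, bits set). The defaults are the
published configuration: population 64, per-bit mutation 0.003, at most 100
generations, 20% initial bit density, double (two-point) crossover, early
stop when 80% of the population ties the best fitness. Selection is
fitness-proportional with a rank-based fallback when fitnesses are
non-positive, plus elitism of one — the source analysis names selection,
crossover and mutation without operator details, and elitism gives the
monotone best-fitness guarantee the tests rely on. The configuration also
carries a `window_width` knob (value 2 in the published parameter table)
whose meaning the original toolbox does not document; it is recorded but
deliberately has no effect beyond standard per-bit mutation. The final
chromosome is refit as a PLS model on the raw selected columns, so the
returned model predicts from raw descriptor values like every other model
in the package.

Empty chromosomes get fitness −∞ (never selected) and are redrawn at
initialization or repaired after mutation by setting one random bit.

## Validation battery

REP% = 100/ȳ · RMSE; RMSECV and RMSEP are the same RMSE applied to
cross-validation and external predictions. External
Q² = 1 − Σ(y−ŷ)²/Σ(y−ȳ_tr)² centres on the *training* mean, as the formula
the analysis used prescribes; because the literature sometimes conflates
this with leave-one-out Q², both are exposed (`q2_external`, `q2_loo`) and
reported separately. The Tropsha battery computes through-origin slopes
k = Σyŷ/Σŷ², k′ = Σyŷ/Σy², the through-origin determination coefficients
R₀² and R₀′², and the gap ratios; the R₀² denominators follow the printed
formula of the source (normalizing by the spread of predictions), with the
more common Golbraikh–Tropsha variant available via
`tropsha(..., convention = "golbraikh")` — the two differ when predictions
are biased, and neither is used as a numeric target.

Y-randomization shuffles y, re-runs the whole model-building procedure and
tabulates (R², Q²) per shuffle. The supplied `pls_builder` reports
*cross-validated* statistics: r² = cor(y, ŷ_cv)² and LOO Q². Training-fit
R² of a multi-latent-variable PLS on shuffled responses is inflated by
overfitting (≈ 0.45 at n = 120, p = 50, 3 LVs) and would mask the
separation the test looks for; published randomization tables showing small
positive R² next to strongly negative Q² are only consistent with
predictive statistics, which is what a chance model should fail at.

Mean effects MF_j = β_jΣ_i d_ij / Σ_j β_jΣ_i d_ij are computed on raw
descriptor values and sum to 1 by construction.

## Applicability domain

Leverage is h_i = x_iᵀ(XᵀX)⁻¹x_i in model space — the inverse is part of
the standard definition even where the formula is sometimes printed without
it (the inverse-free form is not scale-invariant and is incompatible with
the h* threshold). For an MLR model the model space is the autoscaled
selected descriptors (p = number of descriptors); for PLS-family models the
default is latent-variable score space (p = number of LVs), which is the
reading under which the published h* = 3(p+1)/n = 0.25 arithmetic (n = 108,
p = 8 LVs) is exact. Training leverages sum to p (hat-matrix trace; a
tested invariant). A compound is in-domain when h ≤ h* and, where a
residual exists, |standardized residual| ≤ 3; screening probes without
measured activity are classified on leverage alone — necessary for
screening, where no activity exists yet.

## Screening

Scaffolds carry numbered attachment points (`[*:1]`) replaced textually by
substituent SMILES fragments (empty/`H` removes the branch); every
assembled SMILES is re-parsed, and grafts that fail valence-wise are
rejected with a logged reason rather than dropped silently. Candidates are
ranked by predicted activity among in-domain compounds; out-of-domain
candidates are retained and flagged. A staged campaign (screen, pick the
best, modify it further) is expressed as two sequential specification
files, not special-cased logic.

## Synthetic data: what it emulates, and what it does not

`gen_descriptor_data` mixes shared latent factors into descriptor columns
(inducing the block collinearity that motivates PLS and GA selection) and
plants a sparse linear activity y = X_Sβ + ε. Defaults — n = 120 compounds,
50 descriptors, 5 informative at β = 2, noise SD 0.3, within-block
correlation 0.3 — give a signal-to-noise regime where subset recovery is
hard enough to need selection but identifiable, comparable to a curated
QSAR series of ~100 compounds. `gen_molecules` grows valence-respecting
random trees (single bonds, optional one ring closure) over
C/N/O/S/F/Cl/Br with a carbon-weighted element distribution.

What passing tests on these generators shows: the estimators, selection
machinery and domain logic are implemented correctly and recover planted
truth under the stated assumptions. What they do not show: performance on
real medicinal-chemistry series, whose descriptor distributions, activity
cliffs and scaffold structure the generators make no attempt to match. In
the same spirit, the published model statistics (R² ≈ 0.78, Q² ≈ 0.71 for
GA-PLS) are not reproduction targets: they depend on the original
733-descriptor matrix from proprietary software, which was never printed.
What *is* recomputed exactly is the published arithmetic — the h* = 0.25
warning leverage, the pIC50 conversions of the self-consistent activity
rows, and the predicted-minus-experimental residual convention of the
prediction table.

## Numerical choices and degenerate inputs

* Problem sizes in tests and the acceptance script (120 × 50 recovery
  benchmark, 200–1000 random graphs ≤ 12 atoms for kernel oracles, 10
  shuffles for randomization) are chosen to make each property decisive at
  desk scale.
* Sample SD (n−1) everywhere; autoscaling refuses zero-SD columns
  (`prefilter` first).
* PLS stops early if a weight vector underflows (|Xᵀy| < 1e−14); a y with
  no covariance with X degenerates to the intercept-only model rather than
  erroring.
* Leverage falls back to a pseudo-inverse with a warning when XᵀX has
  condition number above 1e12.
* Kennard–Stone on duplicate rows resolves the seed pair by lowest index
  and warns.
* All randomness flows from explicit integer seeds; generators and GA runs
  are bit-reproducible given the seed, and `qsar_gapls` reports a generated
  seed when none is supplied.

## Known limitations

Only 2D descriptor families are computed natively; 3D families (RDF,
MoRSE, WHIM, GETAWAY, geometrical, charge) must be imported via
`read_descriptor_csv`. Aromaticity and charges come from OpenBabel's
perception; exotic valences outside the property table are rejected rather
than guessed. The SMILES writer covers what the generator produces (neutral
atoms, up to 9 ring closures). GA fitness autoscales once on the full
training set rather than per CV fold — the convention of the toolbox
lineage this follows — which slightly flatters cross-validated error for
every chromosome equally.
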