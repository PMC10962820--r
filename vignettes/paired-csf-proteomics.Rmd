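---
title: "Paired CSF proteome analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paired CSF proteome analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deltaprot)
```

# The problem

Longitudinal treatment studies in cerebrospinal-fluid proteomics pair each
patient's pre-treatment sample with a follow-up sample collected after a
period of therapy. The paired design removes between-patient abundance
variation — each patient is their own control — which matters in CSF, where
inter-individual spread often dwarfs treatment effects. This package
implements the complete analysis chain for such designs: label-free
discovery statistics, comparison against disease-vs-control reference
lists, term over-representation, and absolute verification by parallel
reaction monitoring (PRM), together with a synthetic-cohort generator that
gives every stage a recoverable ground truth.

# The discovery model

Log2 LFQ intensities are modelled additively: a protein baseline, a
patient intercept shared by the two samples of a pair, a treatment shift,
and residual noise. The per-patient fold change

$$\mathrm{FC}_{gi} = \log_2 I^{\text{follow-up}}_{gi} - \log_2 I^{\text{baseline}}_{gi}$$

cancels the patient intercept, so its distribution across patients is
centred on the true shift. Three summaries are computed per protein:

* the **median fold change** across patients — robust to the occasional
  outlier pair;
* the **percent changed** — the percentage of available fold changes with
  the same sign as the median (zero fold changes count toward neither
  sign; when the median is exactly zero the larger sign fraction is
  reported). This is a concordance measure: 95 % means 95 % of patients
  moved the same way;
* a **two-sided paired t-test** on the log2 values, BH-corrected across
  all tested proteins.

No normalisation is applied beyond the log2 transform: LFQ intensities
arrive already normalised across runs, and renormalising would distort the
paired structure.

## Filtering

Proteins flagged as potential contaminants, decoy (reverse) hits or "only
identified by site" are removed first; then proteins quantified in fewer
than `min_pairs` (default 2) complete pairs. Missing pairs are dropped per
protein — pairwise-complete analysis — rather than imputed: the fraction
of incomplete pairs is reported per protein (`pct_blanks`) so the reader
can judge coverage, and imputation under abundance-dependent missingness
would bias paired differences in exactly the direction a naive model
assumes away.

## Immunoglobulins and the z-score cutoff

In immune-modulating treatment studies the immunoglobulin class (UniProt
keyword KW-1280) shifts coherently, producing a heavy one-sided shoulder
in the fold-change distribution. A fold-change cutoff estimated on the
full distribution would be dragged by that shoulder, so the reference mean
and standard deviation for the z-score are estimated over
non-immunoglobulin proteins only. Every protein — including
immunoglobulins — is then scored against this reference:
`z_p = 2 * pnorm(-|z|)`, flagged when strictly below `z_alpha` (default
0.05). Verification candidates must meet FDR < 0.01, `z_p` < 0.05 and
percent changed > 80 simultaneously; a `force_include` list admits
proteins of special interest regardless.

## Degenerate inputs

With fewer than two complete pairs, or when all paired differences are
identical (zero variance), the t-statistic is undefined; such proteins are
flagged and excluded from the BH family size rather than given an
arbitrary p-value. One consequence needs a convention downstream: a
protein whose difference is identical and nonzero in every patient is
unambiguous evidence of change even though its t-statistic does not
exist. The concordance categoriser therefore treats undefined-p proteins
with a nonzero median and at least two pairs as changed, directed by the
median's sign. This only matters for noise-free data — real cohorts never
produce exact zero variance — but it keeps the categoriser total.

# Concordance categories

Treatment state (increased / decreased at FDR < 0.01 by fold-change sign,
otherwise unchanged) is crossed with the reference direction, giving six
exhaustive, mutually exclusive categories: *opposite*, *equal*,
*treatment-only*, *disease-only*, *not changed*, *unmatched* (absent from
the reference). The changed states use the FDR criterion only — not the
z-score flag — because the categories ask "did it move", not "did it move
a lot". Reference accessions never quantified in the cohort are reported
in a separate list rather than silently dropped, since accession-matching
failures are informative about both resources.

# Enrichment

Over-representation of a flat term→protein annotation within a subset
against the quantified background uses the exact upper-tail
hypergeometric probability, `phyper(k - 1, K, N - K, n, lower.tail =
FALSE)`. Electronic annotations (evidence code IEA) are excluded by
default; terms without background annotation after filtering are skipped
and do not inflate the BH family. Annotations are taken as given flat
sets — no ontology-graph propagation — which understates enrichment of
broad parent terms; results should be read at the annotation granularity
supplied.

# PRM verification

## Peak QC

A measurement (peptide × sample × replicate) survives when at least three
fragments remain after discarding fragments above 10 ppm mass error, and
every surviving fragment has at least eight points across the
chromatographic peak. The measurement ratio is the summed light area over
the summed heavy area — summing before dividing is robust to
single-fragment dropout, unlike averaging per-fragment ratios (a
per-fragment alternative would weight a noisy low-intensity fragment
equally with a clean dominant one). When exactly one replicate of a pair
is truncated, the clean sibling is used alone; when both are truncated
there is no better evidence available and both are retained.

## Calibration

Reverse curves vary the heavy spike against constant endogenous analyte:
nine levels from 8× down to 0.03× of the estimated 1:1 concentration,
spanning 2.4 orders of magnitude, in trypsinated duplicates. The fit is
weighted least squares with weights 1/concentration, reflecting the
roughly constant *relative* (hence increasing absolute) variance of ratio
measurements. The response is assumed to increase with the spiked
concentration; exports whose ratio convention runs the other way are
handled by `invert_ratio`, which inverts the response before fitting and
quantification.

The linear range replaces visual inspection with a back-calculation rule:
the lowest level is retained such that, refitting on points at or above
it, every retained level's mean back-calculated concentration is within
`rel_bias_tol` (default 20 %, a common targeted-proteomics acceptance
band) of its theoretical value. The rule is monotone in the tolerance —
tightening it never widens the range — and errors explicitly when no
candidate bound qualifies rather than returning a degenerate range.

## Quantification

Concentration = (ratio − intercept) / slope, in fmol/µl injected,
converted to fmol/µl sample by the spike design's conversion factor.
Values below the linear-range lower bound are censored as below the limit
of quantification *before* the log2 transform and replicate averaging; a
sample with one valid replicate uses it alone. Peptide-level paired
statistics then mirror the discovery stage exactly (same median / percent
changed / paired t machinery), BH-corrected at 0.05, with a percentile
bootstrap CI of the median fold change (seeded, 10 000 draws by default).
The bootstrap is a package convention, not a canonical method — the median
has no standard closed-form interval at these n — and is labelled as such.

# The synthetic generator

`simulate_cohort()` emulates the discovery design: log2 baselines normal
across proteins (`protein_sd`, default 2), patient intercepts shared
within pairs (`patient_sd`, 0.5), residual noise per sample (`noise_sd`,
0.3), all on the log2 scale — the t-test machinery assumes approximate
log-normality and the generator makes that assumption explicit.
Missingness is missing-not-at-random: the probability follows a logistic
curve in protein-level log2 abundance (base rate 0.10 at the average
abundance, slope 0.5 per log2 unit), so dim proteins go missing more —
the dominant LFQ missingness mechanism. Immunoglobulin-class proteins
receive a coherent negative shift (`ig_effect_log2`, −0.5) plus extra
missingness (+1 logit), reproducing the distribution distortion that
motivates the z-score reference exclusion. Defaults mirror a paired CSF
study's scale: 56 patients, 1200 proteins, ~5 % immunoglobulins, 25 %
changed by 0.5 log2 units. The distributional parameters are modelling
assumptions, not measured CSF values.

What the generator does *not* emulate: correlated protein modules,
batch/run drift, peptide-to-protein rollup, interference-driven ratio
bias in PRM, retention-time effects. Passing recovery tests therefore
demonstrates the statistics are implemented correctly and behave as
designed under the stated model — not that the model captures every
feature of real CSF data.

`simulate_reference_diffset()` inverts the concordance mapping: given a
target category per protein it constructs reference directions that the
categoriser must recover exactly, which turns the whole
discovery→comparison chain into a checkable round trip.
`simulate_calibration()` adds multiplicative lognormal noise (unit mean,
given CV) around the true line, with an optional low-end saturation term
`conc / (conc + saturation_conc)` to create a detectable nonlinear region
for linear-range tests.

# Reproducibility

Generation is a pure function of its config: the global seed fans out to
per-stage seeds by hashing the stage name (`derive_seed`), so stages are
individually reproducible and independent across seeds, and no function
disturbs the caller's random stream. `run_all()` on a fixed config is
byte-identical across runs.

# Problem sizes in the test suite

The suite validates statistical behaviour at sizes chosen to make the
Monte-Carlo answers stable while keeping a full run in minutes: 1000
random instances per statistic for oracle equivalence, 500 null cohorts
(200 proteins × 30 patients) for FDR control, 100 cohorts at the full 56
patients for shift recovery, 200 seeded duplicate curves for calibration
recovery. Unit tests use single-digit cohort sizes with hand-enumerable
answers.

# Known limitations

* Protein groups are joined on their first accession; multi-accession
  groups are logged but not expanded.
* The reference list is a single consolidated direction per protein;
  merging multiple studies with vote rules is out of scope.
* Flat annotations only — no GO graph traversal.
* The linear-range rule inspects back-calculation bias only; carryover or
  heteroscedasticity beyond the 1/x weighting are not modelled.
* The discovery t-test uses pairwise-complete patients per protein; with
  informative missingness this can bias effect estimates toward the
  better-observed patients, which the `pct_blanks` column is there to
  flag.
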