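---
title: "Methods: coupling intronic DNA methylation to alternative exon usage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupling intronic DNA methylation to alternative exon usage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methsplice)
```

## The scientific question

Dilated cardiomyopathy (DCM) myocardium shows both widespread changes in
DNA methylation and distinctive alternative-splicing patterns. methsplice
implements an epigenome-wide analysis of how these two regulatory layers
are coupled: does the methylation level of an intron predict how often its
neighbouring exon is included in mature transcripts, and does that
relationship differ between diseased and healthy tissue? The pipeline is
designed for a two-cohort case/control study — a larger screening cohort
and an independent replication cohort profiled with RNA-seq plus a
450K-style methylation array — and is exercised end to end on synthetic
data with known ground truth, because patient-level tissue data of this
kind are not publicly distributable.

## Genomic scaffold

Transcript models are flattened per gene into disjoint **exonic counting
bins**: the union of all transcript exons is split at every distinct exon
boundary observed across the gene's transcripts (`flatten_gene_models()`,
implemented with `IRanges::disjoin`). Bins are labelled `E001, E002, ...`
in genomic order; **introns** are the gaps between consecutive bins
(`derive_introns()`). Coordinates are 1-based inclusive throughout, as in
GTF; the only 0-based conversion happens in the BED writers.

A **flank pair** joins an intronic methylation probe to a bordering bin of
the same gene (`build_flank_pairs()`): the bin immediately downstream in
genomic coordinates gives an *intron-exon* pair with distance
`bin.start - pos`, the bin immediately upstream an *exon-intron* pair with
distance `pos - bin.end`. Three conventions are worth stating because they
were genuinely open:

* **Strand is ignored for pairing and distance.** The probe manifest is
  strandless, so "upstream/downstream" is read as genomic, not
  transcriptional, orientation. A strand-aware reading would relabel the
  two pair classes for minus-strand genes without changing their union.
* **A probe exactly on a bin boundary is exonic**, not intronic — bins
  are closed intervals.
* **Overlapping genes are flattened independently** (the sense/antisense
  situation of *TTN* and its antisense lncRNA): a probe pairs only within
  the gene whose intron contains it, and may legitimately do so in two
  genes at once. Association testing is likewise restricted to probe/bin
  combinations of the same gene.

## Quality control

Three filters mirror common practice for this data type, with strict
boundary conventions tested explicitly:

* samples with fewer than 1,000,000 assigned reads are dropped (exactly
  1,000,000 is kept);
* probes flagged as SNP-affected or cross-reactive, and probes on the sex
  chromosomes, are removed;
* exon bins whose inclusion-count total across all retained samples is
  below 6 are removed (exactly 6 is kept).

Counts are normalized by median-of-ratios size factors (`size_factors()`);
the normalization method for exon counts was an open choice and this is
the field default. Each cohort is processed fully independently — own
filters, size factors and principal components — and no cross-cohort batch
correction is applied; the replication join is the only cross-cohort step.
Batch structure (sequencing date, flow cell) is carried in the sample
sheet and can be entered as model covariates rather than removed by matrix
pre-correction, which would distort count distributions for the GLMs.

Methylation beta values are clipped to `[1e-6, 1 - 1e-6]` and converted to
M-values, `M = log2(beta / (1 - beta))`, the scale on which linear
modelling is performed; clipping keeps M finite at measured 0/1. The top
two principal components of the M-value matrix (`top_principal_components()`)
serve as covariates against population and technical stratification. The
PCA sign is fixed deterministically (largest-magnitude loading positive)
so re-runs are byte-identical.

## PSI: percent spliced-in

For bin `b` and sample `s`, with inclusion reads `I`, skip-junction reads
`E`, bin width `L_b` and effective junction length `L_J = read_length - 1`
(default read length 100):

$$\mathrm{PSI} = \frac{I/L_b}{I/L_b + E/L_J}$$

The length normalization makes inclusion and exclusion evidence
comparable per position. Entries with no evidence (`I = E = 0`) are `NA`;
single-bin genes, which cannot accumulate skip reads, have PSI 1 wherever
expressed. The estimator is checked against a per-entry brute-force oracle
in the tests.

## The flank regression

The central model pools all flank pairs of one kind within one group
(e.g. DCM, intron-exon). Per pair, the response is the bin's inclusion
count summed over the group's samples, the offset is the log gene-total
count over the same samples, and the predictor is the group-mean beta of
the intronic probe, optionally adjusted by `log10(distance)`:

$$\log E[y_p] = \log T_p + \alpha + \beta\,\bar{m}_p
  \;(+\, \gamma \log_{10} d_p)$$

"Logistic regression in a quasi-Poisson distribution" is internally
contradictory as a literal recipe; it is resolved here as a **Poisson
log-link GLM with quasi-likelihood dispersion** (`φ` = Pearson χ²/df,
standard errors scaled by `√φ`, t-based p-values on the residual df). The
count-with-offset formulation matches the reported observation unit
(n = pairs, not pairs × samples) and yields a positive coefficient under
positive methylation–usage coupling. The distance covariate enters as
`log10` because pair distances span orders of magnitude. Fits with fewer
than 10 usable pairs, or a constant methylation predictor, are refused
rather than silently degenerate. The fit is returned as a classed
`flank_fit` object with `print`, `summary`, `coef` and `confint` methods.

Parameter recovery, CI coverage and null calibration of this model are
established on pair-level simulations (`simulate_flank_pairs()`) with NB1
noise (`Var = φμ`, the quasi-Poisson variance function), at the study's
pair count (41,158): the estimate is within 10% of the planted coefficient
in ≥95% of seeds, 95% CIs cover at ≥90%, and the p-value is uniform under
the planted null.

## Differential tests

The three genome-wide tests are deliberately simplified re-implementations
rather than wrappers around the standard packages; they are validated by
simulation calibration, not bit-level agreement.

**DGE** (`test_dge()`): per gene, an NB log-linear model with log
size-factor offset. Method-of-moments dispersions are smoothed into a
lowess mean–dispersion trend; the *trend* value enters the GLM family, and
per-gene departures from it are captured as quasi-likelihood scales,
shrunk by empirical Bayes, with a t reference on `d0 + d` df. The
two-layer construction exists because plugging a per-gene estimated
dispersion straight into a Wald standard error is anti-conservative
(~13% null rejections at nominal 5% in our permutation experiments); the
quasi-likelihood layer restores ~5–7%.

**DEU** (`test_deu()`): per bin, the response is (inclusion count,
rest-of-gene count) under a logit-link binomial GLM, condition-only by
default. Two refinements matter: (1) a genome-wide Williams-type
intraclass correlation `ρ` is estimated from first-pass Pearson
dispersions and the binomial weights deflated to `w / (1 + ρ(w - 1))` —
with per-sample biological usage variation, variance grows like `w²`, and
a single multiplicative dispersion under-corrects exactly where counts
are largest; (2) residual per-bin dispersions are shrunk toward a
mean–dispersion trend by the same empirical-Bayes machinery as the
moderated t, and inference uses `d0 + d` df. Bins of single-bin genes are
reported `NA` with a reason.

**DMR** (`test_dmr()`): ordinary least squares of M-values on condition,
sex, age, the five immunosuppressant indicators and PC1/PC2, followed by
the empirical-Bayes moderated t: per-probe variances are modelled as
scaled-F around a prior estimated by moment-matching of the log variances
(`squeeze_var()`, including a Newton `trigamma` inverse), posterior
variance `(d0 s0² + d s²)/(d0 + d)`, t on `d0 + d` df. The implementation
reproduces the reference empirical-Bayes implementation (limma) to ~1e-6
on shared designs, and reduces exactly to the ordinary t at `d0 = 0` and
to complete pooling at `d0 = ∞`. An estimated `d0 = ∞` (log-variance
spread below chi-square expectation) is treated as valid complete pooling;
only a `NaN` estimate falls back to the ordinary t with a warning.

All multiplicity adjustment uses an in-package Benjamini–Hochberg step-up
(`benjamini_hochberg()`), cross-checked against `p.adjust` and a
brute-force oracle.

**Confounded covariates.** Immunosuppressants are taken only by controls
(transplant recipients), so drug indicators can be perfectly aliased with
condition. The design builder resolves rank deficiency deterministically:
columns are admitted left to right (intercept, condition, then covariates)
and any column that does not increase the rank is dropped with a warning —
later-entered aliased covariates lose, condition always stays. Small
cohorts that cannot support the full covariate set drop trailing columns
until a residual degree of freedom remains.

## Association scan, differential correlation, replication

`ewas_scan()` tests each same-gene (probe, bin) combination within one
group: quasi-binomial logit regression of PSI on beta plus PC1/PC2. Effect
sizes follow the **odds ratio per 0.01 beta increment** convention,
`OR = exp(0.01 β̂)`, with Wald t intervals; because the response is a
continuous PSI rather than a binary outcome, complete separation cannot
occur and profile intervals were not needed. The unadjusted within-group
Pearson correlation `r(beta, PSI)` is recorded alongside — it is the
quantity compared across groups. Combinations with fewer than 5 complete
samples, or a constant PSI or beta, are skipped with a logged count.

`variance_explained()` reports the mean R² of the simple regression of
PSI on beta across all combinations, with the normal-approximation 95% CI
`mean ± 1.96 sd/√n`. On coupled synthetic data this rises monotonically
with the generator's coupling strength; on the default fixture it lands
near 2%, sizeable for a genome-wide average.

`diffcor_scan()` compares the two groups' correlations per combination
with **Fisher's z**:

$$z = \frac{\operatorname{atanh} r_1 - \operatorname{atanh} r_2}
  {\sqrt{1/(n_1-3) + 1/(n_2-3)}}$$

BH-adjusted across combinations; `screened` means FDR < 0.05 in the
screening cohort. `directional_replication()` then requires, per
candidate: raw p < 0.05 in the replication cohort, the disease-group
correlation keeping its sign across cohorts, the control-group correlation
keeping its sign across cohorts, and the two groups' signs differing —
the group-reversed pattern. Same-sign differential-magnitude loci are
deliberately rejected by the last clause.

`intersect_deu_dmr()` overlays the raw-p hits of DEU and DMR on the flank
pairs (both p < 0.05 by default) and reports pair and distinct-gene counts
per kind, with a BED of hit regions.

## The synthetic-data generator

`simulate_dataset()` emits a complete two-cohort study: GTF annotation,
probe manifest with blocklists, beta matrices, inclusion/exclusion count
matrices, sample sheets, and a truth table for every planted effect.
Defaults are the study conditions the pipeline targets: 34 DCM / 21
control screening samples, 11 / 5 replication, ~1 intronic probe per
intron, read length 100. `make_fixture()` provides three sizes used
throughout the tests — *tiny* (5 genes, 4+4 samples, sub-second, for
end-to-end plumbing), *small* (500 genes, the default cohort sizes, for
power and calibration), and *paper_scale* (3,400 genes, which yields
roughly 39,000–40,000 analyzable pairs per kind, within 5% of the
41,158-pair study scale).

Generative model, in brief: gene expression is lognormal across genes
with a gamma gene × sample effect (NB marginal, dispersion 0.1) times
lognormal per-sample depth and batch factors; bin inclusion counts are
Poisson around `μ_g · (L_b/1000) · ψ` and skip-junction counts Poisson
around `μ_g · (L_J/1000) · (1-ψ)`, so the PSI estimator is unbiased for
the planted `ψ`. The usage logit carries baseline, a planted DEU shift in
cases for 10% of bins, coupling `1.2 · (beta - 0.5)` from each adjacent
intronic probe (all pairs by default — the genome-wide positive coupling
whose pooled log-scale slope comes out near 0.25, the magnitude the flank
regression reports), and N(0, 0.5) biological noise. Methylation is
logit-normal: probe-level means N(0, 1.5) on the M scale, within-probe
noise sd 0.5, batch shifts, and a +1 M-shift in cases for 5% of probes
(the DMR truth). Immunosuppressant flags are true only in controls, and
batch composition is imbalanced with respect to condition, reproducing
the study's confounding structure.

**Planted correlation loci.** Twenty group-reversed loci carry within-group
(beta, PSI) correlations of −0.75 in cases and +0.75 in controls; ten
same-sign confounds carry (+0.8, +0.45). The ±0.75 level follows an a
priori power analysis of the screening step: at 34/21 samples the expected
Fisher z for a reversed locus is `2·atanh(0.75)/√(1/31+1/18) ≈ 6.6`,
against a BH threshold near `|z| ≈ 3.7` when ~20 of 5,020 combinations are
true — per-locus detection ≈ 0.98, so ≥18/20 recovered with probability
≈ 0.99. At ±0.6 the same arithmetic gives per-locus detection ≈ 0.77 and
≥18/20 almost never; a planted discovery benchmark must be powered to be
informative. Three construction details make the *realized, observed*
correlation meet the target: planted loci sit in top-half-expression genes
with partner bins ≥100 bp (estimable PSI — fittingly, the motivating locus
in real tissue lies in the highly expressed Titin antisense transcript);
each partner bin hosts exactly one planted locus; and the planted PSI is
linear in the latent (sd 0.28 around 0.5, truncated to [0.05, 0.95])
rather than logit-transformed, whose curvature would compress Pearson
correlations. The methylation marginals of planted probes are identical
across groups, so only the correlation — not differential methylation —
distinguishes them. The same-sign confound's weaker arm is 0.45 because a
correlation must be ~2 sampling sd from zero at n = 21 for its *sign* to
be identifiable; with weaker confounds the directionality filter leaks
sign-flipped realizations (~1% of seeds remain even at 0.45, an intrinsic
property of a filter that acts on realized signs).

What the generator does **not** emulate: read-level alignment artefacts,
sequence-driven probe biases, array chemistry, isoform structure beyond
the bin level, correlated methylation between neighbouring probes, and
spatial methylation gradients. Passing tests therefore demonstrate the
statistical machinery under the assumed noise model, not robustness to
every artefact of real tissue data.

## Numerical and reproducibility choices

* All randomness flows from a single integer seed; identical config gives
  byte-identical outputs (the dataset writer records an md5 per file in
  `manifest.json`).
* GLM fitting uses `stats::glm.fit` with tightened convergence
  (`epsilon = 1e-10`) in the flank model so that independently coded
  reference fits agree to ~1e-8.
* Dispersions are floored at 1e-8; beta values clipped at 1e-6; lowess
  trends fall back to a constant prior when fewer than 10 points or a
  degenerate covariate are available.
* Zero-total pairs are excluded pairwise with a logged count; probes on
  chromosomes absent from the annotation are skipped with a logged count,
  not an error.
* Pipeline stages re-read their inputs from disk, so re-running any stage
  with unchanged inputs reproduces its artifacts byte for byte.

## Problem sizes in the shipped tests

The unit suite runs the tiny and small fixtures; the acceptance suite
additionally generates one paper-scale dataset (~44,000 bins × 55
samples, ~40,000 pairs per kind), fits 50 pair-level recovery replicates
at n = 41,158, runs 2,000 Fisher-z null replicates at n = 30/20, 500
flank null fits at n = 2,000, and a 5,030-combination discovery scan in
both cohorts. The full suite completes in a few minutes on one CPU; these
sizes were chosen so each statistical claim is tested at the scale where
its asymptotics matter.

## Known limitations

* The EWAS models PSI as a quasi-binomial response; PSI is an estimate
  with heteroskedastic error that the model treats as exact. Low-coverage
  bins therefore attenuate correlations (visible in the generator
  studies), which is also true of the analogous analysis on real data.
* The flank regression aggregates over samples within a group and so
  cannot adjust for per-sample covariates; covariate adjustment lives in
  the per-sample differential models instead.
* Williams' correction uses a single genome-wide intraclass correlation;
  bins with atypical biological variability keep some residual
  miscalibration that the per-bin empirical-Bayes dispersion only partly
  absorbs.
* `directional_replication()` acts on realized correlation signs; with
  very small replication cohorts (n = 5 controls here) sign agreement is
  itself noisy, which bounds achievable directional-replication rates.
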