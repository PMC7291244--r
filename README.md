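# methsplice

Epigenome-wide analysis of the coupling between **intronic DNA
methylation** and **alternative exon usage**, for case/control cohort
designs of the kind used to study dilated cardiomyopathy (DCM)
myocardium. The package is aimed at statistical genomics analysts who
have bin-level exon counts (inclusion and skip-junction reads) and a
450K-style methylation matrix for the same samples, and want to ask:
does the methylation of an intron predict how often its neighbouring
exon is included — and does that relationship differ between disease
and control?

## What it computes

The genomic scaffold flattens transcript models into disjoint exonic
counting bins, derives introns, and pairs each intronic probe with its
bordering bins (*intron-exon* and *exon-intron* flank pairs). Exon
inclusion is quantified per bin and sample as percent spliced-in,

    PSI = (I / L_b) / (I / L_b + E / L_J),

with inclusion reads `I`, skip-junction reads `E`, bin width `L_b` and
effective junction length `L_J = read_length − 1`.

The central model is a pooled **quasi-Poisson flank regression** over
all pairs of one kind within one group: for pair *p* with group-summed
inclusion count `y_p`, gene total `T_p` and group-mean probe beta `m_p`,

    log E[y_p] = log T_p + α + β·m_p  (+ γ·log10 distance_p),

fitted with Poisson log link, Pearson-χ²/df dispersion, and t-based
inference; `β > 0` means higher intronic methylation goes with higher
usage of the flanking exon. Around it sit:

* simplified differential tests — negative-binomial quasi-likelihood
  DGE, quasi-binomial DEU with Williams-corrected weights and
  empirical-Bayes dispersion shrinkage, and a limma-style moderated-t
  DMR on M-values — with in-package Benjamini–Hochberg adjustment;
* a per-gene methylation–PSI association scan reporting odds ratios per
  0.01 beta increment, `OR = exp(0.01·β̂)`;
* Fisher's z differential-correlation testing between disease and
  control, `z = (atanh r₁ − atanh r₂) / √(1/(n₁−3) + 1/(n₂−3))`, with
  FDR screening and cross-cohort **directional replication** (signs
  consistent across cohorts, opposite between groups);
* the DEU ∩ DMR overlay on flank pairs;
* a fully ground-truth-labelled synthetic data generator
  (`simulate_dataset()`, `make_fixture()`) emulating the two-cohort
  study design, including covariate–condition confounding
  (immunosuppressants only in controls), batch effects, and planted
  group-reversed correlation loci;
* a stage-wise pipeline (`run_pipeline()`, with a thin CLI wrapper in
  `inst/scripts/methsplice-pipeline.R`).

The methods vignette (`vignettes/methylation-splicing.Rmd`) documents
every model, default and numerical choice.

## Worked example

```r
library(methsplice)

sim    <- make_fixture("small", seed = 42)   # 500 genes, 34/21 + 11/5 samples
probes <- filter_probes(sim$probes)
pairs  <- build_flank_pairs(probes, sim$introns, sim$bins)

co  <- sim$cohorts$screening
fit <- flank_regression(pairs, co$inclusion, co$beta, co$sheet,
                        group = "DCM", kind = "intron-exon")
fit
#> Flank quasi-Poisson usage regression
#>   group: DCM   kind: intron-exon   distance-adjusted: FALSE
#>   n pairs: 5773   dispersion: 977.193
#>   methylation coefficient: 0.372686 (se 0.044811), t = 8.32, p = 1.12e-16

w   <- setNames(sim$bins$width,
                paste(sim$bins$gene_id, sim$bins$bin_id, sep = ":"))
psi <- compute_psi(co$inclusion, co$exclusion, w)
ve  <- variance_explained(co$beta, psi,
                          gene_combinations(probes, sim$introns, sim$bins))
sprintf("%.2f%% of PSI variance explained (n = %d tests)",
        100 * ve$mean_r2, ve$n_tests)
#> [1] "2.21% of PSI variance explained (n = 83354 tests)"
```

The coefficient is the pooled log-scale effect of intronic methylation
on flanking-exon usage: here +0.37, i.e. a fully methylated intron
(beta 1 vs 0) predicts a ~45% higher inclusion rate, significant at
p ≈ 1e-16 already at 5,773 pairs — at the full study scale of ~40,000
pairs the bound drops below 1e-40. The variance-explained summary says
intronic methylation accounts for about 2% of PSI variance on average
across all same-gene probe/bin combinations, a small per-locus but
sizeable genome-wide signal.

The full pipeline can also be driven stage-wise on an on-disk dataset:

```r
cfg <- pipeline_config("data", "out", sim_size = "small", seed = 1)
run_pipeline("all", cfg)   # simulate → pair → qc → ... → report
readLines(file.path("out", "report.txt"))
```

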