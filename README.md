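# fieldscape

Multi-platform detection of genomic defects in histologically normal,
cancer-adjacent breast tissue, and survival analysis of its extratumoral
expression subtypes.

Tissue excised well away from a breast tumor usually looks normal under the
microscope, yet can carry occult tumor cells or a broader field-cancerization
effect. `fieldscape` implements, as a tested and reusable R pipeline, the
platform-specific rules for calling such defects from matched
tumor / blood / adjacent-normal assays, plus the downstream expression
subtyping and survival models. It is aimed at cancer genomicists who want to
screen "adjacent normal" specimens before using them as normal controls, and
at methodologists studying field effects.

## What it computes

**Occult tumor from DNA methylation.** Per sample, the adjacent-tissue beta
values (β = M/(M+U) ∈ [0,1]) are regressed on the matched tumor betas across
the 500 most tumor-hypermethylated probes. A mixture of occult tumor cells at
fraction *f* gives adjacent ≈ *f*·tumor + const, so the OLS slope estimates
the contamination. Calls: slope > 0.4 and residual s.e. < 1 → occult tumor;
slope > 0.4 with high residual scatter → field effect; otherwise normal.
Samples are ranked by (slope ↓, residual s.e. ↑).

**Copy-number evidence of tumor.** An adjacent segment (|log2 ratio| > 0.1)
matches a tumor segment when they share ≥ 50% reciprocal overlap, agree in
sign, and no blood segment past the amplitude filter overlaps it (germline
exclusion). Shared altered basepairs are tiered: > 100,000 bp → evidence of
tumor; 1,000–99,999 bp → small evidence; pairs without blood can reach only
"likely evidence".

**Somatic mutation burden.** Tumor SNVs pass a filter cascade (≥ 20×
coverage in all three compartments, tumor VAF > 10%, two-sided Fisher exact
p < 0.05 tumor vs blood, blood VAF < 5%); among variants detected in the
adjacent tissue (≥ 2 alt reads), the fraction with VAF > 1% tiers the burden
none / low / moderate / high. RNA evidence: a sample is positive when ≥ 2
filter-passing loci carry ≥ 2 variant RNA reads.

**Expression subtypes.** miR and mRNA count matrices are RPM- or
upper-quartile-normalized, filtered (RPM ≥ 1 in ≥ 10 libraries), reduced to
the 25% most variant features, and clustered by NMF (Brunet
multiplicative-update, KL divergence) consensus clustering with
consensus-matrix silhouettes. Differential abundance between the two
clusters uses a permutation Wilcoxon statistic with a plug-in FDR, then
|FC| ≥ 1.5 and mean RPM ≥ 25 filters. The two mRNA clusters map to the
active / inactive extratumoral subtypes.

**Integration and survival.** A patient has "any DNA defect" when the exome
burden is moderate/high, OR methylation shows occult tumor, OR copy number
shows (likely) evidence of tumor. Kaplan–Meier curves and multivariable Cox
models (Efron ties, censored at 10 years) relate subtype and defects to
overall survival among ER-positive patients.

A deterministic synthetic-cohort generator (`sim_config()`,
`simulate_cohort()`) produces tumor/blood/adjacent triplets with known
occult fraction, copy-number contamination, mutation burden, subtype effect,
and survival hazard, so every stage is validated by parameter recovery — no
external data needed.

## Worked example

```r
library(fieldscape)

cfg    <- sim_config(n_patients = 102, seed = 1)  # study-scale cohort
cohort <- simulate_cohort(cfg)
report <- run_pipeline(cohort, seed = 1)
print(report)
#> <fieldscape_report>
#>   methylation: 17% occult, 0% field effect
#>   copy number: 11% evidence of tumor
#>   mutations:   26% moderate/high burden, 26% RNA positive
#>   any defect:  32%
#>   miR/mRNA cluster concordance: 0.88
#>   Cox HR (active vs inactive, ER+): 2.28 [1.16, 4.48]
```

The prevalences recover the generator's ground truth (15% occult fraction
injected, 10% copy-number contamination, 25% mutation burden, 90% label
concordance, hazard ratio 3 for the active subtype). Per-sample detail is a
regular data frame per stage:

```r
fit <- fit_occult_regression(cohort$methylation$adjacent[, 1],
                             cohort$methylation$tumor[, 1],
                             attr(report$methylation, "probes"),
                             sample_id = "P001")
classify_methylation(fit)
#> <occult_fit P001: slope 0.779, intercept 0.021, rse 0.0328, n=500, occult_tumor>
```

Here the fitted slope 0.78 estimates this patient's occult tumor-cell
fraction (true value 0.76), and the tight residual scatter makes the call
occult tumor rather than field effect.

A command-line front end wraps the same functions:

```sh
Rscript inst/scripts/fieldscape.R simulate --n-patients 100 --seed 1 --out cohort/
Rscript inst/scripts/fieldscape.R pipeline --dir cohort/ --seed 1 --out report/
```

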