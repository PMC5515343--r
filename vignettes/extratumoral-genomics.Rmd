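---
title: "Detecting genomic defects in cancer-adjacent tissue: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting genomic defects in cancer-adjacent tissue: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fieldscape)
```

Breast tissue excised centimeters away from a tumor margin and passed as
normal by pathology can still harbor malignant cells below the microscopic
detection limit (occult tumor) or carry diffuse molecular abnormality
(field cancerization). `fieldscape` screens such tissue on three DNA
platforms, subtypes its expression landscape, and relates both to survival.
This vignette explains each model, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the design choices
made where the procedure was genuinely open.

## Occult tumor from methylation regression

For a patient with tumor beta values $t_p$ and adjacent-tissue beta values
$a_p$ over probes $p$, a fraction $f$ of occult tumor cells mixed into
otherwise normal tissue gives, per probe,

$$ a_p \approx f\, t_p + (1-f)\, n_p, $$

with $n_p$ the normal baseline. Restricted to probes strongly
hyper-methylated in tumor ($t_p \gg n_p$, baseline low and relatively
flat), the ordinary least-squares slope of $a$ on $t$ estimates $f$. Probes
are chosen as the 500 largest positive tumor-minus-normal mean differences
(hypo-methylated probes are selected too, but only for export/heatmaps; the
regression uses the hyper set, where the contamination signal is cleanest).
Zero-difference probes carry no direction and are never selected; ties
break lexicographically by probe id so selection is reproducible.

Calls use two thresholds, both configurable and strict inequalities:

* `slope_threshold` (default 0.4, dimensionless): slope above it marks
  altered methylation;
* `rse_threshold` (default 1.0, beta units): among altered samples, a
  residual standard error $\sqrt{RSS/(n-2)}$ below it indicates the tight
  linear pattern of occult tumor cells; larger scatter is read as a field
  effect.

A caveat we flag prominently: on the beta scale ($[0,1]$) the residual
standard error of any such regression is bounded well below 1, so with the
default thresholds the field-effect tier is unreachable and high-slope
samples always call occult tumor. The tier exists for users who regress on
other scales (e.g. M-values) or tighten `rse_threshold`; on beta data a
field-effect screen should lower `rse_threshold` to the observed scatter
scale (e.g. 0.1). The classifier itself is a pure threshold rule and is
tested exhaustively against its truth table.

Degenerate inputs error early: fewer than 10 usable probes after NA
removal, or zero variance in the tumor betas (slope undefined). A
cellularity confound check (`cellularity_confound_check()`) correlates the
per-sample median hyper-probe beta with an external cellularity estimate;
no correlation supports that the regression is not merely tracking overall
tumor-cell content.

## Copy-number evidence

Segments are held in 0-based half-open coordinates internally (length is
always `end - start`); the SEG reader converts from the common 1-based
closed dialect by default, and both dialects round-trip. The matching
predicate for an adjacent segment requires:

* amplitude: $|\log_2 \text{ratio}| > 0.1$ (strict) on both sides — a
  dilute occult clone attenuates the tumor log-ratio, so the filter also
  sets the detectability limit;
* $\ge 50\%$ reciprocal overlap: the intersection covers at least half of
  *each* segment's own length;
* sign concordance (on by default, switchable): a gain cannot corroborate
  a loss as shared clonality;
* blood exclusion: any $\ge 1$ bp overlap with a blood segment *passing
  the amplitude filter* vetoes the candidate. Literal "no overlap with
  blood" would veto everything against the genome-tiling near-neutral
  segments that real SEG exports contain, so neutral blood segments never
  veto.

Each adjacent segment matches at most one tumor segment — largest overlap,
ties to the longer then leftmost tumor segment — and the summed overlap
basepairs tier the call: $>100{,}000$ bp evidence of tumor,
$1{,}000$–$99{,}999$ bp small evidence, else normal. The printed ranges
leave exactly 100,000 bp unassigned; we assign it to the evidence tier.
Without a blood sample (pair mode) germline CNVs cannot be excluded, so the
top tier is only "likely evidence". Matching is validated against a
per-base brute-force oracle on a thousand random profiles.

## Somatic mutation burden

The filter cascade keeps variants measurable in all three compartments
(depth $\ge 20$), with tumor VAF $> 0.10$, a two-sided Fisher exact
p $< 0.05$ for tumor vs blood allele counts, and blood VAF $< 0.05$. The
Fisher test is a vectorised exact hypergeometric sum (needed across
thousands of loci) and is checked against `stats::fisher.test` to 1e-12;
sidedness is not dictated by the procedure we reproduce, and two-sided is
the conservative choice. Variants are annotated with a failure reason
rather than dropped, so filter behaviour is auditable.

Burden tiers, as printed, overlap logically ("at least 2 mutations" appears
in three tiers). We resolve them with the precedence *none* (fewer than 2
detected) → *high* (fraction with adjacent VAF $> 1\%$ at least 0.5) →
*low* (fraction at most 0.1) → *moderate* (anything between), which maps
every (count, fraction) pair to exactly one class; the rule is verified
against a hand-written truth table. "Detected in adjacent" uses a $\ge 2$
alt-read floor, mirroring the stated RNA presence rule, since no DNA-side
floor is stated. The denominator of the fraction is the detected set (not
all tumor mutations); both choices are arguments.

## Expression subtypes

miR counts are RPM-normalized (columns sum to $10^6$); mRNA abundances are
upper-quartile normalized within sample (dividing by the 75th percentile of
nonzero values, rescaled by the cohort median so magnitudes stay
comparable). Features must reach RPM $\ge 1$ in $\ge 10$ libraries; the 25%
most variant features enter clustering.

NMF uses the Brunet multiplicative updates minimizing generalized KL
divergence, uniform random initialization from a derived sub-seed,
convergence at relative objective change $\le 10^{-6}$ (checked every 10
iterations) or 2000 iterations. Consensus clustering repeats the
factorization across restarts and records co-clustering frequencies; final
assignments cut an average-linkage tree of $1 -$ consensus — the standard
choice where the original tooling's assignment rule is not restated.
Silhouette widths are computed from the consensus matrix with
dissimilarity $1 - $ consensus (singletons get width 0), measuring each
sample's typical/atypical membership. The rank survey spans k = 2–15; k
stays a user decision (default 2, consistent with the two known
extratumoral subtypes). Cluster labels are arbitrary, so the pipeline
orients the two mRNA clusters by overall abundance of the
variance-selected features (the active-stroma signature up-regulates
them); external centroid files can replace this via the nearest-centroid
classifier (`assign_subtype()`, Spearman or Euclidean, deterministic
lexicographic tie-break, error when under half the centroid features are
present).

Differential abundance uses the standardized Wilcoxon rank-sum statistic
with a permutation null (all distinct label assignments when fewer than
`n_perms = 1000` exist). The plug-in FDR at each observed |statistic|
threshold divides the null exceedance count by the observed count,
capped at 1 and monotonized. We pool null counts across permutations by
their **mean**, not their median: in small discrete designs the median
count at the maximum-statistic cutoff collapses to zero (the permutation
maximum exceeds the observed maximum about half the time), which makes the
median variant declare a false discovery in roughly half of null datasets,
while the mean behaves like the expected-false-positive count the
estimator is meant to be. The median variant remains available
(`null_summary = "median"`). Passing features additionally need
$|FC| \ge 1.5$ (cluster-mean ratio with pseudo-count 0.5; ratios below 1
reported as negative reciprocals) and mean RPM $\ge 25$ in at least one
cluster.

## Integration and survival

A patient carries "any DNA defect" iff exome burden is moderate/high, or
methylation calls occult tumor, or copy number calls (likely) evidence of
tumor; field effects, small CN evidence, low burden, and RNA positivity
never trigger the flag, and missing platforms simply do not contribute
(a patient with no platform is excluded, with a count). Survival uses the
`survival` package: Kaplan–Meier product-limit curves with a log-rank test,
and Cox proportional hazards with Efron ties (Breslow by flag), both after
administrative censoring at 10 years (later events become censorings at the
horizon). Reference levels are fixed — inactive subtype, node-negative,
LumA, stage I, T1, age < 40, no defect — since the original reference
coding is unstated; patients missing a covariate are complete-case
excluded with a logged count, and constant covariates are dropped with a
message rather than breaking the fit. A sensitivity refit excluding raw
stage-IV cases is provided. The association battery chooses chi-square
when all expected counts reach 5, Fisher's exact test for sparse 2×2
tables, and a pooled-variance t-test for age (decade midpoints when exact
ages are absent).

## What the generator emulates — and what it does not

`sim_config()` fixes the whole cohort from one master seed;
per-patient sub-seeds come from a multiplicative hash so extending a
cohort never perturbs existing patients. Noise models are the simplest
consistent with each assay: Gaussian on betas (sd 0.03 by default, clipped
to $[0,1]$), Poisson depths with binomial allele counts (blood alt reads
only via a 0.001 error rate), log-normal-ish counts via Poisson around a
log2 baseline, exponential survival with administrative censoring.

Default study conditions: 102 patients; ~10% carry heavy occult
contamination (copy-number contamination 1, VAF scale 0.5 — high enough
that the attenuated segment log-ratio clears the 0.1 amplitude filter, as
a CN-visible clone must); a further ~5% carry methylation-only occult
signal (fraction uniform in 0.4–0.8); a further ~15% carry a low-VAF
mutation burden (scale 0.1, adjacent VAFs typically under 5%); ~36% of the
rest get a sparse field-effect shift (10% of probes moved toward tumor by
0.3). Tumor VAFs are uniform in 0.13–0.60; 30 somatic SNVs per patient —
the typical whole-exome burden of a breast tumor (~1 mutation/Mb over a
~34 Mb capture). Expression: 10% of features shifted by 1 log2 unit
between subtypes, active prevalence 0.6, miR labels agreeing with mRNA
labels at 0.90, log hazard ratio $\log 3$ on a 0.05/year baseline, censored
at 10 years.

Deliberately *not* emulated: realistic genome coordinates or linkage,
probe annotation, array batch effects (ComBat is out of scope), tumor
heterogeneity beyond a single contamination fraction, correlated clinical
covariates, and cross-platform coupling beyond the shared per-patient
contamination dials. Passing recovery tests therefore shows the rules
invert the stated generative model — it does not certify performance on
real arrays, where probe-level baselines correlate between tumor and
normal and can bias the occult slope upward.

## Numerical choices and problem sizes

Strict inequalities at every stated threshold; exact-tie behaviour is
always deterministic (lexicographic ids, longer-then-leftmost segments,
first label on centroid ties). OLS is solved by the closed-form normal
equations via `lm.fit`; agreement with a hand-written closed form is
asserted to 1e-10, the Fisher p to 1e-12 against enumeration. The test
suite and acceptance script run consensus clustering with 10 survey and
100 final restarts (the reduced schedule; 30/500 reproduce the full
procedure and remain available as arguments), recovery cohorts of 100–200
patients, 50 null simulations for FDR control, and 100/200 seeds for the
Cox recovery and coverage checks — sizes chosen so the whole suite stays
interactive while the Monte-Carlo margins remain wide.
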