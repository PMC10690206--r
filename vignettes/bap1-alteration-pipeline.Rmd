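---
title: "Detecting BAP1 alterations and their consequences: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting BAP1 alterations and their consequences: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bap1sig)
```

# Scope

`bap1sig` implements a multi-omic analysis of BAP1 tumor-suppressor
alteration: somatic mutation calls from several callers are harmonized and
filtered; samples are classified by copy-number-aware alteration state
(`Unaltered`, `MutOnly`, `CNOnly`, `CN+Mut`); altered and unaltered samples
are compared by covariate-adjusted negative-binomial differential
expression; the resulting gene panels drive per-sample signature scores,
mixture-model classification, preranked gene-set enrichment, and
progression-free-interval (PFI) survival stratification. Because the real
cohorts this design targets are controlled-access, the package ships a
synthetic multi-cancer cohort generator with planted truth; every module is
validated against that truth or against closed-form/hand-computed oracles.

# Variant harmonization

Callers emit the same event in different allele representations, so calls
are first normalized: shared suffix then prefix bases are trimmed (with
position adjustment) and pure indels can optionally be left-aligned within
a supplied reference context. Calls identical on
(sample, chromosome, position, ref, alt) collapse to one record whose
caller set is the union; read counts come from the caller with the highest
depth (the callers do not publish a reconciliation rule, so the deepest
observation is used as the best-supported one), and classification
conflicts resolve by a fixed most-deleterious-first ranking
(Nonsense > Frame_Shift > Splice_Site > In_Frame > Missense > other).

Filtering retains calls with a PASS filter flag, variant allele frequency
(VAF) at or above 0.2, alternate read count at or above 2 (both
inclusive), and an impactful consequence (synonymous and non-coding
classes are dropped). A final expression filter keeps only mutations in
samples whose normalized BAP1 expression is at or below the within-tumor-
type median (quantile 0.5 by default; the criterion "low expression within
tumor type" has no published numeric threshold). Manual read review is not
implementable in software; in its place the filter exports a review table
(per-call expression and within-type rank) and accepts an exclusion list.
Types with fewer than 5 expressed samples skip the expression filter with
a warning rather than estimating a quantile from almost nothing.

Indel length is `max(len(ref), len(alt)) - 1` in the padded MAF
representation and the full inserted/deleted length in the minimal
(`"-"`-allele) representation; "long" indels are 40 bp or more.

# Alteration classification

A sample has copy-number loss when its gene-level integer copy number is
below two. Loss-segment extent is summarized per sample as the total width
of merged loss segments overlapping the gene locus (closed intervals, any
base overlap counts; merging gives one width per sample when a locus is
covered by adjacent fragments). The four alteration labels are the 2x2 of
(loss, mutation) and partition the cohort by construction.

# Differential expression

Counts are normalized with median-of-ratios size factors (reference =
genes nonzero in every sample; library-size ratios as a guarded fallback).
Each gene is fit with an NB log-linear model (`Var = mu + alpha mu^2`)
with log size-factor offsets and a per-type design such as
`~ altered + purity + subtype`. The dispersion is estimated per gene by
maximizing the Cox–Reid-adjusted profile likelihood (floored at 1e-8),
alternating with IRLS coefficient fits; the adjustment
(`-1/2 log det X'WX`) removes most of the small-sample downward bias of
the plain MLE, which would otherwise inflate Wald statistics. The Wald
statistic is the alteration coefficient over its standard error with a
two-sided normal reference.

Non-BAP1 chromosome-3p genes are excluded **before** normalization and
testing, not merely before multiple-testing adjustment: BAP1 loss is
frequently arm-level, so 3p genes are co-lost and truly shifted; leaving
them in the median-of-ratios reference biases every sample's size factor
by a few percent in an alteration-correlated direction, which measurably
inflates the null type-I rate. BAP1 itself is always retained.

Adjustment is Benjamini–Hochberg. An optional mean-count-binned weighted
BH mode is provided (weights proportional to each bin's enrichment of
small p-values, normalized to mean 1 so the test budget is conserved); it
captures the mechanism of covariate-weighted testing in a directly
testable form and is off by default. Effect-size shrinkage is out of
scope: raw MLE fold changes with standard errors are reported, since the
signature derivation depends on direction calls, not display magnitudes.
Direction calls use `padj < 0.05` and `|LFC| > 0` by default — the
inclusion rule for signature genes is deliberately permissive because no
stricter published threshold exists; 1.5 is a typical display cutoff for
volcano plots only.

# Signature scores

All scoring uses `log2(normalized count + 1)` — raw-count sums would be
dominated by a handful of high-expression genes — and is computed within
one tumor type. A gene-set score is the z-transform (across samples) of
the per-sample sum of median-centered expression over set members; a
zero-variance guard returns all-zero scores. The alteration signature
weights upregulated genes +1 and downregulated genes -1 before summing, so
a positive score marks a sample transcriptionally similar to altered
samples; by construction the score is antisymmetric under swapping the up
and down sets, and with an empty down set it reduces exactly to the
gene-set z-score. Cross-cohort comparisons compute a reference-derived and
a native signature on the same samples and report Spearman correlation
over pairwise-complete observations (undefined below 3 pairs).

The mutation signature (mutant vs copy-number-only altered samples) is
kept on the raw-sum scale by default because published decision cutoffs
for such scores (e.g. 237 for a pooled five-type analysis, 138 for a
kidney-only analysis) live on the unstandardized scale; both scales are
exposed. Scores are classified by a two-component univariate Gaussian
mixture fit by EM (unequal variances, k = 2, 10 random restarts under a
fixed seed, tolerance 1e-8); the cutoff is the point between the component
means where the posterior probabilities are equal, found by root finding
on the weighted log-density difference, with the midpoint of the means as
fallback when no boundary lies between them. Degenerate fits (an
effectively empty component, or scores without spread) fall back to a
median split with a warning; all-identical scores are all classified
negative. A stored cutoff can be supplied to reproduce previous
classifications.

# Enrichment

Preranked GSEA uses the weighted Kolmogorov–Smirnov running sum (hits
increment by `|stat|^p / sum |stat|^p`, misses decrement by
`1/(N - n_set)`, default `p = 1`); the ranking statistic is the signed
Wald statistic, the standard choice for count-model preranked workflows.
The enrichment score is the extremum of largest magnitude; exact magnitude
ties between the positive and negative extremum (which occur in exhaustive
small-set enumeration) resolve positive-first, identically in the
implementation and its brute-force test oracle. The null is gene-sampling:
same-size random sets, with p-values one-sided by ES sign against the
sign-matched half of the null — the classic permutation-GSEA convention,
under which null p-values are uniform and the attainable minimum is about
`2/n_perm`. NES divides ES by the mean magnitude of sign-matched null
scores. The recurrent-pathway matrix keeps pathways significant
(`padj < 0.05` by default; adjusted rather than nominal, the conservative
reading) in at least 5 cohorts and orders cohorts by average-linkage
hierarchical clustering of NES columns.

# Survival

Stage labels (AJCC roman or arabic, with substages) are reclassified:
stages 0–2 are "low", stage 3 "high", and stage-4 tumors are excluded.
To limit follow-up heterogeneity, records are administratively censored at
the within-tumor-type median follow-up time; the median is taken over all
samples' follow-up times (censored and uncensored — the denominator set is
otherwise unspecified), and late records are truncated-and-censored rather
than dropped, which keeps their person-time. `prepare_survival()` is
idempotent. Kaplan–Meier curves, risk tables, and logrank tests come from
the `survival` package; Cox models maximize the partial likelihood with
the Efron tie correction (tolerance 1e-9, at most 50 iterations), and the
univariate model uses the binary sign of the signature score, not the
continuous score. Monotone likelihoods (complete separation) are reported
as non-convergence with no estimate.

# The synthetic cohort

The generator emulates the schemas and statistical structure of the real
inputs: per-type NB counts (one global dispersion 0.1, `Var = mu + alpha
mu^2`, matching the DE model), alteration-dependent expression shifts,
caller-specific call noise, arm-vs-focal loss segment widths, and
alteration-dependent exponential hazards. Defaults, chosen once as the
study conditions: 2 tumor types of 200 samples; per-sample alteration
probabilities MutOnly 0.05, CNOnly 0.30, CN+Mut 0.05 (a heavily altered
tumor type, where alterations are predominantly copy-number-driven);
100 responsive genes of 2000 at |LFC| 2 (half up, half down, placed off
3p so the arm mask never removes planted signal); 5% of genes on 3p,
co-shifted one copy in CN-altered samples; BAP1 reduced x0.5 per lost copy
and x0.25 with a mutation; 2 callers at per-caller detection 0.95; decoy
artifact calls at 0.15 per sample per caller, each carrying a
disqualifying feature; 10% of true calls are 40–80 bp indels; stage
probabilities (.1, .3, .3, .2, .1) over stages 0–4 so both the
reclassification and the stage-4 exclusion are exercised; true hazard
ratio 3 for altered samples.

Two couplings make the covariates meaningful rather than decorative.
Purity multiplies the observed expression shift (observed LFC = purity x
true LFC), so adjusting for purity has something to recover; purity is
drawn U(0.7, 0.95), the range under which the clonal-heterozygous VAF
model (truncated normal centered at purity/2, sd 0.05) reproduces a VAF
distribution consistent with largely clonal mutations. Calibration checks
that compare the estimated coefficient to the configured LFC set purity to
exactly 1 so the target parameter is the configured value itself.

What the generator does **not** emulate: read-level data, realistic
mutational signatures or hot spots, subclonal architecture, batch or
GC/length biases, dispersion trends over expression, and correlated gene
modules beyond the planted panel. Passing tests therefore demonstrate
correctness of the statistical machinery under the stated model, not
robustness to every artifact of real sequencing data.

# Numerical choices and degenerate inputs

* Dispersion search over `log alpha` in `[log 1e-8, log 20]`, three
  alternating rounds, convergence at 1e-4 on `log alpha`.
* All-zero genes report `p = 1`, no fold change; rank-deficient designs
  error with the collinear columns named; a singular weighted
  cross-product falls back to a no-estimate row.
* Size factors fall back to geometric-mean-scaled library sizes (with a
  warning) when no gene is nonzero everywhere.
* z-scores guard zero standard deviation by returning zeros.
* The EM flags a component as empty below one expected member and falls
  back to a median split; variances are floored at 1e-8 of the data
  variance.
* Segment widths merge book-ended segments (gap 0) before summing.
* Coordinates are 1-based inclusive everywhere (MAF/SEG convention).

# Problem sizes used in the validation suite

The shipped tests and the acceptance script run, per module: the
2 x 200-sample default cohort for the filter chain; 100-sample cohorts
with 1000–2000 genes for DE calibration and power; 120-sample cohorts for
signature scoring; exhaustive ES enumeration up to 8 genes; 500 random
sets at 1000 permutations for null uniformity; 100 replicates of
600-sample cohorts for hazard-ratio coverage; and a 2 x 60-sample cohort
of 600 genes for the end-to-end bit-reproducibility check. These sizes
were chosen so the whole suite exercises every estimator at meaningful
power while remaining quick to run on a laptop.

# Known limitations

* The NB fit is a deliberately compact estimator: no dispersion-trend
  shrinkage by default, no outlier refitting, no independent filtering.
* The weighted-BH mode is a mechanism-level stand-in for full
  covariate-weighted multiple testing and is off by default.
* The mixture classifier assumes exactly two score populations; more
  structure should be modeled upstream.
* Survival modeling covers right censoring only — no competing risks or
  time-varying covariates.
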