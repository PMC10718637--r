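---
title: "Methods: audiometric phenotypes and rare-variant association in adult-onset hearing loss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: audiometric phenotypes and rare-variant association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PresbyScan)
```

# The scientific problem

Adult-onset (age-related) hearing loss is heterogeneous. Two canonical
presbyacusis phenotypes are distinguished by audiogram shape: *metabolic*
(strial) loss, attributed to decline of the cochlear lateral wall, shows
mildly elevated thresholds at low frequencies sloping gently downwards
towards high frequencies; *sensory* loss, attributed to organ of Corti
lesions, shows near-normal low-frequency thresholds with a steep
high-frequency slope. PresbyScan implements a pipeline that (i) assigns
participants to these phenotypes from their pure-tone audiograms, (ii)
builds a clean consensus genotype matrix from multi-caller exome calls,
(iii) looks for genes whose aggregate rare-variant load differs between
phenotype groups, and (iv) scans individual variants for carrier threshold
shifts with a permutation null. Because real clinical-genetic cohorts of
this kind are not redistributable, the package includes a first-class
synthetic-cohort generator whose truth tables drive the test suite.

# Audiogram decomposition and classification

Each ear's audiogram $y(f)$ (dB HL at frequencies $f$) is approximated as a
non-negative combination of two unit-peak template shapes,

$$ y(f) \approx m\,P_{\mathrm{met}}(f) + s\,P_{\mathrm{sen}}(f),
   \qquad m, s \ge 0, $$

fitted by non-negative least squares (`pracma::lsqnonneg`). Because each
shape peaks at exactly 1, the coefficients $m$ and $s$ (the *metabolic* and
*sensory estimates*) are in dB and directly comparable with the rule
thresholds below. The *line-fit error* is the root-mean-square residual in
dB; audiograms whose configuration the two-component model cannot express
(e.g. corner audiograms) produce large errors.

Design choices that were genuinely open:

* **Template shapes.** Empirically derived templates are not
  redistributable here, so the defaults in `defaultProfileBasis()` are
  documented stand-ins constructed to match the verbal phenotype
  descriptions (metabolic: 0.70 rising to 1.00 across 0.25–8 kHz;
  sensory: 0.00 rising steeply to 1.00 above 2 kHz). Studies with access
  to empirical templates should pass them to `profileBasis()`.
* **No intercept.** A free intercept would absorb metabolic-like flat loss
  into a nuisance term, so the fit has none.
* **Error definition.** RMS residual (rather than maximum residual) is
  used; it is the conventional aggregate and behaves smoothly for the
  ≥ 15 dB exclusion rule.
* **Frequency grids.** When ears or cohorts differ in available
  frequencies, both ears are fitted on the intersection of the two ears'
  non-missing frequencies. Template shapes are interpolated onto the
  audiogram's grid linearly in $\log_2 f$, the audiometric octave scale.

Classification applies four rules *strictly sequentially* to the pair of
ear fits (`classifyCase()`): (1) *Unselected* if either ear's line-fit
error is ≥ 15 dB; (2) *Older-Normal* if the summed mean estimates are
< 20 dB with < 10 dB interaural difference in each estimate; (3)
*Metabolic* if mean metabolic ≥ 20 dB, metabolic asymmetry ≤ 15 dB, mean
sensory < 20 dB and metabolic > sensory; (4) *Sensory* if mean sensory
≥ 15 dB, sensory asymmetry ≤ 20 dB, mean metabolic < 25 dB and
sensory > metabolic; otherwise *Unclassified*. Whether magnitude criteria
apply per ear, to the worse ear, or to the across-ear mean is not forced
by the rules as stated; the package uses the across-ear mean for
magnitudes and the absolute left–right difference of each component for
asymmetries — the most conservative symmetric reading — and every
threshold is configurable through `classificationRules()`. Classification
here is purely rule-based; no manual review step is reproduced.

# Consensus genotypes and variant QC

Sites are accepted when the caller combination has demonstrated accuracy:
GATK VQSR tranche 1 plus at least one of BCFtools/Freebayes, or tranche 2
plus BCFtools (`siteQualityGate()`). Per-sample genotypes are merged by
majority; the three-way split hom-ref/het/hom-alt resolves to heterozygous;
single-caller calls and 1-vs-1 splits are missing (`mergeGenotype()`).

Three site filters follow. *Excess heterozygosity* — a signature of
mismapped paralogous reads — is tested with the one-sided exact test on
the Levene–Haldane distribution of the heterozygote count conditional on
allele counts, implemented in `excessHetPValue()`; the default
significance level 1e-6 is a conventional exome-QC choice (the level is a
package decision and configurable). The *cohort allele-frequency* filter
drops sites whose cohort AF exceeds the reference MAF by more than 0.4
(likely aligner miscalls in low-complexity regions); cohort AF is
alternate-dosage over $2\times$ non-missing calls for nuclear sites and
carrier fraction for mitochondrial sites. The final filter keeps *high
impact* variants with reference MAF < 0.1 (strict), treating variants
absent from the MAF source as novel (MAF 0; configurable).

Mitochondrial sites bypass the diploid machinery: calls with depth < 30×
are missing; variant allele fraction > 0.95 is homoplasmic and coded
homozygous; fractions in [0.40, 0.95] are heteroplasmic and coded
heterozygous; lower fractions are considered unreliable calls and coded
missing (40% is the reliable heteroplasmy detection floor at ≥ 30×
coverage).

# Variant-load outlier regression

For a pair of phenotype groups, `countVariantsPerGene()` totals qualifying
variant alleles per gene per group. The default *allele* mode weights
heterozygotes 1 and homozygotes 2 — consistent with homoplasmic
mitochondrial calls being treated as homozygous — and a *carrier* mode
(any non-reference genotype counts 1) is provided because "number of
variants" is also readable as presence counting. Counts are not normalised
for group size: the regression slope absorbs the group-size ratio.

`regressAndFlag()` fits OLS of one group's counts on the other's and flags
genes whose residual $r$ satisfies $r > Q_3 + 6D$ or $r < Q_1 - 6D$, where
$Q_1, Q_3$ are residual quartiles and $D = Q_3 - Q_1$. Quartiles use
linear interpolation between order statistics (`stats::quantile` type 7);
the interpolation rule is pinned for reproducibility and configurable. The
deliberately extreme multiplier 6 makes the rule nearly silent on null
data (measured below).

Outlier lists are tested for over-representation of curated gene sets
(e.g. known deafness genes, highly variable genes) with the upper-tail
hypergeometric probability over the universe of genes with at least one
variant call in the cohort; gene sets are intersected with that universe
first. Benjamini–Hochberg adjustment across a cohort's enrichment tests is
the default (Bonferroni and none are available, since the adjustment used
for published enrichment tables of this kind is not always stated).
`runComparisons()` runs the standard plan — Older-Normal vs all others,
vs Metabolic, vs Sensory, and Metabolic vs Sensory, each optionally
sex-stratified — skipping any stratum whose group falls below 20
participants (small groups do not support a stable count regression), and
merges outliers into a deduplicated candidate list with per-comparison
provenance.

# The threshold-difference scan

For each variant, carriers (heterozygous pooled with homozygous-alternate)
are compared with homozygous-reference participants in three strata (all,
male, female; sex strata use sex-matched references). A stimulus frequency
in one ear *passes* when the carrier-minus-reference mean threshold
difference is ≥ 20 dB in magnitude and the carrier SD is at most the
band cap: 15 dB up to 0.5 kHz, 20 dB to 2 kHz, 25 dB to 4 kHz, 30 dB
above 4 kHz (half-open bands so every standard frequency maps to exactly
one cap). Groupings with fewer than 5 carriers are ineligible; an eligible
grouping becomes a permutation candidate when at least two frequencies
pass in *each* ear and all passing frequencies share one direction, giving
each candidate a single "better"/"worse" label.

The permutation null (20,000 replicates by default) redraws pseudo-carrier
sets of the same size *and sex composition* as the observed carriers from
carriers ∪ reference, within sex even in the "all" stratum, so that
sex-linked threshold differences cannot masquerade as variant effects. A
replicate is *similar* when every (ear, frequency) in the observed passing
set passes the magnitude and SD criteria again under the permuted labels.
Two readings were open here: (a) whether a replicate must reproduce the
whole observed passing set or merely some ≥ 2-per-ear pattern — the
package defaults to the observed set ("the relevant stimulus frequencies")
with the looser reading behind `similar_mode = "min_per_ear"`; (b) whether
the replicate must match the observed direction — the default ignores
direction (magnitude-only), with `direction_in_permutation = TRUE`
available. The empirical p-value is `similar_count / n_perm` — not the
add-one variant — which is the convention that makes the published
permutation counts and p-values mutually consistent; a candidate is
rejected when more than 1000 of 20,000 replicates are similar (nominal
alpha 0.05). BH adjustment is applied only over the retained candidates
with m = number retained; that choice is statistically unusual (the
rejected tests vanish from m) but is faithful to the procedure as
described, and the raw empirical p-values are reported alongside.

# The synthetic-cohort generator

`simulateCohort()` draws, per participant, a phenotype class from a
mixture (defaults 0.2 / 0.3 / 0.3 / 0.2 over Older-Normal / Metabolic /
Sensory / Unclassified-like), then true component magnitudes uniformly
from per-class ranges chosen once to respect the classification-rule
geometry with margin (Older-Normal: both components in [0, 8] dB;
Metabolic: M in [25, 45], S in [0, 14]; Sensory: M in [0, 14],
S in [25, 50]; Unclassified-like: both in [28, 45], which fails the
Metabolic sensory ceiling and the Sensory metabolic ceiling by
construction). Thresholds are the component combination plus independent
Normal(0, 3 dB) noise per ear and frequency, clipped to [-10, 120] dB HL.
Genotypes are drawn under Hardy–Weinberg equilibrium at MAFs uniform on
(0.005, 0.1). Planted load genes multiply the carrier *probability* in the
target class (capped at 1). Planted effect variants receive an exact
carrier count (the ≥ 5-carrier gate makes power sensitive to the realized
count, so MAF draws would add irrelevant variance) and their shift is
added to the carriers' already-generated audiograms — effects are
orthogonal to class structure, which isolates exactly what the scan should
detect. The default grid is the 8 standard clinical frequencies 0.25–8
kHz; `twinsuk_grid = TRUE` gives the alternative grid without 3 kHz.

What the generator does *not* emulate: linkage disequilibrium, population
stratification, relatedness, age–threshold drift, covariance between
noise history and genotype. Passing recovery tests therefore demonstrates
algorithmic correctness under the model's assumptions, not robustness to
those confounders in real cohorts.

# Numerical choices and degenerate inputs

* Component fits need ≥ 2 usable frequencies and a non-collinear basis at
  those frequencies (`rcond` check at 1e-10); violations raise errors.
* A scan frequency with fewer than 2 carrier data points or no reference
  data is unevaluable and never passes; missing thresholds drop a
  participant from that frequency only.
* The excess-het test conditions on the minor-allele count and sums the
  exact conditional probabilities of heterozygote counts at least as
  large as observed (plain exact test, no mid-p).
* Boundary conventions are strict where the rules are strict: cohort AF
  exactly MAF + 0.4 is kept; reference MAF exactly 0.1 is dropped; VAF
  exactly 0.95 is heteroplasmic; fit error exactly 15 dB is Unselected.
* All simulation and permutation randomness flows from a single integer
  seed; reruns are bit-identical.

# Problem sizes used by the tests and the acceptance script

The experiments are sized as the smallest cohorts at which the measured
properties are stable: class recovery and error-control experiments use
500 participants; power and null experiments use 20 seeds at 2000
permutations with an adjusted rejection count of 100 (preserving the
nominal alpha 0.05); the null load experiment uses 2000 genes and the
null scan about 200 variants; oracle-equivalence checks run the exact
enumerations at the sizes where enumeration is exact (Hardy–Weinberg
totals ≤ 30, enrichment universes ≤ 12, 0.1 dB fit grids).

# Known limitations

* The default audiogram templates are stand-ins; absolute component
  estimates (though not the pipeline's behaviour) depend on the template
  choice, and users with empirically derived profiles should supply them.
* The scan tests marginal carrier effects only: no covariate adjustment
  (age, noise history), no kinship handling, and no asymptotic tests;
  with fewer than ~7 carriers the discreteness of the permutation null
  bounds attainable p-values.
* BH over retained candidates only (m = retained) understates the full
  multiplicity of the scan; interpret adjusted values accordingly.
* Enrichment p-values inherit the universe definition (genes with ≥ 1
  call); a different capture design changes the universe and the p-values.
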