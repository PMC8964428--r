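---
title: "Methods: pathway dysregulation scoring and drug prescription"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pathway dysregulation scoring and drug prescription}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdprx)
```

This vignette documents the statistical machinery of `cdprx`, the
assumptions behind each stage, the tunable parameters and their defaults,
and the design choices made where the method left room for interpretation.

## The model in one paragraph

A cancer is represented by a paired case–control expression cohort. Pathway
dysregulation is the GSEA normalized enrichment score (NES) of the
pathway's gene set on the cohort's case-versus-control gene ranking; the
pathways × cancers matrix of these scores (CNS) is the central object.
Downstream, three summaries are read off it: a rank-based *generality*
score measuring pan-cancer consistency of enrichment or depletion, a
three-class *mode of action* (LoF/SoF/GoF) from consensus clustering of
NES profiles, and a *prognostic* label per (pathway, cancer) from an
optimal-cutoff log-rank scan of per-patient ssGSEA activation scores.
Drugs enter as perturbation expression profiles scored by the same GSEA
machinery into a drugs × pathways matrix (PNS); the prescription score
PS = CNS − PNS quantifies how strongly a drug's transcriptional effect
opposes a cancer's pathway dysregulation.

## Enrichment scoring

**Ranking metric.** Signal-to-noise,
$(\bar x_{case} - \bar x_{ctrl}) / (s_{case} + s_{ctrl})$, with each
group's standard deviation floored at $\max(0.2\,|\bar x|,\ 0.2)$. The
floor keeps zero-variance genes finite and is the long-standing GSEA
desktop convention; cohorts with a single sample in a class must use the
log2 fold change of pseudo-counted means instead. Ties in the metric are
broken by gene id, so rankings are reproducible to the byte.

**Running sum.** The enrichment score is the signed maximum deviation of
the weighted Kolmogorov–Smirnov running sum with weight exponent 1: set
members ("hits") increment by $|m_g| / \sum_{S} |m_g|$, non-members
decrement by $1/(N - |S|)$. Because the extrema of the running sum can
only occur immediately before or after hit positions, the score is
computed in $O(|S|)$ from the hit positions alone — this is what makes
1000-trial permutation nulls affordable in pure R. When the positive and
negative extrema tie in magnitude within $10^{-9}$ (a real occurrence for
rational step sizes), the extremum reached earliest in the list wins; an
all-zero metric falls back to equal hit weights.

**Null, NES, p.** Phenotype permutation (class labels reshuffled, metric
recomputed, all sets rescored) is used when both classes have at least 7
samples; below that, $1000$ distinct relabelings do not exist and the
null switches to gene-set permutation (random position sets of the same
size), with a warning when the caller asked for phenotype permutation
explicitly. NES divides the observed ES by the mean |ES| of same-sign
null values; the empirical p carries a +1/+1 pseudo-count so a finite
trial count never reports $p = 0$ (at 1000 trials the floor is
$\approx 10^{-3}$). A set with no same-sign null values gets a flagged
result rather than a silent NaN. FDR is Benjamini–Hochberg across sets
within each cancer. Per-cancer permutation streams are seeded by cohort
*name*, not list position, so reordering cohorts only permutes CNS
columns.

**ssGSEA.** Per-patient activation is the sum over ranked positions of
the gap between the weighted in-set ECDF (weights $= \text{rank}^\alpha$,
$\alpha = 0.25$, higher expression = higher rank) and the unweighted
out-of-set ECDF. It depends only on within-sample ranks, hence is
invariant to any monotone rescaling of one sample's values — the property
that makes it safe across heterogeneously normalized patients. Scores are
used only *within* one cancer's cutoff scan, so no cross-sample
normalization is applied. Constant expression vectors are rejected
(ranks undefined).

## Generality score

With cancers ranked ascending by NES per pathway (ties by cancer label,
stable) and significance masks NES > 0 & p < 0.05 (enrichment) /
NES < 0 & p < 0.05 (depletion) giving counts $w_1, w_2$:

$$a_i = \frac{w_1}{w_1 + w_2} \sum_{k \in \text{enriched}} \frac{r_{ik}}{n},
\qquad
b_i = \frac{w_2}{w_1 + w_2} \sum_{k \in \text{depleted}} -\Bigl(1 - \frac{r_{ik}-1}{n}\Bigr),$$

and $S_i$ is the larger of the two in magnitude, zero on a tie or when
the pathway is nowhere significant. Two choices deserve note:

* **Summation domain.** The sums run over the significance-masked cancers
  only, not all $n$. This is the only reading under which the
  second-tier value 10.45 at $n = 20$ (19 significant cancers, the
  non-significant one at the bottom rank: $(210 - 1)/20$) is attainable —
  full-range summation with the $w$-weight cannot produce it from integer
  counts. The all-significant extremes $\pm 10.5 = \pm(n+1)/2$ come out
  identically under both readings.
* **Significance layer.** The masks use the pre-FDR empirical p (the
  defining inequality is stated on "significance p"), not the adjusted
  layer; both are carried on the `ScoreMatrix` so callers can tighten
  this.

## Mode-of-action classes

Pathways with NES standard deviation above 1.0 (log2-scale data) enter a
consensus matrix accumulated over 500 subsamples of 80% of the pathways,
each clustered by average-linkage hierarchical clustering on Euclidean
distance; the final k = 3 partition cuts average-linkage clustering of
1 − consensus. Clusters are labeled by median NES (most negative → LoF,
most positive → GoF, middle → SoF). Low-variance pathways are assigned
afterwards to the nearest cluster centroid. A generality score at or
beyond ±7.0 overrides an LoF/GoF label in the opposing direction
(`reassign_moa`); the threshold default of 7.0 is a package choice — the
method's one published reassignment example sits at 7.2, and no exact
cut was stated. With `n_resample = 1, subsample = 1` the procedure
degenerates to plain hierarchical clustering, which the tests exploit as
an oracle.

## Survival stratification

Candidates for the PA cutoff are every distinct observed score; strata
below 10% of the cohort (`min_group_frac = 0.1`) are skipped, because
without a minimum the scan trivially minimizes p on 1-patient tails. The
log-rank test is `survival::survdiff`; the package's test suite checks it
against a hand-computed observed-minus-expected oracle. Ties on p break
toward the more balanced split. No multiplicity correction is applied
inside the scan — the method takes the minimum p as-is, an
anti-conservative property inherent to optimal-cutoff stratification that
users should keep in mind when interpreting p-values near the 0.001
threshold. Direction (favorable/adverse) compares restricted-mean
survival of the two strata at the largest follow-up time both strata
share; the estimator was a package choice, the concept (high PA with
longer survival = favorable) is fixed. Patients lacking survival
information are dropped (and counted) at load time.

## SAM differential expression

The d-statistic offsets the Tusher pooled standard error by a fudge
factor $s_0$ chosen on the percentile grid {0, 5, …, 100} of the SEs
(plus 0 itself) to minimize the coefficient of variation of the
d-spread (MAD/0.64) across ten SE-quantile windows. The q-value takes,
at each observed |d| threshold, the median number of permutation-null
exceedances over the number of genes called, then enforces monotonicity
in |d| BH-style (running minimum from the least significant end). A
pooled permutation p accompanies q; under a complete null q concentrates
near 1 (so "fraction q < 0.01" is essentially zero) while p is the
calibrated quantity. Log2 fold changes use mean + 1 pseudo-counts; the
signature filter applies strict inequalities (|log2FC| > 2, q < 0.01 by
default), so boundary genes are excluded.

## Prescription and the triplet network

PNS aggregates instance-level NES by unweighted mean across all of a
drug's instances regardless of cell line (configurable upstream by
pre-grouping profiles). PS = CNS − PNS is *signed*: the method's
worked examples print negative PS for depleted pathways, which is
arithmetically exact only under the signed convention, while |PS| ranks
potency. PNS is implemented as drugs × pathways — the pairing the PS
formula requires — rather than drugs × cancers; a PNS column meets a CNS
cell through their shared pathway. The network filter demands the
pathway be prognostic (p < 0.001) in the cancer *and* |CNS| > 1.5
(strict), and keeps drugs whose PS carries the CNS sign; drugs whose PNS
actually opposes the CNS sign are flagged `reverser`, while same-sign,
smaller-magnitude drugs are retained but rank low. Notably, a pathway at
|CNS| = 1.2588 passes the worked-example table but not the network
threshold — the table is treated as PS arithmetic only, not as network
membership.

## The synthetic-data generator

The generator produces the statistical structure the pipeline assumes,
not TCGA realism: log-normal background expression with gene-specific
(heteroscedastic) variances — deliberately so, to exercise $s_0$
selection; disjoint gene sets (so planted shifts cannot leak between
pathways); additive case-class shifts in per-gene sd units; exponential
survival with hazard $h_0 \cdot \mathrm{HR}^{z(\mathrm{PA})}$ and
exponential censoring whose rate is solved from the competing-exponentials
identity so the expected censored fraction equals the configured rate;
and instance rankings that are standard-normal noise plus a planted shift
for reverser drugs. What it does *not* emulate: gene–gene correlation,
batch effects, overlapping pathways, cell-line-specific pharmacology,
dose–response. Passing tests therefore demonstrate correctness of the
algorithms and their calibration under clean assumptions, not performance
on real cohorts, where correlated genes inflate GSEA nulls and scan
p-values.

Default scale (2000 genes, 50 sets of 20–80 genes, 3 cancers, 20 samples
per class, 3 instances per drug) keeps a full pipeline run around two
minutes on one CPU. The test suite uses smaller versions of the same
properties (hundreds of genes, 100–200 permutations) for unit checks and
the stated sizes — 500 null simulations for calibration, 50 seeds at
n = 300 and HR = 3 for prognostic recovery, 50 drugs for reverser
recovery — in the acceptance checks.

## Degenerate inputs and numerical conventions

* Gene ids are opaque, case-sensitive strings; no alias mapping.
* Gene sets overlapping fewer than 2 measured genes are dropped with a
  count (GSEA needs two positions); filtering is idempotent.
* Constant PA vectors yield an explicit no-split result, not an error;
  zero-event cohorts refuse the log-rank test with "no events".
* Empirical p-values are never 0 (+1/+1 correction); score matrices
  refuse p or FDR layers outside [0, 1].
* Serialization of score matrices keeps 17 significant digits, making
  write→read the identity; all TSV I/O is tab-separated, decimal point,
  UTF-8, unquoted.
* Every stochastic routine takes an explicit seed; the pipeline derives
  per-cohort seeds from cohort names so results are invariant to input
  order.
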