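---
title: "m6A regulator signatures: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{m6A regulator signatures: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m6Asig)
```

## The scientific problem

N6-methyladenosine (m6A) is the most abundant internal modification of
eukaryotic mRNA. Its level is controlled by three groups of regulators:
*writers* (the METTL3/METTL14 methyltransferase complex), *readers*
(the cytosolic YTH-domain proteins YTHDF1/2/3 that transduce the signal)
and *erasers* (the demethylases ALKBH5 and FTO). Because no per-patient
m6A quantification exists in bulk tumor cohorts, a practical surrogate is
the expression of the regulator machinery itself: patients expressing
much writer/reader and little eraser are expected to carry more m6A than
the converse. `m6Asig` implements this surrogate end to end for gastric
cancer (GC) style cohorts: signature construction, patient
stratification, and the survival, mutation, clinical-index and pathway
analyses that quantify what the strata mean clinically.

## Signatures and stratification

Per sample, the writer signature $W$ is the geometric mean of METTL3 and
METTL14 expression, $R$ the geometric mean of YTHDF1/2/3, and $E$ the
geometric mean of ALKBH5 and FTO:

$$ W_s = \Big(\prod_{g \in \{METTL3, METTL14\}} x_{gs}\Big)^{1/2},
\qquad \text{computed as } \exp\big(\tfrac1k \sum_g \ln (x_{gs}+\varepsilon)\big). $$

Geometric means are computed in log space for stability. The pseudocount
$\varepsilon$ is 0 when the matrix is strictly positive (typical for
proteomic intensities) and half the smallest positive matrix value when
zeros occur (typical for RNA-seq quantities); this keeps the signature
strictly positive without distorting positive data at all. Expression
units are deliberately opaque — the loader never rescales — and the
signatures are degree-1 homogeneous in the input units. Whether to
average on the raw or a log2(x+1) scale is genuinely underdetermined for
mixed protein/RNA inputs; the package defaults to the raw-scale
geometric mean (the literal reading of "geometric average") and exposes
`log_transform = TRUE` as an explicit switch.

Each signature is dichotomized at the per-cohort median, `high` strictly
above, with ties assigned to `low` — an arbitrary but deterministic rule
that makes re-runs and permuted-input runs bit-identical. Medians are
never pooled across cohorts. Seven stratification schemes follow:

* **single** W, R, E: `low` / `high`;
* **double** WE, RE, WR: the four cross-classes, e.g. `WL_EH`;
* **triple** WRE: writers and readers jointly double-low (`dL`),
  single-high (`sH`) or double-high (`dH`), crossed with the E level —
  six groups.

Because writers and readers promote while erasers remove m6A, the strata
map onto *m6A-indication* classes: `W` low, `R` low, `E` high, `WL_EH`,
`RL_EH`, `WL_RL` and `WRdL_EH` are **low** m6A-indications; their seven
mirror images are **high**; every other composite stratum is
intermediate. This 7-vs-7 mapping is frozen as a truth table and tested
exhaustively.

An optional cutoff *scan* replaces the median: every observed signature
value that leaves both groups with at least 10% of the cohort is tried,
and the cutoff minimizing the two-group log-rank P is reported together
with the full scan curve. The historical description of this step in the
GC literature invokes "ROC curves" without specifying horizon or axes,
so the package deliberately implements the stated objective — minimum P
— labels the output as a scan, and reports a Bonferroni-corrected P
(multiplied by the number of candidates) because the minimum of many
correlated tests is an optimized quantity.

## Statistical machinery

Survival uses the standard Kaplan–Meier product-limit estimator and the
k-group log-rank test (via the `survival` package), with aggregated
handling of tied death times and deaths-before-censoring at equal times.
Groups under five samples warn rather than error. All-censored input is
defined as statistic 0, P 1.

Clinical indexes are compared between the low- and high-indication
groups with a two-sided Fisher exact test for 2×2 tables — the
sum-of-small-point-probabilities convention, which reproduces published
GC cohort tables to four decimals — and a Pearson chi-square without
continuity correction otherwise. Missing (`"n/a"`) values are excluded
per variable, not per sample, and age is dichotomized at 60 years.
When a larger-than-2×2 table has an expected count below 5 the result is
flagged, and a margin-preserving Monte-Carlo exact test (`exact_mc`) can
be dispatched instead. For the published TCGA Lauren 3×2 table the
Monte-Carlo exact test gives P ≈ 0.0007 while the chi-square gives
0.0018; since the test used for the published 0.0006 is not stated, both
routes are exposed and neither is labeled authoritative.

Mutation-frequency contrasts use the Haldane–Anscombe smoothed fold
change between indication groups,
$FC = \frac{(m_l + \tfrac12)/(n_l + 1)}{(m_h + \tfrac12)/(n_h + 1)}$,
which stays finite when one group carries no mutation. Fold-change
matrices from two cohorts are intersected into UP / DN / discordant
calls per scheme; a gene's consensus is UP (DN) when at least 4 of the 7
schemes agree in both cohorts. The 4/7 fraction is configurable — no
published rule exists for this consensus, and majority-of-schemes is the
weakest call that still requires cross-scheme consistency.

## The enrichment engine

Differential expression between strata is a per-gene Welch t-test
(constant genes are flagged, not fatal), with a configurable DEG
threshold (default P < 0.05 — deliberately explicit because published
DEG counts in this literature rarely state their criterion). Three-set
Venn region counts summarize scheme overlap.

GSEA is implemented in-package as the categorical (phenotype-label
permutation) procedure: genes are ranked by the signal-to-noise ratio
with each group SD floored at 0.2·|group mean| (the original GSEA
convention; the floor prevents division blow-ups for near-constant
genes), ties broken lexicographically for determinism. The weighted
Kolmogorov–Smirnov running sum uses hit increments proportional to
|score|$^p$ (p = 1 default) and uniform miss decrements; the enrichment
score is its maximum-magnitude deviation, computed in O(hits) from the
hit positions and verified against a step-by-step O(N) oracle and an
independent implementation (`fgsea::calcGseaStat`) in the tests.
Significance comes from re-ranking under permuted labels:
NES = ES / mean(|same-sign permuted ES|), the nominal P is the same-sign
exceedance fraction, and FDR q pools signed NES across sets as in the
original method. Phenotype (not gene-set) permutation is used because
the inter-gene correlation of expression data is part of the null being
tested. The permutation stream is seeded and isolated, so results are
bit-reproducible and never perturb user RNG state.

## What the synthetic generator emulates

`generate_cohort()` draws everything from a single per-sample latent m6A
level $z \sim N(0,1)$:

* **Expression.** Regulator log-expression is
  $a\,z + b\,u_{block} + c\,\epsilon$ with block-specific loadings; the
  W and R blocks load $+\sqrt{\rho_{WR}}$ and the E block
  $-|\rho_{WE}|/\sqrt{\rho_{WR}}$, so within-block correlation
  (default 0.7), the positive W–R correlation (0.55) and the negative
  W–E / R–E correlations (−0.4) hold *by construction* — the observed
  proteomic sign pattern is guaranteed rather than tuned. Defaults are
  in the range reported for co-regulated protein complexes. Values are
  exponentiated around per-gene means, hence strictly positive.
  A non-realizable parameter triple (loadings exceeding the within-block
  correlation) errors constructively at parameter time.
* **Survival.** Exponential times with baseline mean 30 months (a
  realistic GC OS scale) and hazard multiplied by `hr_low_vs_high`
  (default 2.5) for the lowest latent tertile; censoring times are
  uniform over a window solved numerically so the expected censoring
  fraction equals `censor_rate` (default 0.3).
* **Mutations.** Seven driver genes (CDH1, TP53, RHOA, MUC6, AR, GLI3,
  SETBP1) with baseline probabilities 0.12–0.45 — the range seen in
  targeted panels of GC cohorts — whose odds are multiplied by 3 in
  below-median-latent (low m6A) patients; half of CDH1 records carry the
  recurrent `p.D254Y` variant so exact-variant queries are exercised.
  Thirty passenger genes mutate independently of the latent factor at
  0.5–8%.
* **Clinical.** Lauren subtype, T/N/M and stage are drawn from ordinal
  logit models shifted by $z$ (diffuse histology and advanced stage
  enriched at low m6A); TMB is log-normal increasing with $z$ and MSI-H
  probability increases with $z$ (both mirror the reported association
  of high TMB/MSI with *low eraser* expression); EBV is an independent
  Bernoulli label, matching the reported null.
* **Enrichment ground truth.** Thirty background genes load negatively
  on $z$ and are packaged as the `ONCOGENIC_SPIKED` set, so the
  high-m6A group should show negative NES — the qualitative oncogenic
  depletion pattern — alongside latent-independent decoy sets.

All randomness flows from one root seed through named substreams
(expression, survival, mutations, clinical, gene sets, permutation), so
any component can be regenerated independently and regeneration is
byte-identical. The hidden truth table (latent level, tertile, true
hazard, spiked genes) is written separately and never read by the
pipeline.

`recovery_report()` turns the generator into a validation instrument: on
powered defaults (n = 600, HR 2.5, OR 3) it checks that the high-m6A
WRE corner outlives the low corner by KM median, that the extreme-corner
log-rank is significant, that every spiked driver earns a cross-cohort
consensus UP call over two independent replicates, and that the spiked
set's NES is negative. Cohorts whose extreme corners hold fewer than 15
patients are flagged underpowered instead of silently passing.

**What the generator does not emulate.** Proteomic intensity
distributions (heavy tails, batch structure, missingness), linked
mutation co-occurrence, non-proportional hazards, cure fractions, and
any real linkage between EBV and expression. Passing recovery therefore
demonstrates that the pipeline detects the modeled structure at
realistic effect sizes — not that real cohorts contain that structure.

## Numerical choices and test scale

Tolerances: geometric means and enrichment scores are checked against
oracles at 1e-12 relative; log-rank against hand computation at 1e-9;
Fisher exact against exhaustive enumeration (all 2×2 tables with
n ≤ 30) at 1e-9. Simulation-based checks use 100–200 seeded replicates
with cohort sizes of 100–600 and 120–1000 permutations — sizes at which
every documented power statement holds with margin while the whole
suite stays interactive. Degenerate inputs (all-equal signature values,
zero-variance correlation inputs, zero margins, constant genes,
empty indication groups) error or flag explicitly rather than
propagating NaN.

## Known limitations

* The m6A-indication labels are a surrogate; the package does not model
  measured m6A levels.
* The minimum-P cutoff scan is an optimized statistic; its uncorrected P
  should not be reported as confirmatory.
* No multiplicity correction is applied across the per-gene mutation
  screen or the 3×3 signature correlation grid, mirroring common
  practice in the source literature; users needing family-wise control
  should apply `p.adjust` downstream.
* Cox modeling, competing risks and time-dependent effects are out of
  scope; the survival layer is strictly KM + log-rank.
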