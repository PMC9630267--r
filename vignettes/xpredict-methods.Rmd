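---
title: "Methods: disorder-gene prioritization on chromosome X"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disorder-gene prioritization on chromosome X}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Roughly a quarter of protein-coding genes on the human X chromosome are
associated with a monogenic disorder, and X-linked disorders are strongly
biased toward neurological phenotypes (intellectual disability, seizures,
language impairment). Yet most chrX genes have no established disease
association, and the chromosome's unusual inheritance makes patient-driven
discovery slow. `xpredict` implements a gene-centred alternative: quantify
what known disorder genes look like — population constraint, sequence
conservation, expression breadth, promoter composition, paralogy — and use
those features to rank the remaining genes by their probability of being
disease-associated.

The package runs entirely on a synthetic gene universe with planted class
structure, so every stage is testable without downloads; real pre-exported
tables in the same layout can be substituted via `pipeline_config(input_dir=)`.

## Pipeline overview

`run_pipeline()` executes eight stages: simulate (or load), annotate,
features, enrich, lme, train, predict, validate. Each writes TSV/JSON
outputs plus a manifest entry (parameters, derived seed, output checksums).
All coordinates are 0-based half-open.

### Gene classification and pre-classification

Genes carry one of three disorder classes: `confirmed`, `PMT` (provisional /
susceptibility / trait associations) or `no_disorder`. Phenotype flags come
from case-insensitive substring matching of curated phrase lists against the
free-text neurologic clinical-synopsis line (`match_phenotype_terms()`);
there is deliberately no negation parsing — "no seizures reported" sets the
seizures flag — because the source synopses are unstructured and the
original searches were plain free-text queries. The flag lists ship as
editable defaults (`default_phenotype_terms()`, or a YAML file).

Crossing class with brain association and tolerance to homozygous
loss-of-function variants yields ten subgroups. Two define the training
classes: **Cbi** (confirmed brain-disorder genes intolerant to homozygous
LoF; label 1.0) and **NDt** (no-disorder genes tolerant to homozygous LoF,
i.e. dispensable; label 0.0). LoF-tolerance is an input flag, not recomputed
from variant data.

### The 83-feature table

`assemble_feature_table()` produces exactly 83 named features in six groups:
35 constraint metrics (LOEUF, misZ, synZ, pLI, pNull, oe_mis_pphen, max_af,
classic_caf, ...), taken per gene from the transcript with the lowest LOEUF;
2 conservation scores (mean per-base phastCons-style score over the
canonical CDS and over the 4 kb promoter window); 35 expression features
stratified by sex (19 adult multi-tissue including cerebellar/other-brain
metavalues and the tissue-specificity index tau; 16 developmental-brain
aggregates by age group); 4 structure attributes (CDS length, exon count,
transcript length, promoter CpG density); 2 positional distances (TSS to
centromere and to the arm telomere); and 5 paralogue summaries.

Conventions worth spelling out:

* **tau** is computed on log2(TPM+1) per-tissue medians after collapsing the
  two cerebellar regions and the other brain regions into two metavalues;
  tau = sum(1 - x_i)/(N - 1) with x_i normalised by the maximal component.
  tau is undefined (masked) for a gene unexpressed in every tissue.
  Genes with tau < 0.6 are conventionally called broadly expressed.
* **Promoter CpG density** is the observed/expected ratio
  CpG/(C x G) x N over the TSS ± 2 kb window (4,001 bases on the annotated
  gene strand; the strand convention is this package's choice). "CG"
  occurrences are counted by a sliding one-base scan.
* **Conservation** averages per-base scores over the union of intervals;
  bases absent from the track are excluded from numerator and denominator —
  missing track data is not evidence of non-conservation.
* **Canonical transcript**: MANE Select if present, else the longest
  APPRIS-annotated transcript (lexicographic transcript-id tie-break, so the
  choice is order-invariant), else the only transcript.
* **Close paralogues**: a gene is flagged when at least one hit has both
  percent-identity metrics strictly above their 95th percentiles (linear
  interpolation between order statistics, `quantile(type = 7)`). Genes with
  no paralogue hits get identity features of 0, not missing: absence of any
  paralogue is informative, and it keeps complete universes free of
  missingness.
* **XCI consensus** across studies uses vote margins the source literature
  leaves qualitative; our rules: fewer than 2 reporting studies gives
  `not_available`; a modal "variable" call gives `variable`; equal
  escape/non-escape counts give `discordant`; the majority side is high
  confidence when all or all-but-one studies agree, low confidence for a
  strict plurality.

Missing values are recorded in a mask and never imputed during assembly.

### Enrichment statistics and LME thresholds

`decile_enrichment()` cuts the pooled non-missing distribution of a metric
at its 10..90% quantiles (type-7 linear interpolation; right-closed
intervals, so boundary ties fall in the lower decile) and Fisher-tests each
decile for enrichment of confirmed genes, Bonferroni-adjusted. The reported
odds ratio is the unconditional sample OR (ad)/(bc) so that the published
log2 convention — add 1e-4 to zero cells before the log — applies exactly;
the conditional MLE is also exposed. The two-sided exact p sums
hypergeometric probabilities not exceeding the observed table's (the
standard convention, matching `fisher.test`).

`derive_thresholds()` converts enrichment into the LME criteria: for LOEUF
the maximal contiguous run of enriched deciles starting at the *low*
extreme, for misZ and exon conservation at the *high* extreme; the threshold
is the run's outer boundary (e.g. three enriched low deciles give the 30%
quantile). Contiguity from the extreme is this package's rule; enrichment
confined to interior deciles disables the criterion with a warning.
Comparisons are inclusive (LOEUF <= L, misZ >= M, exon score >= E), and a
missing feature makes its criterion false for that gene. The minimum number
of criteria defining "LME-positive" is a reported parameter
(`min_criteria`, default 1; 2 gives the stricter cut used for
higher-confidence candidates). The package does
not aim to reproduce any specific published numeric thresholds, which
depend on database snapshots; it reproduces the derivation.

### The classifier tournament

Features are min-max normalised to [0,1] with minima/maxima and imputation
medians taken from the training genes only; out-of-range values clip, and a
feature constant on the training set becomes 0.5 with a warning.

`nested_cv()` runs stratified outer 10-fold / inner 5-fold nested
cross-validation per registry family, selecting hyperparameters by mean
inner MCC (exact grid when the grid has at most 100 combinations, otherwise
100 random draws) and scoring on held-out outer folds. MCC is used
throughout because its chance level is 0 regardless of class imbalance; a
vanishing denominator is defined as 0. Stratification is our choice (the
minority class must appear in every fold). The default registry carries the
five families that won the original tournament — adaptive boosting (shallow
boosted trees), bootstrap-aggregated trees, a linear max-margin classifier,
a multilayer perceptron, a random forest — plus a label-independent dummy
baseline; the 25-family tournament is a registry extension, since the
tournament structure rather than the specific list is the method.

`build_ensemble()` ranks families by mean MCC (ties: lower standard
deviation, then name), refits the top five on all training data, and applies
5-fold cross-validated Platt scaling (a logistic fit on out-of-fold scores)
to families that emit uncalibrated margins — here the linear SVM, whose
library probability machinery is unseedable and is therefore not used.
Reported per-gene probabilities come from these refit models.

### FDR threshold and final predictions

`estimate_fdr_threshold()` scans the distinct observed scores downward,
defining predictions as score >= t, and returns the smallest t such that the
running fraction of known negatives among known-class predictions stays
strictly below the target d for t and every larger candidate — the largest
prediction set whose running FDR never reaches d. If the top score belongs
to a known negative the scan fails explicitly. The scan is fed
**out-of-fold** training scores (`oof_scores()`): refit-on-all scores of
training genes are optimistically separated and understate the threshold,
which measurably breaks FDR control on held-out genes; out-of-fold
estimation restores it. This resolves a genuine ambiguity in the source
method description, which defines D(t)/B(t) with "score < t" while using the
threshold to call predictions from above.

The final rule (default *conjunction*) calls a gene predicted when all five
calibrated probabilities exceed 0.5 **and** the ensemble mean exceeds t; the
*disjunction* variant accepts either condition. Feature importance is the
mean MCC drop over random column permutations.

## The synthetic universe

`generate_universe()` emits mutually consistent inputs — annotations with a
synopsis line, transcript models, per-transcript constraint metrics,
promoters of exactly 4,001 bases centred on the TSS, a segment-constant
conservation track over promoters and coding exons, adult and developmental
expression with sex/tissue/age strata, paralogue hits, variant/domain
tables, database membership, XCI calls — plus a truth record of every
planted parameter. Distribution families follow the shapes of the real
feature distributions: beta for bounded scores, normal for Z-scores,
log-normal for expression and lengths, Poisson for counts; every one of the
83 features has an overridable entry in `default_feature_effects()`. Class
proportions default to the chrX composition (205/26/598 of 829 genes), the
brain fraction to 0.77, and chromosome lengths are scaled-down constants
(1 Mb, centromere at 45–55%) rather than real assembly lengths.

Two design points matter for interpretation:

* **Hidden disease genes.** A quarter of no-disorder genes (configurable)
  draw their features, variant load and database membership from the
  confirmed-gene distributions while keeping the `no_disorder` label, and
  are LoF-intolerant like confirmed genes, so they concentrate in the NDi
  subgroup — the prediction targets. This mirrors the central premise that
  a large minority of unlabelled genes are unrecognized disorder genes, and
  it is what makes the validation stage (variant burden, database overlap)
  non-degenerate.
* **Promoter composition.** Sequences come from a first-order Markov
  construction that preserves marginal base frequencies exactly while
  scaling the C-to-G transition so the expected CpG observed/expected ratio
  equals the requested enrichment; enrichment 0 produces sequences with no
  CG dinucleotide at all.

What the generator does **not** emulate: real human sequence composition,
linkage or spatial correlation between genes, read-level noise, genotypes,
and any correlation structure among features beyond the shared class label.
Passing tests therefore demonstrate that the machinery recovers planted
structure under realistic marginal distributions — not that the defaults
match any real cohort.

## Numerical choices and reproducibility

* Quantiles everywhere use linear interpolation between order statistics
  (`type = 7`); decile assignment is right-closed.
* The two-sided Fisher p uses the probability-mass convention with a 1e-7
  relative tolerance for floating-point ties, exactly as `fisher.test`.
* Mann-Whitney tests follow `wilcox.test`: exact enumeration for small
  tie-free samples, normal approximation with tie correction otherwise.
* Every stochastic step derives its seed from the configuration master
  seed; reruns with an identical configuration produce byte-identical
  outputs (the manifest differs only in timestamps). Tree learners run
  single-threaded for this reason.
* Degenerate inputs fail loudly and early: invalid proportions name the
  offending field, an all-zero expression sample names the sample, a TSS
  inside the centromere is an annotation error, zero covered conservation
  bases is a scoring error.

Problem sizes used by the shipped test suite (chosen once for statistical
power on a single CPU): planted-parameter recovery at 2,000–5,000 genes;
the FDR/sensitivity contract at 5,000 genes over 20 seeds with a 60/40
fit/evaluation split of known-class genes and 3 scoring folds; the
label-permutation nulls at 800–2,000 genes; the end-to-end determinism and
recovery checks on 250–300-gene universes.

## Known limitations

* Substring phenotype matching has no negation or context handling.
* The FDR scan controls the running false discovery proportion among
  known-class genes; it says nothing about genes whose truth status is
  unknown, and with few training negatives the threshold estimate is
  coarse.
* Small universes (a few hundred genes) can legitimately fail to yield an
  FDR threshold when an out-of-fold negative tops the score list; the
  pipeline then predicts nothing under the conjunction rule and says so.
* Feature independence within a class is a simplification; real constraint
  metrics are strongly inter-correlated, which typically makes the
  prediction problem *easier* for ensembles than our independent-feature
  universe.
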