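---
title: "Methods and design notes for ruptureNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for ruptureNet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ruptureNet)
```

`ruptureNet` analyses bulk expression from ruptured and unruptured
intracranial-aneurysm domes, merged from independent microarray series.
This vignette explains the models behind each stage, the tunable
parameters and their defaults, what the synthetic-data generator does and
does not emulate, the numerical choices, and the known limitations. It
states no empirical result that the test suite does not itself compute.

## Preprocessing and merging

Each series is quantile normalised independently (every sample is mapped
onto the vector of row means of the column-sorted matrix; ties within a
column receive the mean of the reference quantiles they span, the standard
convention implemented by `limma::normalizeQuantiles(ties = TRUE)`). An
optional log2 step (`log2Transform()`, shift `epsilon`, default 0) serves
data arriving on a linear scale; the synthetic generator emits data
already on a log2-like scale, so pipeline runs on it disable the step.
Series are then merged on the genes common to all of them, with genes
ordered lexicographically in the C locale for determinism, and the merged
matrix is scaled once, globally, to mean 0 and standard deviation 1
(population convention, i.e. divide by *N*; `sdType = "sample"` is
available). Scaling globally rather than per gene preserves relative
differences between genes, which the network stage relies on. The order —
per-series normalisation, then merge, then one global scaling — follows
the natural reading of a merged-cohort design in which each array series
is normalised within itself before cross-series harmonisation.

Probe-level background correction and probe-to-gene summarisation are out
of scope: the contract starts at a probe-summarised gene × sample matrix,
which is what public repositories typically provide.

The per-series cohort bookkeeping (`summarizeCohort()`) totals patients,
ruptured counts and aneurysm locations across series and pools
time-to-surgery as the ruptured-patient-weighted mean of per-series means,
with the correspondingly pooled SD. Note that pooling printed per-series
summaries is not identical to recomputing from per-patient values; the
integer totals are exact, the pooled mean/SD are the best reconstruction
the summary rows allow.

## Empirical-Bayes batch correction

Merged series differ by platform and laboratory. The correction assumes
the standard location/scale model: for gene *g* in batch *i*,
`y = α_g + γ_ig + δ_ig ε`. Genes are standardised by their grand mean
(batch-size-weighted) and pooled variance; per-batch location and scale
estimates are then shrunk toward batch-level priors — normal for `γ`,
inverse-gamma for `δ²`, hyperparameters by moment matching — through the
conditional-posterior fixed-point iteration, run to an absolute tolerance
of 1e−4 with a 500-iteration cap. The adjusted value is
`((z − γ*)/δ*)·σ_g + α_g`. With a single batch the transformation is the
identity. Zero-variance genes are an error rather than a silent drop, so
upstream filtering stays explicit.

No covariates are protected during correction. When phenotype labels are
available, a Fisher exact test of phenotype against batch is run and a
significant association raises a warning, because phenotype signal is then
partially absorbable by the correction. In the synthetic cohort the
phenotype split is balanced within every batch, which avoids the issue by
design; real merged cohorts are rarely so tidy.

Two behavioural notes, both verified against an independent
implementation of the same estimator and worth knowing when interpreting
diagnostics. First, shrinkage leaves a fraction of the *chance* per-gene
between-batch mean differences in place: when the planted batch effect is
identical for every gene, the moment-matched prior variance is dominated
by sampling noise, the posterior weight on the per-gene estimate is about
one half, and the residual mean absolute per-gene difference lands at
roughly half the chance level (about 0.11 at 50 samples per batch on
unit-variance data) even though the systematic offset itself is removed to
near zero. Second, because batch means are equalised almost exactly,
post-correction between-batch F statistics fall *below* the null range
(medians well under 1) — a signature of EB correction, not of a defect.

## The unsigned co-expression network

The network stage follows the weighted co-expression construction: the
similarity is the absolute Pearson correlation (unsigned network — a gene
anti-correlated with a module still belongs to it), soft-thresholded by a
power β chosen to approximate scale-free topology. For each candidate β
the connectivities `k_i = Σ_j |cor|^β` are binned into 10 logarithmic
bins (empty bins dropped; at least three populated bins are required for
a fit), `log10(frequency)` is regressed on `log10(mean k)`, and the fit
index is R² signed by the negated slope so that only decreasing degree
distributions count. The chosen power is the smallest reaching the target
(default 0.8), otherwise the argmax with ties broken toward the smaller
power. On dense simulated networks of a few hundred genes, very high
powers can produce spuriously good binned fits (most nodes collapse to
near-zero connectivity); for such small problems a restricted candidate
set (for instance `powers = 1:6`) is the appropriate configuration, and
the replicate suites in the tests use it.

The topological overlap matrix re-expresses pairwise similarity through
shared neighbourhoods:
`TOM_ij = (L_ij + a_ij)/(min(k_i, k_j) + 1 − a_ij)` with
`L_ij = Σ_{u≠i,j} a_iu a_uj`. It is computed by dense matrix algebra and
validated against a brute-force triple loop in the tests. Modules come
from average-linkage clustering of `1 − TOM` with a *static* cut at a
fraction (default 0.9) of the maximum merge height and a minimum module
size (default 2, matching reports of real modules as small as two genes).
The adaptive dynamic tree-cut algorithm used by the field's reference
implementation is deliberately not reimplemented; the static cut is a
documented simplification, and its main practical consequence is that
strongly phenotype-shifted modules of opposite direction — which
inter-correlate through the shared phenotype indicator (|r| ≈ 0.5 for a
2-SD shift and a balanced split) — can merge into one cluster.

Each module is summarised by its eigengene: the first right singular
vector, over samples, of the gene-standardised module submatrix, unit
norm, sign-oriented so the mean correlation with the module's own genes
is non-negative. kME (gene–eigengene correlation) is computed for *all*
genes against all modules, because downstream signature construction
ranks by it. Rupture association is a two-sided Mann-Whitney test per
eigengene — exact when both groups have ≤ 8 samples and no ties, normal
approximation with tie and continuity correction otherwise. Raw p-values
at α = 0.05 drive significance calls (replicating uncorrected testing
across modules); Benjamini-Hochberg q-values are reported alongside for
transparency.

## Over-representation

Gene lists are tested against GMT gene sets with the plain hypergeometric
upper tail `P(X ≥ overlap)`; the universe is the set of genes on the
merged matrix (the measured background, not the genome); sets with fewer
than two universe members are skipped and excluded from the Bonferroni
multiplier. This is deliberately *not* the EASE-modified statistic used
by some annotation web services, whose internal background and version
are not reproducible offline.

In the pipeline, the phenotype query lists are built gene-wise: for every
significant module, a member gene follows the module's rupture direction
when its kME is positive and the opposite direction when it is
anti-correlated with the eigengene (gene-level direction = module
direction × sign(kME)). Under the static cut, a merged module can contain
anti-correlated gene groups; module-level direction would silently place
an up-shifted group in the unruptured query, and the sign rule prevents
exactly that.

## Cell-population deconvolution

Bulk aneurysm tissue mixes smooth muscle, endothelium and infiltrating
immune cells. The deconvolution regresses each gene on a reference signal
per cell population: each marker row is divided by its own mean and the
normalised rows are averaged, giving a per-sample relative-abundance
proxy with mean 1. The shipped default panel covers smooth muscle (MCAM,
DES), endothelium (TJP1, SLC2A1, VCAM1, SELE, VWF), macrophages (CD14,
FCGR1A, CD68, TFRC, CCR5), mast cells (KIT, ENPP3) and T cells (CD3D,
CD3E, CD3G, CD4, CD8A, CD8B, IL2RA, IL7R, CCR6).

A gene is attributed to a population when, in ordinary least squares
against that reference: the slope is positive, its two-sided p-value is
below 0.05, the adjusted R² (`1 − (1−R²)(n−1)/(n−2)`) exceeds 0.6, and
the ratio |intercept| / |mean expression| is below 0.5 — i.e. the gene's
expression is mostly proportional to the population's abundance with
little abundance-independent baseline. A zero mean makes the ratio
infinite and fails the criterion by convention. One model is fitted per
(cell type × phenotype) on that phenotype's samples only — ten models for
the default panel — and a cell type's own markers are excluded as
candidates. "Mean expression" in the ratio is the mean over the model's
own (per-phenotype) samples.

This stage consumes the quantile-normalised merged matrix *before* global
z-scaling: an intercept/mean ratio is meaningless on data centred at
zero. The pipeline keeps that checkpoint on disk (`merged_qn.tsv`)
precisely so the deconvolution has a positive-scale input. Note the
checkpoint is also prior to batch correction; per-gene batch offsets
therefore act as extra noise in these regressions, which the acceptance
filter's R² clause absorbs at the simulated batch-effect magnitudes.

## Ontology semantic similarity and the specificity screen

Similarity between ontology terms uses the Wang graph-based measure: a
term's semantics are the contributions of its ancestors, `S(term) = 1`
and `S(parent) = max over edges of w · S(child)` with `is_a` weight 0.8
and `part_of` weight 0.6 (max over paths for multiple parentage);
`sim(a,b)` sums the shared ancestors' contributions relative to the two
semantic totals. Wang is the corpus-free choice — information-content
measures would require an external annotation corpus, which an offline
pipeline cannot assume. Term sets are compared by best-match average:
half the mean of row maxima plus half the mean of column maxima.

The specificity screen asks which processes of the ruptured phenotype
have *low association with every process* of the unruptured phenotype: a
term is specific when its maximum similarity over all opposite-set terms
is strictly below the cutoff (default 0.2). Pairs above 0.8 are reported
as high-similarity matches. The "for all opposite terms" reading (rather
than "for any") is the one consistent with calling a mechanism specific;
a term similar to even one opposite-phenotype process is not.

The OBO parser handles `[Term]` stanzas with `id`, `name`, `is_a` and
`relationship: part_of`, skips obsolete terms, and rejects cyclic graphs
listing the terms on the cycle.

## Drug-signature reversal ranking

The disease signature takes, from every module significantly positively
associated with rupture, its top 10 genes by kME into the up list, and
likewise negative modules into the down list (modules smaller than 10
contribute all members; duplicates keep first occurrence; genes landing
in both lists are removed from both). Both directions feed one query by
default. The reversal score of a drug signature is the signed overlap
score on a −100..+100 scale described in the README: +100 exactly when
the drug inverts the disease signature over all its genes, −100 when it
mimics it, 0 when it shares no genes. This transparent overlap score is a
stand-in for proprietary connectivity-scoring services: it preserves the
scale and the endpoint semantics (perfect reversal / perfect mimic) while
remaining exactly reproducible offline. It is the largest methodological
substitution in the package and scores are comparable only within one
library and query.

## The synthetic-data generator

`simulationConfig()` defines the study conditions the tests run under;
`simulateExpression()`, `simulateOntology()`, `simulateDrugLibrary()` and
`simulateAll()` generate them from a single mandatory seed, with the
order of draws fixed so outputs are reproducible byte for byte.

The default expression design emulates two microarray series of 16
samples each, phenotype balanced within series: 2,000 genes on a
log2-like scale (baselines N(7, 1)); 10 latent-factor modules of 20–80
genes with loadings U(0.7, 1.0) and gene noise SD 0.5; two modules
shifted +2 and two −2 factor-SD units in ruptured samples; five cell
populations with log-normal abundances (CV 0.4, mean 1), macrophage and
T-cell abundance raised 1.5× in ruptured samples, markers and 20
cell-specific genes per population proportional to abundance
(coefficients U(4, 8); marker noise SD 0.05, cell-gene noise SD 0.3); and
per-gene batch effects on the second series (offsets N(0, 0.5), scales
U(0.8, 1.25)). Each emitted series file also carries five series-private
genes so the common-gene merge is genuinely exercised. The planted truth
records the module map (including the cell-population gene groups, which
are real planted co-expression structure), rupture modules with
directions, batch effects, abundances, the cell-specific gene map, and
the true disease signature — the full gene unions of the shifted modules,
since every member moves with the phenotype.

The toy ontology is a rooted `is_a` tree (depth 3, branching 3) plus a
disjoint branch holding three planted rupture-specific terms; annotation
sets draw from the planted module genes so that specific terms enrich
only in the rupture-direction query, shared terms in both, and filler
terms in neither. The drug library holds 50 random signatures plus, by
default, one compound exactly inverting the true disease signature.

What the generator does *not* emulate: probe-level effects, count-based
noise, correlated module factors beyond the phenotype-induced
correlation, partial marker specificity, or phenotype imbalance across
batches. Passing the recovery suites therefore demonstrates correctness
of the machinery under a clean factor model, not performance on real
arrays.

One consequence of the stated conditions is worth flagging: with four
modules sharing a ±2-SD phenotype shift on a balanced cohort, those
modules inter-correlate at |r| ≈ 0.5 in an unsigned network, and under
the static tree cut they can merge (seed-dependent). Recovery of
*rupture association* is unaffected — the merged cluster is strongly
significant, and the sign-of-kME query rule keeps gene-level directions
straight — but partition-level agreement with the planted module map
hovers at the 0.9 adjusted-Rand boundary at the default scale.

## Numerical choices and problem sizes

Determinism: gene order after merging is radix-sorted; module labels are
assigned by decreasing size with ties broken by first gene position;
drug ranks break score ties lexicographically; enrichment rows sort by
raw p then set id. Degenerate inputs error early and name the offending
gene, sample or cell. Exact Mann-Whitney p-values, the hypergeometric
tail, Wang S-values and the TOM are each validated against brute-force
enumeration oracles in the test suite at small sizes (universes ≤ 12,
group sizes ≤ 6, DAGs ≤ 12 terms, 10-gene matrices).

The test suite runs its heavy recovery checks on the generator defaults
(2,000 genes, one full pipeline pass) and its replicate suites (200
replicates for flagging power and for type-I control) on a 200-gene
scale-down with the default 16-samples-per-phenotype cohort, which keeps
the whole suite at around a minute on one core while preserving the
sample sizes that the power statements presuppose.

## Known limitations

* The static tree cut is cruder than dynamic tree cutting; on real data
  expect more merged or unclassified genes than the reference
  implementation would give.
* The reversal score is an overlap statistic, not the proprietary
  characteristic-direction score of online connectivity services; ranks
  are comparable within a run only.
* The deconvolution assumes linear mixing and marker fidelity; marker
  genes regulated by disease state independently of abundance violate it.
* No missing-value support anywhere in the pipeline; impute upstream.
* Block-wise computation for very large gene sets (> 30k) is not
  implemented; the dense TOM is quadratic in memory.
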