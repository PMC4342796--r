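---
title: "Cross-context enhancer prediction: models, parameters, and design choices"
author: "crossmark maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-context enhancer prediction: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Enhancer-associated histone modifications — H3K4me1 and H3K27ac — have been
mapped genome-wide in many cell types, developmental stages and species,
but the contexts biologists care about are far more numerous than the
contexts with data. A natural question is therefore how far such maps
*extrapolate*: if marks were assayed in related stages of a developmental
lineage, in other tissues, or in another species, how well do they identify
the enhancers active in an unassayed target context?

`crossmark` implements a complete evaluation pipeline for this question.
Regions known to be active enhancers in the target context are the
positives; each candidate region is described by a binary vector recording
whether it overlaps the ChIP-seq peak calls of each (context, mark)
dataset; supervised classifiers are trained on these vectors and evaluated
by cross-validation. The contribution of each dataset is then quantified
two ways: by normalized Gini feature importance inside a random forest,
and by univariate Fisher-exact enrichment of each peak set in positives
versus matched background.

## The data model

All intervals are `GRanges`; chromosome sizes are a `Seqinfo`. BED files
(0-based half-open) are converted to the 1-based closed Bioconductor
convention exactly once, in `readBed()` / `writeBed()`; no other coordinate
conversion exists in the package, and round-trips are exact. Strand is
ignored throughout, since histone-mark peaks and enhancer assays are
strand-agnostic. Overlap means sharing at least `minbp` bases
(default 1 bp, the bedtools-intersect convention), so BED-adjacent
intervals never overlap. Duplicate peak records are retained; deduplication
is the caller's decision and overlap indicators are unaffected by it.

The labeled classifier input is an `EnhancerFeatureSet`, a
`RangedSummarizedExperiment` whose rows are regions (positives first),
whose columns are peak datasets, whose single `overlap` assay is the 0/1
matrix, and whose `colData` carries each dataset's context: tissue,
numeric developmental-stage coordinate, species, and mark. Scenario
definitions are just column predicates (`selectFeatures()`), so "lineage
contexts only" or "non-target tissues only" are one-liners.

## Negatives

Two negative sets with deliberately different properties are supported:

* **Genomic background** — for each positive, 10 random regions on the
  same chromosome with exactly the same length (`sampleMatchedNegatives()`,
  the `randomBed` semantics), placed uniformly by rejection sampling and
  excluded from overlapping any known enhancer of any tissue. Per-positive
  exact length matching is a strict reading of "matched to the chromosome
  and length distribution"; it is stronger than distribution-level matching
  and assertable as a multiset identity. Negatives may overlap one another:
  forbidding self-overlap would bias the placement of long regions. No GC,
  repeat or conservation matching is attempted.
* **Other enhancers** — regions validated as enhancers in non-target
  tissues, used directly with label 0 and no sampling. Distinguishing
  these from target enhancers probes tissue *specificity* rather than
  generic regulatory character.

One background draw is made per scenario and shared across folds and
algorithms, keeping comparisons paired.

## Classifiers and evaluation

Six fixed-configuration algorithms are compared: random forest (10 trees,
maximum depth 5, Gini criterion, mean per-tree class-1 probability as the
score), linear SVM (cost 0.1, signed decision value), AdaBoost (50
depth-limited trees, learning rate 1; base depth defaults to 1-level
stumps, with an explicit override because deeper base learners are a
defensible alternative reading), Gaussian naive Bayes (Gaussian
class-conditionals even on binary features — the deliberate, if
statistically eccentric, convention of this evaluation suite — with
additive variance smoothing of 1e-9 times the largest feature variance),
depth-5 decision tree, and 3-nearest-neighbours (Euclidean distance on the
binary vectors; equidistant neighbours resolved in training-row order so
scores are deterministic). Constructing any spec with non-default
hyperparameters requires `override = TRUE`; the fixed suite is part of the
method's definition.

Evaluation is stratified five-fold cross-validation. Stratification is a
design choice: with 1:10 class imbalance, unstratified folds can lose
every positive from a fold. Folds are dealt round-robin within each class,
rotating the starting fold between classes so total fold sizes balance;
per-fold class counts are within one of exact stratification. The summary
statistic is the arithmetic mean of per-fold AUCs — not the AUC of pooled
scores — and the displayed curve is the vertical average of fold ROC
curves on a fixed 101-point FPR grid; the AUC is never recomputed from the
averaged curve. AUC itself is the midrank Mann–Whitney statistic, which
equals the trapezoidal area under the stepped curve; ties are handled by
midranks, so constant scores give exactly 0.5.

Feature importance is normalized Gini impurity decrease from a single
full-data fit (one importance table per task; a per-fold-averaged variant
would also be defensible, but a single fit matches how one table is
reported per task and keeps the table independent of the fold seed). For
forests, importance splits arbitrarily among duplicated or highly
correlated features; tests assert only the sum-preservation this implies.

Enrichment uses the sample odds ratio `(a*d)/(b*c)` — reported as infinite
when `b*c = 0` and `a*d > 0`, and as 1 when both cross-products vanish —
with the two-sided Fisher exact p-value computed by the small-p-values
rule (the convention of mainstream implementations), evaluated in log
space with the customary `1 + 1e-7` relative slack when comparing point
probabilities. Benjamini–Hochberg adjustment is available but off by
default; raw p-values are the primary report. Mid-p variants and OR
confidence intervals are out of scope.

## The synthetic study generator

Because the original inputs of this kind of analysis are large external
downloads, the package ships a generator (`simulateStudy()`) that emulates
their statistical structure so that the entire pipeline is testable
end-to-end, deterministically, in seconds. The generator's defaults define
the reference study:

| parameter | default | meaning |
|---|---|---|
| genome | 4 chromosomes × 10 Mb | placement space |
| target enhancers | 300 | positives of the target context (stage 5) |
| other enhancers | 300 (3 tissues × 100) | tissue panel, lengths 500–3500 bp |
| stages | 0, 2, 4, 6, 8, 10 | lineage contexts, both marks each |
| `p_max` | 0.9 | marking probability at zero developmental distance |
| `lam` | 0.35 | decay rate of marking probability per stage unit |
| `p_bg` | 5 / Mb | spurious peaks per context |
| `shared_frac` | 0.2 | ubiquitously marked fraction of other enhancers |
| `unmappable_frac` | 0.23 | cross-species drop rate |
| `map_jitter_sd` | 300 bp | cross-species coordinate perturbation |
| peak widths | 500–2000 bp | uniform |

A lineage context at stage *s* covers each target enhancer with
probability `p(d) = p_max * exp(-lam * d)`, `d = |s − 5|` — the simplest
monotone model consistent with the qualitative observation that data from
developmentally closer contexts are more informative; no particular
functional form is claimed by the analyses this emulates, and none is
assumed downstream. Draws are independent across (context, mark,
enhancer); real marks are correlated between H3K4me1 and H3K27ac, but
independence makes the closed form recoverable by counting, which the test
suite exploits (observed marking frequencies within three binomial
standard errors of `p(d)`). Non-target tissue contexts mark their own
tissue's enhancers at `p_max` and target enhancers at
`p_max * shared_frac`; a `shared_frac` fraction of other enhancers is
marked in *every* context, emulating ubiquitously active elements that
confound tissue specificity. Spurious peaks arrive as a Poisson process
and may hit enhancers by chance; rejecting them would distort the null, so
they are kept. The cross-species scenario does not move peaks to a second
genome: it degrades the *positives* (`degradeCrossSpecies()`), dropping
23% as unmappable and jittering survivors by Normal(0, 300 bp) rounded to
integers — 300 bp is of the order of a fraction of a peak width, enough to
break marginal overlaps without destroying most of them; no published
value constrains this knob. Enhancer placement is uniform without overlap;
a configuration whose enhancers cannot fit raises a configuration error
rather than degrading silently.

Everything is deterministic given the configuration seed: two simulations
with the same config export byte-identical BED/TSV/JSON trees.

## What the generator does and does not show

Passing the structure-recovery checks demonstrates that the pipeline's
machinery — featurization, sampling, cross-validation, importance,
enrichment — correctly extracts a developmental-proximity signal that is
present by construction. It does not certify performance numbers on real
data: real peak sets have correlated marks, context-dependent peak-calling
depth, sequence- and chromatin-composition biases in both enhancers and
background, and broad cross-tissue sharing of marks at regulatory regions.
One visible consequence of the last point: in the reference study,
*non-target-tissue* features separate target enhancers from other-tissue
enhancers more easily than from genomic background, because each
other-tissue enhancer is strongly marked by its own tissue's contexts and
that anti-signal is nearly perfect here; in real data marks are shared
across tissues far more diffusely and the specificity task is the harder
one for every feature set. The lineage-feature ordering (background easier
than other-enhancers) does hold in the reference study and is asserted in
the acceptance suite. Also note that stages flanking the target on both
sides are simulated from one homogeneous model, whereas real lineages mix
data sources (e.g. purified cell types early, whole organs late), which
can make importances across the boundary incomparable.

## Orchestration, seeds, and problem sizes

`runStudyReport()` executes the full grid: three scenarios × two negative
modes with a random forest, the six-algorithm sweep on lineage features,
per-dataset enrichment of lineage marks, and leave-one-context-out mark
imputation (each lineage dataset's peaks as positives, matched background
negatives, all other datasets as features). Every random draw — study
generation, negative sampling, fold shuffling, forest resampling — derives
from one master seed via a stable string hash of the scenario name, so
re-ordering scenarios cannot change results, and two runs with one master
seed serialize to byte-identical JSON (`writeReportJson()`).

The reference study sizes were chosen so the complete grid runs in well
under a minute on one CPU while leaving every effect far from its standard
error: 3,300 rows in background scenarios (300 positives + 10×), 600 in
other-enhancer scenarios, 18 feature columns, and 12 mark-imputation runs
of roughly 400–4,500 rows each. Unit tests use a reduced study
(2 chromosomes × 4 Mb, 120 + 120 enhancers) where full size adds nothing.

## Known limitations

* Binary presence/absence features only; coverage-fraction or
  signal-strength features are deliberately deferred.
* No read-level simulation or peak-caller emulation; peaks are intervals.
* Mark–mark correlation within a context is not modeled (a shared latent
  activity bit would add it without breaking the closed-form checks).
* The Gaussian naive Bayes variant is kept for fidelity to the evaluation
  suite it reproduces; Bernoulli NB would be the natural model for binary
  features.
* Tree split tie-breaking depends on column order, so Gini importances are
  permutation-equivariant only up to ties among equally good split points.
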