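# crossmark

Quantifying how well enhancer-associated histone marks measured in one
cellular context predict the enhancers of another.

## The problem

H3K4me1 and H3K27ac ChIP-seq maps exist for only a small fraction of the
cell types, developmental stages and species biologists study. When no map
exists for a target context, the common workaround is to borrow maps from
related contexts — a nearby stage of the same lineage, another tissue, or
the homologous tissue in another species. `crossmark` turns that workaround
into a measurable procedure: it evaluates, by supervised classification,
how much enhancer information each surrogate context actually carries about
a target context, and attributes the predictive signal to individual
datasets.

This is a tool for regulatory-genomics analysts: anyone deciding whether
existing epigenomic data justify extrapolation to an unassayed context, or
which context would be most informative to assay next.

## The method

Given target-context enhancers (positives), a negative set, and a panel of
peak-call datasets indexed by context (tissue, developmental-stage
coordinate, species) and mark:

1. **Featurize.** Each region *r* gets a binary vector,
   `x_rc = 1[ r overlaps peaks of dataset c by ≥ 1 bp ]`.
2. **Negatives.** Either 10 random regions per positive, matched exactly
   in chromosome and length and excluded from all known enhancers
   ("genomic background"), or validated enhancers of other tissues
   ("other enhancers").
3. **Classify.** Six fixed-configuration algorithms (random forest of 10
   depth-5 Gini trees with per-tree probability averaging; linear SVM with
   cost 0.1; AdaBoost with 50 stumps; Gaussian naive Bayes; depth-5
   decision tree; 3-NN) under stratified five-fold cross-validation.
   Reported AUC is the arithmetic mean of fold AUCs (midrank Mann–Whitney);
   displayed curves are vertically averaged on a 101-point FPR grid.
4. **Attribute.** Normalized Gini importance per dataset from a full-data
   forest fit, and per-dataset enrichment: sample odds ratio
   `(a·d)/(b·c)` with a two-sided Fisher exact p-value.

A synthetic study generator emulates the regime such evaluations face —
marking probability decaying with developmental distance as
`p(d) = p_max·e^(−λd)`, ubiquitously active confounder elements, Poisson
background peaks, and cross-species mapping loss (23% unmappable, jittered
survivors) — so the full pipeline runs end-to-end, deterministically, with
no downloads.

## Worked example

```r
library(crossmark)

study <- simulateStudy(simulationConfig())
study
#> SyntheticStudy: 4 chromosomes, 300 target + 300 other enhancers, 18 peak sets
#> lineage stages: 0, 2, 4, 6, 8, 10 (target 5); tissues: limb, brain, liver

rep <- runScenario(study, featuresTissue("heart"), "genomic_background",
                   masterSeed = 42, name = "stage_vs_background")
rep
#> CVReport: 5 folds, mean AUC = 0.996 (folds: 0.999, 0.993, 0.998, 0.997, 0.994)
#> top importances: heart_s6_H3K27ac=0.267, heart_s4_H3K4me1=0.186,
#>   heart_s4_H3K27ac=0.184, heart_s6_H3K4me1=0.141, heart_s8_H3K4me1=0.091
```

The lineage contexts identify the target context's enhancers essentially
perfectly against matched background (mean cross-validated AUC 0.996), and
the importance mass concentrates on stages 4 and 6 — the two contexts
flanking the target stage 5 — then falls off with developmental distance.
Univariate enrichment tells the same story:

```r
enr <- enrichAll(targetEnhancers(study),
                 sampleMatchedNegatives(targetEnhancers(study),
                                        studyGenome(study),
                                        exclusions = c(targetEnhancers(study),
                                                       GenomicRanges::granges(otherEnhancers(study))),
                                        seed = 42),
                 peakSets(study),
                 subset(studyManifest(study), tissue == "heart"))
head(enr[order(-enr$odds_ratio), c("dataset_id", "a", "c", "odds_ratio", "p")], 3)
#>          dataset_id   a  c odds_ratio             p
#> 10 heart_s6_H3K27ac 205 59  107.56557 7.374926e-194
#> 3  heart_s4_H3K4me1 195 58   94.20197 8.712862e-181
#> 9  heart_s4_H3K27ac 196 64   86.45673 1.706995e-178
```

Here `a` of 300 positives and `c` of 3,000 matched negatives overlap each
peak set; flanking-stage marks are two orders of magnitude enriched in
target enhancers. `runStudyReport()` runs the complete grid — three
scenarios × two negative modes, the six-algorithm sweep, enrichment, and
leave-one-context-out mark imputation — from one master seed, and
`writeReportJson()` serializes it reproducibly.

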