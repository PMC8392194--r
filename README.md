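# chromoscan

Chromoanagenesis — the catastrophic shattering-and-reassembly of one or a
few chromosomes (chromothripsis and related complex events) — leaves a
recognisable footprint in tumor copy-number data: dense oscillations of
gain/loss states concentrated on the affected chromosomal arms. Calling it
normally requires whole-genome sequencing, which most large tumor cohorts
lack. `chromoscan` detects chromoanagenesis from data those cohorts *do*
have — gene-level thresholded somatic CNA tables (GISTIC
`all_thresholded.by_genes`) and MAF mutation tables — and then
characterises its cancer-type-specific consequences.

It is aimed at cancer genomicists who want to (a) classify samples by
chromoanagenesis status from genic CNA alone and (b) scan for the copy-number
regions, focal genes, driver mutations and mutually exclusive gene pairs
that separate chromoanagenesis from non-chromoanagenesis tumors.

## The method

An **oscillation** is a maximal run of adjacent genes on one chromosomal arm
sharing the same non-neutral collapsed CNA state (−1/0/+1). With
$c_a$ the oscillation count of arm $a$ over all $A$ arms, each sample is
reduced to two features

$$f_1 = \max_a c_a - 3\,\bar c, \qquad
  f_2 = \sqrt{\tfrac1A \sum_a (c_a - \bar c)^2},$$

which are high exactly when oscillations concentrate on one or two arms —
the chromoanagenesis signature — and low when they spread over many arms,
however large the total. A small deterministic CART decision tree on
$(f_1, f_2)$, trained on a stratified 70/15/15 split, calls the status.

Downstream, per-gene two-sided Fisher exact tests (probability-mass
ordering) compare CNA frequency between groups within each cancer type at a
genome-wide threshold of $5\times10^{-7}$ ($= 0.01/20{,}000$, Bonferroni),
significant genes merge into arm-bounded regions, single-gene focal calls
require a ≥2.5 order-of-magnitude p-value gap to both flanking genes, and
MAF-derived burden scans (LOF / missense / nonsynonymous / synonymous,
counted per individual) feed a one-sided hypergeometric mutual-exclusivity
screen with Benjamini–Hochberg q-values. A seeded synthetic-cohort
generator reproduces the study conditions (46.4% prevalence,
arm-concentrated oscillation bursts, drivers at published impairment rates)
so the whole pipeline is testable without protected data. See the methods
vignette (`vignettes/chromoanagenesis-detection.Rmd`) for the full model.

## Worked example

```r
library(chromoscan)

cfg  <- sim_config(n_samples = 800, seed = 11)   # 46.4% chromoanagenesis
sim  <- simulate_cohort(cfg)
feats <- sample_features(sim$cna)
head(feats[, 1:3], 3)
#>      sample_id       f1       f2
#> 1 TCGA-SY-0001 17.28261 4.630639
#> 2 TCGA-SY-0002 21.97826 5.449589
#> 3 TCGA-SY-0003  0.50000 1.118034

lab <- sim$meta$chromoanagenesis
sp  <- stratified_split(feats$sample_id, lab, seed = 12)
tr  <- match(sp$train, feats$sample_id)
te  <- match(sp$test,  feats$sample_id)
tree <- train_tree(feats[tr, c("f1", "f2")], lab[tr])
tree
#> cna_tree: 3 nodes (2 leaves) on features f1, f2

ev <- evaluate_predictions(predict(tree, feats[te, ]), lab[te])
unlist(ev[c("accuracy", "sensitivity", "specificity", "ppv")])
#>    accuracy sensitivity specificity         ppv
#>           1           1           1           1
```

Samples 1–2 carry an oscillation burst on one arm, so their maximal arm
count dwarfs the cross-arm mean ($f_1 \approx 17$–22); sample 3 is a
background genome ($f_1 = 0.5$). On this cleanly separable synthetic cohort
a single split at $f_1 \le 9.86$ classifies the 120 held-out samples
perfectly; on the real labeled cohort this design was calibrated against,
held-out accuracy is in the mid-80s percent.

The same steps run from the shell via the bundled CLI
(`system.file("cli", "chromoscan", package = "chromoscan")`), with
subcommands `simulate`, `features`, `train`, `predict`, `diff-cna`,
`focal`, `diff-snv`, `mutex`, `report`, `pipeline`.

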