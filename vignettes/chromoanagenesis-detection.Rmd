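---
title: "Detecting chromoanagenesis from gene-level copy-number oscillations"
author: "chromoscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting chromoanagenesis from gene-level copy-number oscillations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Chromoanagenesis is an umbrella term for catastrophic one-off chromosomal
events — chromothripsis, chromoplexy, chromoanasynthesis — in which one or a
few chromosomes shatter and reassemble. Its established signature in copy
number data is a dense oscillation of gain/loss states confined to the
affected chromosome(s). Calling it normally requires whole-genome sequencing,
but most large tumor collections only carry gene-level thresholded somatic
copy-number alteration (CNA) calls (GISTIC `all_thresholded.by_genes` tables:
one integer state in $\{-2,-1,0,+1,+2\}$ per gene per sample) plus somatic
mutation tables (MAF). `chromoscan` detects chromoanagenesis from exactly
those inputs and then characterises its cancer-type-specific consequences.

Genic CNA is blind to copy-neutral rearrangements, inversions and
translocations, so a sample whose catastrophic event was largely
copy-neutral is undetectable here; this is a property of the input, not of
the implementation.

## Oscillations and the two selected features

All copy-number logic runs on the sign-collapsed states
$s \in \{-1, 0, +1\}$ — whether a gene's somatic copy number is below, equal
to, or above its reference — because that ternary distinction is the level
at which the detection signature is defined. An **oscillation** is a maximal
run of adjacent genes on one chromosomal arm sharing the same non-neutral
state. Three conventions pin the definition down:

* a neutral ($0$) gene terminates a run and is not itself a run;
* a $+1 \to -1$ boundary separates two runs;
* arms never merge across the centromere.

Let $c_a$ be the oscillation count of arm $a$, over *all* arms annotated in
the gene map (zero counts included). Each sample is summarised by two
features:

$$f_1 = \max_a c_a \;-\; 3\,\overline{c}, \qquad
  f_2 = \sqrt{\tfrac{1}{A}\sum_a (c_a - \overline{c})^2},$$

where $A$ is the number of arms. $f_2$ is the *population* standard
deviation: the arms are the complete population of interest, not a sample
from one, and fixing the divisor makes trained tree thresholds reproducible.
Both features encode the same contrast: a genome with one or two wildly
oscillating arms (the chromoanagenesis signature) scores high, a genome with
many moderately oscillating arms scores low even when its total oscillation
count is higher. This is why raw totals are not usable as features — heavily
rearranged non-chromoanagenesis genomes can carry more oscillations in total
than true chromoanagenesis samples.

A wider candidate set (amplified/deleted gene totals, maximal and mean run
length, runs in highly varied chromosomes) is computed by
`extended_features()` for completeness. The "highly varied chromosomes"
candidate was never precisely defined by its originators; this package
reconstructs it as the total run count over chromosomes whose run count
exceeds the cross-chromosome mean by more than one population SD, and the
classifier does not use it.

## The classifier

`train_tree()` is a deterministic binary CART on $(f_1, f_2)$:

* candidate thresholds are midpoints between consecutive distinct sorted
  feature values;
* the split maximising the Gini impurity decrease wins; ties go to the lower
  feature index, then the lower threshold;
* routing is `value <= threshold` to the left child, including exact
  boundary hits;
* a node becomes a leaf when pure, at `max_depth`, or when no candidate
  split leaves `min_leaf` samples on both sides;
* zero-gain splits are **taken**, not refused. This matches the reference
  CART implementations this tree mirrors and is required to solve
  XOR-arranged data at depth 2, where every root split has zero immediate
  gain. The corresponding invariant is therefore *non-increase* of weighted
  child impurity, not strict decrease.

Greedy CART is not globally optimal: on small random datasets with
unconstrained leaves it can (and measurably does) miss the accuracy-best
depth-2 tree. The acceptance property therefore checks the trainer against
an exhaustive search **over its own model class** — all depth-$\le 2$
axis-aligned trees whose leaves respect the default `min_leaf = 5` — where
the equivalence holds; the unit suite brackets the unconstrained behavior
between the exhaustive optimum (upper bound) and an independent greedy CART,
`rpart` (floor).

Hyperparameters default to `max_depth = 3`, `min_leaf = 5`: two features and
a few hundred training samples justify a shallow tree, and both knobs are
exposed. Evaluation uses a stratified 70/15/15 train/development/test split
(largest-remainder allocation, per-stratum label balance within one sample,
deterministic given a seed). Reported metrics are accuracy
$(TP+TN)/(TP+TN+FP+FN)$, sensitivity, specificity, and positive predictive
value; all four are always emitted. Models serialise to JSON with thresholds
written as 17-significant-digit strings because decimal JSON numbers do not
round-trip IEEE doubles bit-exactly.

## Per-gene association scans

Within one cancer type, and only when both the chromoanagenesis and the
non-chromoanagenesis group have at least 50 samples, every gene is tested
with a two-sided Fisher exact test on (altered, unaltered) × (group). A
sample is "altered" under mode `any` when $s \ne 0$, under `deletion` when
$s < 0$, under `amplification` when $s > 0$. The genome-wide significance
threshold is $5\times10^{-7}$ — a Bonferroni correction of a conservative
$0.01$ level over 20,000 genes — applied strictly ($p < \alpha$).

The two-sided p-value uses probability-mass ordering: with margins fixed,
sum the hypergeometric probabilities of all tables whose probability does
not exceed the observed one, with a relative tie tolerance of $10^{-7}$.
The tolerance is not cosmetic: analytically tied tables land on different
floating-point values, and a strict comparison would drop them
unpredictably. A zero margin yields $p = 1$. The implementation is checked
to $10^{-12}$ against a full-enumeration oracle on every 2×2 table with
total $\le 40$.

**Regions.** Significant genes merge into regions as maximal runs of
adjacent significant genes per arm, with gap tolerance 0 — a single
non-significant gene splits a region, and single-gene runs count. The
parameter-free rule was chosen because region counts on real data depend on
annotation density anyway; the merging is exposed as its own function so a
tolerant variant can be layered on. A region significant under `any` but
sharing no gene with a deletion or amplification region is reported as
`additional` — altered but not directionally enriched.

**Focal calls.** A gene is a single-gene focal alteration when it passes the
genome-wide threshold *and* its p-value is at least `gap_orders` orders of
magnitude smaller than both immediate flanking genes on the same arm
(arm-terminal genes compare against their single neighbor; both neighbors
must satisfy the gap — the conservative reading). The default gap is 2.5
orders; 4.0 is used for extreme cohorts such as UCEC. Comparison is against
the nearest *annotated* neighbors, not the nearest significant ones.

## Mutation-class scans and mutual exclusivity

From a MAF, variants map to classes: LOF (nonsense, frameshift, splice-site,
translation-start, nonstop), missense, synonymous, and other (excluded).
Burden is counted per individual — one count per (gene, class) however many
qualifying variants a patient carries — with nonsynonymous the union of LOF
and missense. Per gene and class, a two-sided Fisher test compares groups;
results below $5\times10^{-3}$ are reported with a direction flag.
Synonymous counts ride along as a visible mutation-rate background.

Mutual exclusivity between a chromoanagenesis-enriched and a
non-chromoanagenesis-enriched gene is tested one-sided: $p = P(X \le
\text{observed co-impairments})$ under the hypergeometric null with fixed
margins ("impaired" = carrying at least one LOF or missense mutation).
Benjamini–Hochberg q-values are computed across all tested pairs and the
screen reports $q < 0.005$. The external service that popularised this
screen is re-implemented here as this explicit test because its exact
variant is not recoverable; the verbal definition — fewer co-mutated
patients than chance expects — is what is implemented.

## The synthetic cohort generator

`simulate_cohort()` and `simulate_mutations()` generate labeled cohorts so
every stage is testable without protected patient data. Defaults encode the
study conditions the pipeline is calibrated against:

* prevalence 0.464 (the labeled-cohort chromoanagenesis rate), subtype
  labels drawn in the 64 : 143 : 164 ratio of chromothripsis-only, mixed,
  and other-complex events;
* chromoanagenesis samples receive an oscillation burst on 1–2 arms:
  alternating amplification/deletion runs (lengths 1–3) separated by single
  neutral genes, with burst size $\sim$ Poisson(30) runs, truncated to arm
  capacity. The single-neutral-separator layout makes the nominal burst
  count exactly recoverable by `segment_arm()`, so the generator is
  verifiable by the feature code it feeds;
* every sample gets background runs at Poisson(1.5) per arm; 15% of
  negatives are "dispersed-high" (Poisson(4) per arm across many arms),
  emulating heavily rearranged genomes with upwards of a hundred oscillations but no
  chromoanagenesis, which keeps the classification problem from collapsing
  onto raw totals;
* two injected drivers at published impairment rates: a
  chromoanagenesis-linked gene (0.794 vs 0.17) and a
  non-chromoanagenesis-linked gene (0.1825 vs 0.725), optionally hard-coupled
  so they never co-occur; passengers at a flat 3% rate; synonymous
  mutations as background. With hard coupling the realized marginal rate of
  the off-class driver drops below its nominal parameter (a sample drawn
  impaired for both keeps only its class-linked driver); real cohorts show
  the printed rates *with* near-exclusivity, so the coupled generator is a
  stricter, not weaker, test of the recovery machinery.

The generator's gene map is synthetic (symbols `G<chrom><arm><index>`,
cytobands compatible with the parser) and 23 chromosomes × 2 arms × 120
genes by default — dense enough for Poisson(30) bursts with run lengths up
to 3, small enough that an 800-sample cohort simulates in seconds. What the
generator does **not** emulate: LOH and copy-neutral events, GC/length
biases of real gene maps, arm-length heterogeneity, correlated passenger
mutations, subclonality, or inter-chromosomal structure. Tests passing on
synthetic cohorts therefore demonstrate that the machinery recovers planted
signals under the declared noise model, not that real-data performance
reaches any particular level.

## Problem sizes and numerical choices

The test and acceptance workloads use: an 800-sample default cohort for
classifier recovery (held-out accuracy must reach 0.85, mirroring the
published real-data calibration of 85.7%); 150 samples per group with
alteration rates 0.6 vs 0.05 for the injected-region scan (≥80% of region
genes flagged, ≤0.1% of null genes); 50 replicates of a 160 vs 300 cohort
for driver and mutual-exclusivity recovery (both drivers below
$5\times10^{-3}$ and the pair below $q=0.005$ in ≥90% of replicates); all
2×2 tables with total ≤40 for the Fisher oracle sweep; 1,000 random vectors
for the segmentation oracle. These sizes keep the full suite around a
minute while leaving the recovery margins wide.

Degenerate inputs are defined, not accidental: empty arms segment to zero
runs; single-class training data yields a depth-0 tree; leaf ties predict
negative; a cohort failing the 50-per-group rule is skipped with a logged
reason rather than an error; zero-margin tables give $p=1$; a p-value of
exactly $5\times10^{-7}$ is *not* significant.

## Limitations

* Chromoanagenesis subtypes (chromothripsis vs other complex events) are
  not distinguished — the labels are consumed at the binary level.
* Within-arm gene order comes from file row order (GISTIC files are
  position-sorted by convention); a coordinate file can override it.
* The 5-level GISTIC states are collapsed to signs everywhere; high- vs
  low-level gains are never distinguished.
* Region counting and the focality neighborhood are declared conventions;
  other defensible conventions exist and would change counts on dense
  significance landscapes.
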