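---
title: "Chromatin-state transition accounting: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromatin-state transition accounting: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markshift)
```

## The problem

Post-translational histone modifications partition promoters into regulatory
classes. Trimethylation of histone H3 lysine 4 (H3K4me3) marks active
promoters, trimethylation of lysine 27 (H3K27me3) marks Polycomb-repressed
chromatin, and genes carrying both marks — *bivalent* genes — are regarded as
transcriptionally poised. Comparing the per-gene configuration of these two
marks between two cellular conditions (for instance a tumor-initiating
glioma culture versus the same culture after its stem-like properties have
been repressed) localizes the epigenetic reorganization that accompanies a
change in cell state, and the genes that switch configuration are natural
candidates for the regulators of that change.

`markshift` implements this comparison as a reusable pipeline: peak calls
for each mark and condition are annotated to genes, every gene is classified
into one of four states, the two per-condition classifications are crossed
into a 4 × 4 transition matrix, and the changed-gene set feeds the standard
downstream analyses (expression stratification, gene-set enrichment,
interaction-network extraction, correlation-circle PCA) plus the wet-lab
statistics used to validate candidates (limiting-dilution frequency
estimation, qPCR and ChIP-qPCR summaries, densitometry).

## The state model

Annotation uses a symmetric window: a gene with body `[tx_start, tx_end)`
claims any peak overlapping `[max(0, tx_start - flank), tx_end + flank)` by
at least one base pair, with `flank = 20000` by default (the ± 20 kb rule;
all coordinates are 0-based half-open, matching BED). Three choices here
were genuinely open and are fixed as follows:

* **Overlap predicate.** One base pair of intersection suffices and strand
  is ignored: the window is symmetric and no strand rule is stated for this
  kind of annotation. A minimum-overlap fraction is not imposed; the flank
  is the only tunable.
* **No uniqueness rule.** A peak marks *every* gene whose window it
  overlaps. The window rule is a coverage rule, not a nearest-gene
  assignment, so genes within 40 kb of each other can share a peak.
* **Transcript collapsing.** Gene tables with one row per transcript are
  collapsed to the per-gene union interval (minimum start, maximum end),
  because states are reported per gene, not per transcript.

Classification is then exact, not statistical:

| has K4me3 | has K27me3 | state |
|---|---|---|
| yes | no  | `K4` |
| no  | yes | `K27` |
| yes | yes | `BIVALENT` |
| no  | no  | `NONE` |

`NONE` is a real state: the gene universe is the entire supplied gene
table, so overall change fractions are relative to all genes, and a gene
with peaks in one condition and none in the other simply transitions to
`NONE`. The transition matrix counts genes by `(state_A, state_B)`; row
percentages are `100 * count / row_total` and are displayed at one decimal
(raw counts are always carried alongside, so no information is lost to
rounding).

A worked example with published-scale counts:

```{r worked-example}
counts <- matrix(0L, 4, 4, dimnames = list(
  c("K4", "K27", "BIVALENT", "NONE"), c("K4", "K27", "BIVALENT", "NONE")))
counts["K4", ] <- c(9652L, 92L, 945L, 391L)
counts["K27", ] <- c(112L, 2400L, 0L, 0L)
counts["BIVALENT", ] <- c(788L, 272L, 1276L, 0L)
tm <- transition_matrix_from_counts(counts, conditions = c("TG1", "TG1-miR"))
round(tm$percentages["K4", ], 1)
round(change_fraction_by_origin(tm), 1)
```

## Expression linkage

Expression matrices are log2 signals normalized against a housekeeping
panel: per sample, the mean log2 signal of the panel is subtracted from
every gene, which removes any per-sample additive offset exactly and fixes
the panel's per-sample mean at zero. The panel is supplied as a plain
one-id-per-line file; only its composition matters, not its size (a
30-gene panel is typical).

`stratify_and_test()` groups per-gene expression (averaged across replicate
samples — replicates are averaged rather than pooled, so each gene
contributes one observation) by chromatin state and runs all pairwise
two-sided **Welch** t tests, including against the pooled `ALL` group.
Welch's unequal-variance form is used throughout because group variances
differ systematically between active and repressed genes. No multiplicity
correction is applied by default — the pairwise grid is small and raw
p-values are the convention for this display — but `adjust = "BH"` is
available. Groups with fewer than two genes, or constant groups, report
`NA` rather than a fabricated p-value. The summary also flags whether the
canonical ordering `median(K4) > median(BIVALENT) > median(NONE) >=
median(K27)` holds.

## Enrichment and network extraction

Gene-set enrichment is the standard one-sided hypergeometric
over-representation test: for a query of `n` genes in a background of `N`,
a term with `K` background members and `k` query hits gets
`p = P(X >= k)` under Hypergeometric(N, K, n), with Benjamini–Hochberg
q-values across terms. The background is explicit and deliberate — e.g.
all genes, or only the mark-changing genes, depending on the question —
and query genes outside it are dropped with a count. Term-size guards
(default 3–2000, applied after intersecting with the background) are
conventional defaults, configurable.

Network extraction keeps interactions with confidence **at or above** the
threshold (inclusive, default 0.7 — "high confidence" in the STRING
convention includes the boundary), induces the subgraph on the requested
node set, and keeps isolated nodes. `augment_network()` models the manual
step of adding a few supplementary factors to connect a fragmented network:
it greedily adds, up to `max_added` (default 3), the candidate that most
increases the number of *original* nodes in the largest connected
component, breaking ties lexicographically. The objective counts original
nodes so a candidate cannot "win" merely by joining itself; greedy search
is the documented behaviour and optimality is not claimed (the test suite
compares it against exhaustive search on small instances and tolerates
rare sub-optimal picks).

## Zone z-scores and the correlation circle

`zone_zscore()` standardizes each gene across anatomical zones with the
sample standard deviation; constant genes map to all zeros rather than
NaN. `pca_circle()` performs PCA on column-standardized data — equivalent
to the eigen-decomposition of the Pearson correlation matrix — and reports
each variable's Pearson correlation with the component scores, the
coordinates of the classical correlation circle. Because PCA signs are
arbitrary, each component is oriented so the lexicographically smallest
variable with a nonzero loading correlates positively; this makes results
reproducible across platforms without affecting any angle or magnitude.

"The query co-varies with the signature along F1" is a visual statement in
the source analyses; this package operationalizes it explicitly as
`covariation_score()`: the cosine similarity between the query's (F1, F2)
correlation vector and the centroid of the signature's vectors, plus a
separate F1 sign-agreement flag. The cosine is the package's own
quantification, flagged as such.

Two numerical notes. For two variables with correlation `r != 0`, the
first component's variable correlations are `±sqrt((1 + r)/2)` — the
closed form used as a test oracle. At `r = 0` exactly the correlation
matrix is the identity and *every* orthonormal basis is an eigenbasis, so
no particular F1 direction is forced; the property is therefore asserted
for `r != 0` and, at sampled `r ≈ 0`, only to sampling tolerance.

## Limiting-dilution statistics

Sphere-formation at doses of 1, 5 and 10 cells per well follows the
single-hit Poisson model: a well seeded with `d` cells is positive with
probability `1 - exp(-lambda d)`, where `lambda` is the frequency of
sphere-forming cells. `elda_fit()` maximizes the binomial likelihood on
the log-lambda scale and reports the estimate in the field's `1/N` display
(`N = 1/lambda` cells per sphere-forming cell, lower confidence limit =
larger `N`).

Confidence intervals are **profile likelihood** at the chi-square(1)
cutoff (3.841): this is a deliberate design choice over the
complementary-log-log GLM Wald intervals of the popular web tool. The two
are asymptotically equivalent, but the profile construction behaves
correctly at the boundaries without ad hoc fixes: an all-negative assay
yields `lambda = 0` ("1/Inf", lower limit `Inf`) with a finite upper-N
bound solved in closed form, and an all-positive assay yields the
symmetric case with a finite lower-N bound. Exact reproduction of
Wald-based published intervals is consequently not claimed; simulation
shows the profile CI covers the truth ~95% of the time at the default
design (3 doses × 16 wells). `elda_compare()` tests equality of two
frequencies by the likelihood-ratio statistic against chi-square(1); when
both assays are entirely negative the frequencies are indistinguishable at
the boundary and the test is reported as absent rather than as p = 1.

qPCR fold changes use the 2^(−ΔΔCt) model against an endogenous reference
(TBP by default), without amplification-efficiency correction. ChIP-qPCR
percent-input adjusts the input Ct for the input dilution
(`ct_input - log2(1/fraction)`, default fraction 1% — a required setting,
as it is rarely printed) and fold enrichment divides percent-input at the
region of interest by a negative-control region.

## What the synthetic generator emulates — and what it does not

`sim_config()` fixes the simulated study conditions once:

* state priors 0.48 / 0.10 / 0.10 / 0.32 over K4 / K27 / bivalent / none,
  echoing the typical observed repartition;
* a transition kernel whose rows give ~12.8% change among K4 genes, 44%
  among K27, 49% among bivalent, with the NONE row solved so the overall
  change rate is 22% under the priors;
* per-state log2 expression means 10 / 8 / 5.5 / 5 with sd 1, a 30-gene
  housekeeping panel (mean 8, sd 0.05) and a per-sample offset (sd 0.5)
  for the normalizer to remove;
* limiting-dilution truth `lambda = 1/5` at doses (1, 5, 10) with 16
  wells per dose;
* three 8-node interaction communities with within/between edge
  probabilities 0.8 / 0.05 and confidences drawn above / below 0.7.

Genes are placed with inter-gene gaps exceeding twice the flank, so
flanked windows never overlap and the render → annotate → classify round
trip recovers the planted state table *exactly*; overlapping-window stress
cases are generated separately (random dense instances) for the annotation
oracle tests only. Peak lengths are uniform on 200–500 bp inside the gene
body, mimicking sonication fragment sizes.

The generator deliberately omits several features of real data: peak
calling noise and width variation beyond fragment size, copy-number and
mappability artifacts, correlated replicate structure, batch effects
beyond a scalar per-sample offset, and any dependence between a gene's
state and its neighbours. Passing round-trip and calibration tests
therefore demonstrates that the *accounting* is correct — not that the
pipeline is robust to peak-caller errors, which enter upstream of its
inputs.

Every generator is a pure function of `(config, seed)`; sub-generators use
fixed offsets of the seed so that, e.g., the gene table does not change
when only the expression parameters do.

## Problem sizes and determinism

The bundled analyses and tests run at deliberately modest sizes chosen to
exercise every code path while keeping a full run fast on a laptop:
300-gene synthetic universes (80–120 genes for repeated round trips),
10,000-gene draws for frequency-recovery bounds, 500 simulated
limiting-dilution assays for CI coverage, 2,000 replicates for test-size
calibration, and n = 10^5 observations for the PCA closed-form check.
Statistical assertions use 3-standard-deviation bounds (or the documented
acceptance bands) so they are stable across seeds.

## Known limitations

* States are binary per mark: peak scores are carried through but not used
  for classification, so marginal peaks count as fully marked.
* The transition matrix is purely descriptive; no differential-binding
  test is attached to a transition.
* Greedy network augmentation can be sub-optimal on adversarial graphs.
* The cosine co-variation score depends on the (F1, F2) plane only; a
  signature spread across deeper components would be under-measured.
* ELDA assumes the single-hit model; heterogeneity or cooperation between
  seeded cells is out of scope.
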