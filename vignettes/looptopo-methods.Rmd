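---
title: "Methods: loop topology classification and the synthetic degron study"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: loop topology classification and the synthetic degron study}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(looptopo)
```

# Scope and model

`looptopo` analyses called chromatin interactions, peak sets and count
tables from an acute CTCF-degradation experiment; it does not process
reads, call peaks or call loops. Its core is a geometric classification of
regulatory (H3K27ac-anchored) interactions against the structural (CTCF)
loop set, surrounded by the differential, accessibility and expression
integrations needed to ask whether CTCF's regulatory effects run through
loops or not.

All coordinates are 0-based half-open (BED convention) everywhere
internally; 1-based dialects are converted at the I/O boundary. Loops are
ordered pairs of same-chromosome anchor intervals with per-condition
contact counts; inter-chromosomal records are rejected rather than
dropped, because every topology relation below is defined only in cis.

# The topology predicates

The published class scheme is schematic, so this package fixes one
concrete, fully-parameterised instantiation and records the configuration
in every output:

* The CTCF loop span `S` defaults to the **anchor-midpoint span**
  (`mid(anchor1)` to `mid(anchor2)`). Midpoints avoid double-counting
  anchor width in containment tests; the outer-envelope span is available
  via `span_mode = "outer"` since the original convention is not stated.
* **Anchor sharing** means the two anchor intervals overlap within
  `slack` bp (default 0). Interiority of an anchor is judged by its
  midpoint, strictly (`s < m < e`); whether the original analysis used
  midpoints or whole intervals is unknowable from the text, so the choice
  is declared rather than asserted.
* **Contain** requires the interaction's midpoints to bracket `S`, with a
  shared anchor counting as containment at that edge. The subtype is the
  number of corresponding-side shared anchors (0/I, 1/II, 2/III). Subtype
  III is textually pinned (interactions identical to CTCF loops, CTCF at
  both anchors); II is pinned by the H3K27ac-solo-anchor analysis; I
  follows by elimination.
* **Cross** needs one midpoint strictly inside and one strictly outside,
  and not contain. **Inside** needs both strictly inside with no shared
  anchor. **Neighbor** needs exactly one shared anchor (either pairing)
  with the other midpoint strictly outside — the interaction extends away
  from the loop body. Everything else contributes no relation.
* Combination over the loop set: relation types {contain, cross} →
  `contain_and_cross`; a single type → that type; none → `outside`; any
  other mixture → `other_composite`. The published five-bar summary never
  explains how mixed configurations were collapsed, so they are reported
  as a distinct bucket instead of being forced into a guess. When several
  contain relations exist, the reported subtype is the largest
  shared-anchor count (III > II > I) — the most CTCF-coupled description
  of the interaction.

Candidate CTCF loops are retrieved from an interval index on outer spans,
with the query window padded by the interaction's own span length plus
slack; the test suite proves index/exhaustive equivalence on random
instances, so the index is an optimisation, never a semantics change.

# Differential machinery

Interaction and ATAC libraries are single pooled libraries per condition
(the usual HiChIP design), so differential calling uses CPM normalisation
(`count × 10⁶ / library total`), a log2 fold change with a pseudocount of
1 CPM, and an exact two-sided binomial test of the post-treatment count
against its depth share given the feature total, with Benjamini–Hochberg
FDR across features. A feature is called only when `fdr ≤ alpha` (0.05)
and `|log2FC| ≥ min_lfc` (1). The underlying caller is unnamed in the
source analysis; a transparent exact scheme was preferred to guessing a
stack, and both thresholds are mandatory config keys surfaced in every
report.

Group comparisons use a two-sided Mann–Whitney U test: exact null
distribution of U for tie-free samples with `min(n, m) ≤ 8`, otherwise
the normal approximation with tie and continuity corrections; two
identical samples give p = 1. CTCF loop "strength" is the normalised
score carried by the loop record; strata are quantile bins (default a
median split into weak/strong) with the boundaries printed, because the
original bin edges are unstated. For contain & cross interactions the
per-interaction balance statistic `log2(max contain strength / max cross
strength)` quantifies promotional vs insulating dominance.

Gene-level DEG calling defaults to the edgeR quasi-likelihood F-test.
A pooled exact rate-ratio test is also provided (`test = "pooled"`) and
is the path checked against a closed-form tail sum, but it assumes
Poisson replicates; with the negative-binomial replicate noise that
expression counts actually carry it is anticonservative and cannot
control FDR, so the dispersion-aware test is the default. Rescue
classification compares each IAA-containing condition's CPM mean to the
untreated baseline with a log2 tolerance of 0.5 (the published rescue is
shown as a heatmap without a numeric criterion; the knob is mandatory and
printed): rescued under the loop-deficient mutant → loop-independent,
rescued under wild-type only → loop-dependent, neither → not rescued.
Genes deviating in the same direction in *all* IAA-containing arms are
treated as auxin-responsive and excluded before rescue classification.
A gene is "associated with" an interaction when either anchor overlaps
the gene's ±1 kb TSS window — the assignment rule is unstated in the
source, and promoter-window overlap is the most conservative explicit
choice.

# The synthetic study

The generator emits a world in which every downstream claim is checkable
against planted truth. It is a *stated world*: parameters encode the
qualitative structure of the real experiment, not its magnitudes.

* **Genome**: one 20-Mb chromosome, split into an active block (40%)
  carrying a slot architecture of convergent-motif CTCF loops (30 loops,
  ~80-kb spans) that hosts the planted H3K27ac classes, and a structural
  block of large CTCF-only loops (16 × 650 kb) that dominates genomic
  coverage and hosts the gene models. The two-tier design mirrors nested
  TAD-scale vs local looping and is what makes structural coverage exceed
  regulatory coverage (the 51% vs 8.8% ordering) — in a purely local
  architecture, contain-type geometry would force the opposite ordering.
* **Classes**: default mix contain I/II/III = 0.18/0.16/0.11,
  contain & cross = 0.33, cross = 0.05, neighbor = 0.08, inside = 0.05,
  outside = 0.04 — contain plus contain & cross just under 80%, cross plus
  outside under 10%, matching the published distribution qualitatively.
  Placements are constructed so the default classifier (slack 0, midpoint
  spans) provably recovers the planted relation and relates to no other
  loop; truth records an `unambiguous` flag.
* **Depletion effects**: IAA multiplies contain-III counts by 0.25,
  contain-II by 0.5, contain-I and the composite classes by 1.0;
  cross-type interactions whose host loop strength reaches the 0.7
  quantile are *enhanced* 2× (insulation loss). These encode the
  pronounced III > II > I weakening and the strong-insulator subset.
* **Counts**: loop strengths are log-normal (meanlog 4, sdlog 0.8 —
  tens-to-hundreds of contacts, plausible for a filtered HiChIP catalog;
  no depth or dispersion figures are published for the real libraries).
  Each feature gets one gamma-jittered latent rate shared across
  conditions and Poisson sampling per library: marginally
  negative-binomial (overdispersed across features) while keeping the
  conditional binomial test exact, the only scheme under which a
  binomial caller for single-library designs can honestly control FDR.
* **ATAC**: 300-bp windows on every CTCF site plus background windows;
  40% of CTCF-peak windows lose accessibility 0.3× under IAA, restored in
  both rescue arms; a ~10% share of affected windows sits on motif-only
  (sub-threshold) CTCF sites, reproducing the Group 1 / Group 2 split.
  Promoter CTCF motifs are centred N(−57, 5) bp upstream of the TSS.
* **Expression**: 2,000 genes × 4 conditions × 3 replicates,
  negative-binomial (dispersion 0.05) around log-normal base means
  (meanlog 5, sdlog 1.5); 10% DEGs, 80% of them down at |log2FC| 1.5.
  Down-DEGs split 0.7/0.2/0.1 into loop-independent / loop-dependent /
  auxin-responsive strata; loop-dependent genes additionally receive an
  EP interaction at their promoter that loses 4× under IAA, and
  promoter-CTCF probabilities are stratum-specific (1.0 for
  loop-independent, 0.9 loop-dependent, 0.25 background).

What a green test does **not** establish: the generator has no distance-
dependent contact decay, no biological replicate structure for
interactions, no chromatin-state segmentation, no antisense
transcription, and gene density is uniform within the structural block.
Recovery rates measured on it validate the algebra and the callers, not
the biological effect sizes of any real dataset.

# Numerical and degenerate-input choices

* Midpoints are `floor((start + end)/2)`; percentages print with
  round-half-up at the requested precision (exactly reproducing printed
  fractions such as 82.8% = 106/128).
* Quantile strata collapse to a single stratum when all strengths are
  equal; empty strata and empty inputs yield empty tables, not errors.
* QC filters are order-independent and idempotent; the identical-element
  merge assigns anchors by midpoint containment with a 2.5-kb nearest
  fallback and exempts unassignable anchors (conservative: never merge on
  weak evidence). Merging conserves per-condition totals exactly.
* A zero denominator, a zero library total, a missing condition, a
  missing config key and a degenerate design are all hard errors naming
  the offending entity.
* Determinism: one integer seed fixes every simulator output byte for
  byte; sub-generators use fixed seed offsets so stages are reproducible
  in or out of the orchestrator, and writers emit no timestamps — reruns
  are file-hash identical.

# Known limitations

Anchors may be fixed-width bins or variable peaks (both are supported;
the original convention is unknown). The `other_composite` bucket means
category percentages are not directly comparable to the published
five-category bar chart for mixed configurations. The pooled DEG test is
provided for transparency but should not be used on overdispersed
replicates. Trans interactions are out of scope by construction.
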