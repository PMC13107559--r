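# looptopo

Topology-aware classification of regulatory chromatin interactions
relative to CTCF loops, with integrated differential interaction,
accessibility and expression analysis for acute CTCF-degradation (auxin
degron) experiments in mouse embryonic stem cells and similar systems.

## The problem

CTCF, together with cohesin, anchors structural chromatin loops at
convergent motif pairs. Acute CTCF degradation collapses these loops, yet
most enhancer/promoter (H3K27ac-marked) interactions and most gene
expression barely move — and the genes that do respond are often rescued
by a loop-deficient CTCF mutant, pointing at loop-*independent* regulation.
Dissecting which regulatory interactions do depend on CTCF loops requires
knowing where each H3K27ac interaction sits **relative to** the CTCF loop
scaffold. `looptopo` implements that spatial classification and everything
needed to exercise it end to end.

For an H3K27ac interaction *h* (anchor midpoints `h₁ < h₂`) and a CTCF
loop *c* with span `S = [s, e)` (anchor-midpoint span by default), the
pairwise relation is:

| relation | definition |
|---|---|
| **contain** | `h₁ ≤ s` and `h₂ ≥ e`, anchor sharing counting as containment at that edge; subtype = number of shared anchors: 0 → I, 1 → II, 2 → III (III coincides with the CTCF loop itself) |
| **cross** | exactly one of `h₁, h₂` strictly inside `S`, the other strictly outside, and not contain |
| **inside** | both midpoints strictly inside `S`, no shared anchor |
| **neighbor** | exactly one anchor shared with `c`, the other midpoint outside `S` (the interaction extends away from the loop body) |
| **outside** | no relation to any CTCF loop |

Per interaction, relations over the whole CTCF loop set are combined:
contain + cross (and nothing else) → **contain & cross** (a loop both
promotes and insulates the same contact); exactly one relation type →
that type; anything else → `other_composite`. "Shared anchor" means the
anchor intervals overlap within a configurable `slack` (default 0 bp);
every report records the full predicate configuration.

Around the classifier sit: loop QC (distance / count / identical-element
merging), anchor typing (C/E/P composites, EP–PP–EE interaction classes),
CPM + exact-binomial differential calling with BH-FDR, Mann–Whitney U
machinery (exact small-sample path), CTCF-centered ATAC window analysis
with motif-to-TSS signed distances, wt/mut rescue classification, the
loop-independent vs loop-dependent mechanism partition, and a fully
deterministic synthetic-study generator with machine-readable ground
truth.

## Worked example

Simulate a CTCF architecture, plant 1,000 H3K27ac interactions with known
classes, classify them, and measure the depletion response per class:

```r
library(looptopo)
cfg  <- sim_config(seed = 1)
arch <- simulate_ctcf_architecture(cfg)
pl   <- plant_h3k27ac_interactions(cfg, arch)
topo <- classify_topology(pl$interactions, arch$loops)
category_distribution(topo)
#>           category count percent
#>            contain   434    43.4
#>              cross    49     4.9
#>  contain_and_cross   335    33.5
#>           neighbor    90     9.0
#>             inside    47     4.7
#>            outside    45     4.5

d <- call_differential(pl$interactions, "untreated", "IAA")
class_response_report(topo, d)[, c("group", "n", "median_log2fc", "p_vs_outside")]
#>              group   n median_log2fc p_vs_outside
#>          contain_I 154         0.184     1.10e-01
#>         contain_II 179        -0.801     3.15e-22
#>        contain_III 101        -1.693     5.91e-21
#>  contain_and_cross 335         0.237     5.55e-01
#>              cross  49         0.414     6.37e-02
#>           neighbor  90         0.225     3.34e-01
#>             inside  47         0.326     3.90e-01
#>    other_composite   0            NA           NA
#>            outside  45         0.293           NA

percent_report(sum(d$call != "unchanged"), nrow(d), 2)$label
#> [1] "13.30% (133/1000)"
```

Reading the output: contain and contain & cross dominate the class mix
(planted to mirror real H3K27ac interaction catalogs); after simulated
CTCF depletion, contain-III interactions (identical to CTCF loops) weaken
most (median log2FC −1.69 vs the outside reference), contain-II weaken
intermediately, and contain-I are statistically indistinguishable from
outside-type interactions — the subtype-ordered response the classifier
is built to expose. `percent_report` renders every headline fraction with
round-half-up printed-precision arithmetic (e.g. `82.8% (106/128)`).

The one-command pipeline (simulate → qc → annotate → classify → diff →
atac → integrate, deterministic and provenance-stamped):

```r
run_pipeline(default_config(seed = 7), "run1/")
```

or from the shell: `Rscript inst/scripts/looptopo.R run --seed 7 --outdir run1/`.

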