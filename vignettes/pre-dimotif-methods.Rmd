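---
title: "Methods: PRE di-motif discovery and Kar4-dependence analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PRE di-motif discovery and Kar4-dependence analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(predimotif)
```

## The biological question and the model

The yeast mating pheromone response is driven by the transcription factor
Ste12, which binds pheromone response elements (PREs; consensus
5'-TGAAACA-3') in promoters, typically as a dimer on a pair of PREs. A
subset of pheromone-induced genes additionally requires the cofactor Kar4.
This package implements the downstream analysis that connects three
observations: (i) Ste12 binding sites are dominated by one dimeric
configuration, two PREs in head-to-tail orientation separated by 4 nt
(H-T 4); (ii) sites driving Kar4-*dependent* transcription carry more
mismatches in their PREs and lose disproportionally more Ste12 occupancy in
a *kar4*Δ strain; (iii) without Kar4, Ste12 redistributes toward a
different configuration, tail-to-tail with 3 nt spacing (T-T 3), at genes
normally not induced.

A *di-motif configuration* is an orientation plus a spacer length
$s \in [0, 100]$. On the top strand the templates are

| orientation | template | strandedness |
|---|---|---|
| H-T | `TGAAACA` · N$^s$ · `TGAAACA` | scanned on both strands |
| T-T | `TGTTTCA` · N$^s$ · `TGAAACA` | pattern equals its own reverse complement |
| H-H | `TGAAACA` · N$^s$ · `TGTTTCA` | pattern equals its own reverse complement |

T-H is not a separate case: it is H-T read on the other strand. Because the
H-H and T-T patterns are reverse-complement invariant (with the two slots
swapping roles), they are scanned once and reported on the + strand;
scanning them on both strands would double-count every occurrence. The
spacer is unconstrained. A match records the per-slot mismatch counts
$(m_1, m_2)$ against the expected 7-mers; `N` bases count as mismatches
inside a slot and are ignored in the spacer.

## Match significance

The original analysis ranked matches with a published log-odds scanner
(FIMO) and noted that the resulting q-value ranking is largely determined
by the number of mismatches. Here significance is defined self-containedly
as an exact match-count tail probability: under an iid background with base
probabilities $b$, position $j$ of the 14 constrained template positions
matches with probability $\pi_j = b(\text{template}_j)$, and the p-value of
a match with $m = m_1 + m_2$ total mismatches is

$$p(m) = P\!\left(X \ge 14 - m\right), \qquad
  X = \sum_{j=1}^{14} \mathrm{Bernoulli}(\pi_j),$$

computed by exact convolution (a binomial tail under the uniform
background). This preserves the mismatch-count ranking exactly, is
independent of any external tool, and is validated in the tests against
full sequence-space enumeration at reduced template widths. Absolute p- and
q-values therefore differ from a log-odds scan; rank order is the contract.
q-values are Benjamini–Hochberg adjusted over all matches of one region-set
scan (one invocation), mirroring a single scanner run over a region set.

A region's *best* match is the lowest q-value after filtering to
$p \le 0.01$; ties are broken by fewer total mismatches, then smaller
spacing, then leftmost position, then + strand. The chain makes the choice
total, so results are invariant to match enumeration order. (Note one
consequence: among several perfect matches in one sequence, the smallest
spacer wins — e.g. a sequence containing perfect H-T 4 and T-T 3 motifs has
best match T-T 3.)

## Region preparation and summaries

Binding sites (points from any peak caller) are expanded to
point ± 120 bp — 241 bp, an intentionally symmetric, odd-width window —
and sites within 60 bp on a chromosome are merged into one region spanning
120 bp beyond the first and last site, to avoid scanning duplicated
sequence. Regions whose matches all fail the p-filter keep an `NA` best and
stay in denominators, so "fraction of regions with best = C" is a fraction
of *all* analyzed regions. Top-k membership ranks one entry per
configuration (that configuration's best match in the region) because the
question "is H-T 4 among the best k possible di-motifs" is about
configurations, not occurrences. The curated H-T 4 list applies the
stricter rules used for logo building: at most 2 mismatches per PRE, 18-mer
centre within 100 bp of the site point, one motif per site, minus-strand
motifs reverse-complemented so both PREs read in consensus direction.

## Peak association, classification, occupancy

Feature starts (genes and LTRs; GFF3 converted to 0-based, strand-aware
starts at the boundary) within 500 bp of a peak point associate with it in
either direction — deliberately not restricted to promoter-side, so
bidirectional promoters give one peak two genes. Peaks nearest an LTR
start, or inside an LTR interval, are flagged, and the flag propagates to
their gene associations for downstream filtering; LTRs are near-identical
copies genome-wide and would otherwise contaminate gene-level statistics.
When a gene has several peaks, its statistics come from the lowest-Q peak
(ties: higher occupancy, then leftmost), a total order so the result is
input-order invariant. Occupancy is the tag count over a region, summed
over strands and replicates before scaling, divided by library-size/10^6
(RPM).

Gene classes use five contrasts (gene, shrunk log2 fold-change, adjusted
p). Thresholds: induced means lfc ≥ 1 *inclusive* ("at least 2-fold") with
padj < 0.01 for the named sets; the broader t60-artifact screen uses
padj < 0.05, flagging genes significantly changed in the same direction in
both the pheromone contrast and the mock-treatment control. Classes:
pheromone-induced ∧ Ste12-dependent genes split into Kar4-dependent
(also ≥ 2-fold down in *kar4*Δ vs wild type) and Kar4-independent (the
rest); *kar4*Δ-only genes respond ≥ 2-fold more strongly without Kar4 and
≥ 2-fold within the *kar4*Δ time course; the up-variant may co-occur with
Kar4-independent induction and is then a co-label, so primary labels
partition the genome. *KAR4* itself is flagged and excluded from
Kar4-dependent counts as a parameter (its class is not identifiable from
these data), not a hard-coded judgment. Genes absent from a contrast are
treated as non-significant there, since differential-expression tools drop
low-count genes.

## Motif activity inference

Promoter affinity for a PSAM $A$ (per-position relative affinities, column
maxima exactly 1; PSPMs convert via $(p_j + \varepsilon)/\max(p_j +
\varepsilon)$) is the REDUCE-style sum over all windows on both strands of
$\prod_j A_j(\text{base})$. An `N` base contributes its column's
background-weighted mean affinity by default (an unbiased placeholder;
configurable to zero the window). Activities are ordinary least squares of
a response (a contrast's fold-changes, or each column of the pseudocounted
log2FC matrix, pseudocount 0.5 added before averaging the reference
samples) on *all* motif affinities jointly, with intercept; collinear
columns are dropped with a warning rather than silently aliased. Outputs
are the signed $-\log_{10} p$ (coefficient direction applied to the
p-value) and, across samples, coefficients rescaled within each motif so
the largest absolute value is 1. Nested-model F-tests are exposed for
reduced-model comparisons. Scoring both strands is a deliberate choice
(di-motif function is orientation-independent); it can shift absolute
coefficient values relative to single-strand scoring.

One empirical note reproduced by the tests: in a joint fit of the wild-type
response on the H-T 4 and T-T 3 PSAMs, H-T 4 is the top *positively*
associated motif while T-T 3 attains a comparably strong *negative*
association — T-T-3-bearing genes are precisely those not induced in wild
type. Ranking by absolute significance alone can therefore flip between
the two; the package reports signed values and the tests assert the
positive-top and sign structure.

## Statistical tests

Enrichment is the exact hypergeometric upper tail
$P(X \ge k)$; the population defaults to the union of the compared sets and
is configurable to a supplied universe, since either convention is
defensible for promoter-content comparisons. The Mann–Whitney U test is
exact by full enumeration of group relabellings with midranks when
$n_x + n_y \le 20$ (the permutation distribution of U is symmetric about
$n_x n_y / 2$, giving a clean two-sided p even under ties) and otherwise
uses the normal approximation with tie correction. BH adjustment wraps the
standard step-up; note it is *not* idempotent — re-adjusting adjusted
values inflates them — so adjusted values are never fed back.

## The synthetic generator: what it emulates, and what it does not

`sim_config()` fixes the study conditions: 800 genes, 200 per class;
promoters 600 bp (the activity-inference window); regions ±120 bp;
Kar4-independent genes carry H-T 4 motifs with sorted mismatch pairs drawn
from {0_0, 0_1, 1_1}, Kar4-dependent from {0_1, 1_1, 1_2, 2_2} (the
degraded end of the spectrum), *kar4*Δ-only genes carry T-T 3 from
{0_0, 0_1}; wild-type occupancy is
$300 \cdot e^{-0.5 (m_1+m_2)} \cdot \mathrm{lognormal}(\sigma)$ RPM and
*kar4*Δ occupancy divides by per-class penalties (1.5, 4, 0.5 — the last
meaning *gain* without Kar4); expression effects per class are chosen so
noise-free tables classify exactly, with gaussian noise of sd
$\sigma = 0.3$ and z-score-derived adjusted p-values otherwise. Mismatch
positions are uniform over the 7 PRE positions by default, with an optional
head-biased mode (first two positions favoured) and an optional dual-motif
mode planting a companion H-T 4 beside the T-T 3. Tags are spread with a
triangular kernel within ±10 bp of the site so RPM over the region recovers
the drawn occupancy to rounding (library 5·10^7, scale 50).

The generator emulates the *statistical structure* the analysis assumes —
iid background, exactly one planted motif, clean class-conditional effect
sizes, symmetric noise. It does not emulate chromatin context, nucleosome
positioning, read-level noise, overlapping genes, or the correlated
mismatch spectra of real promoters. Passing recovery tests therefore shows
the pipeline is correct and well-calibrated under its own assumptions, not
that those assumptions hold in vivo.

## Problem sizes and numerical choices

Tests run the scanner–oracle equivalence on 200 random 300-nt sequences
over all 303 configurations; p-value enumeration at widths 6 and 8;
hypergeometric enumeration for populations up to 12; Mann–Whitney
enumeration up to n = 8 per group. Recovery uses the default 800-gene
bundle for scanning, classification and occupancy, and 100 seeded runs of
2000 × 200 bp promoters with one affinity-driven response and five decoy
PSAMs for the activity ranking (the planted PSAM must win ≥ 99/100) —
sizes chosen to give sampling error well below every asserted margin.
Degenerate inputs are defined, not accidental: empty scans return typed
empty tables, regions shorter than 14 nt are errors, zero-probability PSPM
columns error at ε = 0 and warn otherwise, p = 0 is clamped to the smallest
representable double with a warning, and a constant response yields NA
p-values with a warning rather than spurious certainty.

## Known limitations

Absolute match p/q-values differ from log-odds scanners by construction;
only ranks are comparable. The occupancy model is single-site (no shoulder
or satellite peaks, which the original curation removed by eye). The
classifier consumes shrunk fold-changes and adjusted p-values as given —
no shrinkage or multiple-testing is re-done across contrasts. The
hypergeometric population convention for set comparisons is a parameter,
as the convention used originally is not recoverable from the text.
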