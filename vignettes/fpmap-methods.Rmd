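---
title: "Methods: fingerprint-based physical map construction in fpmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fingerprint-based physical map construction in fpmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpmap)
```

## The problem

A BAC physical map orders large-insert clones along a genome before any
sequence exists. Each clone is reduced to its restriction *fingerprint* —
the multiset of fragment sizes from one enzyme read off an agarose gel
(~17 scoreable bands per 100 kb clone), or from five enzymes read on a
capillary sequencer (HICF, ~178 bands). Two clones overlap when they share
more bands than chance allows; accepted overlaps chain clones into
*contigs*. Contigs are then anchored to a genetic map through pooled
overgo hybridization probes, and to sequenced comparator genomes through
BAC-end sequences. `fpmap` implements this pipeline end to end, together
with a synthetic genome/library generator that provides exact ground truth
for every stage.

## The overlap model

For two unrelated clones with $n_a$ and $n_b$ bands placed uniformly on a
gel of $G$ units, a band of one clone falls within tolerance $t$ of a
given band of the other with probability $p = 2t/G$. With
$n_{hi} = \max(n_a, n_b)$, a band of the smaller clone has some
tolerance-neighbour with probability $\lambda = 1 - (1-p)^{n_{hi}}$, and
the chance of $m$ or more matched bands is the binomial tail

$$S(n_a, n_b, m) \;=\; \sum_{k=m}^{n_{lo}} \binom{n_{lo}}{k}
\lambda^k (1-\lambda)^{n_{lo}-k}.$$

An overlap is called when $S$ falls at or below a cutoff. `sulston_score()`
evaluates the tail with exact log-space binomial coefficients — no normal
approximation — because the decisions the package reproduces sit within a
few percent of their cutoffs: at $t=7$, $G=5000$, cutoff $10^{-12}$, the
minimal matching-band count at $n=17$ is 12 ($S(12)=5.1\cdot10^{-13}$ vs
$S(11)=2.1\cdot10^{-11}$), and a perfect match of 7 bands misses the
cutoff by under 5%, making 8 the minimum informative band count. Both
numbers are recomputed, not stored, and are the package's two acceptance
targets.

Two deliberate conventions, chosen because only they reproduce those
anchors: $p = 2t/G$ (not $(2t+1)/G$, which shifts the $n=17$ threshold to
13), and $\lambda$ built from the *larger* band count with the binomial
over the smaller.

**What the score models — and what it does not.** The binomial counts
bands of one clone having *at least one* tolerance-neighbour in the other,
with reuse. The Monte-Carlo oracle (`sulston_mc_tally()`) simulates
exactly that event on continuous uniform band positions and agrees with
the analytic tail within sampling error at $10^6$ trials. Maximum
bipartite matching without reuse — what `match_bands()` computes on real
profiles, verified against an exhaustive oracle — is a strictly smaller
count whose tail deviates measurably (~25% at $n=10, m=3$); tests compare
each quantity against its own oracle and never conflate the two.

`match_bands()` itself is a greedy two-pointer pass over the sorted band
lists, which attains the maximum matching for the threshold criterion and
breaks ties toward the earliest partner, making every downstream result
order-independent.

## Contig assembly

`assemble()` scores all clone pairs (an Rcpp kernel with early rejection
keeps the desk-scale 2,000-clone, 2M-pair scan under a few seconds),
accepts pairs with $S$ at or below their *effective* cutoff, and takes
connected components with two or more clones as contigs — single linkage,
since the accepted-overlap graph is the published criterion. Clones with
fewer than 2 bands never join. The effective cutoff starts at the stage
base and relaxes by 2, 3 or 4 denary (ten-fold) steps when the pair shares
1, 2 or 3+ hybridization markers, capped at a floor (default $10^{-6}$);
probes hitting more than 50 clones are excluded from assembly use.

The integrated pipeline (`run_integrated_pipeline()`) runs the published
stage list with its parameters as defaults:

| stage | operation | cutoff / tolerance |
|---|---|---|
| 0 | QC: band-count outliers (top/bottom 5% per batch, nearest rank), cross-well contamination (rook-adjacent wells, ≥ 90% mutual band match) | – |
| 1 | preliminary agarose assembly, probe relaxation to 1e-8/1e-7/1e-6 | 1e-10 / 8 |
| 2 | HICF assembly of 2 terminal clones per end of the largest half of contigs, no markers | 1e-50 / 3 |
| 3 | integrated agarose reassembly, probe+HICF relaxation to 1e-10/1e-9/1e-8 | 1e-12 / 7 |
| 4–7 | DQ splitting; end merges 1e-12 → 1e-6; singleton adoption; burying (≥ 80% band containment) | |

HICF evidence enters stage 3 two ways: co-membership in an HICF contig
counts as one shared marker for ordinary pairs, while for pairs of
terminal clones of *distinct* preliminary contigs it relaxes the cutoff by
exactly two denary steps ($10^{-12} \to 10^{-10}$) — the asymmetry keeps a
false HICF join from propagating beyond the clone pair it directly
supports. A pair of 17- and 18-band clones sharing 11 bands
($S = 3.9\cdot10^{-11}$ at tolerance 7) is the boundary case: separate at
every agarose-only stringency, merged only under this rule.

**CB maps and Q clones.** The consensus-band map seeds from the
best-matching pair and inserts remaining clones by decreasing match count,
growing the consensus by each clone's unmatched bands; its length (in CB
units, one unit ≈ one non-overlapping band ≈ 4.1 kb) always lies between
the largest member's band count and the member sum. Offsets are
shortest-path distances on the match graph with edge weight "mean unshared
bands", from the farthest clone — enough to order clones along the contig
and pick terminal clones, without restating FPC's full incremental layout.
A clone is flagged **Q** when fewer than half its bands are matched by its
best-supporting fellow member. We chose this over "alignment to the
consensus at insertion time" deliberately: the multiset consensus
eventually absorbs every band, so insertion-time alignment depends on
insertion order and misses late-inserted bridge clones, whereas
best-member support is order-independent and flags precisely the
high-band-count clones whose accepted joins rest on partial matches
(chimeras, cross-contaminants) — any normally accepted overlap already
implies ~70% of bands matched. Contigs with two or more Q clones are
rebuilt at ten-fold stricter cutoffs until no contig keeps more than one.

## Pooled overgo deconvolution

576 probes fill a 24×24 grid; pools are its rows, columns and wrapped
diagonals ($d = (r+c) \bmod k$; the paper says only "diagonals", the
convention is configurable), so each probe sits in exactly three pools and
two probes never share more than one. For a positive pool set, candidate
probes are the positions whose three pools are all positive; the retained
answers are the inclusion-minimal candidate subsets covering the positive
set, found by exact enumeration (candidate sets are small by the Latin
property). One minimal cover is `UNIQUE`, several are `AMBIGUOUS`, none is
`INCONSISTENT`. Probes are classed low-copy (≤ 29 hits), moderately
(30–99) or highly (≥ 100) repetitive; ≥ 30 hits excludes a probe from
anchoring, > 50 from assembly — the boundary harmonisation ("<30" vs "30
or more" in the source descriptions) resolved toward the Methods wording.

## Anchoring and synteny

Hybridization filtering is sequential: probes with ≥ 30 hits are removed
on input tallies, then BACs with ≥ 8 distinct probes on the filtered
matrix. (Simultaneous tallies would be equivalent at the real library's
probe density but on a 20 Mb desk genome the ~120-copy repeat families
blanket every BAC with repetitive-probe hits, excluding everything — a
pure scale artifact.) A (marker, contig) record supported by a single
BAC-probe pair is a *weak anchor* and never places a contig on the map;
contigs with conflicting strong anchors are reported at all positions,
without arbitration.

Synteny anchoring chains a contig's query hits (BES and probe source
sequences, after removing queries with ≥ 10 hits) along each comparator
chromosome by single linkage with gaps strictly below the window (200 kb
or 1 Mb); chains with ≥ 2 distinct queries become anchors spanning their
hit positions. Coverage is the per-chromosome interval union; gene density
counts gene starts in 200 kb bins; enrichment compares covered bins
against the densest 30%.

## The synthetic world

The generator's defaults state the emulated conditions: 20 Mb desk genome
(the real one is 880 Mb; everything scales by configuration), 30% repeats
in families of ~120 copies of 500 bp units (budget corrected by
$-\log(1-f)$ for overlap), 160 kb organelle with 0.07% clone
contamination, 10× library of 100 ± 5 kb inserts, 3.5% failed
fingerprints, 0.5% chimeras, 0.6% cross-well contaminations, 13 linkage
groups at 600 kb/cM, 1 Mb synteny blocks with 0.3 duplicate-copy retention
and 10% hit loss.

Cut sites are homogeneous Poisson draws fixed *at the genome level*
(agarose: 1/4096 bp; HICF: five independent 1/2500 bp channels), so
overlapping clones share the fragments of their common interval exactly —
the property the whole method rests on. Only internal fragments count:
the two insert-boundary fragments carry vector sequence and are excluded
from band calling, as in the real protocol (including them would add two
private bands per clone and inflate CB lengths ~40% above spanned
length). Scoreable windows of [750, 10000] bp (agarose) and [100, 7600] bp
(HICF) calibrate the means to ~17.4 and ~178 bands; sizes map to gel units
through the conditional exponential CDF, which lands scoreable bands
*uniformly* on the gel — exactly the Sulston null — before comigrating
bands merge. HICF bands are encoded channel-wise
(`band = channel × 2000 + unit`) and match only within a channel. Noise
applies per-band dropout (2%), spurious bands (2%), and position jitter
(50% of bands, ≤ 2 units, below every tolerance in use); these rates are
our choices where the source states none, set once at what routine gel
scoring plausibly produces, and a single `noise = FALSE` switch zeroes
them together with chimeras and cross-well events for the recovery
oracles.

What a green recovery test establishes — and what it does not: on the
noise-free world with genome-level cut sites, co-contig pair precision and
recall against the truth overlap graph are exactly 1, because band
content is unique (repeat *copies* do not share fragments, since no
sequence is simulated — only probe hybridization sees repeats). Real
repeat families with conserved internal restriction sites, partial digest
artifacts, gel lane distortions and scoring OCR errors are outside the
model, so perfect desk recovery does not promise the real map's contig
counts; those are explicitly not reproduction targets.

## Numerical and degenerate-input choices

Cutoffs are compared with `<=`; denary steps multiply by exactly 10.
Ties everywhere break by clone id, then contig id, making every run a
pure function of (input, configuration, seed); module seeds derive from
one master seed by fixed offsets and stay below $2^{31}$. Degenerate
clones (< 2 bands) are set aside as permanent singletons. The DQ
recursion stops if the cutoff underflows $10^{-100}$, shedding members to
singletons rather than looping. `expected_contigs()` uses 4096 bp per
band (the 6-cutter expectation); CB-based coverage defaults to 4097 bp
(the reported all-fingerprint average) — with scoreable-window exclusion
this *underestimates* spanned length, as the source itself cautions; the
tests convert at the per-scoreable-band spacing (insert / mean bands
≈ 5.7 kb) when comparing against truth.

## Known limitations

Single-linkage assembly has no within-contig consistency check beyond DQ
splitting; the CB layout is a contract-bounded approximation, not FPC's
incremental build; HICF tolerance is absolute, not proportional to
fragment size; cross-well geometry assumes rook adjacency on one plate;
pooled deconvolution assumes pools hybridize on one membrane. The
desk-scale world keeps the full pipeline in minutes on one CPU — the
92,160-clone scale of the original project is configuration-reachable but
not performance-tuned.
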