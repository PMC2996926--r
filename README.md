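# fpmap — fingerprint-based BAC physical map construction

`fpmap` builds genome physical maps from BAC restriction fingerprints,
for genome projects that order large-insert clone libraries before (or
alongside) sequencing. It implements the full FPC-style workflow:

- **Sulston-score overlap calling** for single-enzyme agarose
  fingerprints (~17 bands/clone) and 5-enzyme high-information-content
  fingerprints (HICF, ~178 bands/clone), with exact log-space binomial
  tails;
- **contig assembly** with marker- and HICF-aware denary cutoff
  relaxation, consensus-band (CB) maps, Q-clone splitting, end-to-end
  merging, singleton adoption, clone burying, and cross-well /
  band-count QC;
- **pooled overgo deconvolution** on a 24×24 row/column/diagonal probe
  grid (576 probes, 72 pools), with exact minimal-cover semantics;
- **anchoring** of contigs onto a 13-group consensus genetic map (weak
  anchors excluded) and onto comparator genome sequences by window
  chaining of BAC-end/probe BLAST hits, with gene-density enrichment;
- **analytic calculators** — minimum matching-band thresholds, minimum
  informative band counts, Lander–Waterman expected contig numbers;
- a **synthetic genome/library simulator** with complete ground truth
  (repeats, organelle contamination, chimeras, cross-well events,
  whole-genome-duplicated comparators) for validating every stage.

## The model in brief

Two unrelated clones with $n_a, n_b$ bands on a gel of $G$ units share a
band within tolerance $t$ with per-band probability $p = 2t/G$. With
$\lambda = 1-(1-p)^{\max(n_a,n_b)}$, the Sulston score is the exact
binomial tail
$S(m) = \sum_{k\ge m}\binom{n_{lo}}{k}\lambda^k(1-\lambda)^{n_{lo}-k}$;
an overlap is called when $S$ is at or below the cutoff (1e-12 at the
integrated stage, relaxed by 2/3/4 denary steps for 1/2/3+ shared
markers). Expected contig counts follow the Lander–Waterman island
formula $E = N e^{-LN/G\cdot(1-T/L)}$ with $G$ the genome length in
band units.

## Worked example

```r
library(fpmap)
params <- score_params(tolerance = 7, gel_length = 5000, cutoff = 1e-12)

min_match_threshold(17, params)
#> [1] 12
min_informative_band_count(params)
#> [1] 8
sulston_score(17, 17, 11, params)
#> [1] 2.118409e-11
expected_contigs(lw_params(880e6, 4096, 92160, 17, 12))
#> [1] 10790.99
```

Seventeen-band clones need 12 matching bands to reach the 1e-12 cutoff —
11 shared bands score 2.1e-11 and are rejected unless markers or HICF
evidence relax the cutoff; clones under 8 bands can never form supported
joins; and a 92,160-clone, 17-band library is *expected* to fragment into
~10,800 contigs, which is why band number dominates agarose map quality.

A full synthetic run (5 Mb genome, 10×, noisy fingerprints, pooled
probes, integrated HICF pipeline):

```r
cfg      <- sim_config(genome_bp = 5e6, probe_count = 120)
truth    <- simulate_genome(cfg, 1)
clones   <- simulate_library(truth, derive_seed(1, 1))
profiles <- simulate_fingerprints(truth, clones, "AGAROSE", derive_seed(1, 2))
hicf     <- simulate_fingerprints(truth, clones, "HICF",    derive_seed(1, 3))
hits     <- simulate_probe_hits(truth, clones)
evidence <- data.frame(marker_id = hits$probe_id, kind = "PROBE",
                       clone_id = hits$bac_id)

asm <- run_integrated_pipeline(profiles, evidence, pipeline_config(),
                               hicf_profiles = hicf)
asm
#> <fp_assembly> stage=FINAL: 20 contigs, 55 singletons

evaluate_assembly(asm, truth, clones, params)[c("precision", "recall", "purity")]
#> $precision [1] 0.773   $recall [1] 0.905   $purity [1] 0.862

rec <- anchor_contigs(asm, filter_hybridization(hits)$pairs, truth$map)
length(unique(rec$contig_id[!rec$weak]))   # anchored contigs
#> [1] 20
sum(rec$weak)                              # weak anchors, never placed
#> [1] 13
```

With `sim_config(noise = FALSE)` the same pipeline recovers the clone
partition perfectly (pair precision = recall = 1) — the basis of the
acceptance suite.

## Command line

```sh
Rscript -e 'fpmap::fpmap_cli()' analytics --bands 17 --tol 7 --gel 5000 --cutoff 1e-12
# min_match_threshold(n=17, tol=7, gel=5000, cutoff=1e-12) = 12
# min_informative_band_count(tol=7, gel=5000, cutoff=1e-12) = 8
```

Subcommands `simulate`, `assemble`, `integrate`, `anchor`, `synteny`,
`analytics`, `evaluate` chain the stages over files (FPC "sizes" dialect,
TSV marker/map/pool tables, BLAST-tabular hits, BED/GFF3).

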