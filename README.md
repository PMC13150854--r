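# polyChIP

Classifying the direct and indirect target genes of a transcription factor
in an allopolyploid genome, from replicate ChIP-seq peak sets and
RNAi-line differential-expression tables.

When a transcription factor (TF) is knocked down, thousands of genes change
expression — but only a fraction of them are bound by the TF itself. In
polyploid crops the question is harder still: every gene exists as a set of
homoeologs contributed by different parental subgenomes, and binding is
often biased toward one subgenome. `polyChIP` implements the integration
that separates these layers:

1. **Tiered peak reproducibility.** Peaks from two biological replicates
   are filtered (fold enrichment > 2, q < 0.001), matched across
   replicates, and stratified into nested validation levels:
   - **VL1** — found in both replicates after filtering (≥ 1 bp overlap);
   - **VL2** — VL1 with summit distance ≤ 200 bp and IDR ≤ 0.05;
   - **VL3** — VL1 with summit distance ≤ 100 bp and IDR ≤ 0.05.

   The irreproducible discovery rate (IDR) follows the rank-based Gaussian
   copula mixture: replicate scores are reduced to ranks and modelled as
   `p · N₂(μ, μ, σ², σ², ρ) + (1 − p) · N₂(0, 0, 1, 1, 0)`; the local idr
   of a pair is the posterior probability of the irreproducible component,
   and the global IDR at a pair is the expected irreproducible fraction of
   all pairs at least as reproducible.

2. **Promoter-window target assignment.** A gene is a candidate target
   when a peak summit falls between 2 kb upstream and 100 bp downstream of
   its TSS (strand-oriented). Peaks are also classified into genomic
   features (promoter tiers, UTRs, exon, intron, downstream, distal) and
   profiled ±3 kb around TSSs.

3. **DEG integration.** Genes passing `|log2FC| ≥ 1` and `FDR ≤ 0.05`
   consistently across RNAi lines are the selected DEG set; selected genes
   with promoter binding are **direct targets** (per level), selected genes
   without are **indirect targets**. Octoploid gene calls are additionally
   collapsed to unique homoeolog groups.

4. **Subgenome binding bias.** Within each homoeologous chromosome group,
   observed peak counts per subgenome are tested against the
   chromosome-size-proportional expectation
   `E_s = N_group · L_s / Σ_t L_t` with a chi-square test (df = k − 1).

5. **Functional-bin enrichment** (one-sided hypergeometric with BH
   adjustment over a user-supplied hierarchical bin map) and
   **proximity-labeling filtering** (protein groups present in all bait
   replicates and absent from every control replicate).

A seeded synthetic-data generator emulates the target genome layout
(4 subgenomes × 7 chromosome groups, complete homoeolog quartets) with
planted reproducible peaks, planted DEGs, and bait/control proteomics
presence matrices, so the entire pipeline is testable without any external
download.

## Worked example

Simulate a scaled-down octoploid genome and run the one-shot pipeline:

```r
library(polyChIP)

cfg    <- simulationConfig(seed = 7)
genome <- simulateGenome(cfg, dir = "sim")
chip   <- simulateChipReplicates(cfg, genome, dir = "sim")
deg    <- simulateDegTable(cfg, genome, chip$targetGenes, dir = "sim")
prot   <- simulateProteomics(cfg, dir = "sim")

res <- runPipeline(
  list(layout = "sim/genome_layout.tsv", gff3 = "sim/genes.gff3",
       peaksRep1 = "sim/rep1.narrowPeak", peaksRep2 = "sim/rep2.narrowPeak",
       deg = "sim/deg_table.tsv", homoeologMap = "sim/homoeolog_map.tsv",
       proteomics = "sim/proteomics.tsv"),
  outDir = "out")

levelCounts(res$pairs)
#> VL1 VL2 VL3
#> 300 231 225
res$idrFit
#> IdrFit: n = 300 pairs, p = 0.861, mu = 2.241, sigma = 2.965, rho = 0.906
#>   converged after 835 iterations; 231 pairs with global IDR <= 0.05
res$summary
#> Classification of 400 selected DEGs
#>   VL1: 60 direct (15.0%), 38 down / 22 up / 0 mixed
#>   VL2: 45 direct (11.3%), 27 down / 18 up / 0 mixed
#>   VL3: 44 direct (11.0%), 26 down / 18 up / 0 mixed
#>   indirect: 340 (85.0%)
```

Reading the output: all 300 planted reproducible peaks were matched across
replicates (VL1); 231 of them carry a global IDR ≤ 0.05 and summit
distances ≤ 200 bp (VL2), 225 also within 100 bp (VL3). Of the 400
selected DEGs, 60 have a promoter peak and are called direct targets —
15.0%, matching the simulation's planted direct fraction — and the
mixture fit attributes 86% of matched pairs to the reproducible component
with inter-replicate score correlation 0.91. The proximity filter retains
exactly the 12 planted bait-exclusive protein groups (22 unique
proteins). `out/` holds the per-stage TSV/BED/JSON files plus
`manifest.json` with the parameters, input checksums and all stage counts.

A thin command-line wrapper around the same functions is provided at
`inst/scripts/polychip.R` (`simulate` and `run` subcommands).

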