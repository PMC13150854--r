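---
title: "Methods: reproducibility-tiered TF target classification in polyploids"
author: "polyChIP authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reproducibility-tiered TF target classification in polyploids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyChIP)
```

# The analysis problem

Silencing a ripening-regulator transcription factor (TF) in an
allo-octoploid fruit crop perturbs thousands of genes, but expression
changes alone cannot say which genes the TF binds and regulates directly.
`polyChIP` integrates two assays to make that distinction: replicate
ChIP-seq peak sets (where does the TF bind, and how reproducibly?) and
RNAi differential-expression tables (which genes respond to the
knockdown?). Because the host genome is an allopolyploid — four parental
subgenomes, seven homoeologous chromosome groups, every gene present as a
homoeolog quartet — the package also tests whether binding is biased
toward particular subgenomes and collapses octoploid gene calls to unique
homoeolog groups.

This vignette documents the models, the tunable parameters and their
defaults, the numerical choices, what the synthetic-data generator does
and does not emulate, and the known limitations.

# Peak reproducibility and validation levels

Each replicate's narrowPeak set is first filtered with strict
inequalities: fold enrichment **> 2** and q-value **< 0.001** (the
thresholds under which the peaks were called). Filtered peaks are then
matched across replicates: any ≥ 1 bp overlap is a candidate pairing, and
when a peak overlaps several partners the pair with the nearest summits
wins, ties broken by larger overlap, then lexicographic peak name. The
greedy acceptance over this deterministic ordering makes the matching
symmetric in the two replicates and reproducible run to run.

Matched pairs are stratified into nested validation levels, read
cumulatively:

| level | summit distance | IDR | meaning |
|-------|-----------------|------|---------|
| VL1 | — | — | found in both replicates after filtering |
| VL2 | ≤ 200 bp | ≤ 0.05 | reproducible summit position |
| VL3 | ≤ 100 bp | ≤ 0.05 | tightly reproducible summit position |

Distance and IDR thresholds are non-strict (≤), the filter thresholds
strict (>, <), exactly as stated above; all five are arguments of
`filterPeaks()` and `assignValidationLevels()`.

## The IDR model and how it is fitted

The irreproducible discovery rate follows the standard rank-based
Gaussian copula mixture (Li et al. 2011). Per-replicate scores (fold
enrichment by default; the −log10 q channel is a config option, since
either could plausibly drive the ranking) are reduced to ranks,
\(u_i = r_i/(n+1)\), and mapped to pseudo-data \(z_i = G^{-1}(u_i)\)
under the mixture marginal \(G\). The joint model is

\[
(z_1, z_2) \sim p\, N_2\!\big((\mu,\mu), \sigma^2, \rho\big)
 + (1-p)\, N_2\!\big((0,0), 1, 0\big),
\]

with the irreproducible component fixed at independent standard normal.
The **local idr** of a pair is the posterior probability of the
irreproducible component; the **global IDR** at a pair is the running
mean of local idr over all pairs at least as reproducible — the expected
irreproducible fraction of the set selected by thresholding at that pair.
Validation levels threshold the global IDR, the quantity with the
set-level error-rate interpretation.

**Numerical choice: direct copula likelihood instead of ECM.** The
textbook fitting recipe alternates an EM pass with a refresh of the
pseudo-data under the updated marginal. We implemented that first and
found two failure modes on realistic inputs. On nearly pure-reproducible
data (the regime a successful ChIP experiment produces) the refresh
creates a shrinkage feedback: rank-based quantiles have slightly deflated
sample variance, each refresh therefore shrinks \(\sigma\) geometrically,
and the iteration never stabilises. On dependence-free data the
alternative component can instead run away with the entire sample
(\(p \to 1\)), calling everything reproducible — the wrong direction.
Both pathologies vanish when the *true* copula likelihood is maximised,
i.e. the joint mixture density divided by the product of its marginals:
the Jacobian term cancels every marginal-fit artefact, leaving only the
dependence structure to be scored. `estimateIdr()` therefore maximises
the penalised copula log-likelihood directly with Nelder-Mead over the
four parameters (bounded transforms: \(p \in [10^{-4}, 0.9999]\),
\(\mu \in [0.01, 8]\), \(\sigma \in [0.2, 5]\),
\(\rho \in [0, 0.9999]\)), from three fixed starts including the
conventional \((p, \mu, \sigma, \rho) = (0.5, 1, 1, 0.2)\).

Two safeguards resolve the remaining degeneracies:

* a weak \(\log(1-p)\) penalty breaks the label ambiguity of
  dependence-free data toward "irreproducible" (its influence on a real
  mixture is \(O(1/n)\));
* a likelihood-ratio screen: when the copula log-likelihood gain over the
  independence null is below \(\chi^2_{3,0.99}/2\), the fit is declared
  signal-free and every pair receives local idr ≈ 1. Genuinely weak
  signal near this boundary is treated conservatively.

Under this estimator, simulated mixtures with \(p = 0.7, \rho = 0.8\) at
\(n = 2000\) are recovered to within about ±0.03 on both parameters
(the test suite asserts ±0.1); perfectly correlated replicates drive all
pairs to global IDR ≈ 0, and independent replicates drive all pairs
above 0.5. Fits on fewer than 20 pairs are refused as unstable, and
all-tied score vectors are rejected because ranks carry no information.

# Peak annotation and target assignment

Every matched pair is represented by its merged summit (midpoint of the
two replicate summits) — profiles and containment are summit-based
because the summit is the best point estimate of the binding site;
interval-based containment would make target calls a function of peak
width, which varies with sequencing depth.

Feature classification assigns exactly one category per peak by fixed
priority: promoter tiers (0–1, 1–2, 2–3 kb upstream of a TSS) >
5′ UTR > 3′ UTR > exon > intron > downstream (0–3 kb past the gene
end) > distal intergenic. Promoter outranks genic because a summit
upstream of one gene and inside another is more plausibly regulatory.
Within a category the gene with the nearest TSS wins; exact-distance
ties prefer the gene the peak is upstream of, then the lexicographically
smaller gene id — an arbitrary but deterministic rule.

The promoter window for target assignment runs from **2 kb upstream to
100 bp downstream** of the TSS, strand-oriented, both ends inclusive. A
single peak may support several genes (divergent promoters); shrinking
the window can only remove targets (a property the tests assert). TSS
profiles bin the signed summit–TSS distance over ±3 kb (default 50 bp
bins; the bin width must divide the window).

# DEG selection and target classification

The expression input is a long table of per-contrast statistics (gene ×
RNAi line × ripening stage). A contrast qualifies when
\(|\log_2 FC| \ge 1\) and FDR ≤ 0.05 (inclusive, as printed). Whether a
*gene* is selected depends on two rules:

* `requireBothLines` (default TRUE): every RNAi line in the table must
  qualify — consistency across independent silencing lines is the main
  guard against off-target RNAi effects;
* `stageRule`: `"any_stage"` (default) asks each line to qualify in at
  least one stage; `"both_stages"` in every stage. The pooled DEG count
  that anchors the published percentages spans the two stages' DEG sets,
  which is what `any_stage` reproduces; the stricter reading is
  implemented and selectable, and the choice is recorded in the output
  metadata. Neither mode is asserted as "the" published selection — the
  prose is genuinely ambiguous.

Direction is `down` when all qualifying log2FCs are negative, `up` when
all positive, `mixed` otherwise. Mixed genes form their own bucket; the
down/up percentages are computed over the down+up dichotomy only, which
is also how the published 61.2%/38.8% arithmetic works out (581 and 369
over 950). Percentages are rounded half away from zero to one decimal to
match printed values; with zero selected genes they are NA, not 0.

A selected gene bound at any level is **direct** (at every level up to
its highest binding tier — the per-level direct sets inherit the VL
nesting); a selected unbound gene is **indirect**; bound but unselected
genes are reported as `bound_not_DE`. Genes missing from the homoeolog
map are kept and counted in an `unmapped` bucket, because both octoploid
gene counts and collapsed homoeolog counts are reported.

# Subgenome binding bias

Within each homoeologous chromosome group, the expected count for a
subgenome's chromosome is the group total apportioned by chromosome
length, \(E_s = N_g \cdot L_s / \sum_t L_t\); expected counts stay
real-valued for the statistic (rounding is display-only). The test is
Pearson's \(\chi^2 = \sum (O-E)^2/E\) with df = k − 1 against the
chi-square survival function. Tests are per group (df = 3 in the
four-subgenome case) because the biological question — which subgenome
dominates within a homoeologous set — is group-wise; a single pooled
contingency test is easily composed from `countPeaksByChromosome()` if
wanted. Per-group p-values are reported uncorrected by default (the
source analysis states no correction), with Bonferroni-adjusted values
alongside so the reader can apply either. A zero expected cell (empty
chromosome group) is an error advising pooling rather than a silent
continuity fix. Restricting the test to promoter-proximal peaks is the
same machinery applied to a pre-filtered peak set. Under the
size-proportional null the test's empirical type-I error at
\(\alpha = 0.05\) is calibrated (asserted within [0.03, 0.07] over 1000
simulated draws); no mappability- or GC-corrected null is attempted.

# Functional-bin enrichment

`enrichBins()` is a generic over-representation test for hierarchical
bin maps (MapMan-style `a.b.c` paths, truncated to the requested level).
The test is the one-sided hypergeometric upper tail — the ontology's own
tooling does not document its internal test, so the choice is made
explicit here and in the output — with Benjamini–Hochberg adjustment
across tested bins and a top-k selection utility (default 10, matching
the usual "top ten bins" presentation). The official ontology is not
bundled; any two-column gene→bin map works, and the tests ship a toy
three-level ontology. The default universe is all annotated genes;
restricting to expressed genes is the caller's choice.

# Proximity-labeling filter

Protein groups are retained when present in **all** bait replicates
(configurable to ≥ k) and absent from **every** control replicate
(configurable off). "Present" is a boolean from the upstream MS
pipeline, with a peptide-count ≥ 1 binariser for raw-count tables;
no PSM-level modelling is attempted. Unique-protein counts deduplicate
members across retained groups. When the evidence table carries one row
per peptide, `unit = "peptide"` requires every peptide row of a group to
be present in a replicate before the group counts as present there — the
stricter of the two readings of "present across replicates".

# The synthetic-data generator

`simulationConfig()` fixes the study conditions for all tests. The
generator emulates, at desk scale, the structure the analysis assumes:

* **Genome**: 7 groups × 4 subgenomes = 28 chromosomes (~300 kb ± 30 kb
  each), 40 genes per chromosome in complete homoeolog quartets, random
  strands, 1–3 exons, 150 bp terminal UTRs on genes wide enough. The
  scaled-down chromosome size keeps whole-pipeline tests in seconds
  while preserving every structural property the code depends on
  (strand-oriented windows, group/subgenome layout, quartet structure).
* **ChIP replicates**: 300 planted reproducible peaks at promoters of
  sampled genes (−1500 to +50 bp around the TSS), shared fold enrichment
  2 + lognormal(0.8, 0.6) so every planted peak passes the > 2 filter,
  per-replicate summit jitter N(0, 30 bp) — the scale of summit
  variation a well-behaved ChIP experiment shows — and multiplicative
  per-replicate score noise (sdlog 0.1). Irreproducible noise peaks are
  added independently per replicate at rate 0.2 of the planted count,
  plus 10% sub-threshold "weak" peaks that the VL1 filter must remove.
  A per-subgenome placement multiplier plants binding bias when not
  uniform.
* **DEG table**: 400 planted consistent DEGs (|log2FC| = 1 + Exp(1),
  same sign everywhere, FDR ≤ 0.045 in both lines and stages), of which
  15% are drawn from peak-bearing genes — the planted direct fraction,
  mirroring the scale of the real integration — and 60% are
  downregulated, as expected for silencing an activator. Null genes get
  N(0, 0.2) effects and uniform FDR, making false selection essentially
  impossible (≈ 6 × 10⁻⁷ per contrast, to the fourth power across
  contrasts). FDRs are assigned directly: simulating counts and a DE
  model would test someone else's estimator, which is out of scope.
* **Proteomics**: 12 planted bait-exclusive groups (subject to a
  configurable dropout per bait replicate), 30 background groups forced
  to appear in the control, three replicates per condition.

All randomness flows from the config seed through fixed per-stage
substreams, so regenerating one stage never perturbs another's draws,
and equal seeds give byte-identical files.

What the generator does **not** emulate: read-level artefacts
(mappability, GC, duplication), realistic peak shapes and widths,
correlated DEG effects along pathways, homoeolog expression correlation,
and shared peptides between unrelated protein groups. Passing tests
therefore demonstrate the correctness of the integration logic and the
calibration of its statistics under the stated model — not robustness to
upstream artefacts, which belongs to the peak caller and DE model that
sit outside this package.

# Problem sizes used by the test suite

Whole-pipeline tests run on the 1120-gene genome above; oracle-equality
tests use ≤ 10³ × 10³ gene-peak instances against brute-force scans;
IDR parameter recovery uses n = 2000 pairs; chi-square calibration uses
1000 null draws and power uses 100 replicates of 2000 biased peaks.
These sizes were chosen so each statistical assertion has enough
resolution for its tolerance (e.g. a ±0.02 binomial standard error on
the type-I rate) while the full suite stays in a few minutes.

# Known limitations

* IDR is estimated on the two true replicates only; pseudo-replicate
  workflows are not implemented.
* The LR screen makes the IDR conservative near the no-signal boundary.
* Transcript isoforms are not modelled; the TSS is the gene-model start,
  and UTR categories apply only where the GFF3 annotates UTRs.
* The promoter-outranks-genic priority table is a convention, not a
  published specification; alternative priorities change only
  `classifyFeature()`, not target assignment.
* The subgenome test conditions on total peak count per group and
  assumes placement-length proportionality under the null; copy-number
  or assembly-quality differences between subgenomes would violate it.
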