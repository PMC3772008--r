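# SoilMnOx

Community analysis of soil manganese(II)-oxidizing bacteria: activity
assays, ARDRA, DGGE fingerprints and 16S phylotyping.

## What it is for

Surveys of Mn(II)-oxidizing bacteria in stratified soils combine four
computational stages, and SoilMnOx implements all of them as one tested R
pipeline:

1. **Activity quantification** — leucoberbelin blue (LBB) readings at
   620 nm are calibrated against KMnO4 standards, converted to
   MnO2-equivalent concentrations (1 µM MnO2 ↔ 0.4 µM KMnO4), binned into
   four categories — high (≥ 50 µM), medium ([10, 50)), low ([1, 10)),
   none (< 1) — and cross-tabulated by soil horizon (A/B/C).
2. **In-silico ARDRA** — 16S amplicons are digested with HaeIII (GG^CC)
   and Sau3AI (^GATC); isolates are grouped by HaeIII pattern, regrouped
   within each group by Sau3AI pattern, and one representative per group
   is flagged for sequencing.
3. **DGGE densitometry** — bands are called from 1-D lane traces
   (smoothing, rolling-minimum baseline, prominence filter, and the rule
   that a band's relative peak height must exceed 1%); each lane gets a
   Shannon index H = −Σ Pᵢ ln Pᵢ over band probabilities Pᵢ = nᵢ/N, and
   lanes are compared by the band-pattern distance
   D = Σ|Aᵢ − Bᵢ| / P with P = n_A + n_B − c (c = shared bands, absent
   bands counting zero), then ordinated by classical or non-metric MDS
   (Kruskal stress-1).
4. **Phylotyping and trees** — pairwise p-distances cluster sequences into
   phylotypes at < 3% divergence (complete linkage); Kimura two-parameter
   distances, d = −½ln(1 − 2P − Q) − ¼ln(1 − 2Q), feed a from-scratch
   Saitou–Nei neighbor-joining implementation with column-resampling
   bootstrap supports, written as Newick.

A synthetic-data module (random Yule trees, closed-form K2P sequence
evolution, Gaussian-mixture gel lanes, prescribed activity tables) makes
the whole pipeline runnable and testable with no external data.

## Worked example

```r
library(SoilMnOx)

# activity survey with a prescribed horizon x category structure
rec <- simulateActivityTable(list(A = c(8, 32, 143, 9),
                                  B = c(22, 17, 54, 67),
                                  C = c(20, 29, 19, 83)), seed = 1)
tab <- tabulateActivity(rec)
tab
#> ActivityTable: horizon x activity-category counts
#>          high medium low none Total
#> A           8     32 143    9   192
#> B          22     17  54   67   160
#> C          20     29  19   83   151
#> Compiled   50     78 216  159   503
columnPercentages(tab)
#>   high medium    low   none
#>    9.9   15.5   42.9   31.6

# DGGE: simulate three horizon lanes, call bands, summarize diversity
lanes <- simulateCommunityLanes(seed = 1)   # richness 20/12/8 bands
bsets <- lapply(lanes, detectBands)
round(vapply(bsets, shannonIndex, numeric(1)), 3)
#>     A     B     C
#> 2.953 2.441 2.043

# phylotypes and a bootstrapped NJ tree from a simulated alignment
tr  <- simulateTree(6, seed = 4, meanBranchLength = 0.08)
aln <- simulateAlignment(tr, 1000, kappa = 2, seed = 4)
clusterPhylotypes(aln)
#> PhylotypeAssignment: 6 sequence(s) in 6 phylotype(s) at <3% divergence
writeNewickTree(bootstrapSupport(aln, replicates = 100, seed = 4))
#> (t4:0.0307...,(t5:0.0262...,(t3:0.2217...,t6:0.0245...)100:0.0589...)100:0.0429...,
#>  (t1:0.1013...,t2:0.0371...)74:0.0032...);
```

The compiled row says 50 + 78 + 216 = 344 of the 503 isolates (68.4%)
show Mn(II)-oxidizing activity; the percentage vector gives each
category's share of all isolates. The Shannon values fall from the A- to
the C-horizon lane because the simulated richness gradient (20/12/8
bands) carries through band calling. In the Newick string, integer labels
on internal nodes are bootstrap percentages out of 100 replicates.

`runPipeline(config, outDir)` chains all stages (activity | ardra |
dgge+MDS | phylo) from a YAML or list config, writing CSV/Newick outputs
plus a `manifest.txt` with the package version, seeds and parameters;
reruns with the same config are byte-identical.

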