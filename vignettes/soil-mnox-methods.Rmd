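---
title: "Methods: quantifying and fingerprinting soil Mn(II)-oxidizing bacterial communities"
author: "SoilMnOx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying and fingerprinting soil Mn(II)-oxidizing bacterial communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SoilMnOx)
```

SoilMnOx implements the computational side of a stratified-soil survey of
manganese(II)-oxidizing bacteria: colorimetric activity quantification,
restriction-fragment grouping of isolates (ARDRA), diversity and similarity
analysis of DGGE community fingerprints, and 16S rRNA phylotyping with
distance-based phylogenetics. This vignette explains each model and
procedure, the parameters that matter, and the choices made where the
methodology was genuinely open. Every number shown here is computed by the
chunk that prints it.

## Activity assay: from absorbance to categories

The leucoberbelin blue (LBB) assay reads oxidized manganese at 620 nm
against KMnO4 standards. `fitCalibration()` fits the standard line by
ordinary least squares; because Beer–Lambert behavior implies zero
absorbance at zero concentration, a through-origin fit is available
(`throughOrigin = TRUE`), and the default intercept fit makes any baseline
offset visible rather than hidden.

Oxidized-Mn content is expressed as the MnO2-equivalent concentration, with
the fixed stoichiometric reading that 1 µM MnO2 corresponds to 0.4 µM
KMnO4, so `kmno4ToMno2()` is linear through the origin:

```{r}
kmno4ToMno2(0.4)
mno2ToKmno4(1)
```

Isolates are binned into four activity categories: high (≥ 50 µM MnO2),
medium (10–50), low (1–10), none (< 1). The interior boundaries are
half-open, closed on the left — `[10, 50)`, `[1, 10)` — mirroring the
inclusive "≥ 50" convention at the top. A reading of exactly 50 µM is
therefore "high" and exactly 10 µM is "medium":

```{r}
categorizeActivity(c(50, 10, 1, 0.99))
```

`tabulateActivity()` cross-tabulates horizon × category and reports two
percentage views: each category's share of all isolates, and each horizon's
share within a category. Percentages are rounded to one decimal for
presentation (pass `digits = NA` for raw ratios).

```{r}
rec <- simulateActivityTable(list(A = c(8, 32, 143, 9),
                                  B = c(22, 17, 54, 67),
                                  C = c(20, 29, 19, 83)), seed = 1)
tab <- tabulateActivity(rec)
tab
columnPercentages(tab)
withinCategoryPercentages(tab)
```

## In-silico ARDRA

Amplified ribosomal DNA restriction analysis types isolates by the fragment
patterns of their 16S amplicons. `digestSequence()` scans the linear
sequence for every occurrence of the enzyme's recognition site (HaeIII
GG^CC and Sau3AI ^GATC are built in), including overlapping occurrences,
cuts at the enzyme's offset, and drops zero-length pieces; fragment lengths
always sum to the sequence length. The ambiguity code N never matches.

Grouping is two-stage, as in the wet protocol: isolates are first
partitioned by HaeIII pattern, and each HaeIII group is re-partitioned by
Sau3AI pattern. Pattern equality defaults to exact multiset equality
(tolerance 0), the natural criterion for in-silico lengths. Because real
gels cannot resolve near-equal lengths or very short fragments, a "gel
mode" preset (`ardraGelMode()`: 5% length tolerance, 50 bp detection floor)
emulates agarose resolution; under a nonzero tolerance the pattern relation
is no longer transitive, so groups are its single-linkage closure, which is
the only order-independent way to make grouping well defined. Each group's
representative — the isolate one would send for sequencing — is the
lexicographically smallest id, a deterministic stand-in for an unstated
manual choice.

```{r}
seqs <- simulateAmplicons(nGroups = 3, copies = 2, length = 600, seed = 1)
groupByArdra(seqs)
```

## DGGE band calling, Shannon diversity and lane distance

A DGGE lane is represented by its 1-D densitometric trace
(`LaneProfile`). `detectBands()`:

1. smooths with a 5-sample moving average (window configurable);
2. subtracts a rolling-minimum baseline (51 samples) and clips at zero;
3. takes interior local maxima whose topographic prominence is at least
   2% of the maximum intensity as candidate bands;
4. applies the detection rule that only bands whose relative peak height
   (peak height over summed candidate peak height) exceeds 1% are retained;
5. renormalizes the significant probabilities P_i = n_i / N over the
   retained bands.

The 1% rule is applied before renormalization; filtering first and then
renormalizing keeps Σ P_i = 1 exactly, and the order is switchable in
principle because the probabilities are recomputed from retained heights.
Defaults (smoothing 5, baseline 51, prominence 0.02) were chosen for
2,000-sample traces with band widths of a few per mil of lane length; all
are arguments.

Diversity is the Shannon index H = −Σ P_i ln P_i, in natural log units.
The choice of nats (rather than bits) is a configuration option; values
around 2–3 for many-band lanes are consistent with nats.

```{r}
lane <- simulateLane(laneSpec(c(0.2, 0.5, 0.8), c(2, 1, 1), noiseSd = 0,
                              samples = 2001L), "demo", seed = 1)
bs <- detectBands(lane)
bands(bs)
shannonIndex(bs)
```

Lane similarity uses band-presence bookkeeping: with n_A and n_B bands per
lane and c bands common to both (greedy nearest-position matching within a
tolerance of 0.01 of normalized lane length), P = n_A + n_B − c is the
number of distinct band positions. The implemented distance is

D = Σ |A_i − B_i| / P

over those P positions, where A_i and B_i are the significant
probabilities and a band absent from a lane contributes zero. D is 0 for
identical patterns and at most 1 because each lane's probabilities sum
to 1. The exact algebraic form of the original similarity function was
published only as a figure; this form uses every quantity the text defines
(A_i, B_i, absent-as-zero, P) and is exposed as a named strategy so a
presence/absence alternative (Dice, `strategy = "dice"`) can be swapped in
without touching callers — it is a declared reconstruction, not a claim
about the original expression.

## Ordination

`classicalMDS()` (Torgerson double-centering, via `stats::cmdscale`)
provides the metric embedding and the eigenvalue spectrum, including the
negative eigenvalue mass that measures how non-Euclidean the lane distances
are. `nonmetricMDS()` minimizes Kruskal stress-1 with monotone regression
of disparities on distance ranks (via `vegan::monoMDS`, global model,
primary tie treatment), initialized from the classical solution — the
standard practice for community fingerprints, and the package default,
since only the rank order of band-pattern distances is trustworthy.
Convergence uses a relative stress-change tolerance of 1e-6 with at most
300 iterations; the result records the final stress and a convergence
flag. Because the start is deterministic, repeated runs on the same matrix
give identical coordinates. Axis units are arbitrary: configurations are
comparable only up to rotation, reflection and scaling, so scores from
different gels must not be overlaid.

```{r}
set.seed(2)
lanes <- lapply(1:6, function(i) {
  k <- sample(4:9, 1)
  bandSet(paste0("L", i), sort(runif(k, 0.05, 0.95)), runif(k, 0.5, 3))
})
d <- laneDistanceMatrix(lanes)
ord <- nonmetricMDS(d)
ord
```

## Phylotyping and phylogenetics

Sequence divergence uses pairwise deletion: a site contributes only if both
characters are unambiguous bases, gaps and N being excluded pair by pair
(complete deletion is available). The uncorrected p-distance drives
phylotype clustering; the Kimura two-parameter distance,

d = −½ ln(1 − 2P − Q) − ¼ ln(1 − 2Q),

with P and Q the transition and transversion fractions, corrects for
multiple hits and is used for tree building. Saturated pairs (log argument
≤ 0) are flagged undefined rather than truncated.

Phylotypes group sequences that differ by less than 3%. The original
protocol does not state a linkage; complete linkage is the default because
it is the only choice under which the "< 3%" guarantee holds for *every*
pair inside a phylotype (single and average linkage are available).
Reading "differed by < 3%" as uncorrected p-distance follows standard
OTU-grouping practice; the distance model is configurable. The cut is
strict: a pair at exactly 3% is split.

`neighborJoining()` is a from-scratch Saitou–Nei implementation: join the
pair minimizing Q_ij = (n−2)d_ij − Σd_ik − Σd_jk, standard branch-length
formulas, ties broken by the smallest (i, j) pair so results are
reproducible. Negative branch lengths, which NJ can produce on
non-additive input, are retained by default (`clampNegative = TRUE` to
floor them at zero). On additive matrices the generating topology and
branch lengths are recovered exactly. `bootstrapSupport()` resamples
alignment columns with replacement, rebuilds the NJ tree per replicate,
and scores each non-trivial bipartition of the full-data tree by its
replicate percentage; replicates with undefined distances are skipped and
counted. 1,000 replicates is the conventional publication setting; the
package's own tests run 50–100 replicates on quartet alignments, which is
ample to saturate support on a well-separated topology.

```{r}
tr <- simulateTree(6, seed = 4, meanBranchLength = 0.08)
aln <- simulateAlignment(tr, 1000, kappa = 2, seed = 4)
clusterPhylotypes(aln)
bt <- bootstrapSupport(aln, replicates = 50, seed = 4)
writeNewickTree(bt)
```

## The synthetic-data generators

Every analysis stage can be exercised without external data:

* `simulateTree()` grows a Yule (equal-rates) topology by splitting a
  uniformly chosen tip, with i.i.d. exponential branch lengths (default
  mean 0.05 substitutions/site).
* `simulateAlignment()` evolves a uniform random root sequence down the
  tree using the closed-form K2P site transition probabilities per branch
  (with α + 2β = 1 so branch length equals expected substitutions/site):
  exact for any branch length and far faster than event-by-event
  simulation. A two-taxon simulation at total divergence 0.2 with 100,000
  sites re-estimates the distance within ±0.01.
* `simulateLane()` renders a lane as a Gaussian band mixture on a flat
  baseline with additive Gaussian noise, clipped at zero.
  `simulateCommunityLanes()` draws per-horizon lanes from a shared pool of
  30 band positions on [0.05, 0.95] with lognormal(0, 0.35) intensities;
  the default richness gradient 20/12/8 bands for A/B/C horizons mirrors
  the surface-to-substratum loss of diversity qualitatively, so estimated
  H decreases down the profile. These are illustrative defaults, not
  claims about any particular gel.
* `simulateActivityTable()` emits isolate records drawn uniformly within
  each category's interval (high values in [50, 240] µM, matching the
  observed activity range), so tabulation reproduces any requested count
  structure exactly.

What the generators do *not* emulate matters for interpretation: no PCR or
primer bias, no GC-clamp melting behavior, no co-migration of distinct
sequences to one band, no silver-stain response nonlinearity, no lane
warping. Passing tests on synthetic lanes therefore demonstrate that the
*computational* chain is correct and self-consistent, not that band
calling would be this clean on a scanned gel; published per-gel Shannon
values cannot be reproduced without the original densitometry.

## Numerical choices and degenerate inputs

* Band detection quantizes intensities to a relative 1e-9 grid before
  locating run-length maxima, so floating-point jitter on flat stretches
  cannot fabricate peaks; flat or monotone profiles yield an empty band
  set with a warning rather than an error.
* Two empty lanes compare at distance 0 (with a warning); an empty band
  set has no Shannon index (error).
* The phylotype cut subtracts 1e-9 from the threshold before cutting the
  dendrogram so that "less than" is strict at representable boundaries.
* Classical MDS truncates to the available positive eigenvalues with a
  warning; the all-zero matrix embeds at the origin.
* Pipeline runs (`runPipeline()`) are pure functions of (config, seed):
  reruns produce byte-identical CSVs on one platform. Floating-point
  results may differ in the last bits across BLAS builds.

## Problem sizes

The bundled tests and the acceptance script use deliberately small
problems chosen to exercise every code path at interactive speed: 2,000 or
2,001 samples per simulated lane, three-lane gels, alignments of
400–2,000 sites (100,000 for the two-taxon parameter-recovery check),
quartet bootstraps at 50–100 replicates, and 100 six-taxon trees for NJ
topology recovery. All scale linearly if larger studies are needed.

## Known limitations

* The lane distance is a reconstruction of a figure-only formula (see
  above); comparisons against the original software are not possible.
* Non-metric MDS recovers configurations only up to monotone transforms of
  distance; stress values, not coordinates, are the comparable quantity.
* K2P assumes equal base frequencies and no rate variation across sites;
  for 16S fragments at the divergences involved (< 0.25
  substitutions/site) this is standard practice.
* ARDRA gel mode is an idealized resolution model (relative tolerance +
  detection floor); partial digestion and methylation sensitivity are not
  modeled.
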