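---
title: "msimg: methods, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{msimg: methods, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msimg)
```

# The representation problem

A single untargeted LC-MS run is a sequence of scans, each pairing an m/z
array with an intensity array at one retention time. After m/z binning the
run is a large, sparse, non-negative matrix — routinely thousands of scans
by tens of thousands of bins — in which biologically informative signal
concentrates in small, dense islands (elution peaks and their isotope and
adduct companions) on a near-empty background. `msimg` encodes each run as
a small stack of image patches centered on those islands, selected once on
the training set and applied unchanged everywhere. The two properties this
buys are: no cross-sample retention-time alignment (patch locations are
shared indices, not matched features), and no peak integration (the raw
normalized intensities inside each patch are preserved for the downstream
model to interpret).

# Pipeline and assumptions

## Binning and normalization

An ion at m/z value $m$ lands in bin $\lfloor (m - mz_{min})/bin\_size
\rfloor$; intensities in a bin are summed per scan. Ions outside
$[mz_{min}, mz_{max})$ are dropped (the rule is undefined there) and
counted. Scans are row-ordered by retention time (ties keep file order) and
empty scans keep their all-zero row, so row index is always scan index.
Only MS1 scans are read by default; `readSpectra(msLevel = NULL)` keeps all
levels.

The matrix is then scaled so that the 99.9th percentile of its *non-zero*
entries maps to 1, and clipped to $[0,1]$. The percentile is computed as
the **ceiling order statistic** (inverse-CDF definition): the smallest
sorted value with at least the requested mass at or below it. This choice
is deliberate: an order statistic is always an attained data value, so the
contract "the percentile value becomes exactly 1.0 after scaling" holds
exactly, and re-measuring the percentile on the normalized output returns
1.0 to machine precision. Under an interpolated percentile the scale
generally falls strictly between two data values and the re-measured output
percentile lands strictly below 1 by an amount that depends on the local
order-statistic gap — a needless source of irreproducibility. The
assumption behind percentile (rather than max) scaling is that the extreme
top of the intensity distribution is dominated by a handful of saturated
ions; clipping them to 1 sacrifices nothing the classifier needs.

## Density map and non-maximum suppression

The signal mask keeps pixels with normalized intensity strictly greater
than $\tau_{intensity}$; the density map counts mask pixels in a $w \times
w$ box window around each pixel, with windows clipped at the borders
(equivalently, zero-padded mask). The implementation uses a summed-area
table, which is exact for 0/1 counts; the unit tests compare it against a
literal nested-loop window sum.

NMS then iterates: take the global density argmax (ties broken by smallest
row, then smallest column — runs are bit-reproducible), record it if its
density is at least $\tau_{density}$, and zero a patch-sized rectangle
around it on a working copy. For a size $s$ the rectangle spans
$[-\lfloor s/2 \rfloor, +\lceil s/2 \rceil - 1]$ around the peak — the
symmetric window for odd $s$, and a documented, deterministic convention
for even $s$. Iteration stops at the per-sample budget or when the maximum
falls below threshold.

## Greedy coverage selection of patch centers

Per-sample candidates are pooled over the training set. Each selection
round scores every still-available point by the number of available points
(itself included) within Euclidean distance $r = \sqrt{(h/2)^2 + (w/2)^2}$
— the patch's center-to-corner distance — selects the argmax, and marks its
whole circle unavailable. Distances are in pixel units on (row, col): the
matrix is treated as an image, with no physical rescaling of the RT or m/z
axes. The circle boundary is inclusive ($d \le r$, implemented on squared
distances with a $10^{-9}$ slack so exact geometric ties are kept inside).

Three points here were genuinely open and are resolved as package design
choices:

* **The candidate subset each round.** Scores are recomputed over *all*
  currently available points every round — exact greedy. Any proper-subset
  variant would need an extra, undefined selection rule; exact greedy is
  unambiguous, reproducible, and cheap at realistic pool sizes.
* **The stopping rule.** "Remaining peak density too low" is
  operationalized as: stop when the best achievable coverage score falls
  below $\tau_{min\_peaks}$. A coverage score *is* a local peak density, and
  this form makes the isolated-straggler case exact: a lone point scores 1
  and is rejected for any threshold above 1.
* **Tie-breaking.** Equal scores resolve to the smallest row, then smallest
  column, for determinism.

Because a later selection must have been outside every earlier circle, any
two returned centers are more than $r$ apart — patches cannot collide. The
spatial index behind the radius queries is a chunked vectorized distance
computation; the tests verify it is point-for-point identical to an
all-pairs brute-force greedy.

## Entropy ranking and image construction

Each selected center is scored by the mean over training samples of the
patch entropy $H(P) = -\sum_{k=0}^{255} p_k \log_2 p_k$, where $p_k$ is the
proportion of patch pixels whose intensity quantizes to level $k =
\mathrm{round}(255\,v)$ (clamped to $[0,255]$). $H$ ranges from 0 bits
(constant patch) to 8 bits (uniform over all levels). Padded cells
participate in the histogram like any other pixel — the patch is scored as
extracted. Entropy ties in the ranking keep the coverage-selection order.
The top `num_patches` locations are frozen; every sample's image is the
stack of its patches at those locations, in ranking order, with dimension
order (channels, height, width). Patch extraction maps the center to patch
cell $(\lfloor h/2 \rfloor + 1, \lfloor w/2 \rfloor + 1)$ (1-based) and
pads out-of-matrix cells with `padValue`.

Train/test hygiene is structural: candidate generation, coverage selection
and entropy ranking run only inside `msimgFit()`; `msimgTransform()` only
extracts patches at frozen coordinates, and a model restored from its JSON
serialization transforms samples bit-identically to the in-memory original.

# Parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `bin_size`, `mz_min`, `mz_max` | — | Da | Study-specific; no universal default exists. Required configuration. |
| `percentile` | 99.9 | % of non-zero values | Normalization scale. |
| `tauIntensity` | 0.01 | fraction of normalized scale | Above typical electronic/chemical baseline, below any peak of interest. |
| `window` (w) | 9 | pixels, odd | Roughly the footprint of a chromatographic peak across scans at typical sampling rates. |
| `tauDensity` | 5 | mask pixels | Floor on hotspot evidence; raise toward w²/2 for noisy data (the synthetic studies here use 20, see below). |
| `maxPeaks` | 100 | peaks/sample | Per-sample NMS budget. |
| `patchHeight`, `patchWidth` | 224 | pixels | Matches common CNN input conventions; the synthetic studies use 32 to keep matrices small. |
| `tauMinPeaks` | 2 | pooled peaks | Stops coverage selection once only stragglers remain; 2 rejects singleton noise candidates while keeping any center supported by two samples. |
| `numPatches` | 64 | channels | Upper-bounded by the data: the fit fails loudly naming the achievable maximum when the corpus cannot supply enough non-overlapping centers. |

None of the thresholds in the middle block have an authoritative published
value; the defaults are documented working points, and every synthetic
study in the tests states the values it uses.

# The synthetic generator

`syntheticConfig()` / `generateDataset()` emulate the aspects of real runs
the pipeline actually exercises:

* **Sparse hotspot structure.** Default matrices are 256 × 320 with 12
  planted hotspots — large relative to a 32-pixel patch, so a fixed
  32-stride grid has 80 tiles of which most see only background. This
  mirrors the regime the method is designed for, where informative regions
  are rare relative to grid cells.
* **Clustered signal.** Each hotspot is a main 2-D Gaussian (σ = 2 px)
  plus 4 weaker satellites 5–10 px away (25–60% of the apex, σ = 1.4 px,
  kept ≥ 7 px apart) — a stand-in for isotope/adduct companions and elution
  structure. Clusters are what make *centered* patches genuinely richer
  than offset grid tiles: the 256-level histogram is translation-invariant,
  so a lone blob scores the same entropy wherever it sits inside a patch,
  while a split cluster loses part of its level set to the neighboring
  tile.
* **Background.** Salt noise: 2% of cells get a uniform value in
  (0, 0.3]. With w = 9, background windows count ~1.6 mask pixels on
  average against ~75–81 in a cluster core, which is why the synthetic
  studies run NMS at `tauDensity = 20`: comfortably above any noise window,
  comfortably below every core.
* **Class structure.** All samples share one layout and base amplitudes;
  each sample gets ±15% per-cluster amplitude jitter and fresh noise; in
  "case" samples the first 3 clusters are amplified ×2.5 (the
  `classEffect`; 1.0 gives an exchangeable null corpus). Amplitudes are
  clipped at 1, so effect sizes are honest only while base × effect ≤ 1.
* **Separation.** Cluster centers are rejection-sampled at pairwise
  Euclidean distance ≥ 36 px, beyond twice the cluster extent, so distinct
  hotspots never blend; with a 32-pixel patch this also puts every pair of
  centers outside each other's NMS suppression rectangle.

What the generator does *not* emulate — and what green tests therefore do
not certify on real data: chromatographic drift and RT misalignment between
samples, realistic isotope envelope shapes and abundance ratios,
heteroscedastic detector noise, column bleed and solvent background ridges,
and batch effects. The generator's role is to make every algorithmic
contract checkable, not to simulate an instrument.

mzML fixtures (`writeMzMLFixture()`) place one ion at the center m/z of
each non-zero cell, so re-binning with the same grid reproduces the matrix
to float precision; fixtures are written and read through `mzR`.

# Numerical choices and degenerate inputs

* Percentile = ceiling order statistic (rationale above); an all-zero
  matrix normalizes to itself with a warning.
* Density maps are integer-exact (summed-area table over 0/1).
* All argmax operations break ties by smallest row then smallest column;
  entropy ties keep coverage order — every stage is deterministic, and
  seeded runs are byte-stable.
* Circle membership is $d^2 \le r^2 + 10^{-9}$; suppression rectangles and
  patch extents use the $[-\lfloor s/2 \rfloor, +\lceil s/2 \rceil - 1]$
  convention for even sizes.
* Coordinates are 1-based everywhere (row = scan index, col = m/z bin
  index), stated in every file header the package writes. The bin *index*
  returned by `mzBinIndex()` is the 0-based value of the binning formula
  itself; the matrix column is index + 1.
* Matrices and images serialize to annotated TSV (JSON metadata header,
  then dense rows) and models to JSON — all diffable plain text; values
  round-trip at full precision.
* An empty candidate pool, an all-below-threshold density map, and a
  below-threshold first coverage round all return empty results rather than
  errors; requesting more channels than selectable centers is an error that
  names the achievable maximum.

# Problem sizes used in the test suite

The bundled studies are sized for quick, repeated runs: oracle comparisons
use matrices up to 60 × 80 and pools up to 200 points; the entropy
comparison against the grid baseline uses a 40-sample corpus; the
separability study uses 60 + 60 samples (class effect 2.5 and a matched
null) with patch 32 × 32 and 8 channels, scored by ridge-regularized
logistic regression (per-channel mean and standard deviation features)
under stratified 5-fold cross-validation. The full suite runs in well under
a minute on one core.

# Known limitations

* Entropy is a proxy for informativeness, not for class relevance: a
  location can be information-rich and class-irrelevant. The selection is
  unsupervised by design (labels enter only downstream).
* The per-sample peak budget and thresholds interact with instrument
  resolution and bin size; there is no auto-tuning.
* Recovery of planted centers is accurate to a few pixels, not exact: the
  selected center for a hotspot is the best pooled candidate, which drifts
  within the cluster by up to about half the density window.
* The linear separability check is a floor. The encoding is designed as CNN
  input; channel-pooled ridge regression deliberately ignores spatial
  structure inside patches.
* Very small matrices (patch larger than matrix) degrade gracefully but
  uninformatively: grid generation warns and returns nothing, and patch
  extraction pads heavily.
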