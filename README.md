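# msimg

Density-aware multi-channel image encoding of LC-MS runs for phenotype
classification.

Untargeted LC-MS profiling produces, per sample, thousands of scans each
holding paired m/z and intensity arrays — effectively a huge, sparse
two-dimensional intensity surface over retention time × m/z. Conventional
representations either collapse this surface into a peak list (losing raw
signal context) or tile it into a fixed grid of image patches (spending most
patches on empty background and slicing signal regions apart). `msimg`
implements a content-aware alternative: it finds where the signal actually
lives and builds a compact multi-channel image from patches centered on
those regions, ready for a CNN — or any downstream classifier — with no
peak-picking and no cross-sample retention-time alignment.

## Method

For each run, ion intensities are binned onto a fixed m/z grid,
`i = ⌊(mz − mz_min)/bin_size⌋`, and summed per (scan, bin) cell, giving a
matrix **M** of shape (N_scans, N_bins). **M** is scaled so that the 99.9th
percentile of its non-zero values maps to 1 and clipped to [0, 1]
(**M**_norm).

Training-side selection then proceeds in three stages:

1. **Density map + NMS (per sample).** Pixels with intensity > τ_intensity
   form a binary signal mask **S**; a w × w box window summed over **S**
   gives an integer density map **D**, `D_ij = Σ S_xy` over the window.
   Iterative non-maximum suppression repeatedly takes the global maximum of
   **D** (if ≥ τ_density), records it as a candidate peak, and zeroes a
   patch-sized rectangle around it, yielding spatially separated per-sample
   candidates.
2. **Greedy coverage selection (pooled).** All candidates are pooled across
   training samples into P_all. With the coverage radius
   `r = √((h/2)² + (w/2)²)` (patch center to corner), each round scores
   every available point by the number of available points inside its
   r-circle, keeps the argmax, and marks everything inside its circle
   unavailable; it stops when the best score falls below τ_min_peaks. The
   result is a set of non-overlapping patch centers that maximize coverage
   of the pooled signal hotspots.
3. **Entropy ranking.** Each surviving center is scored by the mean, over
   training samples, of the Shannon entropy
   `H(P) = −Σ_k p_k log₂ p_k` of its patch's 256-level intensity histogram;
   the top `num_patches` centers become the **golden locations**.

Every sample — training or held-out — is then encoded as a
`(num_patches, patch_height, patch_width)` tensor whose channel *c* is the
sample's patch at golden location *c* (out-of-bounds cells padded). A
fitted model serializes to JSON and suffices on its own to encode new runs.

The package also ships the fixed-grid sliding-window baseline
(`gridCandidateLocations()`), channel-redundancy diagnostics (inter-channel
Pearson correlation, PCA component counts), a ridge-logistic separability
check, and a synthetic LC-MS generator (Gaussian hotspot clusters with
satellite peaks, salt noise, and class-modulated amplitudes) so the whole
pipeline can be exercised without instrument data.

## Worked example

```r
library(msimg)

cfg <- syntheticConfig()            # 12 planted clusters, 256 x 320 matrices
d   <- generateDataset(cfg, nPerClass = 20, seed = 42)

model <- msimgFit(d$samples, tauDensity = 20, patchHeight = 32L,
                  patchWidth = 32L, numPatches = 8L, maxPeaks = 50L)
#> msimgFit: 481 candidate peaks pooled from 40 samples (12.0/sample)
#> msimgFit: coverage selection kept 12 centers (scores 41..40)
#> msimgFit: kept 8 golden locations, mean entropy 2.765-2.539 bits

model
#> MsimgModel (msimg 0.1.0)
#> BinningSpec: m/z [100, 132) Da, bin 0.1 Da, 320 bins
#>   mask tau 0.01 | density w 9, tau 20, <=50 peaks/sample
#>   patch 32 x 32 (r = 22.63 px), coverage stop tau 2
#>   12 candidate centers -> 8 golden locations

msimgTransform(model, d$samples[[1]])
#> MultiChannelImage 'synth_001_control': 8 channels x 32 x 32 (label 'control')

res <- evaluateSeparability(lapply(d$samples, msimgTransform, model = model),
                            d$labels, folds = 5, seed = 42)
round(c(accuracy = res$accuracy, f1 = res$f1), 3)
#> accuracy       f1
#>        1        1
```

The fit log tells the story: 40 samples each contribute ~12 separated
candidate peaks; greedy coverage collapses the 481 pooled candidates onto
the 12 planted hotspot centers (each covering ~40 pooled peaks); entropy
ranking keeps the 8 most information-rich of them. The resulting 8-channel
32 × 32 encoding linearly separates the two simulated classes perfectly.

A thin command-line front end over the same functions is installed at
`inst/scripts/msimg` (subcommands `build-matrix`, `peaks`, `daps`, `fit`,
`transform`, `simulate`, `diagnose`, `separability`).

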