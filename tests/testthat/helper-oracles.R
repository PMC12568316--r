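# Independent brute-force reference implementations used to check the
# package's vectorized/incremental code paths, plus tiny fixture builders.
# These stay deliberately naive (nested loops, full rescans).

# per-pixel nested-loop window sum with border clipping
oracleDensityMap <- function(mask, w) {
  R <- nrow(mask); C <- ncol(mask); h <- (w - 1) %/% 2
  D <- matrix(0L, R, C)
  for (i in seq_len(R)) for (j in seq_len(C)) {
    rr <- max(1, i - h):min(R, i + h)
    cc <- max(1, j - h):min(C, j + h)
    D[i, j] <- sum(mask[rr, cc])
  }
  D
}

# literal iterative NMS: rescan the full array each round, zero the
# suppression rectangle, smallest-row-then-column tie-break
oracleNms <- function(D, tau, maxPeaks, sh, sw) {
  R <- nrow(D); C <- ncol(D)
  out <- NULL
  for (it in seq_len(maxPeaks)) {
    best <- -Inf; br <- bc <- NA
    for (i in seq_len(R)) for (j in seq_len(C))
      if (D[i, j] > best) { best <- D[i, j]; br <- i; bc <- j }
    if (best < tau) break
    out <- rbind(out, c(br, bc, best))
    for (i in max(1, br - sh %/% 2):min(R, br + (sh + 1) %/% 2 - 1))
      for (j in max(1, bc - sw %/% 2):min(C, bc + (sw + 1) %/% 2 - 1))
        D[i, j] <- 0
  }
  out
}

# all-pairs greedy maximum-coverage selection (no spatial index)
oracleGreedy <- function(points, radius, tauMin) {
  n <- nrow(points)
  avail <- rep(TRUE, n)
  # boundary-inclusive circle, same squared-distance rule as the package
  inside <- outer(seq_len(n), seq_len(n), function(i, j)
    (points$row[i] - points$row[j])^2 + (points$col[i] - points$col[j])^2 <=
      radius^2 + 1e-9)
  out <- NULL
  repeat {
    cand <- which(avail)
    if (!length(cand)) break
    sc <- sapply(cand, function(i) sum(avail & inside[i, ]))
    best <- max(sc)
    if (best < tauMin) break
    tied <- cand[sc == best]
    pick <- tied[order(points$row[tied], points$col[tied])[1]]
    out <- rbind(out, c(points$row[pick], points$col[pick], best))
    avail[avail & inside[pick, ]] <- FALSE
  }
  out
}

# sort-based upper percentile, ceiling order statistic (inverse CDF)
oraclePercentile <- function(v, p) {
  s <- sort(v)
  s[max(1, ceiling(p / 100 * length(s)))]
}

# textbook Pearson correlation computed with explicit loops
oraclePearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sxx <- syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  sxy / sqrt(sxx * syy)
}

# scan list builder: scans = list of list(rt, mz, intensity)
makeScans <- function(...) {
  scans <- list(...)
  attr(scans, "sourceId") <- "fixture"
  scans
}

# random sparse normalized matrix wrapped as a MassSpecMatrix
randomNormalizedMatrix <- function(nr, nc, density = 0.05, seed = 1,
                                   sampleId = "rand") {
  set.seed(seed)
  m <- matrix(0, nr, nc)
  k <- max(1, floor(density * nr * nc))
  m[sample.int(nr * nc, k)] <- runif(k)
  newMSM(m, sampleId = sampleId)
}

# wrap a plain [0,1] matrix as a normalized MassSpecMatrix
newMSM <- function(m, sampleId = "m", label = NA_character_) {
  msimg:::newMassSpecMatrix(m, binningSpec(100, 100 + ncol(m), 1),
    rtAxis = as.numeric(seq_len(nrow(m))), normalized = TRUE,
    sampleId = sampleId, label = label)
}
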