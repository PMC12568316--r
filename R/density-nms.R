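#' @include AllClasses.R
NULL

#' Threshold a normalized matrix into a binary signal mask
#'
#' Pixels with intensity strictly greater than \code{tauIntensity} are
#' effective signal; the rest are background.  The input must already be
#' normalized so that the threshold is a fraction of a common [0, 1] scale.
#'
#' @param matrix a normalized [MassSpecMatrix-class]
#' @param tauIntensity scalar threshold in [0, 1); default 0.01
#' @return a [SignalMask-class]
#' @export
binarize <- function(matrix, tauIntensity = 0.01) {
    stopifnot(is(matrix, "MassSpecMatrix"))
    if (!isTRUE(matrix@normalized))
        stop("binarize() requires a normalized matrix")
    if (length(tauIntensity) != 1L || tauIntensity < 0 || tauIntensity >= 1)
        stop("'tauIntensity' must be a scalar in [0, 1)")
    new("SignalMask", mask = matrix@values > tauIntensity,
        tauIntensity = as.numeric(tauIntensity))
}

#' Estimate the local signal density
#'
#' Slides a w x w box window over the signal mask and counts the signal
#' pixels inside it, producing an integer density surface of the same shape.
#' Windows are clipped at the matrix borders (equivalent to zero-padding),
#' so border densities are counts over the visible part of the window.
#' Computed with a summed-area table, which is exact for 0/1 counts.
#'
#' @param mask a [SignalMask-class]
#' @param w odd window side in pixels; default 9
#' @return a [DensityMap-class]
#' @export
densityMap <- function(mask, w = 9L) {
    stopifnot(is(mask, "SignalMask"))
    w <- as.integer(w)
    if (length(w) != 1L || w < 1L || w %% 2L == 0L)
        stop("'w' must be a single odd positive integer")
    S <- mask@mask
    R <- nrow(S); C <- ncol(S)
    h <- (w - 1L) %/% 2L
    ## summed-area table with a zero top row / left column
    cs <- apply(S * 1, 2L, cumsum)                    # down columns
    if (!is.matrix(cs)) cs <- matrix(cs, nrow = R, ncol = C)
    cs <- t(apply(cs, 1L, cumsum))                    # then across rows
    if (!is.matrix(cs) || nrow(cs) != R) cs <- matrix(cs, nrow = R, ncol = C)
    P <- matrix(0, R + 1L, C + 1L)
    P[-1L, -1L] <- cs
    i1 <- pmax(seq_len(R) - h, 1L); i2 <- pmin(seq_len(R) + h, R)
    j1 <- pmax(seq_len(C) - h, 1L); j2 <- pmin(seq_len(C) + h, C)
    D <- P[i2 + 1L, j2 + 1L, drop = FALSE] - P[i1, j2 + 1L, drop = FALSE] -
         P[i2 + 1L, j1, drop = FALSE] + P[i1, j1, drop = FALSE]
    storage.mode(D) <- "integer"
    new("DensityMap", density = D, window = w)
}

## deterministic argmax of a matrix: smallest row, then smallest column
argmaxRowCol <- function(m, value) {
    hits <- which(m == value, arr.ind = TRUE)
    hits[order(hits[, 1L], hits[, 2L])[1L], , drop = TRUE]
}

#' Extract spatially separated candidate peaks by non-maximum suppression
#'
#' Iteratively picks the global density maximum; if it still meets the
#' density threshold it is recorded as a candidate peak, and the rectangle of
#' the predefined patch size centered on it is zeroed (on a working copy) so
#' the same dense region cannot be re-selected.  Iteration stops after
#' \code{maxPeaks} peaks or when the remaining maximum falls below
#' \code{tauDensity}.  Ties in the argmax are broken by smallest row, then
#' smallest column, so runs are reproducible.
#'
#' The suppression rectangle spans rows \code{[r - floor(h/2),
#' r + ceiling(h/2) - 1]} (and likewise columns), clipped at the borders;
#' for odd sizes this is the symmetric window.
#'
#' @param dmap a [DensityMap-class]; not modified
#' @param tauDensity minimum density for a valid peak (>= 1); default 5
#' @param maxPeaks per-sample peak budget; default 100
#' @param suppressHeight,suppressWidth suppression rectangle = patch size, in
#'   pixels
#' @param sampleId identifier copied into the output rows
#' @return data.frame with columns \code{sampleId}, \code{row}, \code{col},
#'   \code{density}, in extraction order (densities non-increasing); zero
#'   rows when no pixel meets the threshold
#' @export
nmsExtractPeaks <- function(dmap, tauDensity = 5, maxPeaks = 100L,
                            suppressHeight, suppressWidth,
                            sampleId = "sample") {
    stopifnot(is(dmap, "DensityMap"))
    if (tauDensity < 1) stop("'tauDensity' must be >= 1")
    maxPeaks <- as.integer(maxPeaks)
    if (maxPeaks < 1L) stop("'maxPeaks' must be >= 1")
    sh <- as.integer(suppressHeight); sw <- as.integer(suppressWidth)
    if (sh < 1L || sw < 1L) stop("suppression rectangle sizes must be >= 1")
    D <- dmap@density                       # working copy
    R <- nrow(D); C <- ncol(D)
    rows <- integer(0); cols <- integer(0); dens <- integer(0)
    while (length(rows) < maxPeaks) {
        m <- max(D)
        if (m < tauDensity) break
        p <- argmaxRowCol(D, m)
        rows <- c(rows, p[1L]); cols <- c(cols, p[2L])
        dens <- c(dens, as.integer(m))
        r1 <- max(1L, p[1L] - sh %/% 2L)
        r2 <- min(R, p[1L] + (sh + 1L) %/% 2L - 1L)
        c1 <- max(1L, p[2L] - sw %/% 2L)
        c2 <- min(C, p[2L] + (sw + 1L) %/% 2L - 1L)
        D[r1:r2, c1:c2] <- 0L
    }
    data.frame(sampleId = rep(sampleId, length(rows)),
               row = rows, col = cols, density = dens)
}
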