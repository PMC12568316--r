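#' @include AllClasses.R
NULL

## resolve a MassSpecMatrix or plain matrix argument to a plain matrix
asValueMatrix <- function(x) {
    if (is(x, "MassSpecMatrix")) x@values
    else if (is.matrix(x)) x
    else stop("expected a MassSpecMatrix or a matrix")
}

#' Extract a fixed-size patch around a center
#'
#' Cuts the \code{patchHeight} x \code{patchWidth} window centered at
#' \code{center} out of the matrix.  The center is mapped to patch cell
#' \code{(floor(h/2) + 1, floor(w/2) + 1)}; source rows
#' \code{center[1] - floor(h/2)} through \code{center[1] + ceiling(h/2) - 1}
#' are taken (likewise columns), and any part of that window outside the
#' matrix is filled with \code{padValue}.
#'
#' @param matrix a [MassSpecMatrix-class] or plain numeric matrix
#' @param center integer (row, col), 1-based, inside the matrix
#' @param patchHeight,patchWidth patch size in pixels
#' @param padValue fill value for out-of-bounds cells; default 0
#' @return numeric matrix of shape (patchHeight, patchWidth)
#' @export
extractPatch <- function(matrix, center, patchHeight, patchWidth,
                         padValue = 0) {
    v <- asValueMatrix(matrix)
    h <- as.integer(patchHeight); w <- as.integer(patchWidth)
    if (h < 1L || w < 1L) stop("patch sizes must be >= 1")
    r <- as.integer(center[1L]); c <- as.integer(center[2L])
    if (r < 1L || r > nrow(v) || c < 1L || c > ncol(v))
        stop(sprintf("center (%d, %d) outside the %d x %d matrix",
            r, c, nrow(v), ncol(v)))
    r1 <- r - h %/% 2L; r2 <- r + (h + 1L) %/% 2L - 1L
    c1 <- c - w %/% 2L; c2 <- c + (w + 1L) %/% 2L - 1L
    out <- matrix(padValue, h, w)
    sr <- max(r1, 1L):min(r2, nrow(v))
    sc <- max(c1, 1L):min(c2, ncol(v))
    out[sr - r1 + 1L, sc - c1 + 1L] <- v[sr, sc]
    out
}

#' Information entropy of a patch
#'
#' Quantizes the patch intensities (expected in [0, 1]) to 256 grey levels,
#' \code{k = round(v * 255)}, and returns the Shannon entropy of the level
#' histogram in bits: \eqn{H = -\sum_k p_k \log_2 p_k} over levels with
#' \eqn{p_k > 0}.  Ranges from 0 bits (constant patch) to 8 bits (all 256
#' levels equally frequent).  Padded cells take part in the histogram like
#' any other pixel.
#'
#' @param patch numeric matrix (or vector) with values in [0, 1]
#' @return entropy in bits, in [0, 8]
#' @export
patchEntropy <- function(patch) {
    v <- as.numeric(patch)
    if (!length(v)) stop("empty patch")
    if (any(v < 0 | v > 1))
        stop("patch values must lie in [0, 1]")
    k <- pmin(pmax(as.integer(round(v * 255)), 0L), 255L)
    p <- tabulate(k + 1L, nbins = 256L)
    p <- p[p > 0] / length(k)
    -sum(p * log2(p))
}

#' Rank candidate locations by mean entropy across the training set
#'
#' For every candidate center, extracts the corresponding patch from every
#' training matrix, averages the patch entropies, and keeps the
#' \code{numPatches} locations with the highest mean — the "golden
#' locations" that define the image channels for all samples.  Ties are
#' broken by candidate order (earlier candidates first), so rankings are
#' deterministic.
#'
#' @param trainMatrices list of normalized [MassSpecMatrix-class] objects
#'   (all with identical dimensions)
#' @param candidates candidate centers: a data.frame with columns \code{row},
#'   \code{col} (e.g. from [dapsSelect()] or [gridCandidateLocations()])
#' @param patchHeight,patchWidth patch size in pixels
#' @param numPatches how many locations to keep (the image channel count)
#' @param padValue fill value for out-of-bounds patch cells
#' @return a [GoldenLocations-class]
#' @export
rankGoldenLocations <- function(trainMatrices, candidates, patchHeight,
                                patchWidth, numPatches, padValue = 0) {
    if (!length(trainMatrices)) stop("no training matrices")
    if (is.matrix(candidates)) candidates <- as.data.frame(candidates)
    if (!all(c("row", "col") %in% names(candidates)))
        stop("'candidates' needs columns row and col")
    nc <- nrow(candidates)
    if (nc == 0L) stop("no candidate locations")
    if (numPatches > nc)
        stop(sprintf(
            "numPatches = %d exceeds the %d available candidate locations",
            numPatches, nc))
    dims <- vapply(trainMatrices, function(m) dim(asValueMatrix(m)),
                   integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
        stop("training matrices must share dimensions")
    ent <- matrix(0, nrow = length(trainMatrices), ncol = nc)
    for (s in seq_along(trainMatrices)) {
        v <- asValueMatrix(trainMatrices[[s]])
        for (j in seq_len(nc))
            ent[s, j] <- patchEntropy(extractPatch(v,
                c(candidates$row[j], candidates$col[j]),
                patchHeight, patchWidth, padValue))
    }
    meanEnt <- colMeans(ent)
    ord <- order(-meanEnt, seq_len(nc))[seq_len(numPatches)]
    loc <- cbind(row = as.integer(candidates$row[ord]),
                 col = as.integer(candidates$col[ord]))
    new("GoldenLocations", locations = loc, meanEntropies = meanEnt[ord],
        patchHeight = as.integer(patchHeight),
        patchWidth = as.integer(patchWidth), padValue = as.numeric(padValue),
        sourceDim = dims[, 1])
}

#' Stack a sample's golden patches into a multi-channel image
#'
#' Applies a fixed, training-derived set of golden locations to one sample
#' (train or held-out alike): channel c of the output tensor is the sample's
#' patch at golden location c.  Nothing is re-selected or re-ranked here.
#'
#' @param matrix a normalized [MassSpecMatrix-class] with the same dimensions
#'   as the matrices the locations were derived from
#' @param golden a [GoldenLocations-class]
#' @return a [MultiChannelImage-class] with tensor dims
#'   (numPatches, patchHeight, patchWidth)
#' @export
buildMultiChannelImage <- function(matrix, golden) {
    stopifnot(is(golden, "GoldenLocations"))
    v <- asValueMatrix(matrix)
    if (!all(dim(v) == golden@sourceDim))
        stop(sprintf(
            "matrix is %d x %d but the golden locations were derived on %d x %d",
            nrow(v), ncol(v), golden@sourceDim[1], golden@sourceDim[2]))
    np <- numPatches(golden)
    h <- golden@patchHeight; w <- golden@patchWidth
    tens <- array(0, dim = c(np, h, w))
    for (ch in seq_len(np))
        tens[ch, , ] <- extractPatch(v, golden@locations[ch, ], h, w,
                                     golden@padValue)
    sid <- if (is(matrix, "MassSpecMatrix")) matrix@sampleId else "sample"
    lab <- if (is(matrix, "MassSpecMatrix")) matrix@label else NA_character_
    new("MultiChannelImage", tensor = tens, sampleId = sid, label = lab,
        locations = golden@locations)
}

#' Fixed-grid candidate locations (sliding-window baseline)
#'
#' Generates the candidate centers of the grid-partitioning baseline: a
#' patch-sized window slides over the matrix at a fixed stride and every
#' fully contained window contributes its center, scanned row-major from the
#' top-left.  Feeding these into [rankGoldenLocations()] reproduces the
#' grid-based pipeline against which the density-aware selection is compared.
#'
#' @param nRows,nCols matrix dimensions
#' @param patchHeight,patchWidth window size in pixels
#' @param stride step in pixels; a single value or (row, col) pair; defaults
#'   to the patch size (non-overlapping tiles)
#' @return data.frame with columns \code{row}, \code{col}; zero rows (with a
#'   warning) when the patch does not fit
#' @export
gridCandidateLocations <- function(nRows, nCols, patchHeight, patchWidth,
                                   stride = NULL) {
    h <- as.integer(patchHeight); w <- as.integer(patchWidth)
    if (is.null(stride)) stride <- c(h, w)
    stride <- as.integer(rep(stride, length.out = 2L))
    if (any(stride < 1L)) stop("'stride' must be >= 1")
    if (h > nRows || w > nCols) {
        warning("patch larger than the matrix: no grid locations")
        return(data.frame(row = integer(0), col = integer(0)))
    }
    rowStarts <- seq(1L, nRows - h + 1L, by = stride[1L])
    colStarts <- seq(1L, nCols - w + 1L, by = stride[2L])
    grid <- expand.grid(col = colStarts + w %/% 2L,
                        row = rowStarts + h %/% 2L)   # row-major order
    data.frame(row = grid$row, col = grid$col)
}

#' Pairwise correlation between image channels
#'
#' Redundancy diagnostic: for each channel, the patch pixels of all samples
#' are flattened into one long vector, and the Pearson correlation of those
#' per-channel vectors is returned.  Well-separated golden locations should
#' show weak off-diagonal correlation; a fixed grid that tiles one large
#' structure shows strong redundancy.
#'
#' @param images list of [MultiChannelImage-class] objects with identical
#'   dims (>= 2 samples)
#' @return symmetric correlation matrix (channels x channels), unit diagonal;
#'   correlations with a constant channel are reported as 0 with a warning
#' @export
interChannelCorrelation <- function(images) {
    if (length(images) < 2L) stop("need at least 2 samples")
    d <- dim(images[[1L]]@tensor)
    V <- vapply(seq_len(d[1L]), function(ch)
        unlist(lapply(images, function(im) as.numeric(im@tensor[ch, , ]))),
        numeric(length(images) * d[2L] * d[3L]))
    sds <- apply(V, 2L, stats::sd)
    cc <- suppressWarnings(stats::cor(V))
    if (any(sds == 0)) {
        warning("constant channel(s): undefined correlations reported as 0")
        cc[is.na(cc)] <- 0
    }
    diag(cc) <- 1
    cc
}

#' Components needed to reach a cumulative explained-variance target
#'
#' Redundancy diagnostic complementing [interChannelCorrelation()]: runs a
#' PCA on the per-channel patch vectors (one observation per sample-channel
#' pair, one variable per patch pixel) and reports the smallest number of
#' principal components whose cumulative explained variance reaches the
#' requested fraction.  Highly redundant channel sets need few components.
#'
#' @param images list of [MultiChannelImage-class] objects (>= 2 samples)
#' @param varianceFraction target in (0, 1); default 0.95
#' @return integer component count
#' @export
pcaComponentsForVariance <- function(images, varianceFraction = 0.95) {
    if (length(images) < 2L) stop("need at least 2 samples")
    if (varianceFraction <= 0 || varianceFraction >= 1)
        stop("'varianceFraction' must be in (0, 1)")
    d <- dim(images[[1L]]@tensor)
    X <- do.call(rbind, lapply(images, function(im)
        t(vapply(seq_len(d[1L]),
                 function(ch) as.numeric(im@tensor[ch, , ]),
                 numeric(d[2L] * d[3L])))))
    pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
    ev <- pc$sdev^2
    ev <- ev[ev > .Machine$double.eps * max(ev)]
    cum <- cumsum(ev) / sum(ev)
    as.integer(which(cum >= varianceFraction - 1e-12)[1L])
}

#' Channel-redundancy report
#'
#' Convenience wrapper bundling the two diagnostics: the inter-channel
#' Pearson correlation matrix and the component count needed for 95%% (by
#' default) cumulative explained variance.
#'
#' @inheritParams pcaComponentsForVariance
#' @return list with elements \code{correlation}, \code{meanAbsOffDiagonal},
#'   \code{pcaComponents}, \code{varianceFraction}
#' @export
diagnoseRedundancy <- function(images, varianceFraction = 0.95) {
    cc <- interChannelCorrelation(images)
    off <- abs(cc[upper.tri(cc)])
    list(correlation = cc,
         meanAbsOffDiagonal = if (length(off)) mean(off) else NA_real_,
         pcaComponents = pcaComponentsForVariance(images, varianceFraction),
         varianceFraction = varianceFraction)
}
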