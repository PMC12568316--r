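#' @include AllGenerics.R
NULL

#' m/z binning specification
#'
#' Defines the fixed m/z grid shared by all samples of a study: the half-open
#' range \code{[mzMin, mzMax)} is divided into \code{nBins(x)} contiguous bins
#' of width \code{binSize} Da.  An ion at m/z value \eqn{m} falls into bin
#' \eqn{\lfloor (m - mz_{min}) / bin\_size \rfloor} (0-based bin index; matrix
#' column = index + 1).
#'
#' @slot mzMin lower edge of the m/z range (Da)
#' @slot mzMax upper edge of the m/z range (Da, exclusive)
#' @slot binSize bin width (Da)
#'
#' @seealso [binningSpec()], [mzBinIndex()], [buildMassSpecMatrix()]
#' @export
setClass("BinningSpec",
    representation(mzMin = "numeric", mzMax = "numeric", binSize = "numeric"))

setValidity("BinningSpec", function(object) {
    msg <- character()
    if (length(object@mzMin) != 1L || length(object@mzMax) != 1L ||
        length(object@binSize) != 1L)
        msg <- c(msg, "mzMin, mzMax and binSize must be scalars")
    else {
        if (!is.finite(object@mzMin) || !is.finite(object@mzMax) ||
            !is.finite(object@binSize))
            msg <- c(msg, "binning parameters must be finite")
        else {
            if (object@mzMax <= object@mzMin)
                msg <- c(msg, "mzMax must be greater than mzMin")
            if (object@binSize <= 0)
                msg <- c(msg, "binSize must be positive")
        }
    }
    if (length(msg)) msg else TRUE
})

#' Construct a BinningSpec
#'
#' @param mzMin,mzMax m/z range in Da (half-open, \code{mzMax} exclusive)
#' @param binSize bin width in Da
#' @return a [BinningSpec-class] object
#' @examples
#' b <- binningSpec(100, 200, 0.1)
#' nBins(b)
#' @export
binningSpec <- function(mzMin, mzMax, binSize) {
    new("BinningSpec", mzMin = as.numeric(mzMin), mzMax = as.numeric(mzMax),
        binSize = as.numeric(binSize))
}

#' @describeIn BinningSpec-class number of bins,
#'   \code{ceiling((mzMax - mzMin)/binSize)}
#' @param x a \code{BinningSpec}
#' @export
setMethod("nBins", "BinningSpec", function(x)
    as.integer(ceiling((x@mzMax - x@mzMin) / x@binSize - 1e-9)))

setMethod("show", "BinningSpec", function(object) {
    cat(sprintf("BinningSpec: m/z [%g, %g) Da, bin %g Da, %d bins\n",
        object@mzMin, object@mzMax, object@binSize, nBins(object)))
})


#' Two-dimensional mass-spec matrix
#'
#' The per-run container of the pipeline: a dense non-negative matrix with one
#' row per MS scan (ordered by retention time) and one column per m/z bin.
#' Before normalization the entries are summed ion intensities; after
#' [normalizeMatrix()] they lie in [0, 1].  Row/column coordinates are 1-based
#' throughout the package (row = scan index, col = m/z bin index).
#'
#' @slot values numeric matrix, shape (nScans, nBins), non-negative
#' @slot binning the [BinningSpec-class] used to build the columns
#' @slot rtAxis retention time (seconds) of each row, strictly increasing
#' @slot normalized logical flag; when TRUE all values are in [0, 1]
#' @slot sampleId sample identifier
#' @slot label optional class tag (NA when unlabeled)
#' @slot droppedIons count of ions discarded because their m/z fell outside
#'   the binning range
#'
#' @export
setClass("MassSpecMatrix",
    representation(values = "matrix", binning = "BinningSpec",
        rtAxis = "numeric", normalized = "logical", sampleId = "character",
        label = "character", droppedIons = "integer"))

setValidity("MassSpecMatrix", function(object) {
    msg <- character()
    v <- object@values
    if (!is.numeric(v))
        msg <- c(msg, "values must be a numeric matrix")
    if (nrow(v) != length(object@rtAxis))
        msg <- c(msg, "rtAxis length must equal the number of scan rows")
    if (length(object@rtAxis) > 1L && any(diff(object@rtAxis) <= 0))
        msg <- c(msg, "retention times must be strictly increasing")
    if (ncol(v) != nBins(object@binning))
        msg <- c(msg, sprintf("matrix has %d columns but binning implies %d",
            ncol(v), nBins(object@binning)))
    if (length(v) && min(v) < 0)
        msg <- c(msg, "intensities must be non-negative")
    if (isTRUE(object@normalized) && length(v) && max(v) > 1)
        msg <- c(msg, "normalized matrix must have values in [0, 1]")
    if (length(msg)) msg else TRUE
})

newMassSpecMatrix <- function(values, binning, rtAxis, normalized = FALSE,
                              sampleId = "sample", label = NA_character_,
                              droppedIons = 0L) {
    new("MassSpecMatrix", values = values, binning = binning,
        rtAxis = as.numeric(rtAxis), normalized = normalized,
        sampleId = as.character(sampleId), label = as.character(label),
        droppedIons = as.integer(droppedIons))
}

#' @describeIn MassSpecMatrix-class the dense (nScans, nBins) intensity matrix
#' @param x a \code{MassSpecMatrix}
#' @export
setMethod("intensityMatrix", "MassSpecMatrix", function(x) x@values)

#' @describeIn MassSpecMatrix-class the [BinningSpec-class]
#' @export
setMethod("binning", "MassSpecMatrix", function(x) x@binning)

#' @describeIn MassSpecMatrix-class retention times (s) of the scan rows
#' @export
setMethod("rtAxis", "MassSpecMatrix", function(x) x@rtAxis)

#' @describeIn MassSpecMatrix-class TRUE once [normalizeMatrix()] was applied
#' @export
setMethod("isNormalized", "MassSpecMatrix", function(x) x@normalized)

#' @describeIn MassSpecMatrix-class sample identifier
#' @export
setMethod("sampleId", "MassSpecMatrix", function(x) x@sampleId)

#' @describeIn MassSpecMatrix-class class tag (NA when unlabeled)
#' @export
setMethod("sampleLabel", "MassSpecMatrix", function(x) x@label)

#' @describeIn MassSpecMatrix-class matrix dimensions (nScans, nBins)
#' @export
setMethod("dim", "MassSpecMatrix", function(x) dim(x@values))

setMethod("show", "MassSpecMatrix", function(object) {
    cat(sprintf("MassSpecMatrix '%s': %d scans x %d m/z bins (%s)\n",
        object@sampleId, nrow(object@values), ncol(object@values),
        if (object@normalized) "normalized, values in [0,1]" else "raw counts"))
    cat(sprintf("  m/z [%g, %g) Da @ %g Da; RT %.1f-%.1f s",
        object@binning@mzMin, object@binning@mzMax, object@binning@binSize,
        min(object@rtAxis), max(object@rtAxis)))
    if (!is.na(object@label)) cat(sprintf("; label '%s'", object@label))
    cat("\n")
})


#' Binary signal mask
#'
#' Marks the pixels of a normalized mass-spec matrix whose intensity strictly
#' exceeds the intensity threshold \eqn{\tau_{intensity}}; everything else is
#' background.  Produced by [binarize()].
#'
#' @slot mask logical matrix, same shape as the source matrix
#' @slot tauIntensity the threshold used (fraction of the normalized scale)
#' @export
setClass("SignalMask",
    representation(mask = "matrix", tauIntensity = "numeric"))

setValidity("SignalMask", function(object) {
    msg <- character()
    if (!is.logical(object@mask))
        msg <- c(msg, "mask must be a logical matrix")
    if (length(object@tauIntensity) != 1L || object@tauIntensity < 0 ||
        object@tauIntensity >= 1)
        msg <- c(msg, "tauIntensity must be a scalar in [0, 1)")
    if (length(msg)) msg else TRUE
})

#' @describeIn SignalMask-class the logical mask matrix
#' @param x a \code{SignalMask}
#' @export
setMethod("maskMatrix", "SignalMask", function(x) x@mask)

setMethod("show", "SignalMask", function(object) {
    cat(sprintf("SignalMask: %d x %d, tau = %g, %d signal pixels (%.2f%%)\n",
        nrow(object@mask), ncol(object@mask), object@tauIntensity,
        sum(object@mask), 100 * mean(object@mask)))
})


#' Local signal-density map
#'
#' Integer surface counting, for every pixel, the signal-mask ones inside the
#' w x w box window centered there (windows clipped at the borders, equivalent
#' to zero-padding the mask).  High values mark signal hotspots.  Produced by
#' [densityMap()].
#'
#' @slot density integer matrix, same shape as the mask; values in [0, w^2]
#' @slot window odd window side w in pixels
#' @export
setClass("DensityMap",
    representation(density = "matrix", window = "integer"))

setValidity("DensityMap", function(object) {
    msg <- character()
    w <- object@window
    if (length(w) != 1L || w < 1L || w %% 2L == 0L)
        msg <- c(msg, "window must be a single odd positive integer")
    d <- object@density
    if (length(d) && (min(d) < 0 || max(d) > as.double(w)^2))
        msg <- c(msg, "density values must lie in [0, w^2]")
    if (length(msg)) msg else TRUE
})

#' @describeIn DensityMap-class the integer density matrix
#' @param x a \code{DensityMap}
#' @export
setMethod("densityValues", "DensityMap", function(x) x@density)

#' @describeIn DensityMap-class the box-window side w (pixels)
#' @export
setMethod("windowSize", "DensityMap", function(x) x@window)

setMethod("show", "DensityMap", function(object) {
    cat(sprintf("DensityMap: %d x %d, w = %d, max density %d\n",
        nrow(object@density), ncol(object@density), object@window,
        if (length(object@density)) max(object@density) else 0L))
})


#' Golden patch locations
#'
#' The ordered set of patch centers retained for image construction: candidate
#' centers (from the density-aware greedy selection, or from the fixed-grid
#' baseline) ranked by their mean patch information entropy across the
#' training set, truncated to the requested channel count.  Fixed at fit time
#' and applied unchanged to every sample, train or test.
#'
#' @slot locations integer matrix (numPatches x 2), columns \code{row},
#'   \code{col}; 1-based coordinates into the source matrix
#' @slot meanEntropies mean entropy (bits) per location, non-increasing
#' @slot patchHeight,patchWidth patch size in pixels
#' @slot padValue fill value for out-of-bounds patch cells
#' @slot sourceDim (nScans, nBins) of the matrices the locations refer to
#' @export
setClass("GoldenLocations",
    representation(locations = "matrix", meanEntropies = "numeric",
        patchHeight = "integer", patchWidth = "integer", padValue = "numeric",
        sourceDim = "integer"))

setValidity("GoldenLocations", function(object) {
    msg <- character()
    if (ncol(object@locations) != 2L)
        msg <- c(msg, "locations must have two columns (row, col)")
    if (nrow(object@locations) != length(object@meanEntropies))
        msg <- c(msg, "one mean entropy per location is required")
    e <- object@meanEntropies
    if (length(e) > 1L && any(diff(e) > 1e-12))
        msg <- c(msg, "mean entropies must be non-increasing")
    if (object@patchHeight < 1L || object@patchWidth < 1L)
        msg <- c(msg, "patch sizes must be >= 1")
    if (length(object@sourceDim) != 2L)
        msg <- c(msg, "sourceDim must be length 2")
    if (length(msg)) msg else TRUE
})

#' @describeIn GoldenLocations-class the (numPatches x 2) center matrix
#' @param x a \code{GoldenLocations}
#' @export
setMethod("goldenCoords", "GoldenLocations", function(x) x@locations)

#' @describeIn GoldenLocations-class mean entropies (bits), one per location
#' @export
setMethod("meanEntropies", "GoldenLocations", function(x) x@meanEntropies)

#' @describeIn GoldenLocations-class number of retained locations (channels)
#' @export
setMethod("numPatches", "GoldenLocations", function(x)
    nrow(x@locations))

setMethod("show", "GoldenLocations", function(object) {
    cat(sprintf(
        "GoldenLocations: %d locations, patch %d x %d, entropy %.3f-%.3f bits\n",
        nrow(object@locations), object@patchHeight, object@patchWidth,
        if (length(object@meanEntropies)) max(object@meanEntropies) else NA,
        if (length(object@meanEntropies)) min(object@meanEntropies) else NA))
})


#' Multi-channel image representation of one sample
#'
#' A (numPatches, patchHeight, patchWidth) tensor in [0, 1]: channel c holds
#' the sample's patch at golden location c.  This is the model-ready encoding
#' of a run; channel order equals golden-location order.
#'
#' @slot tensor 3-d numeric array, dims (numPatches, patchHeight, patchWidth)
#' @slot sampleId sample identifier
#' @slot label class tag (NA when unlabeled)
#' @slot locations provenance: the (row, col) centers the channels came from
#' @export
setClass("MultiChannelImage",
    representation(tensor = "array", sampleId = "character",
        label = "character", locations = "matrix"))

setValidity("MultiChannelImage", function(object) {
    msg <- character()
    d <- dim(object@tensor)
    if (length(d) != 3L)
        msg <- c(msg, "tensor must be 3-dimensional (channels, height, width)")
    else if (nrow(object@locations) != d[1L])
        msg <- c(msg, "one location per channel is required")
    if (length(object@tensor) &&
        (min(object@tensor) < 0 || max(object@tensor) > 1))
        msg <- c(msg, "tensor values must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' @describeIn MultiChannelImage-class the raw 3-d array
#' @param x a \code{MultiChannelImage}
#' @export
setMethod("imageTensor", "MultiChannelImage", function(x) x@tensor)

#' @describeIn MultiChannelImage-class sample identifier
#' @export
setMethod("sampleId", "MultiChannelImage", function(x) x@sampleId)

#' @describeIn MultiChannelImage-class class tag
#' @export
setMethod("sampleLabel", "MultiChannelImage", function(x) x@label)

#' @describeIn MultiChannelImage-class tensor dims
#'   (numPatches, patchHeight, patchWidth)
#' @export
setMethod("dim", "MultiChannelImage", function(x) dim(x@tensor))

setMethod("show", "MultiChannelImage", function(object) {
    d <- dim(object@tensor)
    cat(sprintf("MultiChannelImage '%s': %d channels x %d x %d%s\n",
        object@sampleId, d[1], d[2], d[3],
        if (!is.na(object@label)) sprintf(" (label '%s')", object@label)
        else ""))
})


#' Fitted patch-selection model
#'
#' Freezes every training-derived quantity needed to transform new samples:
#' the binning grid, normalization percentile, density/NMS thresholds, the
#' greedy-coverage geometry, and the golden locations with their mean
#' entropies.  A serialized model alone (see [writeMsimgModel()]) suffices to
#' encode unseen runs; no training data is consulted at transform time.
#'
#' @slot binning the shared [BinningSpec-class]
#' @slot percentile normalization percentile (percent scale, e.g. 99.9)
#' @slot tauIntensity intensity threshold for the signal mask
#' @slot window density box-window side w (odd, pixels)
#' @slot tauDensity minimum density for an NMS candidate peak
#' @slot maxPeaks per-sample NMS peak budget
#' @slot patchHeight,patchWidth patch size (pixels)
#' @slot radius coverage radius r = sqrt((h/2)^2 + (w/2)^2)
#' @slot tauMinPeaks greedy-coverage stopping threshold
#' @slot centers data.frame of all selected centers (rank, row, col, score)
#' @slot golden the [GoldenLocations-class] applied at transform time
#' @slot version package version string
#' @slot created creation timestamp (informational only)
#' @export
setClass("MsimgModel",
    representation(binning = "BinningSpec", percentile = "numeric",
        tauIntensity = "numeric", window = "integer", tauDensity = "numeric",
        maxPeaks = "integer", patchHeight = "integer", patchWidth = "integer",
        radius = "numeric", tauMinPeaks = "numeric", centers = "data.frame",
        golden = "GoldenLocations", version = "character",
        created = "character"))

setValidity("MsimgModel", function(object) {
    msg <- character()
    r <- sqrt((object@patchHeight / 2)^2 + (object@patchWidth / 2)^2)
    if (abs(object@radius - r) > 1e-9)
        msg <- c(msg, "radius is inconsistent with the patch size")
    if (object@golden@patchHeight != object@patchHeight ||
        object@golden@patchWidth != object@patchWidth)
        msg <- c(msg, "golden locations carry a different patch size")
    if (length(msg)) msg else TRUE
})

#' @describeIn MsimgModel-class number of image channels
#' @param x a \code{MsimgModel}
#' @export
setMethod("numPatches", "MsimgModel", function(x) numPatches(x@golden))

setMethod("show", "MsimgModel", function(object) {
    cat(sprintf("MsimgModel (msimg %s)\n", object@version))
    show(object@binning)
    cat(sprintf(
        "  mask tau %g | density w %d, tau %g, <=%d peaks/sample\n",
        object@tauIntensity, object@window, object@tauDensity,
        object@maxPeaks))
    cat(sprintf(
        "  patch %d x %d (r = %.2f px), coverage stop tau %g\n",
        object@patchHeight, object@patchWidth, object@radius,
        object@tauMinPeaks))
    cat(sprintf("  %d candidate centers -> %d golden locations\n",
        nrow(object@centers), numPatches(object@golden)))
})
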