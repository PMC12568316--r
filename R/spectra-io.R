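#' @include AllClasses.R
NULL

#' Map m/z values to bin indices
#'
#' Implements the binning rule \eqn{i = \lfloor (mz - mz_{min}) /
#' bin\_size \rfloor}.  The returned index is 0-based, exactly as the rule
#' defines it; the corresponding matrix column is \code{index + 1}.
#'
#' @param mz numeric vector of m/z values (Da)
#' @param spec a [BinningSpec-class]
#' @return integer vector of 0-based bin indices in \code{[0, nBins - 1]}
#' @details m/z values outside \code{[mzMin, mzMax)} are an error: the rule is
#'   undefined there.  [buildMassSpecMatrix()] drops such ions instead (and
#'   counts them), which is the behaviour wanted when reading real runs.
#' @examples
#' b <- binningSpec(100, 200, 0.1)
#' mzBinIndex(c(100.0, 150.55), b)   # 0, 505
#' @export
mzBinIndex <- function(mz, spec) {
    stopifnot(is(spec, "BinningSpec"))
    if (any(!is.finite(mz)))
        stop("non-finite m/z value")
    if (any(mz < spec@mzMin | mz >= spec@mzMax))
        stop(sprintf("m/z value outside the binning range [%g, %g)",
            spec@mzMin, spec@mzMax))
    as.integer(floor((mz - spec@mzMin) / spec@binSize))
}

#' Read scans from an mzML file
#'
#' Thin reader over \pkg{mzR}: returns the spectrum list consumed by
#' [buildMassSpecMatrix()], one element per scan with the retention time and
#' the parallel m/z / intensity arrays.  Only MS1 scans are kept by default.
#'
#' @param path an mzML file (indexed or plain)
#' @param msLevel integer MS levels to keep, or NULL for all levels
#' @return a list of scans, each \code{list(rt =, mz =, intensity =)}, with
#'   attribute \code{sourceId} set to the file name
#' @export
readSpectra <- function(path, msLevel = 1L) {
    if (!requireNamespace("mzR", quietly = TRUE))
        stop("reading mzML requires the 'mzR' package")
    if (!file.exists(path))
        stop("file not found: ", path)
    fh <- mzR::openMSfile(path)
    on.exit(mzR::close(fh))
    hdr <- mzR::header(fh)
    keep <- if (is.null(msLevel)) seq_len(nrow(hdr))
            else which(hdr$msLevel %in% msLevel)
    if (!length(keep))
        stop("no scans at the requested MS level in ", path)
    pk <- mzR::peaks(fh)
    if (is.matrix(pk)) pk <- list(pk)
    scans <- lapply(keep, function(i) {
        m <- pk[[i]]
        list(rt = hdr$retentionTime[i],
             mz = as.numeric(m[, 1L]),
             intensity = as.numeric(m[, 2L]))
    })
    attr(scans, "sourceId") <- basename(path)
    scans
}

#' Build the scans x m/z-bins matrix from a spectrum list
#'
#' Bins every ion of every scan onto the shared m/z grid and sums all ion
#' intensities that fall into the same bin; one matrix row per scan, rows
#' ordered by retention time (ties keep file order).  Ions whose m/z lies
#' outside the binning range are dropped and counted.  Scans with no ions
#' yield an all-zero row, so row index always equals scan index.
#'
#' @param spectra scan list as returned by [readSpectra()]: each element has
#'   \code{rt} (seconds) and parallel numeric \code{mz} / \code{intensity}
#'   vectors (intensities non-negative)
#' @param spec a [BinningSpec-class]
#' @param sampleId sample identifier stored in the result
#' @param label optional class tag
#' @return an unnormalized [MassSpecMatrix-class]
#' @seealso [normalizeMatrix()]
#' @export
buildMassSpecMatrix <- function(spectra, spec, sampleId = NULL,
                                label = NA_character_) {
    stopifnot(is(spec, "BinningSpec"))
    if (!is.list(spectra) || length(spectra) == 0L)
        stop("'spectra' must be a non-empty list of scans")
    if (is.null(sampleId)) {
        sampleId <- attr(spectra, "sourceId")
        if (is.null(sampleId)) sampleId <- "sample"
    }
    rts <- vapply(spectra, function(s) as.numeric(s$rt[1L]), numeric(1))
    if (any(!is.finite(rts)))
        stop("every scan needs a finite retention time")
    ord <- order(rts)            # stable: ties keep file order
    nb <- nBins(spec)
    vals <- matrix(0, nrow = length(spectra), ncol = nb)
    dropped <- 0L
    for (t in seq_along(ord)) {
        s <- spectra[[ord[t]]]
        mz <- as.numeric(s$mz); inten <- as.numeric(s$intensity)
        if (length(mz) != length(inten))
            stop("scan ", ord[t], ": m/z and intensity lengths differ")
        if (!length(mz)) next
        if (any(inten < 0))
            stop("scan ", ord[t], ": negative intensity")
        inRange <- mz >= spec@mzMin & mz < spec@mzMax
        dropped <- dropped + sum(!inRange)
        if (!any(inRange)) next
        idx <- mzBinIndex(mz[inRange], spec) + 1L
        acc <- rowsum(inten[inRange], idx)
        vals[t, as.integer(rownames(acc))] <- acc[, 1L]
    }
    # strictly-increasing RT is required by the container; de-duplicate ties
    rtSorted <- rts[ord]
    if (anyDuplicated(rtSorted))
        rtSorted <- rtSorted + (seq_along(rtSorted) - 1) * 1e-9
    if (dropped > 0L)
        message(sprintf("buildMassSpecMatrix: dropped %d out-of-range ions",
            dropped))
    newMassSpecMatrix(vals, spec, rtSorted, normalized = FALSE,
        sampleId = sampleId, label = label, droppedIons = dropped)
}

## Upper percentile of a numeric vector as the ceiling order statistic
## (inverse-CDF definition): the smallest sorted value with at least p percent
## of the data at or below it.  Under this definition the percentile is always
## an attained data value, so dividing by it maps that value to exactly 1.
percentileOfNonzero <- function(v, percentile) {
    n <- length(v)
    k <- max(1L, min(n, as.integer(ceiling(percentile / 100 * n))))
    sort(v, partial = k)[k]
}

#' Percentile-normalize a mass-spec matrix
#'
#' Rescales a raw intensity matrix to [0, 1]: the given upper percentile of
#' the matrix's non-zero values becomes the maximum, everything is divided by
#' it and clipped to [0, 1].  Zeros stay exactly zero.  The percentile is the
#' ceiling order statistic of the non-zero multiset (inverse-CDF definition),
#' so the scale is an attained value and maps to exactly 1 — results are
#' bit-comparable across implementations of the same definition.
#'
#' @param matrix an unnormalized [MassSpecMatrix-class]
#' @param percentile percent scale, default 99.9
#' @return the normalized [MassSpecMatrix-class]
#' @export
normalizeMatrix <- function(matrix, percentile = 99.9) {
    stopifnot(is(matrix, "MassSpecMatrix"))
    if (isTRUE(matrix@normalized))
        stop("matrix is already normalized")
    if (percentile <= 0 || percentile > 100)
        stop("'percentile' must be in (0, 100]")
    v <- matrix@values
    nz <- v[v > 0]
    if (!length(nz)) {
        warning("all-zero matrix: nothing to normalize")
        out <- matrix
        out@normalized <- TRUE
        return(out)
    }
    scale <- percentileOfNonzero(nz, percentile)
    out <- matrix
    out@values <- pmin(v / scale, 1)
    out@normalized <- TRUE
    out
}
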