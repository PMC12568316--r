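#' @include AllClasses.R
NULL

## run 'expr' under a fixed RNG seed without disturbing the caller's stream
withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(suppressWarnings(
            rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(as.integer(seed))
    expr
}

#' Configuration of the synthetic LC-MS generator
#'
#' Describes the sparse scans x m/z-bins matrices the generator emulates:
#' isolated 2-D Gaussian signal blobs (peak clusters in RT x m/z) on a
#' near-empty background, plus sparse uniform "salt" noise, with a subset of
#' blobs intensity-modulated in the positive class.  All amplitudes live on
#' the normalized [0, 1] scale, so generated matrices are flagged normalized
#' and feed straight into the density/selection stages.
#'
#' @param nScans,nBins matrix dimensions (default 256 x 320, large relative
#'   to a 32-pixel patch so that most fixed-grid tiles see only background,
#'   as in real high-dimensional runs)
#' @param nPeaks number of planted signal clusters (default 12)
#' @param peakAmplitudeRange cluster apex amplitudes drawn uniformly from
#'   this interval (default c(0.4, 0.9))
#' @param peakSigmaRT,peakSigmaMZ Gaussian widths of the main peak in pixels
#'   (default 2)
#' @param minSeparation minimum pairwise Euclidean distance between cluster
#'   centers, pixels (default 36: beyond twice the cluster extent, so
#'   distinct hotspots never blend)
#' @param nSatellites weaker companion peaks per cluster, mimicking isotope /
#'   adduct partners and elution tails around a hotspot (default 4)
#' @param satelliteOffsetRange radial offset of satellites from their main
#'   peak, pixels (default c(5, 10))
#' @param satelliteAmpRange satellite apex as a fraction of the cluster
#'   amplitude (default c(0.25, 0.6))
#' @param satelliteSigma Gaussian width of satellites, pixels (default 1.4;
#'   kept small so the density maximum stays at the cluster core)
#' @param noiseDensity fraction of cells receiving a salt-noise point
#'   (default 0.02)
#' @param noiseAmplitude noise values drawn uniformly from
#'   (0, noiseAmplitude] (default 0.3)
#' @param nModulated how many blobs (the first ones) carry the class signal
#'   (default 3)
#' @param classEffect multiplicative amplitude factor applied to the
#'   modulated blobs in the positive class (default 2.5; 1.0 = null corpus)
#' @param amplitudeJitter per-sample, per-blob multiplicative jitter,
#'   uniform in \code{1 +/- amplitudeJitter} (default 0.15)
#' @param mzMin,binSize m/z metadata for the generated matrices (defaults
#'   100 Da, 0.1 Da)
#' @return a validated config (list of class \code{msimgSyntheticConfig})
#' @export
syntheticConfig <- function(nScans = 256L, nBins = 320L, nPeaks = 12L,
                            peakAmplitudeRange = c(0.4, 0.9),
                            peakSigmaRT = 2, peakSigmaMZ = 2,
                            minSeparation = 36, nSatellites = 4L,
                            satelliteOffsetRange = c(5, 10),
                            satelliteAmpRange = c(0.25, 0.6),
                            satelliteSigma = 1.4, noiseDensity = 0.02,
                            noiseAmplitude = 0.3, nModulated = 3L,
                            classEffect = 2.5, amplitudeJitter = 0.15,
                            mzMin = 100, binSize = 0.1) {
    cfg <- list(nScans = as.integer(nScans), nBins = as.integer(nBins),
        nPeaks = as.integer(nPeaks),
        peakAmplitudeRange = as.numeric(peakAmplitudeRange),
        peakSigmaRT = peakSigmaRT, peakSigmaMZ = peakSigmaMZ,
        minSeparation = minSeparation,
        nSatellites = as.integer(nSatellites),
        satelliteOffsetRange = as.numeric(satelliteOffsetRange),
        satelliteAmpRange = as.numeric(satelliteAmpRange),
        satelliteSigma = satelliteSigma, noiseDensity = noiseDensity,
        noiseAmplitude = noiseAmplitude,
        nModulated = as.integer(min(nModulated, nPeaks)),
        classEffect = classEffect, amplitudeJitter = amplitudeJitter,
        mzMin = mzMin, binSize = binSize)
    stopifnot(cfg$nScans >= 1, cfg$nBins >= 1, cfg$nPeaks >= 0,
        length(cfg$peakAmplitudeRange) == 2,
        all(cfg$peakAmplitudeRange >= 0), all(cfg$peakAmplitudeRange <= 1),
        cfg$peakSigmaRT > 0, cfg$peakSigmaMZ > 0,
        cfg$noiseDensity >= 0, cfg$noiseDensity <= 1,
        cfg$noiseAmplitude >= 0, cfg$noiseAmplitude <= 1,
        cfg$classEffect > 0, cfg$amplitudeJitter >= 0,
        cfg$amplitudeJitter < 1, cfg$binSize > 0,
        cfg$nSatellites >= 0, length(cfg$satelliteOffsetRange) == 2,
        all(cfg$satelliteOffsetRange >= 0),
        length(cfg$satelliteAmpRange) == 2,
        all(cfg$satelliteAmpRange >= 0), all(cfg$satelliteAmpRange <= 1),
        cfg$satelliteSigma > 0)
    class(cfg) <- "msimgSyntheticConfig"
    cfg
}

syntheticBinning <- function(cfg)
    binningSpec(cfg$mzMin, cfg$mzMin + cfg$nBins * cfg$binSize, cfg$binSize)

## sample one element of a vector (safe for length-1 vectors)
resample1 <- function(x) x[sample.int(length(x), 1L)]

## rejection-sample cluster centers respecting the minimum pairwise
## separation; a margin keeps the whole cluster (satellites included) inside
drawCenters <- function(cfg, maxTries = 5000L) {
    satExtent <- if (cfg$nSatellites > 0L)
        cfg$satelliteOffsetRange[2L] + ceiling(3 * cfg$satelliteSigma)
    else 0
    marginR <- min(ceiling(max(3 * cfg$peakSigmaRT, satExtent)) + 1,
                   max(1, (cfg$nScans - 1) %/% 2))
    marginC <- min(ceiling(max(3 * cfg$peakSigmaMZ, satExtent)) + 1,
                   max(1, (cfg$nBins - 1) %/% 2))
    rows <- integer(0); cols <- integer(0)
    tries <- 0L
    while (length(rows) < cfg$nPeaks) {
        tries <- tries + 1L
        if (tries > maxTries)
            stop(sprintf(
                "could not place %d peaks at separation %g in %d x %d",
                cfg$nPeaks, cfg$minSeparation, cfg$nScans, cfg$nBins))
        r <- resample1(marginR:(cfg$nScans - marginR))
        c <- resample1(marginC:(cfg$nBins - marginC))
        if (length(rows)) {
            d <- sqrt((rows - r)^2 + (cols - c)^2)
            if (min(d) < cfg$minSeparation) next
        }
        rows <- c(rows, r); cols <- c(cols, c)
    }
    cbind(row = rows, col = cols)
}

## additive Gaussian blob on a local window (+/- 4 sigma) of matrix 'm'
addBlob <- function(m, center, amplitude, sigmaR, sigmaC) {
    er <- ceiling(4 * sigmaR); ec <- ceiling(4 * sigmaC)
    rr <- max(1L, center[1L] - er):min(nrow(m), center[1L] + er)
    cc <- max(1L, center[2L] - ec):min(ncol(m), center[2L] + ec)
    g <- amplitude * exp(-outer((rr - center[1L])^2 / (2 * sigmaR^2),
                                (cc - center[2L])^2 / (2 * sigmaC^2), "+"))
    m[rr, cc] <- m[rr, cc] + g
    m
}

## draw the shared geometry of a corpus: cluster centers plus, per cluster,
## the satellite offsets and relative amplitudes
drawLayout <- function(cfg) {
    centers <- drawCenters(cfg)
    sats <- lapply(seq_len(cfg$nPeaks), function(k) {
        if (cfg$nSatellites == 0L)
            return(cbind(dr = numeric(0), dc = numeric(0), frac = numeric(0)))
        ## satellites are kept >= 7 px apart so no satellite pair forms a
        ## denser spot than the cluster core
        dr <- dc <- numeric(0)
        tries <- 0L
        while (length(dr) < cfg$nSatellites && tries < 500L) {
            tries <- tries + 1L
            ang <- stats::runif(1L, 0, 2 * pi)
            rad <- stats::runif(1L, cfg$satelliteOffsetRange[1L],
                                cfg$satelliteOffsetRange[2L])
            y <- rad * sin(ang); x <- rad * cos(ang)
            if (length(dr) &&
                min(sqrt((dr - y)^2 + (dc - x)^2)) < 7) next
            dr <- c(dr, y); dc <- c(dc, x)
        }
        cbind(dr = dr, dc = dc,
              frac = stats::runif(length(dr),
                                  cfg$satelliteAmpRange[1L],
                                  cfg$satelliteAmpRange[2L]))
    })
    list(centers = centers, satellites = sats)
}

renderSample <- function(cfg, layout, amplitudes, sampleId, label) {
    centers <- layout$centers
    m <- matrix(0, cfg$nScans, cfg$nBins)
    for (k in seq_len(nrow(centers))) {
        m <- addBlob(m, centers[k, ], amplitudes[k],
                     cfg$peakSigmaRT, cfg$peakSigmaMZ)
        s <- layout$satellites[[k]]
        for (j in seq_len(nrow(s)))
            m <- addBlob(m,
                c(round(centers[k, 1L] + s[j, "dr"]),
                  round(centers[k, 2L] + s[j, "dc"])),
                amplitudes[k] * s[j, "frac"],
                cfg$satelliteSigma, cfg$satelliteSigma)
    }
    if (cfg$noiseDensity > 0 && cfg$noiseAmplitude > 0) {
        nNoise <- floor(cfg$noiseDensity * length(m))
        if (nNoise > 0) {
            cells <- sample.int(length(m), nNoise)
            m[cells] <- m[cells] + stats::runif(nNoise, 0, cfg$noiseAmplitude)
        }
    }
    m <- pmin(m, 1)
    newMassSpecMatrix(m, syntheticBinning(cfg),
        rtAxis = as.numeric(seq_len(cfg$nScans)), normalized = TRUE,
        sampleId = sampleId, label = label)
}

sampleAmplitudes <- function(cfg, label) {
    a <- stats::runif(cfg$nPeaks, cfg$peakAmplitudeRange[1L],
                      cfg$peakAmplitudeRange[2L])
    if (identical(label, "case") && cfg$nModulated > 0L)
        a[seq_len(cfg$nModulated)] <- a[seq_len(cfg$nModulated)] *
            cfg$classEffect
    pmin(a, 1)
}

#' Generate one synthetic LC-MS matrix with ground truth
#'
#' Draws blob centers by rejection sampling under the configured minimum
#' separation, renders the Gaussian blobs plus salt noise, clips to [0, 1]
#' and returns the matrix together with the planted truth.  The positive
#' class (\code{label = "case"}) has its designated blobs scaled by
#' \code{classEffect}.  Identical seeds give identical output.
#'
#' @param config a [syntheticConfig()] object
#' @param label \code{"control"} or \code{"case"}
#' @param seed integer RNG seed
#' @return list with elements \code{matrix} (a normalized
#'   [MassSpecMatrix-class]) and \code{truth} (list: \code{centers} matrix,
#'   \code{modulated} blob indices, \code{amplitudes}, \code{label})
#' @export
generateSample <- function(config, label = "control", seed = 1L) {
    stopifnot(inherits(config, "msimgSyntheticConfig"),
              label %in% c("control", "case"))
    withSeed(seed, {
        layout <- drawLayout(config)
        amp <- sampleAmplitudes(config, label)
        msm <- renderSample(config, layout, amp,
            sampleId = sprintf("synth_%s_seed%d", label, as.integer(seed)),
            label = label)
        list(matrix = msm,
             truth = list(centers = layout$centers,
                          satellites = layout$satellites,
                          modulated = seq_len(config$nModulated),
                          amplitudes = amp, label = label))
    })
}

#' Generate a labeled two-class synthetic corpus
#'
#' All samples share one blob-center layout and one set of base apex
#' amplitudes (both drawn once from the seed); each sample then gets
#' independent multiplicative amplitude jitter and fresh salt noise, and
#' positive-class samples have the designated blobs scaled by
#' \code{classEffect}.  With \code{classEffect = 1} the two classes are
#' exchangeable by construction (a null corpus).
#'
#' @param config a [syntheticConfig()] object
#' @param nPerClass samples per class (labels balanced)
#' @param seed integer RNG seed
#' @return list with \code{samples} (list of normalized
#'   [MassSpecMatrix-class], controls first), \code{labels} (character),
#'   and \code{truth} (shared \code{centers}, \code{modulated} ids,
#'   \code{baseAmplitudes})
#' @export
generateDataset <- function(config, nPerClass, seed = 1L) {
    stopifnot(inherits(config, "msimgSyntheticConfig"), nPerClass >= 1)
    withSeed(seed, {
        layout <- drawLayout(config)
        baseAmp <- stats::runif(config$nPeaks, config$peakAmplitudeRange[1L],
                                config$peakAmplitudeRange[2L])
        labels <- rep(c("control", "case"), each = nPerClass)
        samples <- vector("list", length(labels))
        for (i in seq_along(labels)) {
            jit <- if (config$amplitudeJitter > 0)
                stats::runif(config$nPeaks, 1 - config$amplitudeJitter,
                             1 + config$amplitudeJitter)
            else rep(1, config$nPeaks)
            a <- baseAmp * jit
            if (labels[i] == "case" && config$nModulated > 0L)
                a[seq_len(config$nModulated)] <-
                    a[seq_len(config$nModulated)] * config$classEffect
            samples[[i]] <- renderSample(config, layout, pmin(a, 1),
                sampleId = sprintf("synth_%03d_%s", i, labels[i]),
                label = labels[i])
        }
        list(samples = samples, labels = labels,
             truth = list(centers = layout$centers,
                          satellites = layout$satellites,
                          modulated = seq_len(config$nModulated),
                          baseAmplitudes = baseAmp))
    })
}

#' Write a matrix out as an mzML fixture
#'
#' Serializes a mass-spec matrix as a plausible mzML run: one spectrum per
#' scan row, and one ion per non-zero cell, placed at the center m/z of its
#' bin so that re-binning with the same [BinningSpec-class] reproduces the
#' matrix.  Useful for exercising the mzML reader without real instrument
#' files.
#'
#' @param matrix a [MassSpecMatrix-class]
#' @param path output file path (.mzML)
#' @return \code{path}, invisibly
#' @seealso [readSpectra()], [buildMassSpecMatrix()]
#' @export
writeMzMLFixture <- function(matrix, path) {
    if (!requireNamespace("mzR", quietly = TRUE))
        stop("writing mzML requires the 'mzR' package")
    stopifnot(is(matrix, "MassSpecMatrix"))
    v <- matrix@values
    b <- matrix@binning
    n <- nrow(v)
    pks <- vector("list", n)
    for (t in seq_len(n)) {
        j <- which(v[t, ] > 0)
        mzs <- b@mzMin + (j - 0.5) * b@binSize
        pks[[t]] <- cbind(mz = mzs, intensity = v[t, j])
    }
    counts <- vapply(pks, nrow, integer(1))
    hdr <- data.frame(
        seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = 1L,
        polarity = 1L, peaksCount = counts,
        totIonCurrent = vapply(pks, function(p) sum(p[, 2L]), numeric(1)),
        retentionTime = matrix@rtAxis,
        basePeakMZ = vapply(pks, function(p)
            if (nrow(p)) p[which.max(p[, 2L]), 1L] else 0, numeric(1)),
        basePeakIntensity = vapply(pks, function(p)
            if (nrow(p)) max(p[, 2L]) else 0, numeric(1)),
        collisionEnergy = 0, ionisationEnergy = 0,
        lowMZ = vapply(pks, function(p)
            if (nrow(p)) min(p[, 1L]) else 0, numeric(1)),
        highMZ = vapply(pks, function(p)
            if (nrow(p)) max(p[, 1L]) else 0, numeric(1)),
        precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
        precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
        mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
        injectionTime = 0, filterString = "",
        spectrumId = sprintf("scan=%d", seq_len(n)), centroided = TRUE,
        ionMobilityDriftTime = NA_real_,
        isolationWindowTargetMZ = NA_real_,
        isolationWindowLowerOffset = NA_real_,
        isolationWindowUpperOffset = NA_real_,
        scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_)
    mzR::writeMSData(pks, path, header = hdr, outformat = "mzml")
    invisible(path)
}
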