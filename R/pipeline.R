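#' @include AllClasses.R
NULL

#' Fit the patch-selection model on a training corpus
#'
#' Runs the full training-side pipeline on a list of normalized matrices:
#' per sample, threshold to a signal mask, estimate the density map and
#' extract candidate peaks by non-maximum suppression; pool all candidates;
#' run the greedy density-aware coverage selection; and rank the selected
#' centers by mean patch entropy across the corpus.  The result freezes
#' everything needed to transform new samples.
#'
#' @param samples list of normalized [MassSpecMatrix-class] objects sharing
#'   one binning and dimension
#' @param tauIntensity signal-mask threshold; default 0.01
#' @param window density box-window side w (odd); default 9
#' @param tauDensity minimum density of an NMS candidate; default 5
#' @param maxPeaks per-sample NMS budget; default 100
#' @param patchHeight,patchWidth patch size in pixels; default 224
#' @param tauMinPeaks greedy-coverage stopping threshold; default 2
#' @param numPatches image channel count; default 64.  Fails with the
#'   achievable maximum in the message when the corpus cannot support it —
#'   the number of selectable centers is a property of the data.
#' @param padValue patch padding value; default 0
#' @param percentile normalization percentile recorded for provenance
#'   (matrices arrive already normalized); default 99.9
#' @param verbose log per-stage counts; default TRUE
#' @return a [MsimgModel-class]
#' @seealso [msimgTransform()], [writeMsimgModel()]
#' @export
msimgFit <- function(samples, tauIntensity = 0.01, window = 9L,
                     tauDensity = 5, maxPeaks = 100L,
                     patchHeight = 224L, patchWidth = 224L,
                     tauMinPeaks = 2, numPatches = 64L, padValue = 0,
                     percentile = 99.9, verbose = TRUE) {
    if (!length(samples)) stop("no training samples")
    if (!all(vapply(samples, function(s)
            is(s, "MassSpecMatrix") && isTRUE(s@normalized), logical(1))))
        stop("all training samples must be normalized MassSpecMatrix objects")
    b <- samples[[1L]]@binning
    say <- function(...) if (verbose) message(sprintf(...))
    peaks <- vector("list", length(samples))
    for (i in seq_along(samples)) {
        dm <- densityMap(binarize(samples[[i]], tauIntensity), window)
        peaks[[i]] <- nmsExtractPeaks(dm, tauDensity, maxPeaks,
            suppressHeight = patchHeight, suppressWidth = patchWidth,
            sampleId = samples[[i]]@sampleId)
    }
    pool <- do.call(rbind, peaks)
    say("msimgFit: %d candidate peaks pooled from %d samples (%.1f/sample)",
        nrow(pool), length(samples), nrow(pool) / length(samples))
    if (!nrow(pool))
        stop("no candidate peaks found; lower tauIntensity/tauDensity")
    sel <- dapsSelect(pool, patchHeight, patchWidth, tauMinPeaks)
    say("msimgFit: coverage selection kept %d centers (scores %s..%s)",
        nrow(sel), if (nrow(sel)) max(sel$score) else "-",
        if (nrow(sel)) min(sel$score) else "-")
    if (nrow(sel) < numPatches)
        stop(sprintf(paste0(
            "numPatches = %d requested but only %d non-overlapping centers ",
            "are selectable from this corpus; the achievable maximum is %d"),
            numPatches, nrow(sel), nrow(sel)))
    golden <- rankGoldenLocations(samples, sel, patchHeight, patchWidth,
                                  numPatches, padValue)
    say("msimgFit: kept %d golden locations, mean entropy %.3f-%.3f bits",
        numPatches(golden), max(meanEntropies(golden)),
        min(meanEntropies(golden)))
    new("MsimgModel", binning = b, percentile = as.numeric(percentile),
        tauIntensity = as.numeric(tauIntensity), window = as.integer(window),
        tauDensity = as.numeric(tauDensity), maxPeaks = as.integer(maxPeaks),
        patchHeight = as.integer(patchHeight),
        patchWidth = as.integer(patchWidth),
        radius = coverageRadius(patchHeight, patchWidth),
        tauMinPeaks = as.numeric(tauMinPeaks), centers = sel,
        golden = golden,
        version = as.character(utils::packageVersion("msimg")),
        created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' Encode a sample with a fitted model
#'
#' Applies the frozen golden locations to one normalized matrix (train or
#' held-out alike) and returns its multi-channel image.  Purely
#' deterministic; the model is not modified and no training data is needed.
#'
#' @param model a [MsimgModel-class]
#' @param sample a normalized [MassSpecMatrix-class] on the same binning
#'   grid as the training corpus
#' @return a [MultiChannelImage-class]
#' @export
msimgTransform <- function(model, sample) {
    stopifnot(is(model, "MsimgModel"), is(sample, "MassSpecMatrix"))
    if (!isTRUE(sample@normalized))
        stop("sample must be normalized before transformation")
    mb <- model@binning; sb <- sample@binning
    if (abs(mb@mzMin - sb@mzMin) > 1e-9 || abs(mb@binSize - sb@binSize) > 1e-9 ||
        nBins(mb) != nBins(sb))
        stop("sample binning does not match the model's binning (provenance mismatch)")
    buildMultiChannelImage(sample, model@golden)
}

#' Serialize / restore a fitted model
#'
#' The model is written as human-diffable JSON holding the binning grid, all
#' thresholds, the selected centers and the golden locations with their mean
#' entropies.  Coordinates in the file are 1-based (row = scan index, col =
#' m/z bin index).  \code{readMsimgModel()} restores an object that
#' transforms samples identically to the original.
#'
#' @param model a [MsimgModel-class]
#' @param path JSON file path
#' @return \code{writeMsimgModel}: \code{path} invisibly;
#'   \code{readMsimgModel}: the restored [MsimgModel-class]
#' @export
writeMsimgModel <- function(model, path) {
    stopifnot(is(model, "MsimgModel"))
    g <- model@golden
    obj <- list(
        format = "msimg-model-v1",
        coordinates = "1-based (row = scan index, col = m/z bin index)",
        version = model@version, created = model@created,
        binning = list(mzMin = model@binning@mzMin,
                       mzMax = model@binning@mzMax,
                       binSize = model@binning@binSize),
        percentile = model@percentile, tauIntensity = model@tauIntensity,
        window = model@window, tauDensity = model@tauDensity,
        maxPeaks = model@maxPeaks, patchHeight = model@patchHeight,
        patchWidth = model@patchWidth, radius = model@radius,
        tauMinPeaks = model@tauMinPeaks,
        centers = model@centers,
        golden = list(rows = as.integer(g@locations[, "row"]),
                      cols = as.integer(g@locations[, "col"]),
                      meanEntropies = g@meanEntropies,
                      padValue = g@padValue,
                      sourceDim = g@sourceDim))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}

#' @rdname writeMsimgModel
#' @export
readMsimgModel <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!identical(obj$format, "msimg-model-v1"))
        stop("not an msimg model file: ", path)
    golden <- new("GoldenLocations",
        locations = cbind(row = as.integer(obj$golden$rows),
                          col = as.integer(obj$golden$cols)),
        meanEntropies = as.numeric(obj$golden$meanEntropies),
        patchHeight = as.integer(obj$patchHeight),
        patchWidth = as.integer(obj$patchWidth),
        padValue = as.numeric(obj$golden$padValue),
        sourceDim = as.integer(obj$golden$sourceDim))
    new("MsimgModel",
        binning = binningSpec(obj$binning$mzMin, obj$binning$mzMax,
                              obj$binning$binSize),
        percentile = as.numeric(obj$percentile),
        tauIntensity = as.numeric(obj$tauIntensity),
        window = as.integer(obj$window),
        tauDensity = as.numeric(obj$tauDensity),
        maxPeaks = as.integer(obj$maxPeaks),
        patchHeight = as.integer(obj$patchHeight),
        patchWidth = as.integer(obj$patchWidth),
        radius = as.numeric(obj$radius),
        tauMinPeaks = as.numeric(obj$tauMinPeaks),
        centers = as.data.frame(obj$centers),
        golden = golden, version = as.character(obj$version),
        created = as.character(obj$created))
}

## per-image pooled features: mean and sd of each channel
imageFeatures <- function(images) {
    t(vapply(images, function(im) {
        nc <- dim(im@tensor)[1L]
        m <- vapply(seq_len(nc), function(ch) mean(im@tensor[ch, , ]),
                    numeric(1))
        s <- vapply(seq_len(nc), function(ch) stats::sd(im@tensor[ch, , ]),
                    numeric(1))
        c(m, s)
    }, numeric(2L * dim(images[[1L]]@tensor)[1L])))
}

#' Linear-classifier separability check
#'
#' A lightweight sanity check of how class-separable the image encoding is:
#' each image is pooled to per-channel mean and standard deviation features,
#' and a ridge-regularized logistic regression is evaluated under stratified
#' k-fold cross-validation.  This is a floor, not a benchmark — the encoding
#' is designed as CNN input — but a separable corpus should score highly and
#' a null corpus should sit at chance.
#'
#' @param images list of [MultiChannelImage-class] objects
#' @param labels class labels; taken from the images when NULL.  Exactly two
#'   classes are required.
#' @param folds number of CV folds; default 5
#' @param seed RNG seed for the fold assignment; fixed seed, fixed numbers
#' @param lambda ridge penalty passed to \pkg{glmnet}; default 0.01
#' @return list with \code{accuracy}, \code{accuracySD}, \code{f1},
#'   \code{f1SD}, \code{foldAccuracy}, \code{foldF1}, \code{folds},
#'   \code{n}
#' @export
evaluateSeparability <- function(images, labels = NULL, folds = 5L,
                                 seed = 1L, lambda = 0.01) {
    if (is.null(labels))
        labels <- vapply(images, function(im) im@label, character(1))
    labels <- as.character(labels)
    if (length(labels) != length(images))
        stop("one label per image is required")
    classes <- sort(unique(labels))
    if (length(classes) != 2L)
        stop("exactly two classes are required, got ",
             length(classes))
    pos <- if ("case" %in% classes) "case" else classes[2L]
    X <- imageFeatures(images)
    y <- as.integer(labels == pos)
    n <- length(y)
    withSeed(seed, {
        fold <- integer(n)
        for (cl in classes) {
            idx <- which(labels == cl)
            fold[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
        }
        acc <- f1 <- numeric(folds)
        for (k in seq_len(folds)) {
            test <- fold == k
            fit <- glmnet::glmnet(X[!test, , drop = FALSE], y[!test],
                family = "binomial", alpha = 0, lambda = lambda,
                standardize = TRUE)
            pr <- as.numeric(stats::predict(fit,
                newx = X[test, , drop = FALSE], type = "response"))
            pred <- as.integer(pr > 0.5)
            acc[k] <- mean(pred == y[test])
            tp <- sum(pred == 1 & y[test] == 1)
            fp <- sum(pred == 1 & y[test] == 0)
            fn <- sum(pred == 0 & y[test] == 1)
            f1[k] <- if (2 * tp + fp + fn == 0) 0
                     else 2 * tp / (2 * tp + fp + fn)
        }
        list(accuracy = mean(acc), accuracySD = stats::sd(acc),
             f1 = mean(f1), f1SD = stats::sd(f1),
             foldAccuracy = acc, foldF1 = f1, folds = folds, n = n)
    })
}
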