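#' @include AllClasses.R
NULL

#' Write / read a mass-spec matrix as annotated TSV
#'
#' Plain-text, diff-friendly serialization of a [MassSpecMatrix-class]: a
#' short header of \code{#}-prefixed lines (format tag, coordinate
#' convention, one JSON metadata line) followed by the dense matrix, one
#' tab-separated row per scan.  \code{readMsMatrix()} restores the object
#' exactly (values round-trip through full-precision decimal text).
#'
#' @param matrix a [MassSpecMatrix-class]
#' @param path output file (.tsv; conventionally .msm.tsv)
#' @return \code{writeMsMatrix}: \code{path} invisibly;
#'   \code{readMsMatrix}: the restored [MassSpecMatrix-class]
#' @export
writeMsMatrix <- function(matrix, path) {
    stopifnot(is(matrix, "MassSpecMatrix"))
    meta <- list(mzMin = matrix@binning@mzMin, mzMax = matrix@binning@mzMax,
        binSize = matrix@binning@binSize, rtAxis = matrix@rtAxis,
        normalized = matrix@normalized, sampleId = matrix@sampleId,
        label = matrix@label, droppedIons = matrix@droppedIons)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("# msimg mass-spec matrix v1",
        "# coordinates: 1-based (row = scan index, col = m/z bin index)",
        paste0("# meta: ",
            jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                             na = "null"))), con)
    utils::write.table(format(matrix@values, digits = 17, trim = TRUE,
                              scientific = TRUE),
        con, sep = "\t", row.names = FALSE, col.names = FALSE,
        quote = FALSE)
    invisible(path)
}

#' @rdname writeMsMatrix
#' @export
readMsMatrix <- function(path) {
    lines <- readLines(path, n = 3L)
    if (!identical(lines[1L], "# msimg mass-spec matrix v1"))
        stop("not an msimg matrix file: ", path)
    meta <- jsonlite::fromJSON(sub("^# meta: ", "", lines[3L]))
    vals <- as.matrix(utils::read.table(path, sep = "\t", comment.char = "#",
        colClasses = "numeric"))
    dimnames(vals) <- NULL
    newMassSpecMatrix(vals,
        binningSpec(meta$mzMin, meta$mzMax, meta$binSize),
        rtAxis = as.numeric(meta$rtAxis),
        normalized = isTRUE(meta$normalized),
        sampleId = meta$sampleId,
        label = if (is.null(meta$label)) NA_character_
                else as.character(meta$label),
        droppedIons = as.integer(meta$droppedIons))
}

#' Write / read candidate-peak and center tables
#'
#' TSV serialization for the tabular intermediates (NMS peaks, selected
#' centers), with a comment header documenting the 1-based coordinate
#' convention.
#'
#' @param table a data.frame (e.g. from [nmsExtractPeaks()] or
#'   [dapsSelect()])
#' @param path TSV file path
#' @return \code{writePeakTable}: \code{path} invisibly;
#'   \code{readPeakTable}: the data.frame
#' @export
writePeakTable <- function(table, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(
        "# msimg peak table; coordinates 1-based (row = scan, col = m/z bin)",
        con)
    suppressWarnings(utils::write.table(table, con, sep = "\t",
        row.names = FALSE, quote = FALSE))
    invisible(path)
}

#' @rdname writePeakTable
#' @export
readPeakTable <- function(path) {
    utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                      stringsAsFactors = FALSE)
}

#' Write a multi-channel image as annotated TSV
#'
#' Stores the (numPatches, h, w) tensor channel-by-channel: a JSON metadata
#' header, then for each channel a \code{## channel c @ (row, col)} marker
#' followed by its h x w patch.  \code{readMsImage()} restores the object.
#'
#' @param image a [MultiChannelImage-class]
#' @param path output file (.tsv)
#' @return \code{writeMsImage}: \code{path} invisibly; \code{readMsImage}:
#'   the restored [MultiChannelImage-class]
#' @export
writeMsImage <- function(image, path) {
    stopifnot(is(image, "MultiChannelImage"))
    d <- dim(image@tensor)
    meta <- list(numPatches = d[1L], patchHeight = d[2L],
        patchWidth = d[3L], sampleId = image@sampleId, label = image@label)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("# msimg multi-channel image v1",
        "# coordinates: 1-based (row = scan index, col = m/z bin index)",
        paste0("# meta: ",
            jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                             na = "null"))), con)
    for (ch in seq_len(d[1L])) {
        writeLines(sprintf("## channel %d @ (%d, %d)", ch,
            image@locations[ch, 1L], image@locations[ch, 2L]), con)
        utils::write.table(format(image@tensor[ch, , ], digits = 17,
                                  trim = TRUE, scientific = TRUE),
            con, sep = "\t", row.names = FALSE, col.names = FALSE,
            quote = FALSE)
    }
    invisible(path)
}

#' @rdname writeMsImage
#' @export
readMsImage <- function(path) {
    lines <- readLines(path)
    if (!identical(lines[1L], "# msimg multi-channel image v1"))
        stop("not an msimg image file: ", path)
    meta <- jsonlite::fromJSON(sub("^# meta: ", "", lines[3L]))
    np <- meta$numPatches; h <- meta$patchHeight; w <- meta$patchWidth
    tens <- array(0, dim = c(np, h, w))
    locs <- matrix(0L, np, 2L, dimnames = list(NULL, c("row", "col")))
    chHead <- grep("^## channel ", lines)
    if (length(chHead) != np) stop("corrupt image file: ", path)
    for (k in seq_len(np)) {
        hd <- lines[chHead[k]]
        locs[k, ] <- as.integer(
            strsplit(gsub("^.*\\(|\\).*$", "", hd), ",\\s*")[[1L]])
        block <- lines[(chHead[k] + 1L):(chHead[k] + h)]
        tens[k, , ] <- do.call(rbind,
            lapply(strsplit(block, "\t"), as.numeric))
    }
    new("MultiChannelImage", tensor = tens, sampleId = meta$sampleId,
        label = if (is.null(meta$label)) NA_character_
                else as.character(meta$label),
        locations = locs)
}
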