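#' @include AllClasses.R
NULL

#' Coverage radius of a patch
#'
#' Distance from a patch's center to its diagonal corner,
#' \eqn{r = \sqrt{(h/2)^2 + (w/2)^2}}.  A circle of this radius around a
#' selected center covers (at least) the whole patch, so two centers farther
#' apart than r have disjoint coverage circles' centers.
#'
#' @param patchHeight,patchWidth patch size in pixels (> 0)
#' @return the radius r in pixels
#' @examples
#' coverageRadius(6, 8)    # 5: the 3-4-5 triangle
#' @export
coverageRadius <- function(patchHeight, patchWidth) {
    if (patchHeight <= 0 || patchWidth <= 0)
        stop("patch sizes must be positive")
    sqrt((patchHeight / 2)^2 + (patchWidth / 2)^2)
}

## neighbor lists within 'radius' (Euclidean, boundary inclusive), computed in
## row blocks so memory stays O(block * n) even for large pools; this is the
## package's radius-query index (each point's list includes itself)
radiusNeighbors <- function(rows, cols, radius, block = 512L) {
    n <- length(rows)
    r2 <- radius^2 + 1e-9       # tolerate float noise at the boundary
    nbrs <- vector("list", n)
    for (start in seq(1L, n, by = block)) {
        idx <- start:min(n, start + block - 1L)
        d2 <- outer(rows[idx], rows, "-")^2 + outer(cols[idx], cols, "-")^2
        inside <- d2 <= r2
        for (k in seq_along(idx))
            nbrs[[idx[k]]] <- which(inside[k, ])
    }
    nbrs
}

#' Coverage score of a candidate peak
#'
#' The number of currently available candidate peaks (itself included) lying
#' within Euclidean distance \code{radius} of point \code{i} — the quantity
#' the greedy selection maximizes each round.
#'
#' @param points data.frame of pooled candidate peaks with columns \code{row}
#'   and \code{col}
#' @param i index of the point to score (must be available)
#' @param radius coverage radius in pixels (boundary inclusive)
#' @param available logical vector marking the still-available points;
#'   defaults to all available
#' @return integer coverage count, >= 1
#' @export
scorePoint <- function(points, i, radius, available = NULL) {
    if (is.null(available)) available <- rep(TRUE, nrow(points))
    if (!available[i])
        stop("point ", i, " is not available")
    d2 <- (points$row - points$row[i])^2 + (points$col - points$col[i])^2
    sum(available & d2 <= radius^2 + 1e-9)
}

#' Greedy density-aware selection of non-overlapping patch centers
#'
#' Operates on the pooled candidate peaks of all training samples.  Each
#' round scores every still-available point by how many available points its
#' coverage circle contains, picks the highest-scoring one (ties: smallest
#' row, then smallest column) as the next patch center, and marks everything
#' inside its circle — itself included — unavailable.  Selection stops when
#' the best score drops below \code{tauMinPeaks} (the remaining points are
#' too sparse to anchor a patch) or no points remain.
#'
#' Any two returned centers are therefore separated by more than
#' \code{radius}, which guarantees spatially distinct patches.
#'
#' @param points data.frame of pooled candidate peaks, columns \code{row},
#'   \code{col} (e.g. row-bound outputs of [nmsExtractPeaks()])
#' @param patchHeight,patchWidth patch size defining the coverage radius via
#'   [coverageRadius()]
#' @param tauMinPeaks stop when the best coverage score is below this;
#'   default 2 (singleton stragglers never anchor a patch)
#' @param radius override the coverage radius (pixels); computed from the
#'   patch size when NULL
#' @return data.frame with columns \code{rank}, \code{row}, \code{col},
#'   \code{score}, in selection order; scores are non-increasing
#' @export
dapsSelect <- function(points, patchHeight, patchWidth, tauMinPeaks = 2,
                       radius = NULL) {
    if (!is.data.frame(points) || !all(c("row", "col") %in% names(points)))
        stop("'points' must be a data.frame with columns row and col")
    if (nrow(points) == 0L)
        stop("empty candidate pool")
    if (tauMinPeaks < 1) stop("'tauMinPeaks' must be >= 1")
    if (is.null(radius)) radius <- coverageRadius(patchHeight, patchWidth)
    n <- nrow(points)
    nbrs <- radiusNeighbors(points$row, points$col, radius)
    avail <- rep(TRUE, n)
    selRow <- integer(0); selCol <- integer(0); selScore <- integer(0)
    repeat {
        cand <- which(avail)
        if (!length(cand)) break
        scores <- vapply(cand, function(i) sum(avail[nbrs[[i]]]), integer(1))
        best <- max(scores)
        if (best < tauMinPeaks) break
        top <- cand[scores == best]
        top <- top[order(points$row[top], points$col[top])[1L]]
        selRow <- c(selRow, points$row[top])
        selCol <- c(selCol, points$col[top])
        selScore <- c(selScore, best)
        avail[nbrs[[top]]] <- FALSE
    }
    data.frame(rank = seq_along(selRow), row = selRow, col = selCol,
               score = selScore)
}
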