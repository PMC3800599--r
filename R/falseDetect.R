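## False-contour detection: a point of a stopped snake is "false" when, in
## the 3x3 grid neighborhood around it, every external force vector is
## nearly parallel to the contour tangent (the stalled configuration at a
## concavity mouth); real contour points see forces nearly perpendicular to
## the contour.  Segment-level judgement then aggregates the per-point flags.

#' Maximum tangent-vs-force angle in a 3x3 neighborhood
#'
#' Computes \eqn{T = \max_{(i,j)} t_{(i,j)}} over the 3x3 block of grid
#' nodes centered on the node nearest to \code{p}, where each
#' \eqn{t_{(i,j)}} is the acute angle between the (undirected) tangent line
#' and the force vector at node (i, j), i.e. \eqn{\arccos|t \cdot \hat v|}
#' in [0, 90] degrees.  Force vectors with magnitude below \code{minForce}
#' are skipped; if all nine are skipped the angle is 0 degrees, so a contour
#' stalled in a null field is treated as false.
#'
#' @param tangent unit tangent vector, length 2.
#' @param p point (x, y) inside the field bounds.
#' @param fld a \code{VectorField}.
#' @param minForce magnitude floor for a force vector to participate.
#' @return angle in degrees, in [0, 90].
#' @export
pointMaxAngle <- function(tangent, p, fld, minForce = 1e-8) {
    h <- nrow(fld@u); w <- ncol(fld@u)
    cx <- min(max(round(p[1]), 2L), w - 1L)
    cy <- min(max(round(p[2]), 2L), h - 1L)
    rows <- (cy - 1L):(cy + 1L)
    cols <- (cx - 1L):(cx + 1L)
    uu <- as.vector(fld@u[rows, cols])
    vv <- as.vector(fld@v[rows, cols])
    mag <- sqrt(uu^2 + vv^2)
    keep <- mag >= minForce
    if (!any(keep)) return(0)
    cosang <- abs(tangent[1] * uu[keep] + tangent[2] * vv[keep]) / mag[keep]
    max(acos(pmin(pmax(cosang, -1), 1))) * 180 / pi
}

#' Flag false points of a stopped contour
#'
#' A point is flagged iff its \code{\link{pointMaxAngle}} is <= theta: every
#' force around it runs along the contour rather than across it.  Taking
#' the maximum over the nine neighboring forces makes the test robust to
#' single irregular force directions near the real contour.
#'
#' @param contour a stopped \code{Contour}.
#' @param fld the external \code{VectorField} it evolved in.
#' @param params a \code{\link{detectorParams}} object.
#' @return logical vector of per-point flags.
#' @export
classifyPoints <- function(contour, fld, params = detectorParams()) {
    tg <- contourTangents(contour)
    p <- contour@points
    vapply(seq_len(nrow(p)), function(i)
        pointMaxAngle(tg[i, ], p[i, ], fld, params@minForce) <= params@theta,
        logical(1))
}

#' Segment-level false-contour judgement
#'
#' The contour is partitioned into \code{l = max(1, round(N /
#' pointsPerSegment))} contiguous, equal-as-possible segments starting at
#' point 1.  Segment i is false iff
#' \deqn{\left(\sum_{X(s) \in L_i} FP_{X(s)}\right) \cdot l / U > \eta}
#' with U = N the contour point count (strict inequality), i.e. iff the
#' within-segment fraction of false points exceeds eta.  Adjacent false
#' segments (cyclically) are merged into maximal false runs for downstream
#' magnet processing.
#'
#' @param contour a \code{Contour}.
#' @param flags logical per-point flags from \code{\link{classifyPoints}}.
#' @param params a \code{\link{detectorParams}} object.
#' @return A \code{\link{FalseSegmentReport-class}} object.
#' @export
detectFalseSegments <- function(contour, flags, params = detectorParams()) {
    n <- nrow(contour@points)
    stopifnot(length(flags) == n)
    l <- max(1L, as.integer(round(n / params@pointsPerSegment)))
    ## equal-as-possible contiguous blocks starting at index 1
    sizes <- rep(n %/% l, l)
    extra <- n %% l
    if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    ends <- cumsum(sizes)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    isFalse <- vapply(seq_len(l), function(i)
        sum(flags[starts[i]:ends[i]]) * l / n > params@eta, logical(1))
    seg <- data.frame(start = starts, end = ends, isFalse = isFalse)
    ## merge cyclically adjacent false segments into maximal runs
    runs <- list()
    if (any(isFalse)) {
        fi <- which(isFalse)
        grp <- cumsum(c(1L, diff(fi) != 1L))
        byGrp <- split(fi, grp)
        ## wrap-around: last segment false and first segment false
        if (length(byGrp) > 1L && isFalse[l] && isFalse[1L]) {
            byGrp[[1L]] <- c(byGrp[[length(byGrp)]], byGrp[[1L]])
            byGrp[[length(byGrp)]] <- NULL
        }
        runs <- lapply(byGrp, function(segIdx)
            unlist(lapply(segIdx, function(i) starts[i]:ends[i]), use.names = FALSE))
        names(runs) <- NULL
    }
    new("FalseSegmentReport", pointFlags = as.logical(flags), segments = seg,
        nFalseSegments = sum(isFalse), falseRuns = runs)
}

#' Export a false-segment report as JSON
#'
#' Writes the per-point flags, segment ranges and the parameters used, for
#' debugging overlays.
#'
#' @param report a \code{FalseSegmentReport}.
#' @param params the \code{DetectorParams} used.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeReportJSON <- function(report, params, path) {
    jsonlite::write_json(list(
        point_flags = as.integer(report@pointFlags),
        segments = report@segments,
        n_false_segments = report@nFalseSegments,
        parameters = list(theta = params@theta,
                          points_per_segment = params@pointsPerSegment,
                          eta = params@eta, min_force = params@minForce)),
        path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}
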