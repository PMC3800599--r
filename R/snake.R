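## Closed parametric contour: construction, resampling, tangents, and
## semi-implicit evolution under internal elasticity/rigidity forces plus an
## external force field.

.signedArea <- function(p) {
    n <- nrow(p)
    j <- c(2:n, 1L)
    sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2]) / 2
}

.orientLabel <- function(p) if (.signedArea(p) >= 0) "ccw" else "cw"

#' Construct a contour from a point matrix
#'
#' Orientation is derived from the signed (shoelace) area in the package's
#' y-down pixel frame: positive area is labelled \code{"ccw"}.
#'
#' @param points numeric N x 2 matrix (columns x, y); the contour is
#'   implicitly closed.
#' @return A \code{\link{Contour-class}} object.
#' @export
makeContour <- function(points) {
    points <- unname(as.matrix(points))
    new("Contour", points = points, orientation = .orientLabel(points))
}

#' @rdname perimeter
#' @export
setMethod("perimeter", "Contour", function(x) {
    p <- x@points
    n <- nrow(p)
    d <- p[c(2:n, 1L), ] - p
    sum(sqrt(rowSums(d^2)))
})

## segment (p1,p2) vs (p3,p4) proper intersection test
.segsIntersect <- function(p1, p2, p3, p4) {
    d1 <- p2 - p1; d2 <- p4 - p3
    den <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(den) < 1e-12) return(FALSE)
    t <- ((p3[1] - p1[1]) * d2[2] - (p3[2] - p1[2]) * d2[1]) / den
    s <- ((p3[1] - p1[1]) * d1[2] - (p3[2] - p1[2]) * d1[1]) / den
    t > 1e-9 && t < 1 - 1e-9 && s > 1e-9 && s < 1 - 1e-9
}

.isSimplePolygon <- function(p) {
    n <- nrow(p)
    idx <- function(i) ((i - 1L) %% n) + 1L
    for (i in seq_len(n)) {
        for (j in seq_len(n)) {
            if (j <= i) next
            if (j == i + 1L || (i == 1L && j == n)) next  # adjacent edges
            if (.segsIntersect(p[i, ], p[idx(i + 1L), ],
                               p[j, ], p[idx(j + 1L), ]))
                return(FALSE)
        }
    }
    TRUE
}

#' Initialize a contour from marked points
#'
#' Builds a closed piecewise-linear curve through the markers (emulating
#' interpolation of manually marked points) and resamples it to uniform
#' spacing.
#'
#' @param markers numeric matrix (>= 3 rows) of (x, y) marker points forming
#'   a simple polygon.
#' @param spacing target point spacing in px.
#' @return A \code{\link{Contour-class}} object.
#' @export
initContour <- function(markers, spacing = 1) {
    markers <- unname(as.matrix(markers))
    if (nrow(markers) < 3L) stop("need at least 3 marker points")
    if (!.isSimplePolygon(markers)) stop("marker polygon is self-intersecting")
    resampleContour(makeContour(markers), spacing)
}

#' Resample a contour to uniform arc-length spacing
#'
#' The number of points is \code{max(8, round(perimeter / spacing))}; the
#' first resampled point coincides with the contour's first point, and the
#' orientation label is recomputed from the signed area.
#'
#' @param contour a \code{Contour}.
#' @param spacing target consecutive-point spacing in px.
#' @return A resampled \code{Contour}.
#' @export
resampleContour <- function(contour, spacing = 1) {
    p <- contour@points
    n <- nrow(p)
    pc <- rbind(p, p[1L, , drop = FALSE])   # explicit closure
    seglen <- sqrt(rowSums((pc[-1L, , drop = FALSE] - pc[-(n + 1L), , drop = FALSE])^2))
    L <- sum(seglen)
    if (L < 1e-9) stop("degenerate (zero-perimeter) contour")
    s <- c(0, cumsum(seglen))
    m <- max(8L, as.integer(round(L / spacing)))
    t <- (seq_len(m) - 1L) * L / m
    seg <- findInterval(t, s, rightmost.closed = TRUE)
    seg <- pmin(pmax(seg, 1L), n)
    frac <- (t - s[seg]) / pmax(seglen[seg], 1e-300)
    q <- pc[seg, , drop = FALSE] +
        frac * (pc[seg + 1L, , drop = FALSE] - pc[seg, , drop = FALSE])
    makeContour(q)
}

#' Unit tangent vectors along a contour
#'
#' Central differences with periodic indexing: the tangent at point i is the
#' normalized \code{p[i+1] - p[i-1]}.  Coincident neighbors fall back to a
#' one-sided difference with a warning.
#'
#' @param contour a \code{Contour}.
#' @return N x 2 matrix of unit tangents.
#' @export
contourTangents <- function(contour) {
    p <- contour@points
    n <- nrow(p)
    t <- p[c(2:n, 1L), , drop = FALSE] - p[c(n, 1:(n - 1L)), , drop = FALSE]
    len <- sqrt(rowSums(t^2))
    bad <- len < 1e-12
    if (any(bad)) {
        warning("coincident neighbors; one-sided tangent used at ",
                sum(bad), " point(s)")
        fwd <- p[c(2:n, 1L), , drop = FALSE] - p
        t[bad, ] <- fwd[bad, , drop = FALSE]
        len[bad] <- pmax(sqrt(rowSums(t[bad, , drop = FALSE]^2)), 1e-300)
    }
    t / len
}

## Eigenvalues of the periodic internal-force system (I + gamma * A), where
## A is the circulant pentadiagonal stiffness matrix built from alpha
## (elasticity, second differences) and beta (rigidity, fourth differences).
.snakeEig <- function(n, alpha, beta, gamma) {
    row1 <- numeric(n)
    add <- function(off, val) {
        i <- ((off %% n) + n) %% n + 1L
        row1[i] <<- row1[i] + val
    }
    add(0L, 1 + gamma * (2 * alpha + 6 * beta))
    add(1L, -gamma * (alpha + 4 * beta)); add(-1L, -gamma * (alpha + 4 * beta))
    add(2L, gamma * beta);                add(-2L, gamma * beta)
    Re(stats::fft(row1))
}

.circSolve <- function(eig, b) Re(stats::fft(stats::fft(b) / eig, inverse = TRUE)) / length(b)

#' Evolve a snake under internal and external forces
#'
#' Performs semi-implicit (Kass-style) update steps: the internal terms
#' \eqn{\alpha X'' - \beta X''''} are treated implicitly through the periodic
#' pentadiagonal system \eqn{(I + \gamma A)^{-1}}, applied per coordinate via
#' the circulant eigendecomposition, while the external force is explicit:
#' \deqn{X_{t+1} = (I + \gamma A)^{-1}(X_t + \gamma \kappa F(X_t)).}
#' The contour is resampled to uniform spacing after every step and counts as
#' stopped once the maximum per-point displacement (measured before
#' resampling) stays below \code{stopEps} for \code{stopWindow} consecutive
#' steps.
#'
#' @param contour a \code{Contour}.
#' @param forceAt function mapping an N x 2 point matrix to an N x 2 matrix
#'   of external force vectors (e.g. built from \code{\link{fieldAt}}).
#' @param params a \code{\link{snakeParams}} object.
#' @param nSteps step budget for this call (default \code{params@maxSteps}).
#' @return list with elements \code{contour}, \code{stopped} (logical),
#'   \code{steps} (steps actually run), \code{lastDisp} (last max per-point
#'   displacement in px).
#' @export
evolveContour <- function(contour, forceAt, params = snakeParams(),
                          nSteps = params@maxSteps) {
    stopifnot(is(contour, "Contour"), is.function(forceAt),
              is(params, "SnakeParams"))
    pts <- contour@points
    eig <- NULL; eigN <- -1L
    quiet <- 0L; stopped <- FALSE; steps <- 0L; disp <- NA_real_
    for (step in seq_len(nSteps)) {
        n <- nrow(pts)
        if (n != eigN) {
            eig <- .snakeEig(n, params@alpha, params@beta, params@gamma)
            eigN <- n
        }
        f <- forceAt(pts)
        bx <- pts[, 1] + params@gamma * params@kappa * f[, 1]
        by <- pts[, 2] + params@gamma * params@kappa * f[, 2]
        newPts <- cbind(.circSolve(eig, bx), .circSolve(eig, by))
        ## stop criterion tracks shape change: the displacement component
        ## normal to the contour.  Tangential sliding (e.g. forces running
        ## along a stalled segment) is reparameterization, not motion, and
        ## is absorbed by the per-step resampling.
        tg <- contourTangents(makeContour(pts))
        d <- newPts - pts
        disp <- max(abs(d[, 1] * -tg[, 2] + d[, 2] * tg[, 1]))
        cNew <- resampleContour(makeContour(newPts), params@spacing)
        pts <- cNew@points
        steps <- step
        quiet <- if (disp < params@stopEps) quiet + 1L else 0L
        if (quiet >= params@stopWindow) { stopped <- TRUE; break }
    }
    list(contour = makeContour(pts), stopped = stopped, steps = steps,
         lastDisp = disp)
}

## --- contour I/O -----------------------------------------------------------

#' Read / write contours as CSV or JSON
#'
#' CSV files have two columns \code{x, y} with a header row.  JSON files
#' store a list of \code{[x, y]} pairs plus the orientation as metadata.
#'
#' @param contour a \code{Contour}.
#' @param path file path.
#' @return readers return a \code{Contour}; writers return \code{path}
#'   invisibly.
#' @export
writeContourCSV <- function(contour, path) {
    utils::write.csv(data.frame(x = contour@points[, 1], y = contour@points[, 2]),
                     path, row.names = FALSE)
    invisible(path)
}

#' @rdname writeContourCSV
#' @export
readContourCSV <- function(path) {
    d <- utils::read.csv(path)
    makeContour(cbind(d$x, d$y))
}

#' @rdname writeContourCSV
#' @export
writeContourJSON <- function(contour, path) {
    jsonlite::write_json(
        list(points = unname(apply(contour@points, 1L, function(r) r,
                                   simplify = FALSE)),
             orientation = contour@orientation),
        path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeContourCSV
#' @export
readContourJSON <- function(path) {
    d <- jsonlite::read_json(path, simplifyVector = TRUE)
    makeContour(if (is.list(d$points)) do.call(rbind, d$points) else d$points)
}
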