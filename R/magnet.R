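## Magnetostatic corrective force.  Hypothetical electric currents run along
## the object boundary (the image-gradient rotated by 90 degrees); their
## Biot-Savart style out-of-plane magnetic field B exerts an in-plane force
## on the current-carrying false contour, perpendicular to the contour and
## directed into the concavity, which is added locally to the external field.

#' Boundary currents from the image gradient
#'
#' Selects boundary pixels (gradient magnitude >= \code{edgeFrac} of the
#' maximum) and assigns each the current vector
#' \deqn{\Gamma = (-1)^\lambda (-I_y, I_x),}
#' the image gradient rotated by 90 degrees; \eqn{\lambda = 1} yields a
#' counter-clockwise current, \eqn{\lambda = 2} clockwise.
#'
#' @param img a \code{GrayImage}.
#' @param lambdaDir \code{"ccw"} (lambda = 1) or \code{"cw"} (lambda = 2).
#' @param edgeFrac fraction of the maximum gradient magnitude a pixel must
#'   reach to count as boundary.
#' @param sigma Gaussian width for the image gradient.
#' @return A \code{\link{MagneticSource-class}} object (possibly empty, with
#'   a warning, if no pixel passes the threshold).
#' @export
boundaryCurrent <- function(img, lambdaDir = c("ccw", "cw"), edgeFrac = 0.3,
                            sigma = 1) {
    lambdaDir <- match.arg(lambdaDir)
    g <- imageGradient(img, sigma)
    mag <- sqrt(g$Ix^2 + g$Iy^2)
    sel <- which(mag >= edgeFrac * max(mag) & mag > 0)
    if (length(sel) == 0L) {
        warning("no boundary point passes the gradient threshold; empty source")
        return(new("MagneticSource", points = matrix(0, 0, 2),
                   currents = matrix(0, 0, 2), lambdaDir = lambdaDir))
    }
    rows <- ((sel - 1L) %% nrow(mag)) + 1L
    cols <- ((sel - 1L) %/% nrow(mag)) + 1L
    lam <- if (lambdaDir == "ccw") 1L else 2L
    sgn <- (-1)^lam
    cur <- cbind(sgn * -g$Iy[sel], sgn * g$Ix[sel])
    new("MagneticSource", points = cbind(cols, rows), currents = cur,
        lambdaDir = lambdaDir)
}

#' Out-of-plane magnetic field of the boundary currents
#'
#' Biot-Savart style sum over boundary points c:
#' \deqn{B(p) = \sum_c \frac{[\Gamma(c) \times \hat R_{p,c}]_z}
#'   {|p - c|^2 + \epsilon^2},}
#' with \eqn{\hat R_{p,c}} the unit vector from p to c and the planar cross
#' product \eqn{\Gamma_x \hat R_y - \Gamma_y \hat R_x}.  The physical
#' constants (mu0 / 4 pi, per-point current magnitude) are folded to 1; all
#' scaling is routed through the field-update weight k.  The softening
#' \eqn{R^2 \to R^2 + \epsilon^2} removes the singularity at R = 0.
#'
#' @param src a \code{MagneticSource}.
#' @param p numeric length-2 vector or N x 2 matrix of evaluation points.
#' @param softenEps softening length in px.
#' @return numeric vector of B values (positive = out of the image plane in
#'   this sign convention).
#' @export
magneticField <- function(src, p, softenEps = 1) {
    if (is.null(dim(p))) p <- matrix(p, ncol = 2)
    np <- nrow(p)
    if (nrow(src@points) == 0L) return(numeric(np))
    B <- numeric(np)
    cx <- src@points[, 1]; cy <- src@points[, 2]
    gx <- src@currents[, 1]; gy <- src@currents[, 2]
    for (i in seq_len(np)) {
        rx <- cx - p[i, 1]; ry <- cy - p[i, 2]
        r2 <- rx^2 + ry^2
        r <- sqrt(r2)
        ok <- r > 1e-12
        B[i] <- sum((gx[ok] * ry[ok] - gy[ok] * rx[ok]) /
                    (r[ok] * (r2[ok] + softenEps^2)))
    }
    B
}

#' Magnetic force on a false contour segment
#'
#' The false contour carries current \eqn{I_s} along its tangent direction
#' \eqn{\Upsilon(s)}; in the out-of-plane field B the resulting in-plane
#' force at point i is
#' \deqn{F_i = I_s\,(t_{iy} B_i,\; -t_{ix} B_i),}
#' which is perpendicular to the tangent at every point and points inward or
#' outward depending on the signs of B and the current direction.
#'
#' @param contour a \code{Contour}.
#' @param segment integer vector of point indices (a false run).
#' @param src a \code{MagneticSource} (empty source gives zero forces with a
#'   warning).
#' @param params a \code{\link{magnetParams}} object.
#' @return length(segment) x 2 matrix of force vectors.
#' @export
magneticForce <- function(contour, segment, src, params = magnetParams()) {
    stopifnot(all(segment >= 1L), all(segment <= nrow(contour@points)))
    tg <- contourTangents(contour)[segment, , drop = FALSE]
    if (nrow(src@points) == 0L) {
        warning("empty magnetic source; zero forces")
        return(matrix(0, length(segment), 2))
    }
    B <- magneticField(src, contour@points[segment, , drop = FALSE],
                       params@softenEps)
    params@iS * cbind(tg[, 2] * B, -tg[, 1] * B)
}

#' Add weighted magnetic forces to the external field near a false segment
#'
#' Returns a copy of the field where, within a tent-shaped halo of radius
#' \code{halo} px around each false-segment point, \code{k * F} is splatted
#' onto the grid: each grid node inside the halo of the segment takes the
#' force of its nearest segment point, weighted by the separable tent weight
#' \eqn{w = (1 - |dx|/halo)(1 - |dy|/halo)} (which reduces to bilinear
#' weights for halo = 1).  Nodes farther than \code{halo} from every segment
#' point are untouched, which is what keeps the field semi-dynamic: static
#' away from the false part, updated only around it.
#'
#' @param fld the external \code{VectorField}.
#' @param contour the stopped \code{Contour}.
#' @param segment integer vector of false-run point indices.
#' @param forces matrix of per-point forces from \code{\link{magneticForce}}.
#' @param params a \code{\link{magnetParams}} object.
#' @return A new \code{VectorField}.
#' @export
updateField <- function(fld, contour, segment, forces, params = magnetParams()) {
    stopifnot(nrow(forces) == length(segment))
    if (params@k == 0 || length(segment) == 0L) return(fld)
    u <- fld@u; v <- fld@v
    h <- nrow(u); w <- ncol(u)
    halo <- params@halo
    pts <- contour@points[segment, , drop = FALSE]
    ## collect candidate nodes in the bounding box of the run
    x0 <- max(1L, floor(min(pts[, 1]) - halo))
    x1 <- min(w, ceiling(max(pts[, 1]) + halo))
    y0 <- max(1L, floor(min(pts[, 2]) - halo))
    y1 <- min(h, ceiling(max(pts[, 2]) + halo))
    if (x1 < x0 || y1 < y0) return(fld)
    gx <- seq.int(x0, x1); gy <- seq.int(y0, y1)
    nodeX <- rep(gx, each = length(gy))
    nodeY <- rep(gy, times = length(gx))
    ## nearest segment point per node (Euclidean), tent weight per axis
    bestD2 <- rep(Inf, length(nodeX))
    bestI <- rep(0L, length(nodeX))
    for (i in seq_len(nrow(pts))) {
        d2 <- (nodeX - pts[i, 1])^2 + (nodeY - pts[i, 2])^2
        upd <- d2 < bestD2
        bestD2[upd] <- d2[upd]
        bestI[upd] <- i
    }
    dx <- abs(nodeX - pts[bestI, 1])
    dy <- abs(nodeY - pts[bestI, 2])
    wgt <- pmax(0, 1 - dx / halo) * pmax(0, 1 - dy / halo)
    keep <- wgt > 0
    if (any(keep)) {
        idx <- cbind(nodeY[keep], nodeX[keep])
        u[idx] <- u[idx] + params@k * wgt[keep] * forces[bestI[keep], 1]
        v[idx] <- v[idx] + params@k * wgt[keep] * forces[bestI[keep], 2]
    }
    new("VectorField", u = u, v = v, mu = fld@mu,
        iterationsRun = fld@iterationsRun)
}
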