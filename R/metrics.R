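## Boundary-distance metrics between a segmented contour and a reference
## boundary.

## min distance from each point in P (N x 2) to the closed polyline Q
.pointsToPolyline <- function(P, Q) {
    n <- nrow(Q)
    a <- Q
    b <- Q[c(2:n, 1L), , drop = FALSE]
    best <- rep(Inf, nrow(P))
    for (i in seq_len(n)) {
        ax <- a[i, 1]; ay <- a[i, 2]
        dx <- b[i, 1] - ax; dy <- b[i, 2] - ay
        l2 <- dx^2 + dy^2
        if (l2 < 1e-300) {
            d2 <- (P[, 1] - ax)^2 + (P[, 2] - ay)^2
        } else {
            t <- pmin(pmax(((P[, 1] - ax) * dx + (P[, 2] - ay) * dy) / l2, 0), 1)
            d2 <- (P[, 1] - (ax + t * dx))^2 + (P[, 2] - (ay + t * dy))^2
        }
        best <- pmin(best, d2)
    }
    sqrt(best)
}

#' Boundary distance between two closed contours
#'
#' Symmetric surface distances: the distance from every point of
#' \code{contour} to the \code{reference} polyline and from every reference
#' point to the contour polyline.  \code{mean} is the mean of the pooled
#' bidirectional distances (mean absolute surface distance); \code{max} is
#' the pooled maximum (symmetric Hausdorff over the sampled points).
#'
#' @param contour,reference \code{Contour} objects (typically both sampled
#'   at ~1 px spacing).
#' @return list with \code{mean}, \code{max}, \code{meanContourToRef},
#'   \code{meanRefToContour}, \code{maxRefToContour}.
#' @export
boundaryDistance <- function(contour, reference) {
    d1 <- .pointsToPolyline(contour@points, reference@points)
    d2 <- .pointsToPolyline(reference@points, contour@points)
    list(mean = mean(c(d1, d2)), max = max(d1, d2),
         meanContourToRef = mean(d1), meanRefToContour = mean(d2),
         maxRefToContour = max(d2))
}
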