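## Synthetic test objects with known ground-truth boundaries: a convex disc,
## a square with one deep narrow slot ("ushape"), a square with several
## slots ("multi_concave"), and an annulus ("ring").  All randomness (the
## additive intensity noise) is seeded through the ShapeSpec.

.withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv())
    if (had) old <- get(".Random.seed", envir = globalenv())
    set.seed(seed)
    on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
            else rm(".Random.seed", envir = globalenv()))
    expr
}

.renderMask <- function(spec) {
    n <- spec@size
    cx <- (n + 1) / 2
    hw <- round(n / 4)        # object half-width
    mask <- matrix(FALSE, n, n)
    xs <- matrix(rep(seq_len(n), each = n), n, n)   # column coordinate
    ys <- matrix(rep(seq_len(n), times = n), n, n)  # row coordinate
    cutSlot <- function(mask, side) {
        half <- (spec@mouthWidth - 1) / 2
        d <- spec@depth
        sel <- switch(side,
            top    = abs(xs - cx) <= half & ys >= cx - hw & ys <= cx - hw + d,
            bottom = abs(xs - cx) <= half & ys <= cx + hw & ys >= cx + hw - d,
            left   = abs(ys - cx) <= half & xs >= cx - hw & xs <= cx - hw + d,
            right  = abs(ys - cx) <= half & xs <= cx + hw & xs >= cx + hw - d)
        mask[sel] <- FALSE
        mask
    }
    switch(spec@kind,
        disc = {
            mask <- (xs - cx)^2 + (ys - cx)^2 <= (n / 4)^2
        },
        ushape = {
            if (spec@depth > 2 * hw - 3) stop("concavity exceeds the object")
            mask <- abs(xs - cx) <= hw & abs(ys - cx) <= hw
            mask <- cutSlot(mask, "top")
        },
        multi_concave = {
            if (spec@depth > 2 * hw - 3) stop("concavity exceeds the object")
            mask <- abs(xs - cx) <= hw & abs(ys - cx) <= hw
            sides <- rep(c("top", "bottom", "left", "right"),
                         length.out = spec@nConcavities)
            for (s in sides) mask <- cutSlot(mask, s)
        },
        ring = {
            r2 <- (xs - cx)^2 + (ys - cx)^2
            mask <- r2 <= (n / 4)^2 & r2 >= (n / 8)^2
        })
    mask
}

.traceMask <- function(mask) {
    n <- nrow(mask)
    ## contourLines wants z[i, j] at (x[i], y[j]); our mask is [row=y, col=x]
    cl <- grDevices::contourLines(seq_len(n), seq_len(n),
                                  t(mask * 1), levels = 0.5)
    if (length(cl) == 0L) stop("mask has no 0.5 iso-contour")
    lens <- vapply(cl, function(l) length(l$x), numeric(1))
    best <- cl[[which.max(lens)]]
    p <- cbind(best$x, best$y)
    if (sum((p[1L, ] - p[nrow(p), ])^2) < 1e-18)
        p <- p[-nrow(p), , drop = FALSE]
    p
}

#' Generate a synthetic shape and its ground-truth boundary
#'
#' Renders the binary object (foreground 1, background 0), optionally blurs
#' it and adds seeded Gaussian intensity noise (clipped to [0, 1]).  The
#' ground-truth contour is traced from the clean binary mask as the 0.5
#' iso-contour at subpixel precision, resampled to 1 px spacing, oriented
#' counter-clockwise.
#'
#' @param spec a \code{\link{shapeSpec}} object.
#' @return list with elements \code{image} (a \code{GrayImage}) and
#'   \code{truth} (a \code{Contour}).
#' @export
makeShape <- function(spec) {
    stopifnot(is(spec, "ShapeSpec"))
    mask <- .renderMask(spec)
    truth <- resampleContour(makeContour(.traceMask(mask)), 1)
    if (truth@orientation != "ccw")
        truth <- makeContour(truth@points[rev(seq_len(nrow(truth@points))), ])
    img <- mask * 1
    if (spec@blurSigma > 0) img <- .convSep(img, .gaussKernel1d(spec@blurSigma))
    if (spec@noiseSd > 0)
        img <- .withSeed(spec@seed,
                         img + matrix(stats::rnorm(length(img), 0, spec@noiseSd),
                                      nrow(img), ncol(img)))
    list(image = grayImage(pmin(pmax(img, 0), 1)), truth = truth)
}

#' Enclosing initial contour around a ground-truth boundary
#'
#' The convex hull of the truth points, offset outward by \code{margin} px
#' (each hull edge shifted along its outward normal; vertices at the
#' intersections of adjacent offset edges), resampled to 1 px spacing and
#' oriented like the truth contour.  Emulates an initial contour drawn
#' loosely around the object.
#'
#' @param truth a \code{Contour}.
#' @param margin outward offset in px (> 0).
#' @return A \code{Contour}.
#' @export
enclosingInit <- function(truth, margin = 10) {
    stopifnot(margin > 0)
    p <- truth@points
    hull <- p[rev(grDevices::chull(p)), , drop = FALSE]  # chull is clockwise
    if (.signedArea(hull) < 0) hull <- hull[rev(seq_len(nrow(hull))), ]
    m <- nrow(hull)
    nxt <- c(2:m, 1L)
    prv <- c(m, 1:(m - 1L))
    d <- hull[nxt, ] - hull
    len <- sqrt(rowSums(d^2))
    d <- d / len
    nrm <- cbind(d[, 2], -d[, 1])  # outward normal of a ccw (positive-area) polygon
    off <- matrix(NA_real_, m, 2)
    for (i in seq_len(m)) {
        a1 <- hull[prv[i], ] + margin * nrm[prv[i], ]; d1 <- d[prv[i], ]
        a2 <- hull[i, ] + margin * nrm[i, ];           d2 <- d[i, ]
        den <- d1[1] * d2[2] - d1[2] * d2[1]
        if (abs(den) < 1e-9) {
            off[i, ] <- a2
        } else {
            t <- ((a2[1] - a1[1]) * d2[2] - (a2[2] - a1[2]) * d2[1]) / den
            off[i, ] <- a1 + t * d1
        }
    }
    out <- resampleContour(makeContour(off), 1)
    if (out@orientation != truth@orientation)
        out <- makeContour(out@points[rev(seq_len(nrow(out@points))), ])
    out
}
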