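## Image loading, smoothing, gradients, edge maps, mask rasterization.

## --- low-level stencils ----------------------------------------------------
## All stencils use replicate (nearest-pixel) border padding, implemented by
## clamping index vectors.

.clampIdx <- function(i, n) pmin(pmax(i, 1L), n)

#' @keywords internal
.gaussKernel1d <- function(sigma) {
    r <- max(1L, ceiling(3 * sigma))
    x <- seq(-r, r)
    k <- exp(-x^2 / (2 * sigma^2))
    k / sum(k)
}

## Separable convolution with a symmetric 1-D kernel, replicate padding.
.convSep <- function(m, kern) {
    r <- (length(kern) - 1L) %/% 2L
    nr <- nrow(m); nc <- ncol(m)
    out <- matrix(0, nr, nc)
    for (s in seq_along(kern))           # along rows (y direction)
        out <- out + kern[s] * m[.clampIdx(seq_len(nr) + s - r - 1L, nr), , drop = FALSE]
    res <- matrix(0, nr, nc)
    for (s in seq_along(kern))           # along columns (x direction)
        res <- res + kern[s] * out[, .clampIdx(seq_len(nc) + s - r - 1L, nc), drop = FALSE]
    res
}

## Central differences, replicate padding.  x runs along columns, y along
## rows (y increases downward).
.centralDiffX <- function(m) {
    nc <- ncol(m)
    (m[, .clampIdx(seq_len(nc) + 1L, nc), drop = FALSE] -
     m[, .clampIdx(seq_len(nc) - 1L, nc), drop = FALSE]) / 2
}

.centralDiffY <- function(m) {
    nr <- nrow(m)
    (m[.clampIdx(seq_len(nr) + 1L, nr), , drop = FALSE] -
     m[.clampIdx(seq_len(nr) - 1L, nr), , drop = FALSE]) / 2
}

## 5-point Laplacian, replicate padding.
.laplacian5 <- function(m) {
    nr <- nrow(m); nc <- ncol(m)
    m[.clampIdx(seq_len(nr) + 1L, nr), , drop = FALSE] +
        m[.clampIdx(seq_len(nr) - 1L, nr), , drop = FALSE] +
        m[, .clampIdx(seq_len(nc) + 1L, nc), drop = FALSE] +
        m[, .clampIdx(seq_len(nc) - 1L, nc), drop = FALSE] - 4 * m
}

## --- construction / IO -----------------------------------------------------

#' Construct a grayscale image from a matrix
#'
#' @param m numeric matrix with values in [0, 1]; rows are image rows (y),
#'   columns are x.
#' @return A \code{\link{GrayImage-class}} object.
#' @export
grayImage <- function(m) {
    m <- pmin(pmax(m, 0), 1)  # guard tiny numeric excursions
    new("GrayImage", pixels = unname(as.matrix(m)))
}

#' Load a grayscale image from PNG or TIFF
#'
#' Multi-channel inputs are converted to luminance (Rec. 601 weights); an
#' alpha channel is dropped.  Intensities are scaled to [0, 1] by the file's
#' bit depth (both readers already deliver that scale).
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @return A \code{\link{GrayImage-class}} object.
#' @export
readGrayImage <- function(path) {
    if (!file.exists(path)) stop("image file not found: ", path)
    ext <- tolower(tools::file_ext(path))
    a <- switch(ext,
        png = png::readPNG(path),
        tif = ,
        tiff = tiff::readTIFF(path),
        stop("unsupported image format '", ext, "' (PNG or TIFF expected)"))
    if (length(dim(a)) == 3L) {
        nch <- dim(a)[3]
        a <- if (nch >= 3L)
            0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
        else a[, , 1]
    }
    if (length(a) == 0L) stop("zero-size image: ", path)
    if (nrow(a) < 16L || ncol(a) < 16L)
        stop("image must be at least 16 x 16 pixels")
    grayImage(a)
}

#' Write a binary mask as 8-bit PNG (255 inside, 0 outside)
#'
#' @param mask logical matrix.
#' @param path output PNG path.
#' @return Invisibly, \code{path}.
#' @export
writeMask <- function(mask, path) {
    png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
    invisible(path)
}

## --- gradients and edge map ------------------------------------------------

#' Smoothed image gradient
#'
#' Central-difference gradient of the (optionally Gaussian-smoothed) image,
#' with replicate border padding.
#'
#' @param img a \code{GrayImage}.
#' @param sigma Gaussian smoothing width in px; 0 means raw central
#'   differences.
#' @return list with matrices \code{Ix}, \code{Iy}.
#' @export
imageGradient <- function(img, sigma = 0) {
    stopifnot(is(img, "GrayImage"), sigma >= 0)
    m <- img@pixels
    if (sigma > 0) m <- .convSep(m, .gaussKernel1d(sigma))
    list(Ix = .centralDiffX(m), Iy = .centralDiffY(m))
}

#' Edge map of an image
#'
#' Computes the scalar edge-strength map f = |grad I|^2 (variant
#' \code{"grad_sq"}) or f = |grad(G_sigma * I)|^2
#' (\code{"smoothed_grad_sq"}), normalized so max(f) = 1 unless f is
#' identically zero, together with the central-difference gradient of the
#' normalized f.  The gradient of f seeds the GVF diffusion.
#'
#' @param img a \code{GrayImage}.
#' @param variant \code{"smoothed_grad_sq"} (default) or \code{"grad_sq"}.
#' @param sigma Gaussian width in px (required > 0 for the smoothed variant).
#' @return An \code{\link{EdgeMap-class}} object.
#' @export
edgeMap <- function(img, variant = c("smoothed_grad_sq", "grad_sq"), sigma = 1) {
    variant <- match.arg(variant)
    stopifnot(is(img, "GrayImage"), sigma >= 0)
    if (variant == "smoothed_grad_sq" && sigma <= 0)
        stop("variant 'smoothed_grad_sq' requires sigma > 0")
    g <- imageGradient(img, if (variant == "grad_sq") 0 else sigma)
    f <- g$Ix^2 + g$Iy^2
    mx <- max(f)
    if (mx > 0) f <- f / mx
    new("EdgeMap", f = f, fx = .centralDiffX(f), fy = .centralDiffY(f),
        sigma = sigma, variant = variant)
}

## --- rasterization ---------------------------------------------------------

#' Rasterize a closed contour to a pixel mask
#'
#' Even-odd scanline fill: a pixel center is inside if a horizontal ray
#' crosses the polygon an odd number of times.
#'
#' @param contour a \code{Contour}.
#' @param height,width output mask dimensions in px.
#' @return logical matrix, TRUE inside the contour.
#' @export
contourMask <- function(contour, height, width) {
    p <- contour@points
    n <- nrow(p)
    x1 <- p[, 1]; y1 <- p[, 2]
    x2 <- p[c(2:n, 1), 1]; y2 <- p[c(2:n, 1), 2]
    mask <- matrix(FALSE, height, width)
    for (row in seq_len(height)) {
        yr <- row
        crosses <- ((y1 <= yr) & (y2 > yr)) | ((y2 <= yr) & (y1 > yr))
        if (!any(crosses)) next
        xs <- x1[crosses] + (yr - y1[crosses]) / (y2[crosses] - y1[crosses]) *
            (x2[crosses] - x1[crosses])
        xs <- sort(xs)
        if (length(xs) %% 2L == 1L) xs <- xs[-length(xs)]  # degenerate tangency
        if (length(xs) < 2L) next
        for (i in seq(1L, length(xs) - 1L, by = 2L)) {
            lo <- ceiling(xs[i]); hi <- floor(xs[i + 1L])
            if (hi >= lo)
                mask[row, max(1L, lo):min(width, hi)] <- TRUE
        }
    }
    mask
}
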