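## Generics and simple accessors / show methods.

#' Image pixel matrix
#' @param x a \code{GrayImage}.
#' @return numeric matrix of intensities in [0, 1].
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname pixels
#' @export
setMethod("pixels", "GrayImage", function(x) x@pixels)

#' Image dimensions
#' @param x a \code{GrayImage}.
#' @return integer pixel count.
#' @export
setGeneric("imageWidth", function(x) standardGeneric("imageWidth"))

#' @rdname imageWidth
#' @export
setMethod("imageWidth", "GrayImage", function(x) ncol(x@pixels))

#' @rdname imageWidth
#' @export
setGeneric("imageHeight", function(x) standardGeneric("imageHeight"))

#' @rdname imageWidth
#' @export
setMethod("imageHeight", "GrayImage", function(x) nrow(x@pixels))

#' Contour points
#' @param x a \code{Contour}.
#' @return numeric N x 2 matrix with columns x, y.
#' @export
setGeneric("contourPoints", function(x) standardGeneric("contourPoints"))

#' @rdname contourPoints
#' @export
setMethod("contourPoints", "Contour", function(x) x@points)

#' Number of contour points
#' @param x a \code{Contour}.
#' @return integer.
#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))

#' @rdname nPoints
#' @export
setMethod("nPoints", "Contour", function(x) nrow(x@points))

#' Contour orientation
#' @param x a \code{Contour}.
#' @return \code{"ccw"} or \code{"cw"}.
#' @export
setGeneric("orientation", function(x) standardGeneric("orientation"))

#' @rdname orientation
#' @export
setMethod("orientation", "Contour", function(x) x@orientation)

#' Contour perimeter
#' @param x a \code{Contour}.
#' @return total closed-polyline length in px.
#' @export
setGeneric("perimeter", function(x) standardGeneric("perimeter"))

#' Field components
#' @param x a \code{VectorField}.
#' @return numeric matrix.
#' @export
setGeneric("fieldU", function(x) standardGeneric("fieldU"))

#' @rdname fieldU
#' @export
setMethod("fieldU", "VectorField", function(x) x@u)

#' @rdname fieldU
#' @export
setGeneric("fieldV", function(x) standardGeneric("fieldV"))

#' @rdname fieldU
#' @export
setMethod("fieldV", "VectorField", function(x) x@v)

#' Evaluate a vector field at subpixel points
#'
#' Bilinear interpolation of (u, v) at arbitrary subpixel positions.  Points
#' outside the grid are clamped to the border with a warning.
#'
#' @param fld a \code{VectorField}.
#' @param p numeric length-2 vector or N x 2 matrix of (x, y) positions.
#' @return N x 2 matrix of interpolated (u, v) vectors.
#' @export
setGeneric("fieldAt", function(fld, p) standardGeneric("fieldAt"))

setMethod("show", "GrayImage", function(object) {
    cat(sprintf("GrayImage %d x %d (h x w), range [%.3f, %.3f]\n",
                nrow(object@pixels), ncol(object@pixels),
                min(object@pixels), max(object@pixels)))
})

setMethod("show", "EdgeMap", function(object) {
    cat(sprintf("EdgeMap (%s, sigma=%g) %d x %d, max f = %g\n",
                object@variant, object@sigma, nrow(object@f), ncol(object@f),
                max(object@f)))
})

setMethod("show", "VectorField", function(object) {
    cat(sprintf("VectorField %d x %d, mu=%g, %d iterations, max |V| = %.4g\n",
                nrow(object@u), ncol(object@u), object@mu,
                object@iterationsRun,
                sqrt(max(object@u^2 + object@v^2))))
})

setMethod("show", "Contour", function(object) {
    cat(sprintf("Contour with %d points (%s), perimeter %.1f px\n",
                nrow(object@points), object@orientation, perimeter(object)))
})

setMethod("show", "FalseSegmentReport", function(object) {
    cat(sprintf("FalseSegmentReport: %d/%d points flagged, %d/%d segments false\n",
                sum(object@pointFlags), length(object@pointFlags),
                object@nFalseSegments, nrow(object@segments)))
})

setMethod("show", "MagneticSource", function(object) {
    cat(sprintf("MagneticSource with %d boundary points (%s current)\n",
                nrow(object@points), object@lambdaDir))
})

setMethod("show", "RunResult", function(object) {
    cat(sprintf("RunResult: %d round(s), %d field update(s), convergedClean = %s\n",
                nrow(object@rounds), object@nFieldUpdates,
                object@convergedClean))
})
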