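#' @import methods
NULL

## ---------------------------------------------------------------------------
## Pixel-grid objects
##
## Coordinate convention shared by every class in the package: pixel centers
## sit at integer coordinates, x is the column index, y the row index, origin
## at the top-left corner, y increasing downward.  Matrices are indexed
## [row, col] = [y, x].  Contours store subpixel (x, y) doubles.
## ---------------------------------------------------------------------------

#' Grayscale image
#'
#' A single-channel image with intensities in \code{[0, 1]}.
#'
#' @slot pixels numeric matrix, rows are image rows (y), columns are x.
#' @exportClass GrayImage
setClass("GrayImage", representation(pixels = "matrix"), validity = function(object) {
    p <- object@pixels
    if (!is.numeric(p)) return("pixels must be numeric")
    if (nrow(p) < 2L || ncol(p) < 2L) return("image must be at least 2x2")
    if (any(!is.finite(p))) return("pixels must be finite")
    if (min(p) < -1e-9 || max(p) > 1 + 1e-9) return("pixels must lie in [0, 1]")
    TRUE
})

#' Edge map
#'
#' Scalar edge-strength map f(x, y) (large near intensity edges, normalized
#' to max 1 unless identically zero) together with its central-difference
#' gradient components.
#'
#' @slot f numeric matrix, edge strength, >= 0.
#' @slot fx,fy numeric matrices, gradient of \code{f} (d/dx along columns,
#'   d/dy along rows).
#' @slot sigma Gaussian pre-smoothing width in pixels (0 = none).
#' @slot variant character, \code{"grad_sq"} or \code{"smoothed_grad_sq"}.
#' @exportClass EdgeMap
setClass("EdgeMap",
    representation(f = "matrix", fx = "matrix", fy = "matrix",
                   sigma = "numeric", variant = "character"),
    validity = function(object) {
        if (any(dim(object@fx) != dim(object@f)) ||
            any(dim(object@fy) != dim(object@f)))
            return("fx, fy must match f in shape")
        if (any(!is.finite(object@f))) return("f must be finite")
        if (min(object@f) < -1e-12) return("f must be non-negative")
        mx <- max(object@f)
        if (mx > 0 && abs(mx - 1) > 1e-9) return("f must be normalized to max 1")
        TRUE
    })

#' External force vector field
#'
#' Two-component vector field V(x, y) = (u, v) on the pixel grid, typically
#' the converged gradient vector flow of an edge map.
#'
#' @slot u,v numeric matrices (x- and y-components).
#' @slot mu GVF smoothness weight used to compute the field (NA if not GVF).
#' @slot iterationsRun number of diffusion iterations actually run.
#' @exportClass VectorField
setClass("VectorField",
    representation(u = "matrix", v = "matrix", mu = "numeric",
                   iterationsRun = "integer"),
    validity = function(object) {
        if (any(dim(object@u) != dim(object@v))) return("u, v must match in shape")
        if (any(!is.finite(object@u)) || any(!is.finite(object@v)))
            return("field must be finite")
        TRUE
    })

## ---------------------------------------------------------------------------
## Contours
## ---------------------------------------------------------------------------

#' Closed contour (snake)
#'
#' Ordered closed polyline of subpixel points; point N connects back to
#' point 1.  Orientation is recomputed from the signed area whenever the
#' contour is resampled.
#'
#' @slot points numeric N x 2 matrix, columns x, y.
#' @slot orientation \code{"ccw"} or \code{"cw"} (sign of the shoelace area
#'   in the image's y-down coordinate frame; "ccw" = positive signed area).
#' @exportClass Contour
setClass("Contour",
    representation(points = "matrix", orientation = "character"),
    validity = function(object) {
        p <- object@points
        if (ncol(p) != 2L) return("points must be N x 2")
        if (nrow(p) < 3L) return("contour needs at least 3 points")
        if (any(!is.finite(p))) return("contour points must be finite")
        if (!object@orientation %in% c("ccw", "cw"))
            return("orientation must be 'ccw' or 'cw'")
        TRUE
    })

## ---------------------------------------------------------------------------
## Parameter objects (validated at construction)
## ---------------------------------------------------------------------------

#' @exportClass GvfParams
setClass("GvfParams",
    representation(mu = "numeric", maxIters = "integer", dt = "numeric",
                   tol = "numeric"),
    validity = function(object) {
        if (object@mu <= 0) return("mu must be > 0")
        if (object@dt <= 0) return("dt must be > 0")
        if (object@dt > 1 / (4 * object@mu) + 1e-12)
            return("explicit scheme requires dt <= 1/(4*mu)")
        if (object@maxIters < 1L) return("maxIters must be >= 1")
        if (object@tol < 0) return("tol must be >= 0")
        TRUE
    })

#' GVF diffusion parameters
#'
#' @param mu smoothness weight of the GVF energy; larger values suit noisier
#'   images (default 0.2).
#' @param maxIters iteration cap for the explicit diffusion scheme.
#' @param dt explicit time step; must satisfy \code{dt <= 1/(4*mu)}.  The
#'   default \code{1/(4*mu + 1)} additionally keeps the scheme stable
#'   against the data-term weight \code{fx^2 + fy^2} (at most 1 on a
#'   normalized edge map).
#' @param tol stop when the mean absolute per-pixel update falls below this.
#' @return A \code{GvfParams} object.
#' @export
gvfParams <- function(mu = 0.2, maxIters = 2000L, dt = 1 / (4 * mu + 1),
                      tol = 1e-5) {
    new("GvfParams", mu = mu, maxIters = as.integer(maxIters), dt = dt, tol = tol)
}

#' @exportClass SnakeParams
setClass("SnakeParams",
    representation(alpha = "numeric", beta = "numeric", gamma = "numeric",
                   kappa = "numeric", spacing = "numeric", maxSteps = "integer",
                   stopEps = "numeric", stopWindow = "integer"),
    validity = function(object) {
        if (object@alpha < 0 || object@beta < 0) return("alpha, beta must be >= 0")
        if (object@gamma <= 0) return("gamma must be > 0")
        if (object@maxSteps < 1L) return("maxSteps must be >= 1")
        if (object@spacing < 0.5 || object@spacing > 2)
            return("spacing must lie in [0.5, 2] px")
        if (object@stopWindow < 1L) return("stopWindow must be >= 1")
        TRUE
    })

#' Snake evolution parameters
#'
#' @param alpha elasticity (tension) weight (default 0.6).
#' @param beta rigidity (bending) weight (default 0.3).
#' @param gamma evolution step size of the semi-implicit update.
#' @param kappa external-force weight.
#' @param spacing target point spacing in px for the per-step resampling.
#' @param maxSteps evolution step cap for one call.
#' @param stopEps,stopWindow the contour counts as stopped once the maximum
#'   per-point displacement stays below \code{stopEps} px for
#'   \code{stopWindow} consecutive steps.
#' @return A \code{SnakeParams} object.
#' @export
snakeParams <- function(alpha = 0.6, beta = 0.3, gamma = 1, kappa = 1,
                        spacing = 1, maxSteps = 200L, stopEps = 0.03,
                        stopWindow = 10L) {
    new("SnakeParams", alpha = alpha, beta = beta, gamma = gamma, kappa = kappa,
        spacing = spacing, maxSteps = as.integer(maxSteps), stopEps = stopEps,
        stopWindow = as.integer(stopWindow))
}

#' @exportClass DetectorParams
setClass("DetectorParams",
    representation(theta = "numeric", pointsPerSegment = "integer",
                   eta = "numeric", minForce = "numeric"),
    validity = function(object) {
        if (object@theta <= 0 || object@theta >= 90)
            return("theta must lie in (0, 90) degrees")
        if (object@pointsPerSegment < 2L) return("pointsPerSegment must be >= 2")
        if (object@eta <= 0 || object@eta > 1) return("eta must lie in (0, 1]")
        if (object@minForce < 0) return("minForce must be >= 0")
        TRUE
    })

#' False-contour detector parameters
#'
#' @param theta angle threshold in degrees: a contour point is false when
#'   every tangent-vs-force angle in its 3x3 neighborhood is <= theta
#'   (default 20).
#' @param pointsPerSegment nominal points per contour segment used when the
#'   contour is split for segment-level judgement (default 50).
#' @param eta within-segment false-point fraction threshold (strict ">",
#'   default 0.8).
#' @param minForce force vectors with magnitude below this are skipped when
#'   taking the maximum angle; if all 9 are skipped the angle is 0 degrees so
#'   a contour stalled in a null field is flagged.
#' @return A \code{DetectorParams} object.
#' @export
detectorParams <- function(theta = 20, pointsPerSegment = 50L, eta = 0.8,
                           minForce = 1e-8) {
    new("DetectorParams", theta = theta,
        pointsPerSegment = as.integer(pointsPerSegment), eta = eta,
        minForce = minForce)
}

#' @exportClass MagnetParams
setClass("MagnetParams",
    representation(k = "numeric", lambdaDir = "character", edgeFrac = "numeric",
                   softenEps = "numeric", halo = "numeric", iS = "numeric",
                   gradSigma = "numeric"),
    validity = function(object) {
        if (object@k < 0) return("k must be >= 0")
        if (!object@lambdaDir %in% c("auto", "ccw", "cw"))
            return("lambdaDir must be 'auto', 'ccw' or 'cw'")
        if (object@edgeFrac <= 0 || object@edgeFrac >= 1)
            return("edgeFrac must lie in (0, 1)")
        if (object@softenEps <= 0) return("softenEps must be > 0")
        if (object@halo < 1) return("halo must be >= 1 px")
        if (object@gradSigma < 0) return("gradSigma must be >= 0")
        TRUE
    })

#' Magnetostatic force parameters
#'
#' @param k weight of the magnetic force when it is added to the external
#'   field (default 0.6).
#' @param lambdaDir direction of the hypothetical boundary current:
#'   \code{"ccw"}, \code{"cw"}, or \code{"auto"} (match the initial contour's
#'   orientation, valid for initial contours strictly inside or outside the
#'   object).
#' @param edgeFrac boundary points are pixels whose gradient magnitude is at
#'   least this fraction of the maximum.
#' @param softenEps softening length in px for the Biot-Savart denominator
#'   (R^2 -> R^2 + softenEps^2).
#' @param halo radius in px of the region around each false-segment point
#'   where the field is updated.
#' @param iS current magnitude on the false contour (folded to 1; only the
#'   product with \code{k} matters).
#' @param gradSigma Gaussian width for the image gradient feeding the
#'   boundary current.
#' @return A \code{MagnetParams} object.
#' @export
magnetParams <- function(k = 0.6, lambdaDir = "auto", edgeFrac = 0.3,
                         softenEps = 1, halo = 3, iS = 1, gradSigma = 1) {
    new("MagnetParams", k = k, lambdaDir = lambdaDir, edgeFrac = edgeFrac,
        softenEps = softenEps, halo = halo, iS = iS, gradSigma = gradSigma)
}

## ---------------------------------------------------------------------------
## Detector / magnet result objects
## ---------------------------------------------------------------------------

#' False-segment report
#'
#' @slot pointFlags logical vector, per-point false flags.
#' @slot segments data.frame with columns \code{start}, \code{end} (inclusive
#'   point indices) and \code{isFalse}; the segments tile the contour once.
#' @slot nFalseSegments number of segments judged false.
#' @slot falseRuns list of integer index vectors: maximal runs of adjacent
#'   false segments (cyclically merged), used for magnet processing.
#' @exportClass FalseSegmentReport
setClass("FalseSegmentReport",
    representation(pointFlags = "logical", segments = "data.frame",
                   nFalseSegments = "integer", falseRuns = "list"),
    validity = function(object) {
        seg <- object@segments
        if (!all(c("start", "end", "isFalse") %in% names(seg)))
            return("segments needs start, end, isFalse columns")
        covered <- sum(seg$end - seg$start + 1L)
        if (covered != length(object@pointFlags))
            return("segments must tile the contour exactly once")
        if (object@nFalseSegments != sum(seg$isFalse))
            return("nFalseSegments inconsistent with segment flags")
        TRUE
    })

#' Magnetic source: boundary points carrying current
#'
#' @slot points M x 2 matrix of boundary pixel positions (x, y).
#' @slot currents M x 2 matrix of current vectors Gamma(c).
#' @slot lambdaDir \code{"ccw"} or \code{"cw"}.
#' @exportClass MagneticSource
setClass("MagneticSource",
    representation(points = "matrix", currents = "matrix",
                   lambdaDir = "character"),
    validity = function(object) {
        if (nrow(object@points) != nrow(object@currents))
            return("points and currents must have the same length")
        if (nrow(object@points) > 0 && (ncol(object@points) != 2L ||
                                        ncol(object@currents) != 2L))
            return("points and currents must be M x 2")
        if (any(!is.finite(object@currents))) return("currents must be finite")
        if (!object@lambdaDir %in% c("ccw", "cw"))
            return("lambdaDir must be 'ccw' or 'cw'")
        TRUE
    })

## ---------------------------------------------------------------------------
## Driver objects
## ---------------------------------------------------------------------------

#' @exportClass RunConfig
setClass("RunConfig",
    representation(snake = "SnakeParams", gvf = "GvfParams",
                   detector = "DetectorParams", magnet = "MagnetParams",
                   edgeVariant = "character", edgeSigma = "numeric",
                   maxOuterRounds = "integer", seed = "integer"),
    validity = function(object) {
        if (object@maxOuterRounds < 1L) return("maxOuterRounds must be >= 1")
        if (!object@edgeVariant %in% c("grad_sq", "smoothed_grad_sq"))
            return("edgeVariant must be 'grad_sq' or 'smoothed_grad_sq'")
        TRUE
    })

#' Full run configuration
#'
#' Bundles the per-module parameters plus the outer-loop bound.  Defaults are
#' alpha = 0.6, beta = 0.3, mu = 0.2, k = 0.6, theta = 20, eta = 0.8 and
#' 50 points per detector segment.
#'
#' @param snake,gvf,detector,magnet parameter objects (see
#'   \code{\link{snakeParams}}, \code{\link{gvfParams}},
#'   \code{\link{detectorParams}}, \code{\link{magnetParams}}).
#' @param edgeVariant,edgeSigma edge-map variant and smoothing width.
#' @param maxOuterRounds cap on evolve/detect/update rounds.
#' @param seed seed for stochastic fixture generation (the segmentation
#'   pipeline itself is deterministic).
#' @return A \code{RunConfig} object.
#' @export
runConfig <- function(snake = snakeParams(), gvf = gvfParams(),
                      detector = detectorParams(), magnet = magnetParams(),
                      edgeVariant = "smoothed_grad_sq", edgeSigma = 1,
                      maxOuterRounds = 20L, seed = 1L) {
    new("RunConfig", snake = snake, gvf = gvf, detector = detector,
        magnet = magnet, edgeVariant = edgeVariant, edgeSigma = edgeSigma,
        maxOuterRounds = as.integer(maxOuterRounds), seed = as.integer(seed))
}

#' Segmentation run result
#'
#' @slot finalContour the stopped contour after the last round.
#' @slot rounds data.frame with one row per outer round: snake steps run,
#'   number of false segments, whether the field was updated, stop reason.
#' @slot convergedClean TRUE iff the last detection found zero false segments.
#' @slot nFieldUpdates number of rounds that updated the external field.
#' @slot externalField the final external force field.
#' @slot lastReport the last \code{FalseSegmentReport}.
#' @exportClass RunResult
setClass("RunResult",
    representation(finalContour = "Contour", rounds = "data.frame",
                   convergedClean = "logical", nFieldUpdates = "integer",
                   externalField = "VectorField",
                   lastReport = "FalseSegmentReport"),
    validity = function(object) {
        if (nrow(object@rounds) < 1L) return("rounds must be non-empty")
        last <- object@rounds$nFalseSegments[nrow(object@rounds)]
        lastClean <- !is.na(last) && last == 0L
        if (object@convergedClean != lastClean)
            return("convergedClean inconsistent with last round")
        TRUE
    })

## ---------------------------------------------------------------------------
## Synthetic fixtures
## ---------------------------------------------------------------------------

#' @exportClass ShapeSpec
setClass("ShapeSpec",
    representation(kind = "character", size = "integer", mouthWidth = "numeric",
                   depth = "numeric", nConcavities = "integer",
                   blurSigma = "numeric", noiseSd = "numeric", seed = "integer"),
    validity = function(object) {
        if (!object@kind %in% c("disc", "ushape", "multi_concave", "ring"))
            return("kind must be disc, ushape, multi_concave or ring")
        if (object@size < 32L) return("size must be >= 32 px")
        if (object@mouthWidth < 3) return("mouthWidth must be >= 3 px")
        if (object@depth >= object@size / 2) return("depth must be < size/2")
        if (object@noiseSd < 0) return("noiseSd must be >= 0")
        if (object@nConcavities < 1L) return("nConcavities must be >= 1")
        TRUE
    })

#' Synthetic shape specification
#'
#' Describes the binary test objects: a disc (convex control), a square with
#' one deep narrow slot ("ushape"), a square with several slots
#' ("multi_concave"), and an annulus ("ring").
#'
#' @param kind one of \code{"disc"}, \code{"ushape"}, \code{"multi_concave"},
#'   \code{"ring"}.
#' @param size image side length in px.
#' @param mouthWidth concavity mouth width in px.
#' @param depth concavity depth in px.
#' @param nConcavities number of concavities for \code{"multi_concave"}.
#' @param blurSigma Gaussian blur applied to the rendered image (px).
#' @param noiseSd additive Gaussian intensity noise (after blur), clipped to
#'   [0, 1].
#' @param seed RNG seed for the noise.
#' @return A \code{ShapeSpec} object.
#' @export
shapeSpec <- function(kind = "ushape", size = 256L, mouthWidth = 9,
                      depth = 40, nConcavities = 3L, blurSigma = 1,
                      noiseSd = 0, seed = 1L) {
    new("ShapeSpec", kind = kind, size = as.integer(size),
        mouthWidth = mouthWidth, depth = depth,
        nConcavities = as.integer(nConcavities), blurSigma = blurSigma,
        noiseSd = noiseSd, seed = as.integer(seed))
}
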