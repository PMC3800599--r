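## Gradient vector flow: diffusion of the edge-map gradient over the grid.

#' Compute the gradient vector flow field
#'
#' Minimizes the GVF energy
#' \deqn{\varepsilon = \iint \mu(u_x^2+u_y^2+v_x^2+v_y^2) +
#'   |\nabla f|^2 |V - \nabla f|^2 \, dx\,dy}
#' by explicit Euler iteration of its Euler-Lagrange diffusion equations
#' \eqn{\mu \nabla^2 u - (u - f_x)(f_x^2 + f_y^2) = 0} (and likewise for v),
#' initialized at \eqn{V = \nabla f}, with a 5-point Laplacian and replicate
#' border padding.  Iteration stops when the mean absolute per-pixel update
#' drops below \code{tol} or after \code{maxIters} iterations.
#'
#' The smoothness weight \eqn{\mu} trades edge fidelity against smoothness
#' (use larger values for noisier images).  Where \eqn{|\nabla f|} is large
#' the converged field nearly equals \eqn{\nabla f}; elsewhere diffusion
#' spreads the edge information across the whole grid, which is what gives
#' GVF snakes their large capture range.
#'
#' @param em an \code{\link{EdgeMap-class}}.
#' @param params a \code{\link{gvfParams}} object.
#' @return A \code{\link{VectorField-class}} with \code{iterationsRun} set.
#' @export
computeGVF <- function(em, params = gvfParams()) {
    ## NB: the explicit scheme needs dt*(8*mu + 2*max(b)) <= 2 for a
    ## monotone energy decrease; the default dt = 1/(4*mu + 1) guarantees
    ## this for any normalized edge map (b = fx^2 + fy^2 <= 1).
    stopifnot(is(em, "EdgeMap"), is(params, "GvfParams"))
    fx <- em@fx; fy <- em@fy
    b <- fx^2 + fy^2
    u <- fx; v <- fy
    dt <- params@dt; mu <- params@mu
    iters <- 0L
    for (it in seq_len(params@maxIters)) {
        du <- dt * (mu * .laplacian5(u) - (u - fx) * b)
        dv <- dt * (mu * .laplacian5(v) - (v - fy) * b)
        u <- u + du
        v <- v + dv
        if (any(!is.finite(u)) || any(!is.finite(v)))
            stop("GVF iteration diverged (non-finite values at iteration ", it, ")")
        iters <- it
        if ((mean(abs(du)) + mean(abs(dv))) / 2 < params@tol) break
    }
    new("VectorField", u = u, v = v, mu = mu, iterationsRun = iters)
}

#' Discrete GVF energy
#'
#' The discretized functional whose Euler-Lagrange equations
#' \code{\link{computeGVF}} iterates: forward-difference smoothness terms
#' (replicate padding, so boundary differences are zero) plus the
#' data term \eqn{|\nabla f|^2 |V-\nabla f|^2}.
#'
#' @param em an \code{EdgeMap}.
#' @param u,v field component matrices.
#' @param mu smoothness weight.
#' @return scalar energy.
#' @export
gvfEnergy <- function(em, u, v, mu) {
    fwdX <- function(m) {
        nc <- ncol(m)
        m[, .clampIdx(seq_len(nc) + 1L, nc), drop = FALSE] - m
    }
    fwdY <- function(m) {
        nr <- nrow(m)
        m[.clampIdx(seq_len(nr) + 1L, nr), , drop = FALSE] - m
    }
    b <- em@fx^2 + em@fy^2
    smooth <- sum(fwdX(u)^2 + fwdY(u)^2 + fwdX(v)^2 + fwdY(v)^2)
    data <- sum(b * ((u - em@fx)^2 + (v - em@fy)^2))
    mu * smooth + data
}

#' @rdname fieldAt
#' @export
setMethod("fieldAt", "VectorField", function(fld, p) {
    if (is.null(dim(p))) p <- matrix(p, ncol = 2)
    h <- nrow(fld@u); w <- ncol(fld@u)
    x <- p[, 1]; y <- p[, 2]
    if (any(x < 1 | x > w | y < 1 | y > h)) {
        warning("point(s) outside field bounds clamped to border")
        x <- pmin(pmax(x, 1), w)
        y <- pmin(pmax(y, 1), h)
    }
    x0 <- pmin(floor(x), w - 1); y0 <- pmin(floor(y), h - 1)
    tx <- x - x0; ty <- y - y0
    i00 <- cbind(y0, x0);     i01 <- cbind(y0, x0 + 1)
    i10 <- cbind(y0 + 1, x0); i11 <- cbind(y0 + 1, x0 + 1)
    bil <- function(m)
        (1 - tx) * (1 - ty) * m[i00] + tx * (1 - ty) * m[i01] +
        (1 - tx) * ty * m[i10] + tx * ty * m[i11]
    cbind(bil(fld@u), bil(fld@v))
})

## --- field caching (flat binary dump + JSON sidecar) ----------------------

#' Write / read a vector field cache
#'
#' The field is dumped as little-endian doubles (u then v, column-major)
#' next to a JSON sidecar recording shape, mu and iterations, so expensive
#' GVF fields can be reused between CLI runs.
#'
#' @param fld a \code{VectorField}.
#' @param path base path; \code{.bin} and \code{.json} are appended.
#' @return \code{writeField}: invisibly, the base path.  \code{readField}:
#'   a \code{VectorField}.
#' @export
writeField <- function(fld, path) {
    con <- file(paste0(path, ".bin"), "wb")
    on.exit(close(con))
    writeBin(as.vector(c(fld@u, fld@v)), con, size = 8, endian = "little")
    jsonlite::write_json(
        list(height = nrow(fld@u), width = ncol(fld@u), mu = fld@mu,
             iterations_run = fld@iterationsRun),
        paste0(path, ".json"), auto_unbox = TRUE)
    invisible(path)
}

#' @rdname writeField
#' @export
readField <- function(path) {
    meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
    n <- meta$height * meta$width
    con <- file(paste0(path, ".bin"), "rb")
    on.exit(close(con))
    raw <- readBin(con, "double", n = 2 * n, size = 8, endian = "little")
    new("VectorField",
        u = matrix(raw[seq_len(n)], meta$height, meta$width),
        v = matrix(raw[n + seq_len(n)], meta$height, meta$width),
        mu = meta$mu, iterationsRun = as.integer(meta$iterations_run))
}
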