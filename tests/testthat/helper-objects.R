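# Shared builders for small in-code fixtures.

constImage <- function(n = 16, value = 0.5) grayImage(matrix(value, n, n))

# vertical step: left half dark, right half bright
stepImage <- function(n = 24) {
    m <- matrix(0, n, n)
    m[, (n %/% 2 + 1):n] <- 1
    grayImage(m)
}

# edge map of an image with a single bright pixel at the center
peakEdgeMap <- function(n = 7, sigma = 1) {
    m <- matrix(0, n, n)
    m[(n + 1) %/% 2, (n + 1) %/% 2] <- 1
    edgeMap(grayImage(m), "smoothed_grad_sq", sigma)
}

makeField <- function(u, v) {
    new("VectorField", u = u, v = v, mu = NA_real_, iterationsRun = 0L)
}

circlePoints <- function(n, r, cx = 0, cy = 0) {
    th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
    cbind(cx + r * cos(th), cy + r * sin(th))
}

# dense Gaussian smoothing oracle: full 2-D kernel, replicate padding
denseSmoothOracle <- function(m, sigma) {
    r <- max(1L, ceiling(3 * sigma))
    k1 <- exp(-(-r:r)^2 / (2 * sigma^2)); k1 <- k1 / sum(k1)
    K <- outer(k1, k1)
    nr <- nrow(m); nc <- ncol(m)
    out <- matrix(0, nr, nc)
    cl <- function(i, n) pmin(pmax(i, 1L), n)
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
        acc <- 0
        for (a in -r:r) for (b in -r:r)
            acc <- acc + K[a + r + 1L, b + r + 1L] *
                m[cl(i + a, nr), cl(j + b, nc)]
        out[i, j] <- acc
    }
    out
}

centralDiffOracle <- function(m, axis = c("x", "y")) {
    axis <- match.arg(axis)
    nr <- nrow(m); nc <- ncol(m)
    cl <- function(i, n) pmin(pmax(i, 1L), n)
    out <- matrix(0, nr, nc)
    for (i in seq_len(nr)) for (j in seq_len(nc))
        out[i, j] <- if (axis == "x")
            (m[i, cl(j + 1L, nc)] - m[i, cl(j - 1L, nc)]) / 2
        else (m[cl(i + 1L, nr), j] - m[cl(i - 1L, nr), j]) / 2
    out
}

# direct quadratic minimization of the discrete GVF energy (independent of
# the diffusion path): L-BFGS-B on the 2*n*n unknowns with analytic gradient
gvfMinimizeOracle <- function(em, mu) {
    nr <- nrow(em@f); nc <- ncol(em@f); n <- nr * nc
    b <- em@fx^2 + em@fy^2
    cl <- function(i, k) pmin(pmax(i, 1L), k)
    lap <- function(m)
        m[cl(seq_len(nr) + 1L, nr), , drop = FALSE] +
        m[cl(seq_len(nr) - 1L, nr), , drop = FALSE] +
        m[, cl(seq_len(nc) + 1L, nc), drop = FALSE] +
        m[, cl(seq_len(nc) - 1L, nc), drop = FALSE] - 4 * m
    obj <- function(z)
        gvfEnergy(em, matrix(z[seq_len(n)], nr, nc),
                  matrix(z[n + seq_len(n)], nr, nc), mu)
    grad <- function(z) {
        u <- matrix(z[seq_len(n)], nr, nc)
        v <- matrix(z[n + seq_len(n)], nr, nc)
        c(-2 * mu * lap(u) + 2 * b * (u - em@fx),
          -2 * mu * lap(v) + 2 * b * (v - em@fy))
    }
    o <- stats::optim(c(em@fx, em@fy), obj, grad, method = "L-BFGS-B",
                      control = list(maxit = 20000, factr = 10))
    list(u = matrix(o$par[seq_len(n)], nr, nc),
         v = matrix(o$par[n + seq_len(n)], nr, nc),
         convergence = o$convergence)
}

# dense semi-implicit snake step oracle: explicit circulant matrix + solve()
snakeStepOracle <- function(pts, f, alpha, beta, gamma, kappa) {
    n <- nrow(pts)
    A <- matrix(0, n, n)
    for (i in seq_len(n)) {
        add <- function(off, val) {
            j <- ((i - 1L + off) %% n) + 1L
            A[i, j] <<- A[i, j] + val
        }
        add(0L, 2 * alpha + 6 * beta)
        add(1L, -(alpha + 4 * beta)); add(-1L, -(alpha + 4 * beta))
        add(2L, beta); add(-2L, beta)
    }
    C <- diag(n) + gamma * A
    cbind(solve(C, pts[, 1] + gamma * kappa * f[, 1]),
          solve(C, pts[, 2] + gamma * kappa * f[, 2]))
}
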