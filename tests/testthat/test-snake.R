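test_that("contour initialization reproduces a marker polygon", {
    sq <- initContour(rbind(c(10, 10), c(30, 10), c(30, 30), c(10, 30)), 1)
    expect_equal(nPoints(sq), 80L)
    expect_equal(orientation(sq), "ccw")
    p <- contourPoints(sq)
    onEdge <- abs(p[, 1] - 10) < 1e-9 | abs(p[, 1] - 30) < 1e-9 |
              abs(p[, 2] - 10) < 1e-9 | abs(p[, 2] - 30) < 1e-9
    expect_true(all(onEdge))

    # collinear markers plus one are a valid (triangular) polygon
    tri <- initContour(rbind(c(0, 0), c(10, 0), c(20, 0), c(10, 15)), 2)
    per <- 20 + 2 * sqrt(10^2 + 15^2)
    expect_equal(nPoints(tri), round(per / 2))

    bowtie <- rbind(c(0, 0), c(10, 10), c(10, 0), c(0, 10))
    expect_error(initContour(bowtie, 1), "self-intersecting")
})

test_that("circle markers interpolate close to the circle", {
    mk <- circlePoints(12, 20, 50, 50)
    ctr <- initContour(mk, 1)
    p <- contourPoints(ctr)
    dev <- abs(sqrt((p[, 1] - 50)^2 + (p[, 2] - 50)^2) - 20)
    # piecewise-linear chords of a 12-gon sag by 20*(1-cos(pi/12)) = 0.68 px
    expect_lt(max(dev), 0.7)
})

test_that("resampling is idempotent, preserves perimeter, and spaces points evenly", {
    ctr <- makeContour(circlePoints(100, 30, 0, 0))
    again <- resampleContour(ctr, perimeter(ctr) / 100)
    expect_lt(max(abs(contourPoints(again) - contourPoints(ctr))), 1e-9)

    sq <- makeContour(rbind(c(0, 0), c(25, 0), c(25, 25), c(0, 25)))
    rs <- resampleContour(sq, 2)
    expect_equal(nPoints(rs), 50L)
    # chords spanning the four right-angle corners shorten the polyline by
    # up to (2 - sqrt(2)) * spacing/2 each
    expect_lt(abs(perimeter(rs) - 100) / 100, 0.025)
    expect_equal(orientation(rs), orientation(sq))
    smooth <- makeContour(circlePoints(100, 30, 0, 0))
    rs2 <- resampleContour(smooth, 1)
    expect_lt(abs(perimeter(rs2) - perimeter(smooth)) / perimeter(smooth), 0.01)

    # chord spacing on a regular 20-gon: uniform within the vertex sagitta
    poly <- makeContour(circlePoints(20, 30, 0, 0))
    rs <- resampleContour(poly, 1)
    q <- contourPoints(rs); m <- nrow(q)
    sp <- sqrt(rowSums((q[c(2:m, 1L), ] - q)^2))
    target <- perimeter(rs) / m
    expect_lt(max(abs(sp - target)) / target, 0.02)

    degenerate <- makeContour(matrix(c(5, 5, 5, 5, 5, 5), 3, 2))
    expect_error(resampleContour(degenerate, 1), "degenerate")
})

test_that("tangents are unit central differences with periodic indexing", {
    sq <- initContour(rbind(c(0, 0), c(20, 0), c(20, 20), c(0, 20)), 1)
    p <- contourPoints(sq); tg <- contourTangents(sq)
    midTop <- which.min((p[, 1] - 10)^2 + p[, 2]^2)
    expect_equal(abs(tg[midTop, ]), c(1, 0))

    circ <- makeContour(circlePoints(60, 25, 0, 0))
    tg <- contourTangents(circ)
    radial <- contourPoints(circ) / 25
    expect_lt(max(abs(rowSums(tg * radial))), 1e-3)

    set.seed(12)
    pts <- circlePoints(15, 10, 40, 40) + matrix(rnorm(30, 0, 0.5), 15, 2)
    ctr <- makeContour(pts)
    tg <- contourTangents(ctr)
    n <- 15
    raw <- pts[c(2:n, 1L), ] - pts[c(n, 1:(n - 1L)), ]
    expect_equal(tg, raw / sqrt(rowSums(raw^2)))
})

test_that("one evolution step equals the dense pentadiagonal solve oracle", {
    set.seed(3)
    pts <- circlePoints(10, 10, 50, 50) + matrix(rnorm(20, 0, 0.3), 10, 2)
    ctr <- makeContour(pts)
    ff <- function(q) cbind(sin(q[, 1] / 5), cos(q[, 2] / 7))
    sp <- snakeParams(alpha = 0.6, beta = 0.3, gamma = 1.2, kappa = 0.8,
                      spacing = 2, maxSteps = 1L)
    got <- evolveContour(ctr, ff, sp, nSteps = 1L)$contour
    oracle <- snakeStepOracle(pts, ff(pts), 0.6, 0.3, 1.2, 0.8)
    want <- resampleContour(makeContour(oracle), 2)  # same per-step resample
    expect_lt(max(abs(contourPoints(got) - contourPoints(want))), 1e-10)
})

test_that("elasticity alone shrinks a circle monotonically", {
    ctr <- makeContour(circlePoints(80, 25, 50, 50))
    sp <- snakeParams(alpha = 0.5, beta = 0, stopEps = 1e-9, stopWindow = 50L)
    zero <- function(q) matrix(0, nrow(q), 2)
    per <- perimeter(ctr)
    for (i in 1:5) {
        ctr <- evolveContour(ctr, zero, sp, nSteps = 1L)$contour
        expect_lt(perimeter(ctr), per)
        per <- perimeter(ctr)
    }
})

test_that("zero force with zero stiffness is a fixed point that stops", {
    ctr <- makeContour(circlePoints(40, 12, 30, 30))
    sp <- snakeParams(alpha = 0, beta = 0, stopEps = 0.1, stopWindow = 6L,
                      maxSteps = 50L, spacing = perimeter(ctr) / 40)
    ev <- evolveContour(ctr, function(q) matrix(0, nrow(q), 2), sp)
    expect_true(ev$stopped)
    expect_equal(ev$steps, 6L)
    expect_lt(max(abs(contourPoints(ev$contour) - contourPoints(ctr))), 1e-9)
})

test_that("the internal-force solve conserves the centroid of a closed contour", {
    ctr <- makeContour(circlePoints(90, 30, 60, 60))
    sp <- snakeParams(alpha = 0.6, beta = 0.3)
    ev <- evolveContour(ctr, function(q) matrix(0, nrow(q), 2), sp, nSteps = 1L)
    before <- colMeans(contourPoints(ctr))
    after <- colMeans(contourPoints(ev$contour))
    expect_lt(max(abs(after - before)), 1e-6)
})

test_that("contours round-trip through CSV and JSON", {
    ctr <- makeContour(circlePoints(20, 12, 30, 40))
    tmp <- withr::local_tempdir()
    csv <- file.path(tmp, "c.csv"); js <- file.path(tmp, "c.json")
    writeContourCSV(ctr, csv)
    expect_equal(contourPoints(readContourCSV(csv)), contourPoints(ctr),
                 tolerance = 1e-12)
    writeContourJSON(ctr, js)
    back <- readContourJSON(js)
    expect_equal(contourPoints(back), contourPoints(ctr), tolerance = 1e-12)
    expect_equal(orientation(back), orientation(ctr))
})
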