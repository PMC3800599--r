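test_that("the 3x3 maximum angle matches hand-enumerable cases", {
    u1 <- matrix(1, 5, 5); v0 <- matrix(0, 5, 5)
    fld <- makeField(u1, v0)                       # all forces (1, 0)
    expect_equal(pointMaxAngle(c(1, 0), c(3, 3), fld), 0)

    fld <- makeField(v0, u1)                       # all forces (0, 1)
    expect_equal(pointMaxAngle(c(1, 0), c(3, 3), fld), 90)

    # eight forces (1,0), one (1,1)/sqrt(2): the maximum is 45 degrees
    u <- matrix(1, 5, 5); v <- matrix(0, 5, 5)
    u[2, 3] <- 1 / sqrt(2); v[2, 3] <- 1 / sqrt(2)
    expect_equal(pointMaxAngle(c(1, 0), c(3, 3), makeField(u, v)), 45)

    # the acute angle ignores force and tangent sign
    expect_equal(pointMaxAngle(c(-1, 0), c(3, 3), makeField(u, v)), 45)

    # all nine below the magnitude floor: stalled-field convention, 0 degrees
    tiny <- makeField(matrix(1e-12, 5, 5), matrix(0, 5, 5))
    expect_equal(pointMaxAngle(c(1, 0), c(3, 3), tiny, minForce = 1e-8), 0)
})

test_that("perpendicular forces mark a real contour, parallel forces a false one", {
    n <- 40
    circ <- makeContour(circlePoints(72, 12, (n + 1) / 2, (n + 1) / 2))
    xs <- matrix(rep(seq_len(n), each = n), n, n)
    ys <- matrix(rep(seq_len(n), times = n), n, n)
    rx <- xs - (n + 1) / 2; ry <- ys - (n + 1) / 2
    rmag <- pmax(sqrt(rx^2 + ry^2), 1e-9)
    radial <- makeField(rx / rmag, ry / rmag)
    tangential <- makeField(-ry / rmag, rx / rmag)

    expect_false(any(classifyPoints(circ, radial, detectorParams(theta = 20))))
    expect_true(all(classifyPoints(circ, tangential, detectorParams(theta = 20))))
})

test_that("one irregular perpendicular force in the 3x3 block rescues the point", {
    # rectangle in a uniform horizontal field: the horizontal sides are
    # parallel to every force and get flagged
    rect <- initContour(rbind(c(5, 5), c(25, 5), c(25, 11), c(5, 11)), 1)
    u <- matrix(1, 30, 30); v <- matrix(0, 30, 30)
    fld <- makeField(u, v)
    flags <- classifyPoints(rect, fld, detectorParams(theta = 20))
    p <- contourPoints(rect)
    horiz <- abs(p[, 2] - 5) < 1e-6 & p[, 1] > 7 & p[, 1] < 23
    vert <- abs(p[, 1] - 25) < 1e-6 & p[, 2] > 6 & p[, 2] < 10
    expect_true(all(flags[horiz]))
    expect_false(any(flags[vert]))

    # poke a single perpendicular vector next to one flagged point: the max
    # over the nine angles now exceeds theta and the point is not flagged
    target <- which(horiz & abs(p[, 1] - 15) < 0.5)[1]
    u2 <- u; v2 <- v
    u2[4, 15] <- 0; v2[4, 15] <- 1
    flags2 <- classifyPoints(rect, makeField(u2, v2), detectorParams(theta = 20))
    expect_false(flags2[target])
    expect_true(all(flags2[horiz & abs(p[, 1] - 15) > 2.5]))
})

test_that("segment judgement applies the strict within-segment fraction rule", {
    ctr <- makeContour(circlePoints(50, 10, 20, 20))
    par <- detectorParams(eta = 0.8, pointsPerSegment = 50L)  # l = 1

    rep0 <- detectFalseSegments(ctr, rep(FALSE, 50), par)
    expect_equal(rep0@nFalseSegments, 0L)
    expect_length(rep0@falseRuns, 0L)

    f45 <- c(rep(TRUE, 45), rep(FALSE, 5))   # 45 * (1/50) = 0.9 > 0.8
    expect_equal(detectFalseSegments(ctr, f45, par)@nFalseSegments, 1L)

    f40 <- c(rep(TRUE, 40), rep(FALSE, 10))  # 0.8 is not > 0.8
    expect_equal(detectFalseSegments(ctr, f40, par)@nFalseSegments, 0L)
})

test_that("segments tile the contour and adjacent false segments merge", {
    ctr <- makeContour(circlePoints(100, 15, 20, 20))
    par <- detectorParams(pointsPerSegment = 10L, eta = 0.8)
    flags <- rep(FALSE, 100)
    flags[21:40] <- TRUE                      # blocks 3 and 4 fully false
    rep1 <- detectFalseSegments(ctr, flags, par)
    expect_equal(nrow(rep1@segments), 10L)
    expect_equal(sum(rep1@segments$end - rep1@segments$start + 1L), 100L)
    expect_equal(rep1@nFalseSegments, 2L)
    expect_length(rep1@falseRuns, 1L)
    expect_equal(rep1@falseRuns[[1]], 21:40)

    flags <- rep(FALSE, 100)
    flags[c(91:100, 1:10)] <- TRUE            # wrap-around: blocks 10 and 1
    rep2 <- detectFalseSegments(ctr, flags, par)
    expect_equal(rep2@nFalseSegments, 2L)
    expect_length(rep2@falseRuns, 1L)
    expect_setequal(rep2@falseRuns[[1]], c(91:100, 1:10))
})

test_that("point flags are invariant to contour orientation reversal", {
    set.seed(21)
    n <- 30
    fld <- makeField(matrix(rnorm(n * n), n, n), matrix(rnorm(n * n), n, n))
    ctr <- makeContour(circlePoints(48, 9, (n + 1) / 2, (n + 1) / 2))
    rev <- makeContour(contourPoints(ctr)[48:1, ])
    f1 <- classifyPoints(ctr, fld, detectorParams(theta = 30))
    f2 <- classifyPoints(rev, fld, detectorParams(theta = 30))
    expect_identical(f1, f2[48:1])
})

test_that("raising theta only adds flags; raising eta only removes false segments", {
    set.seed(22)
    n <- 30
    fld <- makeField(matrix(rnorm(n * n), n, n), matrix(rnorm(n * n), n, n))
    ctr <- makeContour(circlePoints(60, 10, (n + 1) / 2, (n + 1) / 2))
    thetas <- c(10, 25, 45, 70)
    flagSets <- lapply(thetas, function(th)
        classifyPoints(ctr, fld, detectorParams(theta = th)))
    for (i in seq_len(length(thetas) - 1L))
        expect_true(all(flagSets[[i + 1]][flagSets[[i]]]))

    flags <- flagSets[[3]]
    etas <- c(0.2, 0.5, 0.8, 0.95)
    nf <- vapply(etas, function(e)
        detectFalseSegments(ctr, flags,
                            detectorParams(eta = e, pointsPerSegment = 10L)
                            )@nFalseSegments, integer(1))
    expect_true(all(diff(nf) <= 0L))
})

test_that("the report exports to JSON with its parameters", {
    ctr <- makeContour(circlePoints(20, 8, 15, 15))
    par <- detectorParams(pointsPerSegment = 10L)
    rep1 <- detectFalseSegments(ctr, rep(c(TRUE, FALSE), each = 10), par)
    tmp <- withr::local_tempfile(fileext = ".json")
    writeReportJSON(rep1, par, tmp)
    back <- jsonlite::read_json(tmp, simplifyVector = TRUE)
    expect_equal(back$n_false_segments, 1L)
    expect_equal(back$parameters$theta, 20)
    expect_equal(sum(back$point_flags), 10L)
})
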