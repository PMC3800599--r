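test_that("a convex object converges in one round with no field updates", {
    shp <- makeShape(shapeSpec("disc", size = 128L))
    init <- enclosingInit(shp$truth, 10)
    r <- runSegmentation(shp$image, init, runConfig())
    expect_true(r@convergedClean)
    expect_equal(r@nFieldUpdates, 0L)
    d <- boundaryDistance(r@finalContour, shp$truth)
    expect_lt(d$mean, 1.5)
})

test_that("the magnetostatic update drives the snake into a deep concavity", {
    shp <- makeShape(shapeSpec("ushape", size = 256L, mouthWidth = 24,
                               depth = 40))
    init <- enclosingInit(shp$truth, 10)
    det <- detectorParams(theta = 45, pointsPerSegment = 5L)
    plain <- runSegmentation(shp$image, init,
        runConfig(detector = det, magnet = magnetParams(k = 0),
                  maxOuterRounds = 30L))
    full <- runSegmentation(shp$image, init,
        runConfig(detector = det, magnet = magnetParams(k = 0.6),
                  maxOuterRounds = 30L))
    dPlain <- boundaryDistance(plain@finalContour, shp$truth)
    dFull <- boundaryDistance(full@finalContour, shp$truth)
    expect_false(plain@convergedClean)       # stalls, keeps reporting false
    expect_gt(dPlain$max, 20)                # half the concavity depth
    expect_true(full@convergedClean)
    expect_gt(full@nFieldUpdates, 0L)
    expect_lt(dFull$mean, 0.5)
    expect_lt(dFull$mean, dPlain$mean)
})

test_that("identical inputs give bit-identical results", {
    shp <- makeShape(shapeSpec("ushape", size = 128L, mouthWidth = 20,
                               depth = 45))
    init <- enclosingInit(shp$truth, 8)
    cfg <- runConfig(detector = detectorParams(theta = 45, pointsPerSegment = 5L),
                     maxOuterRounds = 5L)
    r1 <- runSegmentation(shp$image, init, cfg)
    r2 <- runSegmentation(shp$image, init, cfg)
    expect_identical(contourPoints(r1@finalContour),
                     contourPoints(r2@finalContour))
    expect_identical(r1@rounds, r2@rounds)
    expect_identical(r1@externalField@u, r2@externalField@u)
})

test_that("bookkeeping ties field updates to rounds that found false parts", {
    shp <- makeShape(shapeSpec("ushape", size = 128L, mouthWidth = 20,
                               depth = 45))
    init <- enclosingInit(shp$truth, 8)
    cfg <- runConfig(detector = detectorParams(theta = 45, pointsPerSegment = 5L),
                     maxOuterRounds = 8L)
    r <- runSegmentation(shp$image, init, cfg)
    expect_equal(r@nFieldUpdates, sum(r@rounds$fieldUpdated))
    withFalse <- !is.na(r@rounds$nFalseSegments) & r@rounds$nFalseSegments > 0L
    expect_equal(sum(r@rounds$fieldUpdated), sum(withFalse))
    expect_identical(r@convergedClean,
        !is.na(r@rounds$nFalseSegments[nrow(r@rounds)]) &&
        r@rounds$nFalseSegments[nrow(r@rounds)] == 0L)
})

test_that("degenerate runs fail loudly", {
    img <- constImage(64)
    tiny <- initContour(circlePoints(12, 3, 32, 32), 1)
    expect_error(runSegmentation(img, tiny, runConfig(maxOuterRounds = 2L)),
                 "collapsed")
    outside <- makeContour(circlePoints(12, 40, 32, 32))
    expect_error(runSegmentation(img, outside, runConfig()), "outside")
})

test_that("YAML configuration maps onto parameter objects with overrides", {
    tmp <- withr::local_tempfile(fileext = ".yaml")
    yaml::write_yaml(list(snake = list(alpha = 0.4, stopEps = 0.05),
                          gvf = list(mu = 0.3),
                          detector = list(theta = 35),
                          magnet = list(k = 0.2),
                          max_outer_rounds = 7), tmp)
    cfg <- configFromYAML(tmp)
    expect_equal(cfg@snake@alpha, 0.4)
    expect_equal(cfg@gvf@mu, 0.3)
    expect_equal(cfg@detector@theta, 35)
    expect_equal(cfg@magnet@k, 0.2)
    expect_equal(cfg@maxOuterRounds, 7L)
    cfg2 <- configFromYAML(tmp, overrides = list(magnet = list(k = 0.9)))
    expect_equal(cfg2@magnet@k, 0.9)
    expect_equal(cfg2@gvf@mu, 0.3)
    # defaults without a file follow the reference parameter setting
    d <- configFromYAML()
    expect_equal(c(d@snake@alpha, d@snake@beta, d@gvf@mu, d@magnet@k,
                   d@detector@theta, d@detector@eta), c(0.6, 0.3, 0.2, 0.6, 20, 0.8))
    expect_equal(d@detector@pointsPerSegment, 50L)
})

test_that("the CLI round-trips fixture generation and segmentation", {
    tmp <- withr::local_tempdir()
    imgP <- file.path(tmp, "disc.png"); truthP <- file.path(tmp, "truth.csv")
    status <- cliMain(c("fixture", "--shape", "disc", "--size", "96",
                        "--out-image", imgP, "--out-contour", truthP))
    expect_equal(status, 0L)
    expect_true(file.exists(imgP) && file.exists(truthP))

    truth <- readContourCSV(truthP)
    initP <- file.path(tmp, "init.csv")
    writeContourCSV(enclosingInit(truth, 8), initP)
    outC <- file.path(tmp, "out.csv"); outM <- file.path(tmp, "mask.png")
    outR <- file.path(tmp, "report.json")
    status <- suppressMessages(
        cliMain(c("segment", "--image", imgP, "--init", initP,
                  "--out-contour", outC, "--out-mask", outM,
                  "--out-report", outR)))
    expect_equal(status, 0L)
    seg <- readContourCSV(outC)
    d <- boundaryDistance(seg, truth)
    expect_lt(d$mean, 1.5)
    rep1 <- jsonlite::read_json(outR, simplifyVector = TRUE)
    expect_true(rep1$final$converged_clean)
    mask <- png::readPNG(outM)
    expect_equal(mask[48, 48], 1)  # disc interior filled

    # missing init file: usage error, no partial outputs
    bad <- file.path(tmp, "none.csv")
    status <- suppressMessages(
        cliMain(c("segment", "--image", imgP, "--init", bad,
                  "--out-contour", file.path(tmp, "x.csv"))))
    expect_equal(status, 2L)
    expect_false(file.exists(file.path(tmp, "x.csv")))
})
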