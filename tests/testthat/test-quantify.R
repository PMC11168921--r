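discFixture <- function(seed = 1, R = 3, noiseFree = TRUE, ...) {
    sp <- if (noiseFree) phantomSpecNoiseFree("disc_xy", seed = seed,
                                              enrichmentR = R, ...)
          else phantomSpec("disc_xy", seed = seed, enrichmentR = R, ...)
    ph <- makePhantom(sp)
    tis <- tissueMaskFromMatrix(ph$truth@tissueMask, 0.5)
    list(ph = ph, tis = tis,
         part = partitionRimCentre(tis, sp@rimWidthTrue),
         mark = getPlane(ph$stack, "mark"),
         dapi = getPlane(ph$stack, "dapi"))
}

test_that("rim/centre ratio: uniform fields, identical channels, exact R", {
    fx <- discFixture(seed = 1, R = 3)
    ## identical channels -> exactly 1, any spatial pattern
    expect_identical(rimCentreRatio(fx$mark, fx$mark, fx$part)$ratio, 1)
    ## uniform mark and reference -> exactly 1
    u <- makePlane(matrix(7, 160, 160)); v <- makePlane(matrix(3, 160, 160))
    expect_equal(rimCentreRatio(u, v, fx$part)$ratio, 1)
    ## noise-free phantom with matching rim geometry -> R to 1e-6
    r <- rimCentreRatio(fx$mark, fx$dapi, fx$part)$ratio
    expect_equal(r, 3, tolerance = 1e-6)
    ## ... and the ratio agrees with the brute-force masked-sum oracle
    expect_equal(r, oracleRimCentreRatio(planeValues(fx$mark),
                                         planeValues(fx$dapi),
                                         rimMask(fx$part),
                                         centreMask(fx$part)),
                 tolerance = 1e-12)
})

test_that("rim/centre ratio is invariant to rescaling either channel", {
    fx <- discFixture(seed = 6, R = 2, noiseFree = FALSE)
    r0 <- rimCentreRatio(fx$mark, fx$dapi, fx$part)$ratio
    for (s in c(0.01, 3, 250)) {
        ms <- makePlane(planeValues(fx$mark) * s)
        ds <- makePlane(planeValues(fx$dapi) * s)
        expect_equal(rimCentreRatio(ms, fx$dapi, fx$part)$ratio, r0,
                     tolerance = 1e-12)
        expect_equal(rimCentreRatio(fx$mark, ds, fx$part)$ratio, r0,
                     tolerance = 1e-12)
    }
    ## an additive offset on the mark is undone by background subtraction
    shifted <- makePlane(planeValues(fx$mark) + 40)
    expect_equal(rimCentreRatio(shifted, fx$dapi, fx$part,
                                backgroundOffset = 40)$ratio, r0,
                 tolerance = 1e-12)
})

test_that("rim/centre ratio raises on empty regions and zero reference", {
    fx <- discFixture()
    none <- matrix(FALSE, 160, 160)
    expect_error(rimCentreRatio(fx$mark, fx$dapi, fx$part, restrict = none),
                 class = "discRim_measurement_error")
    zero <- makePlane(matrix(0, 160, 160))
    expect_error(rimCentreRatio(fx$mark, zero, fx$part),
                 class = "discRim_measurement_error")
})

test_that("compartment ratios: symmetry, one-sided enrichment, one-sided errors", {
    fx <- discFixture(seed = 2, R = 3)
    comp <- new("CompartmentMask", positive = fx$ph$truth@positiveMask,
                negative = fx$ph$truth@negativeMask)
    pair <- compartmentRatioPair(fx$mark, fx$dapi, fx$part, comp)
    ## symmetric phantom: both compartments see the same enrichment
    expect_equal(pair$ratio[1], pair$ratio[2], tolerance = 1e-6)
    expect_equal(pair$ratio[1], 3, tolerance = 1e-6)
    ## enrichment confined to the positive half
    mv <- planeValues(fx$dapi)
    enr <- matrix(1, 160, 160)
    enr[rimMask(fx$part) & comp@positive] <- 4
    oneSided <- makePlane(mv * enr)
    pair2 <- compartmentRatioPair(oneSided, fx$dapi, fx$part, comp)
    expect_equal(pair2$ratio[pair2$compartment == "reporter_positive"], 4,
                 tolerance = 1e-6)
    expect_equal(pair2$ratio[pair2$compartment == "reporter_negative"], 1,
                 tolerance = 1e-6)
    ## empty positive mask: NA on that side only, with a warning
    empty <- new("CompartmentMask",
                 positive = matrix(FALSE, 160, 160),
                 negative = fx$ph$truth@tissueMask)
    expect_warning(pair3 <- compartmentRatioPair(fx$mark, fx$dapi, fx$part,
                                                 empty),
                   "reporter_positive")
    expect_true(is.na(pair3$ratio[1]))
    expect_false(is.na(pair3$ratio[2]))
})

test_that("rim totals are masked sums: indicator, linearity, oracle", {
    fx <- discFixture(seed = 3)
    comp <- new("CompartmentMask", positive = fx$ph$truth@positiveMask,
                negative = fx$ph$truth@negativeMask)
    ones <- makePlane(matrix(1, 160, 160))
    tot1 <- rimTotalIntensity(ones, fx$part, comp)
    expect_identical(unname(tot1["reporter_positive"]),
                     sum(rimMask(fx$part) & comp@positive) * 1)
    set.seed(8); rnd <- matrix(rexp(160^2), 160, 160)
    tr <- rimTotalIntensity(makePlane(rnd), fx$part, comp)
    expect_equal(unname(tr["reporter_positive"]),
                 sum(rnd[rimMask(fx$part) & comp@positive]), tolerance = 1e-12)
    expect_equal(unname(rimTotalIntensity(makePlane(2 * rnd), fx$part, comp)),
                 unname(2 * tr), tolerance = 1e-12)
})

test_that("projected intensity ratio handles identity, scaling and truth", {
    ph <- makeDiscPhantom(phantomSpec("disc_xy", seed = 12, nz = 4))
    st <- ph$stack
    expect_identical(projectedIntensityRatio(st, "mark", "mark"), 1)
    double <- new("ImageStack",
                  planes = list(a = planes(st)$dapi, b = 2 * planes(st)$dapi),
                  channelRoles = c(a = "dapi", b = "mark"),
                  pixelSizeXY = 0.5, pixelSizeZ = 1, discId = "x")
    expect_equal(projectedIntensityRatio(double, "a", "b"), 2,
                 tolerance = 1e-12)
    ## matches the quotient of brute-force channel totals
    expect_equal(projectedIntensityRatio(st, "dapi", "mark"),
                 sum(planes(st)$mark) / sum(planes(st)$dapi),
                 tolerance = 1e-12)
    expect_error(projectedIntensityRatio(
        new("ImageStack", planes = list(a = planes(st)$dapi * 0,
                                        b = planes(st)$mark),
            channelRoles = c(a = "dapi", b = "mark"), pixelSizeXY = 0.5,
            pixelSizeZ = 1, discId = "x"), "a", "b"),
        class = "discRim_measurement_error")
})

test_that("nucleus measurement reproduces hand arithmetic and phantom truth", {
    ## 4-pixel nucleus with values 1..4 -> mean 2.5
    lab <- matrix(0L, 6, 6); lab[3, 2:3] <- 1L; lab[4, 2:3] <- 1L
    li <- labelImageFromMatrix(lab, "nuclei", 1)
    ch <- matrix(0, 6, 6); ch[3, 2] <- 1; ch[4, 2] <- 2; ch[3, 3] <- 3
    ch[4, 3] <- 4
    rec <- measureNuclei(li, list(v = makePlane(ch, 1)))
    expect_equal(rec$mean_v, 2.5)
    expect_equal(rec$area, 4L)
    ## constant channel -> every mean equals the constant
    ph <- makeCrossSectionPhantom(phantomSpecNoiseFree("cross_section",
                                                       seed = 4))
    tis <- tissueMaskFromMatrix(ph$truth@tissueMask, 0.5)
    nuc <- labelImageFromMatrix(
        discRim:::.renderObjects(96, 256,
                                 as.matrix(ph$truth@nuclei[, c("y", "x")]),
                                 4), "nuclei", 0.5)
    const <- measureNuclei(nuc, list(c = makePlane(matrix(5, 96, 256), 0.5)))
    expect_true(all(const$mean_c == 5))
    ## phantom truth: noise-free means recovered exactly on true labels
    got <- measureNuclei(nuc, list(mark = getPlane(ph$stack, "mark")))
    expect_equal(got$mean_mark, ph$truth@nuclei$mean_mark, tolerance = 1e-9)
    expect_identical(nrow(measureNuclei(
        labelImageFromMatrix(matrix(0L, 4, 4), "nuclei", 1),
        list(v = makePlane(matrix(1, 4, 4), 1)))), 0L)
})

test_that("surface distances match construction and the pairwise oracle", {
    ph <- makeCrossSectionPhantom(phantomSpecNoiseFree("cross_section",
                                                       seed = 7))
    tis <- tissueMaskFromMatrix(ph$truth@tissueMask, 0.5)
    nuc <- labelImageFromMatrix(
        discRim:::.renderObjects(96, 256,
                                 as.matrix(ph$truth@nuclei[, c("y", "x")]),
                                 4), "nuclei", 0.5)
    rec <- measureNuclei(nuc, list(mark = getPlane(ph$stack, "mark")))
    rec <- annotateSurfaceDistance(rec, nuc, tis)
    expect_equal(rec$dist_surface, ph$truth@nuclei$requestedDepth,
                 tolerance = 0.5)   # placement quantization <= 1 px
    ## small-image exhaustive oracle
    m <- matrix(FALSE, 40, 40); m[8:32, 6:36] <- TRUE
    lab <- matrix(0L, 40, 40)
    lab[10:12, 10:12] <- 1L; lab[20:23, 25:28] <- 2L
    tis2 <- tissueMaskFromMatrix(m, 1)
    li <- labelImageFromMatrix(lab, "nuclei", 1)
    rec2 <- measureNuclei(li, list(v = makePlane(m * 1, 1)))
    rec2 <- annotateSurfaceDistance(rec2, li, tis2)
    d <- oracleDistToBackground(m)
    for (k in 1:2)
        expect_equal(rec2$dist_surface[k], min(d[lab == k]), tolerance = 1e-12)
    ## boundary nucleus is within one pixel of the surface
    lab3 <- matrix(0L, 40, 40); lab3[8, 20] <- 1L
    li3 <- labelImageFromMatrix(lab3, "nuclei", 1)
    r3 <- annotateSurfaceDistance(
        measureNuclei(li3, list(v = makePlane(m * 1, 1))), li3, tis2)
    expect_lte(r3$dist_surface, 1)
})

test_that("mitochondrion distances: contact, 3-4-5 and the pairwise oracle", {
    empty <- matrix(0L, 12, 12)
    nl <- empty; nl[1, 1] <- 1L
    ml <- empty; ml[4, 5] <- 1L       # offset (3, 4) -> distance 5
    nuc <- labelImageFromMatrix(nl, "nuclei", 1)
    mito <- labelImageFromMatrix(ml, "mitochondria", 1)
    rec <- measureNuclei(nuc, list(v = makePlane(matrix(1, 12, 12), 1)))
    expect_equal(annotateMitoDistance(rec, nuc, mito)$dist_mito, 5)
    ## overlap -> 0
    expect_equal(annotateMitoDistance(rec, nuc,
                                      labelImageFromMatrix(nl, "mitochondria",
                                                           1))$dist_mito, 0)
    ## random small images match the exhaustive pairwise search
    set.seed(123)
    for (k in 1:3) {
        nl <- matrix(0L, 30, 30); ml <- matrix(0L, 30, 30)
        nl[sample(900, 12)] <- 1L
        ml[sample(900, 20)] <- 1L
        ml[nl > 0L] <- 0L
        nuc <- labelImageFromMatrix(nl, "nuclei", 1)
        mito <- labelImageFromMatrix((ml > 0L) * 1L, "mitochondria", 1)
        rec <- measureNuclei(nuc, list(v = makePlane(matrix(1, 30, 30), 1)))
        got <- annotateMitoDistance(rec, nuc, mito)$dist_mito
        expect_equal(got, oracleMinPairDist(nl > 0L, ml > 0L),
                     tolerance = 1e-12)
    }
})

test_that("distance binning and reference-bin normalization are exact", {
    rec <- data.frame(disc_id = "d", label = 1:4,
                      dist_surface = c(2, 3, 7, 12),
                      mean_mark = c(10, 20, 15, 5))
    out <- binAndNormalize(rec, "mark")
    expect_identical(out$bin, c("<5", "<5", "5-10", ">10"))
    expect_equal(out$normalized_intensity, c(10, 20, 15, 5) / 15,
                 tolerance = 1e-12)
    expect_identical(nrow(out), nrow(rec))
    ## boundary: exactly 5 um lands in the 5-10 bin (half-open bins)
    b <- binAndNormalize(data.frame(dist_surface = c(1, 5, 10),
                                    mean_mark = c(1, 1, 1)), "mark")
    expect_identical(b$bin, c("<5", "5-10", ">10"))
    ## all records in the reference bin -> mean normalized value is 1
    a <- binAndNormalize(data.frame(dist_surface = c(1, 2, 3),
                                    mean_mark = c(3, 6, 9)), "mark")
    expect_equal(mean(a$normalized_intensity), 1)
    expect_error(binAndNormalize(data.frame(dist_surface = c(7, 12),
                                            mean_mark = c(1, 2)), "mark"),
                 class = "discRim_input_error")
})

test_that("replicate normalization anchors each replicate's controls at 1", {
    d <- data.frame(value = c(2, 4, 6), replicate = "r1",
                    group = c("ctrl", "ctrl", "trt"))
    out <- replicateNormalize(d, "ctrl")
    expect_equal(out$normalized, c(2/3, 4/3, 2), tolerance = 1e-12)
    ## control-only input: per-replicate means exactly 1
    d2 <- data.frame(value = c(1, 3, 10, 30),
                     replicate = rep(c("r1", "r2"), each = 2),
                     group = "ctrl")
    out2 <- replicateNormalize(d2, "ctrl")
    expect_equal(as.numeric(tapply(out2$normalized, out2$replicate, mean)),
                 c(1, 1))
    ## identical true effects agree across replicates with different gains
    d3 <- data.frame(value = c(10, 10, 25, 40, 40, 100),
                     replicate = rep(c("r1", "r2"), each = 3),
                     group = rep(c("ctrl", "ctrl", "trt"), 2))
    out3 <- replicateNormalize(d3, "ctrl")
    expect_equal(out3$normalized[3], out3$normalized[6], tolerance = 1e-12)
    expect_error(replicateNormalize(
        data.frame(value = 1, replicate = "r1", group = "trt"), "ctrl"),
        class = "discRim_input_error")
})

test_that("ratiometric maps: identity, scale invariance, floor masking", {
    sp <- makeSensorPhantom(phantomSpecNoiseFree("sensor", seed = 2))
    tis <- tissueMaskFromMatrix(sp$truth@tissueMask, 0.5)
    a405 <- getPlane(sp$stack, "sensor405")
    ## identical channels -> ratio 1 in validity
    m1 <- ratiometricMap(a405, a405, tis)
    expect_true(all(m1@values[m1@validity] == 1))
    ## scaling both channels leaves the map unchanged
    m0 <- ratiometricMap(getPlane(sp$stack, "sensor488"), a405, tis)
    ms <- ratiometricMap(makePlane(planeValues(getPlane(sp$stack,
                                                        "sensor488")) * 3),
                         makePlane(planeValues(a405) * 3), tis,
                         floor = 3 * 0.05 * max(planeValues(a405)))
    expect_equal(ms@values[ms@validity], m0@values[m0@validity],
                 tolerance = 1e-12)
    ## floor excludes dim pixels
    dim2 <- makePlane(matrix(c(0.1, 100), 2, 2))
    top <- makePlane(matrix(50, 2, 2))
    mm <- ratiometricMap(top, dim2, NULL, floor = 1)
    expect_identical(mm@validity, matrix(c(FALSE, TRUE), 2, 2))
    expect_true(all(is.na(mm@values[!mm@validity])))
})
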