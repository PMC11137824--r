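# Structural observables and the OH-bond-scaling transform.

test_that("RDF of ideal-gas sites in a periodic box is flat at 1", {
    n <- 60L
    top <- waterTopology(n)
    box <- 20
    nf <- 40L
    set.seed(42)
    co <- array(stats::runif(3L * nSites(top) * nf, 0, box),
                c(nSites(top), 3L, nf))
    tr <- newTrajectory(top, co, 1, box = box)
    cen <- matrix(box / 2, nf, 3L)
    rdf <- electronSiteRDF(tr, cen, species = "H", binWidth = 0.5, rMax = 9)
    inner <- rdf[rdf$r > 2 & rdf$r < 9, ]
    expect_true(all(abs(inner$value - 1) <= 3 / sqrt(pmax(inner$counts, 1))))
    expect_error(electronSiteRDF(tr, cen, rMax = 11), "half the box")
})

test_that("a single fixed site lands in its distance bin; cluster mode integrates to the site count", {
    top <- waterTopology(1)
    fr <- rigidWaterFrame()            # H1 at exactly 1.012 from O... use O as centroid
    tr <- newTrajectory(top, fr, 1)
    rdf <- electronSiteRDF(tr, matrix(0, 1, 3), species = "O",
                           binWidth = 0.1, rMax = 5, mode = "cluster-shell")
    expect_equal(sum(rdf$counts), 1)
    expect_equal(rdf$r[rdf$counts == 1], 0.05)   # O sits at the centroid bin
    # integral of n(r) 4 pi r^2 dr over a multi-site cluster = site count
    top6 <- waterTopology(6)
    x6 <- cavityFrame()
    tr6 <- newTrajectory(top6, x6, 1)
    rdfH <- electronSiteRDF(tr6, matrix(0, 1, 3), species = "H",
                            binWidth = 0.05, rMax = 8)
    expect_equal(sum(rdfH$value * 4 * pi * rdfH$r^2 * 0.05), 12,
                 tolerance = 0.01)
})

test_that("OH-distance distribution reports exact delta and thermal widths", {
    top <- waterTopology(2)
    fr <- rbind(rigidWaterFrame(r0 = 1.0, thetaDeg = 109.47),
                rigidWaterFrame(r0 = 1.0, thetaDeg = 109.47,
                                origin = c(4, 0, 0)))
    tr <- newTrajectory(top, fr, 1)
    oh <- ohDistanceDistribution(tr)
    expect_equal(oh$mean, 1.0, tolerance = 1e-12)
    expect_equal(oh$sd, 0, tolerance = 1e-12)
    # classical thermal OH width: equipartition of the harmonic stretch
    ff <- loadForceField()
    top1 <- waterTopology(20)
    x0 <- toyCluster(20, seed = 1)
    cfg <- simulationConfig(top1, nSteps = 1200, temperature = 250,
                            quantum = FALSE, seed = 9)
    eq <- equilibrate(cfg, list(x = x0, v = NULL))
    cfg2 <- simulationConfig(top1, nSteps = 1500, temperature = 250,
                             quantum = FALSE, seed = 10)
    run <- runQCMD(cfg2, list(x = eq$x, v = eq$v))
    Tkin <- mean(run$ledger$temperature)
    oh2 <- ohDistanceDistribution(run$trajectory)
    target <- sqrt(especConstants$kB * Tkin / ff$kr)
    expect_equal(oh2$sd, target, tolerance = 0.15)
    # GSTA broadens the OH distribution (the sign of the nuclear quantum
    # effect on bond-length fluctuations)
    kern <- buildKernel(0.5, 100, 250)
    ohq <- ohDistanceDistribution(filterTrajectory(run$trajectory, kern))
    expect_gt(ohq$sd, oh2$sd)
})

test_that("OH scaling preserves COM, inertia axes and angle, and inverts exactly", {
    top <- waterTopology(2)
    fr <- rbind(rigidWaterFrame(r0 = 1.0, thetaDeg = 109.47),
                rigidWaterFrame(origin = c(3.5, 1, -2)))
    expect_equal(scaleOHBonds(fr, top, 1.0), fr, tolerance = 1e-12)
    sc <- scaleOHBonds(fr, top, 1.1)
    m <- top@siteMasses
    for (i in 1:2) {
        idx <- 3 * i - 2 + 0:2
        a <- fr[idx, ]; b <- sc[idx, ]
        # bonds scaled, angle unchanged
        rb <- function(x) c(sqrt(sum((x[2, ] - x[1, ])^2)),
                            sqrt(sum((x[3, ] - x[1, ])^2)))
        expect_equal(rb(b), 1.1 * rb(a), tolerance = 1e-12)
        ang <- function(x) {
            u <- x[2, ] - x[1, ]; v <- x[3, ] - x[1, ]
            acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2)))
        }
        expect_equal(ang(b), ang(a), tolerance = 1e-10)
        # center of mass fixed
        mm <- m[idx]
        expect_equal(colSums(b * mm) / sum(mm), colSums(a * mm) / sum(mm),
                     tolerance = 1e-10)
        # inertia axes parallel (uniform scaling: tensors proportional)
        inertia <- function(x) {
            com <- colSums(x * mm) / sum(mm)
            r <- sweep(x, 2, com)
            diag(sum(mm * rowSums(r^2)), 3) - t(r * mm) %*% r
        }
        Ia <- inertia(a); Ib <- inertia(b)
        expect_equal(Ib / (1.1^2), Ia, tolerance = 1e-10)
    }
    # exact inverse composition
    back <- scaleOHBonds(sc, top, 1 / 1.1)
    expect_equal(back, fr, tolerance = 1e-9)
    expect_error(scaleOHBonds(fr, top, -1), "positive")
})

test_that("scaling-ladder trends are recovered from injected linear data", {
    mkTab <- function(f, slopeGap, seed) {
        base <- 1.5 + slopeGap * (f - 1) +
                0.02 * espec:::.especGauss(200, seed)
        d <- data.frame(config = rep(1:200, each = 2),
                        k = rep(1:2, 200),
                        deltaE = as.vector(rbind(base, base + 0.3)),
                        f = 1)
        excitationTable(d)
    }
    lad <- lapply(c(0.9, 1.0, 1.1), function(f) list(
        f = f, table = mkTab(f, slopeGap = 2.0, seed = round(100 * f)),
        E0 = -3 + 1.5 * (1 - f) + 0.02 * espec:::.especGauss(200, round(f * 7))))
    rep <- scalingLadder(lad)
    expect_true(rep$e0Decreasing)
    expect_true(rep$gapIncreasing)
    expect_equal(unname(rep$slopeGap1[["slope"]]), 2.0, tolerance = 0.05)
    expect_equal(unname(rep$slopeE0[["slope"]]), -1.5, tolerance = 0.05)
    expect_true(rep$slopeGap1[["lo"]] <= 2.0 && 2.0 <= rep$slopeGap1[["hi"]])
    # equal tables for all f: zero slope, no monotonic trend
    flat <- lapply(c(0.9, 1.0, 1.1), function(f) list(
        f = f, table = mkTab(f, slopeGap = 0, seed = 5),
        E0 = rep(-3, 200)))
    rep0 <- scalingLadder(flat)
    expect_equal(unname(rep0$slopeE0[["slope"]]), 0, tolerance = 1e-10)
    expect_false(rep0$e0Decreasing && rep0$gapIncreasing)
    expect_error(scalingLadder(lad[1]), "at least 2")
})
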