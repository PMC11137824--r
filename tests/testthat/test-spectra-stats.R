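# Spectrum assembly, Gaussian sub-band fitting, moment statistics and the
# classical-vs-quantized comparison machinery.

test_that("single and two-point deposits obey the quadrature identity", {
    tab <- excitationTable(data.frame(config = 1, k = 1, deltaE = 1.72,
                                      f = 0.9))
    sp <- assembleSpectrum(tab)
    expect_equal(sum(sp@total) * sp@binWidth, 0.9, tolerance = 1e-10)
    expect_equal(sp@energy[which.max(sp@total)], 1.72,
                 tolerance = sp@binWidth)
    tab2 <- excitationTable(data.frame(config = 1, k = 1:2,
                                       deltaE = c(1, 2), f = 0.5))
    mom <- spectralMoments(tab2)
    expect_equal(mom$m1, 1.5, tolerance = 1e-12)
    expect_equal(mom$sd, 0.5, tolerance = 1e-12)
    expect_equal(mom$m0, 1.0, tolerance = 1e-12)
    expect_true(mom$degenerate)          # one configuration: no CI
    # single transition: SD = 0
    mom1 <- spectralMoments(tab)
    expect_equal(mom1$sd, 0)
})

test_that("smoothing preserves mass and sub-band additivity exactly", {
    tab <- toyExcitationTable(nConfig = 500, K = 3, gapMean = 1.7,
                              gapSD = 0.25, seed = 2)
    sp <- assembleSpectrum(tab, smooth = 0.010)
    expect_equal(sum(sp@total) * sp@binWidth, sp@meanSumF, tolerance = 1e-10)
    expect_equal(sp@total, rowSums(sp@subbands), tolerance = 1e-12)
    expect_true(all(sp@total >= -1e-12))
    nm <- normalizeSpectrum(sp)
    expect_equal(max(nm@total), 1, tolerance = 1e-12)
})

test_that("Gaussian parameters are recovered from generated gap ensembles", {
    # noise-free self-consistency at 1e-6
    x <- seq(0.5, 3, by = 0.005)
    y <- exp(-(x - 1.72)^2 / (2 * 0.3^2))
    sp <- methods::new("Spectrum", energy = x, total = y,
        subbands = matrix(y, ncol = 1), binWidth = 0.005,
        normalization = "raw", meanSumF = sum(y) * 0.005, tag = "exact")
    fit <- fitSubbands(sp)
    expect_equal(fit$fits$center, 1.72, tolerance = 1e-6)
    expect_equal(fit$fits$sigma, 0.3, tolerance = 1e-6)
    expect_equal(fit$fits$amplitude, 1, tolerance = 1e-6)
    expect_equal(fit$fits$fwhm / fit$fits$sigma, 2.3548, tolerance = 1e-4)
    # seeded Normal(1.72, 0.30^2) ensemble, 2000 configurations
    tab <- toyExcitationTable(nConfig = 2000, K = 1, gapMean = 1.72,
                              gapSD = 0.30, seed = 7)
    spt <- assembleSpectrum(tab, smooth = 0.010)
    ft <- fitSubbands(spt)
    expect_lt(abs(ft$fits$center - 1.72), 0.02)
    # fitted sigma carries the 10 meV smoothing in quadrature
    expect_lt(abs(ft$fits$sigma - sqrt(0.30^2 + 0.010^2)), 0.02)
    # FWHM of fitted total ~ 2.355 x sample SD of the raw gaps
    sdRaw <- stats::sd(excitationData(tab)$deltaE)
    expect_equal(ft$totalFWHM / sdRaw, 2.355, tolerance = 0.03)
})

test_that("a constructed three-Gaussian mixture is fitted with small residual", {
    x <- seq(0.8, 3.2, by = 0.005)
    pars <- list(c(1.0, 1.67, 0.18), c(0.9, 1.91, 0.20), c(0.7, 2.14, 0.22))
    sub <- sapply(pars, function(p) p[1] * exp(-(x - p[2])^2 / (2 * p[3]^2)))
    sp <- methods::new("Spectrum", energy = x, total = rowSums(sub),
        subbands = sub, binWidth = 0.005, normalization = "raw",
        meanSumF = sum(sub) * 0.005, tag = "mixture")
    fit <- fitSubbands(sp)
    expect_equal(fit$fits$center, c(1.67, 1.91, 2.14), tolerance = 1e-6)
    expect_gt(fit$totalMax, 1.67)
    expect_lt(fit$totalMax, 2.14)
    expect_lt(max(fit$fits$residual), 1e-8)
})

test_that("bootstrap CI width matches the CLT prediction on Normal gaps", {
    tab <- toyExcitationTable(nConfig = 2000, K = 1, gapMean = 2.0,
                              gapSD = 0.25, seed = 11)
    mom <- spectralMoments(tab, nBoot = 1000, seed = 3)
    half <- diff(mom$ci$m1) / 2
    clt <- 1.96 * 0.25 / sqrt(2000)
    expect_equal(half, clt, tolerance = 0.2)
    expect_true(mom$ci$m1[1] <= mom$m1 && mom$m1 <= mom$ci$m1[2])
    expect_true(mom$ci$sd[1] <= mom$sd && mom$sd <= mom$ci$sd[2])
    # moments come from raw transitions: insensitive to bin width
    spA <- assembleSpectrum(tab, binWidth = 0.005)
    spB <- assembleSpectrum(tab, binWidth = 0.02)
    mA <- sum(spA@energy * spA@total) / sum(spA@total)
    mB <- sum(spB@energy * spB@total) / sum(spB@total)
    expect_equal(mA, mom$m1, tolerance = 1e-3)
    expect_equal(mB, mom$m1, tolerance = 1e-3)
})

test_that("self-comparison is null; constructed shift/broadening is detected", {
    tab <- toyExcitationTable(nConfig = 500, K = 3, gapMean = 2.0,
                              gapSD = 0.2, seed = 4)
    cmp0 <- compareSpectra(tab, tab)
    expect_equal(cmp0$meanShift, 0, tolerance = 1e-14)
    expect_equal(cmp0$F, 1, tolerance = 1e-12)
    expect_equal(cmp0$tP, 0.5, tolerance = 1e-12)
    # two seeded ensembles mimicking a quantized broadening + small shift
    cl <- toyExcitationTable(nConfig = 2000, K = 3, gapMean = 2.098,
                             gapSD = 0.234 / sqrt(3), seed = 21)
    qu <- toyExcitationTable(nConfig = 2000, K = 3, gapMean = 2.084,
                             gapSD = 0.284 / sqrt(3), seed = 22)
    cmp <- compareSpectra(cl, qu)
    expect_lt(cmp$FP, 0.05)              # broadening detected
    expect_gt(cmp$sdRatio, 1)
    expect_lt(cmp$meanShift, 0)
    # consistency with the direct standard tests on the same samples
    mc <- espec:::.configMeans(cl)
    mq <- espec:::.configMeans(qu)
    tt <- stats::t.test(mq, mc, alternative = "less")
    expect_equal(cmp$tP, tt$p.value, tolerance = 1e-12)
    expect_error(compareSpectra(cl, toyExcitationTable(10, K = 2)),
                 "mismatched K")
})

test_that("p-state splitting <E3-E1> is reported with paired CIs", {
    cl <- toyExcitationTable(nConfig = 400, K = 3, gapMean = 2.0,
                             gapSD = 0.2, offsets = c(0.2, 0.394), seed = 8)
    qu <- toyExcitationTable(nConfig = 400, K = 3, gapMean = 2.0,
                             gapSD = 0.2, offsets = c(0.2, 0.448), seed = 9)
    cmp <- compareSpectra(cl, qu)
    expect_equal(cmp$splitting$classical[["mean"]], 0.394, tolerance = 1e-10)
    expect_equal(cmp$splitting$quantized[["mean"]], 0.448, tolerance = 1e-10)
    expect_equal(cmp$splitting$delta, 0.054, tolerance = 1e-10)
})
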