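# Grid eigensolver oracles: closed-form spectra, dipole matrix elements,
# oscillator-strength sum rule, Hellmann-Feynman vs finite differences.

test_that("potential construction: empty sum, Coulomb limit, mirror symmetry", {
    top1 <- waterTopology(1)
    pp <- loadPseudopotential()
    g <- gridSpec(12, 16)
    expect_equal(buildPotentialGrid(matrix(0, 0, 3), waterTopology(1), g, pp),
                 numeric(16^3) * 0, tolerance = 1e-15)
    # single-site screened Coulomb tends to -q/r beyond the screening length
    q <- 0.41
    A <- pp$elements$H$A
    r <- seq(4, 5.5, by = 0.25)        # r >> 1/A
    v <- espec:::.siteTerm(r, q, pp$elements$H)
    exact <- -especConstants$coulombConstant * q / r
    expect_equal(v, exact, tolerance = 1e-3)
    # finite atop the nucleus
    expect_true(is.finite(espec:::.siteTerm(0, q, pp$elements$H)))
    # mirror-symmetric pair of molecules gives a mirror-symmetric potential
    top2 <- waterTopology(2)
    fr <- rbind(rigidWaterFrame(origin = c(-3, 0, 0)),
                rigidWaterFrame(origin = c(-3, 0, 0)))
    fr[4:6, 1] <- -fr[1:3, 1]          # mirror x of molecule 1
    fr[4:6, 2:3] <- fr[1:3, 2:3]
    v2 <- array(buildPotentialGrid(fr, top2, g, pp), c(16, 16, 16))
    # mirror about the x = 0 plane: axis index i <-> 18 - i (i = 2..16)
    expect_equal(v2[2:16, , ], v2[16:2, , ], tolerance = 1e-12)
})

test_that("free-particle spectrum matches the plane-wave closed form", {
    g <- gridSpec(10, 16)
    st <- solveStates(numeric(16^3), g, K = 3)
    k <- especConstants
    exact <- (2 * pi * k$hbar / 10)^2 / (2 * k$me)
    expect_equal(energies(st)[1], 0, tolerance = 1e-8)
    expect_equal(energies(st)[2:4], rep(exact, 3), tolerance = 1e-8)
})

test_that("harmonic-well states reproduce all HO closed forms", {
    k <- especConstants
    g <- gridSpec(24, 32)
    omega <- 1 / k$hbar                         # hbar*omega = 1 eV
    st <- solveStates(harmonicWell(g, 1), g, K = 3)
    # E0 = 3/2 hbar omega; triply degenerate p states at gap 1 eV
    expect_equal(energies(st)[1], 1.5, tolerance = 1e-3)
    expect_equal(transitionEnergies(st), rep(1, 3), tolerance = 1e-3)
    # orthonormality on the grid
    h3 <- (g@L / g@M)^3
    gram <- crossprod(wavefunctions(st)) * h3
    expect_lt(max(abs(gram - diag(4))), 1e-8)
    # dipole matrix elements: |<p|x|0>|^2 = hbar/(2 m omega) per p state
    mu2 <- rowSums(st@dipoles^2)
    expect_equal(mu2, rep(k$hbar / (2 * k$me * omega), 3), tolerance = 1e-3)
    # oscillator strengths saturate the one-electron sum rule
    expect_equal(sum(oscStrengths(st)), 1, tolerance = 1e-3)
    expect_true(all(oscStrengths(st) >= 0))
    # radius of gyration of the Gaussian ground state
    expect_equal(radiusOfGyration(st), sqrt(3 * k$hbar / (2 * k$me * omega)),
                 tolerance = 1e-3)
    # parity: mu_00 vanishes by gauge, even-state dipoles by selection rule
    cen <- groundStateCentroid(st)
    expect_equal(cen, g@origin, tolerance = 1e-6)
})

test_that("doubling the dipole at fixed gap quadruples f; zero dipole gives zero f", {
    st0 <- methods::new("ElectronStates", energies = c(0, 1), grid = gridSpec(8, 8),
        wfn = matrix(0, 2, 2), deltaE = 1,
        dipoles = matrix(c(0.3, 0, 0), 1, 3), f = 0, residuals = c(0, 0))
    f1 <- oscillatorStrengths(st0)
    st0@dipoles <- 2 * st0@dipoles
    expect_equal(oscillatorStrengths(st0), 4 * f1, tolerance = 1e-12)
    st0@dipoles <- st0@dipoles * 0
    expect_equal(oscillatorStrengths(st0), 0)
})

test_that("Hellmann-Feynman forces match finite-difference energy gradients", {
    top <- waterTopology(2)
    x <- cavityFrame()[1:6, ]
    pp <- loadPseudopotential()
    g <- gridSpec(18.17, 16, origin = colMeans(x))
    e0 <- function(xx) {
        v <- buildPotentialGrid(xx, top, g, pp)
        energies(solveStates(v, g, K = 0, tol = 1e-9))[1]
    }
    v <- buildPotentialGrid(x, top, g, pp)
    st <- solveStates(v, g, K = 0, tol = 1e-9)
    hf <- hellmannFeynmanForces(x, st, top, pp)
    h <- 1e-3
    for (s in c(1L, 5L)) for (d in 1:3) {
        xp <- x; xp[s, d] <- xp[s, d] + h
        xm <- x; xm[s, d] <- xm[s, d] - h
        expect_lt(abs(hf[s, d] + (e0(xp) - e0(xm)) / (2 * h)), 1e-3)
    }
    # zero molecules -> zero forces
    expect_equal(hellmannFeynmanForces(matrix(0, 0, 3), st,
                                       waterTopology(1), pp),
                 matrix(0, 0, 3))
})

test_that("an idealized cavity binds the electron with s-p type transitions", {
    top <- waterTopology(6)
    x <- cavityFrame()
    pp <- loadPseudopotential()
    g <- gridSpec(18.17, 32, origin = c(0, 0, 0))
    v <- buildPotentialGrid(x, top, g, pp)
    st <- solveStates(v, g, K = 3)
    expect_lt(energies(st)[1], -0.2)            # bound ground state
    expect_true(all(transitionEnergies(st) > 0.3))
    expect_true(all(diff(energies(st)) >= -1e-10))
    # near-degenerate p manifold carries most of the intensity
    expect_gt(sum(oscStrengths(st)), 0.3)
    expect_lt(sum(oscStrengths(st)), 1 + 1e-3)
    # residuals honored
    expect_true(all(st@residuals <= 1e-8))
})
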