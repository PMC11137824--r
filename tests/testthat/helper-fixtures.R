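# Shared fixtures, all generated in code.

# a single rigid water at the force-field equilibrium geometry
rigidWaterFrame <- function(r0 = 1.012, thetaDeg = 113.24, origin = c(0, 0, 0)) {
    th <- thetaDeg * pi / 180
    rbind(origin,
          origin + r0 * c(1, 0, 0),
          origin + r0 * c(cos(th), sin(th), 0))
}

# idealized octahedral cavity: n=6 waters at radius R, one OH of each
# pointing at the center -- a clean electron-binding geometry
cavityFrame <- function(R = 3.0, r0 = 1.012, thetaDeg = 113.24) {
    th <- thetaDeg * pi / 180
    dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                  c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
    x <- matrix(0, 18, 3)
    for (i in 1:6) {
        u <- -dirs[i, ]
        p <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
        p <- p - sum(p * u) * u
        p <- p / sqrt(sum(p^2))
        O <- dirs[i, ] * R
        x[3 * i - 2, ] <- O
        x[3 * i - 1, ] <- O + r0 * u
        x[3 * i, ] <- O + r0 * (cos(th) * u + sin(th) * p)
    }
    x
}

# harmonic-well potential grid with hbar*omega = gapEV on grid g
harmonicWell <- function(g, gapEV = 1) {
    k <- especConstants
    omega <- gapEV / k$hbar
    pts <- gridPoints(g)
    0.5 * k$me * omega^2 * rowSums(sweep(pts, 2, g@origin)^2)
}
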