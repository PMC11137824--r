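# Seed-deterministic generators of inputs with known statistical
# structure.  These validate mechanics and plumbing at desk scale; they
# make no attempt to mimic bulk water structure or full-scale numerics.

#' Harmonic-mode time series
#'
#' Deterministic mode emits A cos(2 pi nu t); thermal mode draws
#' amplitude and phase per replica from the classical Boltzmann
#' distribution of a harmonic oscillator at temperature T (mode energy
#' exponential with mean kB T, uniform phase).  Energies are sampled by
#' stratified inversion by default, which pins ensemble averages at
#' their population values to O(1/n^2) while keeping the marginal
#' distribution Boltzmann -- the point of the generator is to serve as a
#' numerically tight oracle ensemble.
#'
#' @param nu mode frequency, fs^-1 (see \code{wavenumberToFrequency}).
#' @param mass oscillator mass in atomic mass units.
#' @param duration length of each series, fs.
#' @param dt sampling interval, fs (must satisfy dt < 1/(2 nu)).
#' @param mode "cosine" or "thermal".
#' @param amplitude cosine amplitude, A.
#' @param temperature K (thermal mode).
#' @param nReplicas number of thermal replicas.
#' @param seed integer seed.
#' @param stratified use stratified energy sampling (thermal mode).
#' @return list with \code{times} (fs), \code{x} (time x replica matrix,
#'   A), \code{v} (same shape, A/fs), and the spec fields.
#' @export
harmonicTrajectory <- function(nu, mass = 1.008, duration = 2000, dt = 0.5,
                               mode = c("cosine", "thermal"),
                               amplitude = 0.1, temperature = 300,
                               nReplicas = 1L, seed = 1L,
                               stratified = TRUE) {
    mode <- match.arg(mode)
    if (dt >= 1 / (2 * nu)) stop("dt violates the Nyquist limit for nu")
    t <- seq(0, duration, by = dt)
    omega <- 2 * pi * nu
    m <- mass * especConstants$amu
    if (mode == "cosine") {
        x <- matrix(amplitude * cos(omega * t), ncol = 1L)
        v <- matrix(-amplitude * omega * sin(omega * t), ncol = 1L)
    } else {
        kT <- especConstants$kB * temperature
        u <- if (stratified) {
            p <- (seq_len(nReplicas) - 0.5) / nReplicas
            p[order(.especRand(nReplicas, seed + 11L))]   # seeded shuffle
        } else .especRand(nReplicas, seed + 11L) + 0.5
        En <- -kT * log(1 - u)                 # exponential energies
        A <- sqrt(2 * En / (m * omega^2))
        phi <- 2 * pi * (.especRand(nReplicas, seed + 23L) + 0.5)
        x <- outer(t, seq_len(nReplicas),
                   function(tt, i) A[i] * cos(omega * tt + phi[i]))
        v <- outer(t, seq_len(nReplicas),
                   function(tt, i) -A[i] * omega * sin(omega * tt + phi[i]))
    }
    list(times = t, x = x, v = v, nu = nu, mass = mass, dt = dt,
         temperature = if (mode == "thermal") temperature else NULL,
         mode = mode)
}

#' Filter plain time series with a quantization kernel
#'
#' Applies the moving-window convolution of \code{filterTrajectory} to
#' bare series (columns of a matrix), dropping the half-window margins.
#' Used with \code{harmonicTrajectory} ensembles in the filter oracles.
#'
#' @param x numeric vector or time x series matrix.
#' @param kernel a \code{FilterKernel}.
#' @return filtered matrix, \code{length(kernel@g) - 1} rows shorter.
#' @export
filterSeries <- function(x, kernel) {
    x <- as.matrix(x)
    n <- length(kernel@g)
    m <- (n - 1L) / 2L
    if (nrow(x) < n) stop("series shorter than the filter window")
    y <- stats::filter(x, kernel@g, method = "convolution", sides = 2L)
    matrix(y[(m + 1L):(nrow(x) - m), ], ncol = ncol(x))
}

#' Relaxed toy water cluster
#'
#' Places n waters on a jittered sphere with random orientations and
#' relaxes them on the classical force field by damped steepest descent
#' until the largest site force falls below \code{fTol}.  Deterministic
#' for a given seed.  A mechanics/plumbing fixture -- not a thermally
#' equilibrated structure.
#'
#' @param n number of molecules (>= 2).
#' @param seed integer seed.
#' @param ffParams force-field parameters.
#' @param fTol force convergence threshold, eV/A.
#' @param maxIter steepest-descent iteration cap.
#' @param orient "random", or "inward" to point one OH bond of every
#'   water at the cluster center -- a cavity-like seed for excess-electron
#'   binding (the anion analog of a dangling-OH coordination shell).
#' @return nsites x 3 coordinate matrix, A.
#' @export
toyCluster <- function(n, seed = 1L, ffParams = loadForceField(),
                       fTol = 0.05, maxIter = 5000L,
                       orient = c("random", "inward")) {
    orient <- match.arg(orient)
    stopifnot(n >= 2L)
    top <- waterTopology(n)
    shellR <- max(2.2, 1.93 * n^(1 / 3))
    # rejection-place O atoms with O-O > 2.6 A
    Opos <- matrix(0, n, 3L)
    ctr <- 0L
    for (i in seq_len(n)) {
        repeat {
            ctr <- ctr + 1L
            u <- .especRand(3L, seed * 1000L + ctr * 7L)
            p <- u / sqrt(sum(u^2) + 1e-12) *
                 shellR * (0.8 + 0.4 * (.especRand(1L, seed * 991L + ctr) + 0.5))
            if (i == 1L || min(sqrt(rowSums(sweep(Opos[seq_len(i - 1L), ,
                drop = FALSE], 2L, p)^2))) > 2.6) {
                Opos[i, ] <- p
                break
            }
            if (ctr > 10000L) stop("could not place cluster oxygens")
        }
    }
    x <- matrix(0, 3L * n, 3L)
    r0 <- ffParams$r0
    th <- ffParams$theta0
    for (i in seq_len(n)) {
        # molecular orientation from hashed unit vectors; "inward" points
        # the first OH at the cluster center
        a <- if (orient == "inward") -Opos[i, ] / sqrt(sum(Opos[i, ]^2))
             else .especGauss(3L, seed * 77L + i)
        a <- a / sqrt(sum(a^2))
        b <- .especGauss(3L, seed * 177L + i)
        b <- b - sum(a * b) * a
        b <- b / sqrt(sum(b^2))
        h1 <- a
        h2 <- cos(th) * a + sin(th) * b
        O <- Opos[i, ]
        x[3L * i - 2L, ] <- O
        x[3L * i - 1L, ] <- O + r0 * h1
        x[3L * i, ] <- O + r0 * h2
    }
    # damped steepest descent; inward seeds are only de-clashed (a full
    # classical relaxation would rotate the dangling OH bonds away from
    # the cavity -- the electron is what stabilizes them)
    if (orient == "inward") maxIter <- min(maxIter, 300L)
    alpha <- 0.002
    fe <- classicalForces(x, top, ffParams)
    for (it in seq_len(maxIter)) {
        fmax <- sqrt(max(rowSums(fe$forces^2)))
        if (fmax < fTol) break
        step <- alpha * fe$forces
        cap <- 0.1 / max(sqrt(rowSums(step^2)))   # max displacement 0.1 A
        if (cap < 1) step <- step * cap
        xn <- x + step
        fen <- tryCatch(classicalForces(xn, top, ffParams),
                        error = function(e) NULL)
        if (is.null(fen) || fen$energy > fe$energy + 1e-12) {
            alpha <- alpha / 2
            if (alpha < 1e-8) break
        } else {
            x <- xn
            fe <- fen
            alpha <- min(alpha * 1.1, 0.02)
        }
    }
    if (orient == "random" && sqrt(max(rowSums(fe$forces^2))) >= fTol)
        warning("cluster relaxation stopped above the force tolerance")
    x
}

#' Seeded toy excitation table
#'
#' Per-configuration transition energies: gap 1 is Normal(gapMean,
#' gapSD^2), higher transitions add the fixed \code{offsets}, so the
#' per-configuration ordering in k is preserved by construction.
#' Oscillator strengths follow \code{fRule} (constant by default).
#'
#' @param nConfig number of configurations.
#' @param K transitions per configuration.
#' @param gapMean mean of the first gap, eV.
#' @param gapSD SD of the gaps, eV.
#' @param offsets nonnegative increments added for k = 2..K (length
#'   K-1; default 0.22 eV spacing).
#' @param fRule function(k) giving oscillator strengths, or a constant.
#' @param seed integer seed.
#' @param tag provenance tag.
#' @return an \code{ExcitationTable}.
#' @export
toyExcitationTable <- function(nConfig, K = 3L, gapMean = 1.72,
                               gapSD = 0.3, offsets = NULL, fRule = 1,
                               seed = 1L, tag = "synthetic") {
    K <- as.integer(K)
    if (is.null(offsets)) offsets <- if (K > 1L) 0.22 * seq_len(K - 1L) else numeric(0)
    stopifnot(length(offsets) == K - 1L, all(offsets >= 0), gapSD >= 0)
    base <- gapMean + gapSD * .especGauss(nConfig, seed)
    base <- pmax(base, 1e-3)
    fk <- if (is.function(fRule)) vapply(seq_len(K), fRule, numeric(1))
          else rep(fRule, K)
    d <- data.frame(
        config = rep(seq_len(nConfig), each = K),
        k = rep(seq_len(K), nConfig),
        deltaE = as.vector(vapply(base, function(b) b + c(0, offsets),
                                  numeric(K))),
        f = rep(fk, nConfig))
    excitationTable(d, tag = tag)
}
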