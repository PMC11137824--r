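# Generalized smoothed trajectory analysis (GSTA): classical coordinates
# are convolved with a symmetric kernel whose frequency-domain gain is the
# square root of the quantum/classical harmonic-oscillator energy ratio
# w(nu).  Amplitudes then scale by sqrt(w), so quadratic observables (mode
# energies, variances) scale by w, which is the harmonic-oscillator
# quantum correction.

#' Quantum/classical harmonic-oscillator energy ratio w(nu)
#'
#' \code{w(nu) = (h nu / 2 kB T) * coth(h nu / 2 kB T)}: the ratio of the
#' mean energy of a quantum harmonic oscillator (including zero-point
#' energy) to the classical equipartition energy kB T at temperature T.
#' \code{w -> 1} as \code{nu -> 0} (the classical limit) and
#' \code{w -> h nu / 2 kB T} for \code{h nu >> kB T}.
#'
#' @param nu frequency, fs^-1 (vectorized, must be >= 0).
#' @param temperature T in K (> 0).
#' @return numeric vector, \code{w >= 1}.
#' @examples
#' gstaWeight(0, 300)                                  # 1: classical limit
#' gstaWeight(wavenumberToFrequency(3700), 300)        # OH stretch, ~8.9
#' @export
gstaWeight <- function(nu, temperature) {
    if (temperature <= 0) stop("temperature must be positive")
    if (any(nu < 0)) stop("frequencies must be nonnegative")
    u <- especConstants$h * nu / (2 * especConstants$kB * temperature)
    w <- rep(1, length(u))
    big <- u > 1e-8
    # u*coth(u); for u > ~20, coth(u) = 1 to double precision
    w[big] <- ifelse(u[big] > 20, u[big], u[big] / tanh(u[big]))
    w
}

#' Build the discrete quantization filter kernel
#'
#' Samples \code{sqrt(w(nu))} at the FFT frequencies of a moving window
#' of length \code{window} fs, inverse-transforms, centers and
#' renormalizes to unit sum.  The kernel length is forced odd
#' (\code{2*floor(W/(2 dt)) + 1} taps) so it is exactly symmetric about
#' its center; by construction its discrete transfer gain at each window
#' FFT frequency equals \code{sqrt(w(nu))}.
#'
#' @param dt trajectory sampling interval, fs.
#' @param window window length W, fs (100-200 fs is the standard range;
#'   default 150).
#' @param temperature T in K.
#' @return a \code{FilterKernel}.
#' @examples
#' k <- buildKernel(0.5, 150, 300)
#' sum(k@g)   # 1: unit DC gain
#' @export
buildKernel <- function(dt, window = 150, temperature = 300) {
    if (dt <= 0) stop("dt must be positive")
    m <- floor(window / (2 * dt))
    n <- 2L * m + 1L
    if (n < 9L)
        stop("window too short: need at least 8 samples to represent sqrt(w)")
    j <- 0:(n - 1L)
    nu <- pmin(j, n - j) / (n * dt)       # |frequency| of each FFT bin, fs^-1
    gain <- sqrt(gstaWeight(nu, temperature))
    g <- Re(stats::fft(gain, inverse = TRUE)) / n
    g <- g[c((m + 2L):n, 1L:(m + 1L))]    # center the zero-lag tap
    g <- g / sum(g)
    methods::new("FilterKernel", dt = dt, window = window,
                 temperature = temperature, g = g)
}

#' Transfer gain of a kernel at given frequencies
#'
#' Evaluates the discrete-time Fourier transform of the symmetric kernel,
#' \code{G(nu) = g0 + 2 sum_s g_s cos(2 pi nu s dt)}.  At the window's
#' FFT frequencies this equals \code{sqrt(w(nu))} exactly.
#'
#' @param kernel a \code{FilterKernel}.
#' @param nu frequencies, fs^-1.
#' @return numeric gains.
#' @export
kernelGain <- function(kernel, nu) {
    m <- (length(kernel@g) - 1L) / 2L
    gs <- kernel@g[(m + 1L):(2L * m + 1L)]   # center tap then positive lags
    vapply(nu, function(f)
        gs[1] + 2 * sum(gs[-1] * cos(2 * pi * f * kernel@dt * seq_len(m))),
        numeric(1))
}

#' Quantize a trajectory by moving-window convolution
#'
#' Convolves every Cartesian coordinate (and velocity, when present)
#' independently with the kernel.  The first and last W/2 of the
#' trajectory are dropped rather than padded: padding would fabricate
#' dynamics at the ends.  Filtering must act on the dense trajectory
#' (sampling below the Nyquist limit of the OH stretch, dt <= 4 fs)
#' before any frame striding.
#'
#' @param traj a \code{Trajectory} with uniform spacing equal to
#'   \code{kernel@dt}.
#' @param kernel a \code{FilterKernel}.
#' @return a \code{Trajectory} tagged "quantized", shorter than the input
#'   by \code{length(kernel@g) - 1} frames.
#' @export
filterTrajectory <- function(traj, kernel) {
    if (abs(traj@dtStore - kernel@dt) > 1e-9 * kernel@dt)
        stop("trajectory spacing does not match kernel dt")
    n <- length(kernel@g)
    m <- (n - 1L) / 2L
    nf <- nFrames(traj)
    if (nf < n) stop("trajectory shorter than the filter window")
    ns <- nSites(traj)
    keep <- (m + 1L):(nf - m)
    filt <- function(a) {
        # frames x (3 ns) matrix; stats::filter convolves each column
        x <- matrix(aperm(a, c(3L, 1L, 2L)), nrow = nf)
        y <- stats::filter(x, kernel@g, method = "convolution", sides = 2L)
        y <- matrix(y[keep, , drop = FALSE], nrow = length(keep))
        aperm(array(y, c(length(keep), ns, 3L)), c(2L, 3L, 1L))
    }
    co <- filt(traj@coords)
    ve <- if (length(traj@velocities)) filt(traj@velocities) else NULL
    newTrajectory(traj@topology, co, traj@dtStore, velocities = ve,
                  box = if (length(traj@box)) traj@box else NULL,
                  tag = "quantized", t0 = traj@times[keep[1]])
}
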