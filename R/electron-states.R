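#' Solve the one-electron grid Hamiltonian
#'
#' Computes the lowest K+1 eigenpairs of T + V on the cubic grid (kinetic
#' operator applied spectrally via FFT), normalizes the wavefunctions on
#' the grid, and derives transition energies, transition dipoles and
#' oscillator strengths for the K transitions from the ground state.
#'
#' @param vpot potential on the grid, eV (length M^3).
#' @param grid a \code{GridSpec}.
#' @param K number of excited states (transitions) wanted.
#' @param tol eigensolver residual tolerance.
#' @param start optional warm-start matrix of trial vectors (columns).
#' @param seed deterministic-start seed.
#' @param blockSize Lanczos expansion block width; keep >= 4 near
#'   degeneracies (cold starts), 1 suffices for warm-started
#'   ground-state-only solves.
#' @param ... further arguments to the block Lanczos driver.
#' @return an \code{ElectronStates}.
#' @examples
#' g <- gridSpec(24, 16)
#' pts <- gridPoints(g)
#' k <- especConstants
#' omega <- 1 / k$hbar                      # hbar*omega = 1 eV
#' v <- 0.5 * k$me * omega^2 * rowSums(pts^2)
#' st <- solveStates(v, g, K = 3)
#' transitionEnergies(st)                   # ~1 eV, triply degenerate
#' @export
solveStates <- function(vpot, grid, K, tol = 1e-8, start = NULL,
                        seed = 1L, blockSize = max(4L, K + 1L), ...) {
    if (!all(is.finite(vpot))) stop("potential must be finite")
    eig <- lowestEigenpairs(vpot, grid, nev = K + 1L, tol = tol,
                            start = start, seed = seed,
                            blockSize = blockSize, ...)
    if (!eig$converged)
        stop("eigensolver did not converge: residuals ",
             paste(sprintf("%.2e", eig$residuals), collapse = " "))
    h3 <- (grid@L / grid@M)^3
    wfn <- eig$vectors / sqrt(h3)          # L2-normalized on the grid
    st <- methods::new("ElectronStates",
        energies = eig$values, wfn = wfn, grid = grid,
        deltaE = if (K > 0) eig$values[-1] - eig$values[1] else numeric(0),
        dipoles = matrix(0, max(K, 0L), 3L), f = numeric(max(K, 0L)),
        residuals = eig$residuals)
    if (K > 0) {
        st@dipoles <- transitionDipoles(st)
        st@f <- oscillatorStrengths(st)
    }
    st
}

#' Transition dipoles from the ground state
#'
#' \code{mu_k0 = e <psi_k| r |psi_0>} with r measured from the
#' ground-state centroid (gauge choice: transition dipoles between
#' orthogonal states are origin-independent, but fixing the gauge makes
#' diagnostics like \code{mu_00 = 0} reproducible).
#'
#' @param states an \code{ElectronStates}.
#' @return K x 3 matrix, e A.
#' @export
transitionDipoles <- function(states) {
    grid <- states@grid
    h3 <- (grid@L / grid@M)^3
    pts <- gridPoints(grid)
    psi0 <- states@wfn[, 1]
    cen <- groundStateCentroid(states)
    K <- ncol(states@wfn) - 1L
    mu <- matrix(0, K, 3L)
    for (k in seq_len(K)) {
        ov <- states@wfn[, k + 1L] * psi0 * h3
        mu[k, ] <- c(sum(ov * (pts[, 1] - cen[1])),
                     sum(ov * (pts[, 2] - cen[2])),
                     sum(ov * (pts[, 3] - cen[3])))
    }
    mu
}

#' Ground-state electron centroid
#'
#' @param states an \code{ElectronStates}.
#' @return length-3 position of the ground-state density centroid, A.
#' @export
groundStateCentroid <- function(states) {
    grid <- states@grid
    h3 <- (grid@L / grid@M)^3
    rho <- states@wfn[, 1]^2 * h3
    pts <- gridPoints(grid)
    c(sum(rho * pts[, 1]), sum(rho * pts[, 2]), sum(rho * pts[, 3]))
}

#' Oscillator strengths
#'
#' \code{f_k = 2 m_e dE_k |mu_k0|^2 / (3 hbar^2)}, dimensionless.  For a
#' complete one-electron spectrum these satisfy the Thomas-Reiche-Kuhn
#' sum rule \code{sum f = 1}; a truncated basis gives \code{sum f <= 1}.
#'
#' @param states an \code{ElectronStates}.
#' @return numeric vector of length K.
#' @export
oscillatorStrengths <- function(states) {
    k <- especConstants
    mu2 <- rowSums(states@dipoles^2)
    if (all(mu2 == 0) && ncol(states@wfn) > 1L)
        mu2 <- rowSums(transitionDipoles(states)^2)
    2 * k$me * states@deltaE * mu2 / (3 * k$hbar^2)
}

#' Radius of gyration of the ground-state distribution
#'
#' \code{r_g = sqrt(<psi_0|(r - <r>)^2|psi_0>)}: the effective size of
#' the excess electron.
#'
#' @param states an \code{ElectronStates}.
#' @return r_g in A.
#' @export
radiusOfGyration <- function(states) {
    grid <- states@grid
    h3 <- (grid@L / grid@M)^3
    rho <- states@wfn[, 1]^2 * h3
    pts <- gridPoints(grid)
    cen <- groundStateCentroid(states)
    sqrt(sum(rho * ((pts[, 1] - cen[1])^2 + (pts[, 2] - cen[2])^2 +
                    (pts[, 3] - cen[3])^2)))
}
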