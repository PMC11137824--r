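# Grid Hamiltonian machinery: the kinetic operator is applied spectrally
# via FFT on the periodic cubic grid; the lowest eigenpairs come from a
# block Lanczos / Rayleigh-Ritz iteration with full reorthogonalization
# and thick restarts.  Block size >= 4 resolves the near-degenerate
# p-manifold of cavity-bound electrons.

# Deterministic start vectors from a vectorized hash, independent of R's
# global RNG, so eigensolves are bit-stable and never perturb user random
# streams.
.especRand <- function(n, seed) {
    i <- seq_len(n)
    x <- sin(i * 12.9898 + (seed %% 65536) * 78.233) * 43758.5453
    (x - floor(x)) - 0.5
}

# Precompute hbar^2 k^2 / (2 m_e) on the FFT frequency grid (eV).
.kineticFactor <- function(grid) {
    M <- grid@M
    kv <- 2 * pi / grid@L * c(0:(M / 2), seq.int(-M / 2 + 1L, -1L))
    k2 <- outer(outer(kv^2, kv^2, `+`), kv^2, `+`)
    especConstants$hbar^2 / (2 * especConstants$me) * k2
}

# Apply T + V to the columns of psi (M^3 x b).
.applyHamiltonian <- function(psi, vpot, kfac, M) {
    out <- psi * vpot
    for (j in seq_len(ncol(psi))) {
        ft <- stats::fft(array(psi[, j], c(M, M, M)))
        out[, j] <- out[, j] +
            Re(stats::fft(kfac * ft, inverse = TRUE)) / length(ft)
    }
    out
}

# Kinetic-energy preconditioner (Davidson-style): residuals are damped in
# Fourier space by 1/(T_k + tau), which equalizes convergence across the
# wide kinetic spectrum of the grid.
.applyKineticPrec <- function(psi, kfac, M, tau) {
    pre <- 1 / (kfac + tau)
    for (j in seq_len(ncol(psi))) {
        ft <- stats::fft(array(psi[, j], c(M, M, M)))
        psi[, j] <- Re(stats::fft(pre * ft, inverse = TRUE)) / length(ft)
    }
    psi
}

# Orthonormalize the columns of X against basis V (twice, for stability),
# then among themselves; drops columns that become numerically null.
.orthogonalize <- function(X, V = NULL) {
    for (rep in 1:2) {
        if (!is.null(V) && ncol(V) > 0L)
            X <- X - V %*% crossprod(V, X)
    }
    keep <- integer(0)
    for (j in seq_len(ncol(X))) {
        x <- X[, j]
        if (length(keep))
            x <- x - X[, keep, drop = FALSE] %*% crossprod(X[, keep, drop = FALSE], x)
        nrm <- sqrt(sum(x^2))
        if (nrm > 1e-10) {
            X[, j] <- x / nrm
            keep <- c(keep, j)
        }
    }
    X[, keep, drop = FALSE]
}

#' Lowest eigenpairs of the grid Hamiltonian
#'
#' Thick-restart block Lanczos for the operator T + V.  Start vectors are
#' deterministic (seeded) unless a warm-start block is supplied, in which
#' case convergence typically takes a handful of iterations -- this is
#' what makes per-step eigensolves affordable during dynamics.
#'
#' @param vpot potential on the grid, eV (length M^3 vector).
#' @param grid a \code{GridSpec}.
#' @param nev number of eigenpairs wanted (K+1 states).
#' @param tol residual tolerance, \code{||H psi - E psi|| <= tol} in the
#'   unit-norm vector sense.
#' @param blockSize expansion block width (>= 4 recommended near
#'   degeneracies; default \code{max(4, nev)}).
#' @param maxBasis basis size triggering a thick restart.
#' @param maxMatvec cap on Hamiltonian applications.
#' @param start optional warm-start matrix (M^3 x any) of trial vectors.
#' @param seed integer seed for the deterministic start vectors.
#' @return list with \code{values} (eV), \code{vectors} (unit-norm
#'   columns), \code{residuals}, \code{matvecs}.
#' @keywords internal
lowestEigenpairs <- function(vpot, grid, nev, tol = 1e-8,
                             blockSize = max(4L, nev), maxBasis = NULL,
                             maxMatvec = 3000L, start = NULL, seed = 1L) {
    M <- grid@M
    n <- M^3
    kfac <- .kineticFactor(grid)
    if (nev + 1L >= n) stop("nev too large for grid")
    b <- as.integer(blockSize)
    if (is.null(maxBasis)) maxBasis <- max(4L * nev + 2L * b, 10L * b)
    maxBasis <- min(maxBasis, n - 1L)

    X <- matrix(.especRand(n * b, seed), n, b)
    if (!is.null(start)) {
        start <- as.matrix(start)
        nc <- min(ncol(start), b)
        X[, seq_len(nc)] <- start[, seq_len(nc)]
    }
    V <- .orthogonalize(X)
    HV <- .applyHamiltonian(V, vpot, kfac, M)
    matvecs <- ncol(V)

    repeat {
        Hp <- crossprod(V, HV)
        Hp <- (Hp + t(Hp)) / 2
        es <- eigen(Hp, symmetric = TRUE)
        ord <- order(es$values)
        theta <- es$values[ord]
        Y <- es$vectors[, ord, drop = FALSE]
        nv <- min(nev, ncol(V))
        Ry <- HV %*% Y[, seq_len(nv), drop = FALSE] -
              V %*% Y[, seq_len(nv), drop = FALSE] %*%
              diag(theta[seq_len(nv)], nv)
        res <- sqrt(colSums(Ry^2))
        if ((ncol(V) >= nev && all(res <= tol)) || matvecs >= maxMatvec) {
            vec <- V %*% Y[, seq_len(nv), drop = FALSE]
            return(list(values = theta[seq_len(nv)], vectors = vec,
                        residuals = res, matvecs = matvecs,
                        converged = all(res <= tol)))
        }
        if (ncol(V) + b > maxBasis) {
            keep <- min(2L * nev + b, ncol(V))
            V <- V %*% Y[, seq_len(keep), drop = FALSE]
            HV <- HV %*% Y[, seq_len(keep), drop = FALSE]
        }
        # expand with preconditioned residual directions of the
        # unconverged states
        tau <- max(1, theta[nv] - theta[1])
        Xnew <- .applyKineticPrec(Ry[, res > tol, drop = FALSE], kfac, M, tau)
        if (ncol(Xnew) < b) {
            pad <- matrix(.especRand(n * (b - ncol(Xnew)), seed + matvecs), n,
                          b - ncol(Xnew))
            Xnew <- cbind(Xnew, pad)
        }
        Xnew <- .orthogonalize(Xnew[, seq_len(b), drop = FALSE], V)
        if (!ncol(Xnew)) {
            Xnew <- .orthogonalize(
                matrix(.especRand(n * b, seed + 7L * matvecs), n, b), V)
        }
        V <- cbind(V, Xnew)
        HV <- cbind(HV, .applyHamiltonian(Xnew, vpot, kfac, M))
        matvecs <- matvecs + ncol(Xnew)
    }
}
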