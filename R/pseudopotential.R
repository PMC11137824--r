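# Electron-water pseudopotential: per-site screened-Coulomb terms whose
# long-range limit matches the water model's partial charges, plus
# short-range Gaussian repulsion/screening.  Everything is smooth and
# finite, including atop nuclei, so Hellmann-Feynman gradients exist
# everywhere.

.erf <- function(x) 2 * stats::pnorm(sqrt(2) * x) - 1

#' Load pseudopotential parameters
#'
#' Reads a YAML parameter file describing, per element, the erf screening
#' constant \code{A} (1/A) of the Coulomb term and Gaussian terms with
#' amplitudes \code{B} (eV) and exponents \code{C} (1/A^2).  The site
#' term is
#' \deqn{V_s(r) = -k_c q_s \, \mathrm{erf}(A_s r)/r + \sum_i B_i e^{-C_i r^2}}
#' with \code{k_c} the Coulomb constant; beyond the screening length this
#' tends to the bare Coulomb interaction of the site charge with the
#' (negative) electron.
#'
#' @param path YAML file; default is the parameter set shipped with the
#'   package.
#' @return list with per-element parameter lists.
#' @export
loadPseudopotential <- function(path = system.file("extdata",
        "pseudopotential_tb_style_synthetic.yaml", package = "espec")) {
    p <- yaml::read_yaml(path)
    for (el in c("O", "H"))
        if (is.null(p$elements[[el]]))
            stop("pseudopotential parameter file missing element ", el)
    p
}

# Site-term value (eV) and radial derivative (eV/A) at distances r for one
# element; q is the site charge in units of e.  The electron carries
# charge -e, so V_coul = -kc * q * erf(A r)/r.
.siteTerm <- function(r, q, par, deriv = FALSE) {
    kc <- especConstants$coulombConstant
    A <- par$A
    small <- r < 1e-6
    rs <- ifelse(small, 1e-6, r)
    if (!deriv) {
        v <- -kc * q * .erf(A * rs) / rs
        v[small] <- -kc * q * 2 * A / sqrt(pi)
        for (g in par$gauss) v <- v + g$B * exp(-g$C * r^2)
        v
    } else {
        d <- -kc * q * (2 * A / sqrt(pi) * exp(-(A * rs)^2) / rs -
                        .erf(A * rs) / rs^2)
        d[small] <- 0
        for (g in par$gauss) d <- d - 2 * g$C * g$B * r * exp(-g$C * r^2)
        d
    }
}

# Minimum-image displacement components for a cubic box (vectorized).
.minImage <- function(d, box) d - box * round(d / box)

# M^3 x nsites distance matrix from grid points to sites.
.gridSiteDistances <- function(pts, sites, box = NULL) {
    n <- nrow(sites)
    out <- matrix(0, nrow(pts), n)
    for (s in seq_len(n)) {
        d1 <- pts[, 1] - sites[s, 1]
        d2 <- pts[, 2] - sites[s, 2]
        d3 <- pts[, 3] - sites[s, 3]
        if (!is.null(box)) {
            d1 <- .minImage(d1, box); d2 <- .minImage(d2, box)
            d3 <- .minImage(d3, box)
        }
        out[, s] <- sqrt(d1 * d1 + d2 * d2 + d3 * d3)
    }
    out
}

# Shared grid-site displacement field for one frame: component and
# radial distances, computed once per step and reused by the potential
# build and the Hellmann-Feynman quadrature.
.gridSiteField <- function(pts, sites, box = NULL) {
    n <- nrow(sites)
    d1 <- matrix(0, nrow(pts), n); d2 <- d1; d3 <- d1; r <- d1
    for (s in seq_len(n)) {
        a <- pts[, 1] - sites[s, 1]
        b <- pts[, 2] - sites[s, 2]
        c0 <- pts[, 3] - sites[s, 3]
        if (!is.null(box)) {
            a <- .minImage(a, box); b <- .minImage(b, box)
            c0 <- .minImage(c0, box)
        }
        d1[, s] <- a; d2[, s] <- b; d3[, s] <- c0
        r[, s] <- sqrt(a * a + b * b + c0 * c0)
    }
    list(d1 = d1, d2 = d2, d3 = d3, r = r)
}

.potentialFromField <- function(fld, topology, params) {
    v <- numeric(nrow(fld$r))
    el <- topology@siteElements
    q <- topology@siteCharges
    for (s in seq_len(ncol(fld$r)))
        v <- v + .siteTerm(fld$r[, s], q[s], params$elements[[el[s]]])
    if (!all(is.finite(v))) stop("non-finite potential value")
    v
}

.hfFromField <- function(fld, states, topology, params) {
    grid <- states@grid
    h3 <- (grid@L / grid@M)^3
    rho <- states@wfn[, 1]^2 * h3
    el <- topology@siteElements
    q <- topology@siteCharges
    ns <- ncol(fld$r)
    F <- matrix(0, ns, 3L)
    for (s in seq_len(ns)) {
        r <- fld$r[, s]
        dv <- .siteTerm(r, q[s], params$elements[[el[s]]], deriv = TRUE)
        wt <- rho * dv / ifelse(r < 1e-8, 1, r)
        F[s, ] <- c(sum(wt * fld$d1[, s]), sum(wt * fld$d2[, s]),
                    sum(wt * fld$d3[, s]))
    }
    if (!all(is.finite(F))) stop("non-finite Hellmann-Feynman force")
    F
}

#' Build the electron-water potential on a grid
#'
#' Sums the parameterized site terms of all water sites at every grid
#' point.  Minimum-image convention is applied when a box edge is given.
#'
#' @param frame nsites x 3 coordinate matrix, A.
#' @param topology the \code{WaterTopology} (supplies site charges).
#' @param grid a \code{GridSpec}.
#' @param params parameter list from \code{loadPseudopotential}.
#' @param box optional cubic box edge, A.
#' @return numeric vector of length M^3, eV (x index fastest).
#' @export
buildPotentialGrid <- function(frame, topology, grid, params, box = NULL) {
    pts <- gridPoints(grid)
    v <- numeric(nrow(pts))
    if (nMolecules(topology) == 0L || nrow(frame) == 0L) return(v)
    r <- .gridSiteDistances(pts, frame, box)
    if (!all(is.finite(r))) stop("non-finite grid-site distance")
    el <- topology@siteElements
    q <- topology@siteCharges
    for (s in seq_len(ncol(r)))
        v <- v + .siteTerm(r[, s], q[s], params$elements[[el[s]]])
    if (!all(is.finite(v))) stop("non-finite potential value")
    v
}

#' Hellmann-Feynman forces on the water sites
#'
#' Forces exerted by the ground-state electron density on each site,
#' \code{F_s = -<psi0| dV/dR_s |psi0>}, evaluated by grid quadrature of
#' the analytic radial gradient of the site term.  The screened
#' pseudopotential keeps the gradient finite everywhere.
#'
#' @param frame nsites x 3 coordinates, A.
#' @param states an \code{ElectronStates} (ground state used).
#' @param topology the \code{WaterTopology}.
#' @param params pseudopotential parameters.
#' @param box optional box edge, A.
#' @return nsites x 3 matrix of forces, eV/A.
#' @export
hellmannFeynmanForces <- function(frame, states, topology, params,
                                  box = NULL) {
    grid <- states@grid
    ns <- nrow(frame)
    F <- matrix(0, max(ns, 0L), 3L)
    if (ns == 0L) return(F)
    pts <- gridPoints(grid)
    h3 <- (grid@L / grid@M)^3
    rho <- states@wfn[, 1]^2 * h3          # integrates to 1
    el <- topology@siteElements
    q <- topology@siteCharges
    for (s in seq_len(ns)) {
        d1 <- pts[, 1] - frame[s, 1]
        d2 <- pts[, 2] - frame[s, 2]
        d3 <- pts[, 3] - frame[s, 3]
        if (!is.null(box)) {
            d1 <- .minImage(d1, box); d2 <- .minImage(d2, box)
            d3 <- .minImage(d3, box)
        }
        r <- sqrt(d1 * d1 + d2 * d2 + d3 * d3)
        dv <- .siteTerm(r, q[s], params$elements[[el[s]]], deriv = TRUE)
        rr <- ifelse(r < 1e-8, 1, r)
        wt <- rho * dv / rr
        # F_s = + sum rho * V'(r) * (r_p - R_s)/r  (grid point minus site)
        F[s, ] <- c(sum(wt * d1), sum(wt * d2), sum(wt * d3))
    }
    if (!all(is.finite(F))) stop("non-finite Hellmann-Feynman force")
    F
}
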