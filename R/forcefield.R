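# Flexible simple point-charge water: harmonic intramolecular stretch and
# bend, O-O Lennard-Jones, site-site Coulomb.  Intermolecular terms are
# multiplied by a cubic Hermite taper that switches smoothly (value and
# first derivative continuous) from 1 at r_c - delta to 0 at r_c; beyond
# r_c pairs do not interact.  All forces are analytic gradients, so
# isolated clusters conserve momentum and angular momentum exactly
# (central pair forces).

#' Load water force-field parameters
#'
#' @param path YAML parameter file; default is the flexible simple
#'   point-charge set shipped with the package.
#' @return list of parameters (energies eV, lengths A, angles rad).
#' @export
loadForceField <- function(path = system.file("extdata",
        "water_spcflex.yaml", package = "espec")) {
    p <- yaml::read_yaml(path)
    p$theta0 <- p$theta0_deg * pi / 180
    p
}

# Taper value and derivative on [r1, rc]; 1 below, 0 above.  Quintic
# smoothstep: continuous through the second derivative, which long NVE
# runs need (a C^1 switch injects secular energy noise at the cutoff).
.taper <- function(r, rc, delta) {
    r1 <- rc - delta
    u <- pmin(pmax((r - r1) / delta, 0), 1)
    s <- 1 - u^3 * (10 - 15 * u + 6 * u^2)
    ds <- -30 * u^2 * (1 - u)^2 / delta
    list(s = s, ds = ds)
}

# Precompute intermolecular site pair lists for a topology.
.pairList <- function(topology) {
    ns <- nSites(topology)
    mol <- rep(seq_len(topology@nMolecules), each = 3L)
    idx <- which(outer(mol, mol, `!=`) & upper.tri(matrix(0, ns, ns)),
                 arr.ind = TRUE)
    i <- idx[, 1]; j <- idx[, 2]
    el <- topology@siteElements
    list(i = i, j = j,
         qq = especConstants$coulombConstant *
              topology@siteCharges[i] * topology@siteCharges[j],
         oo = el[i] == "O" & el[j] == "O")
}

#' Classical water forces and potential energy
#'
#' Analytic gradients of the flexible simple point-charge force field.
#' Intermolecular pair interactions are tapered near the cutoff; the
#' minimum-image convention applies when a box is present.
#'
#' @param frame nsites x 3 coordinates, A.
#' @param topology a \code{WaterTopology}.
#' @param params force-field parameter list (\code{loadForceField}).
#' @param box optional cubic box edge, A.
#' @param pairs optional precomputed pair list (reused across MD steps).
#' @return list with \code{forces} (nsites x 3, eV/A) and \code{energy}
#'   (eV).
#' @export
classicalForces <- function(frame, topology, params, box = NULL,
                            pairs = NULL) {
    ns <- nrow(frame)
    n <- topology@nMolecules
    if (ns != 3L * n)
        stop("frame must have 3 sites per molecule (got ", ns,
             " for ", n, " molecules)")
    F <- matrix(0, ns, 3L)
    E <- 0

    # --- intramolecular -----------------------------------------------------
    iO <- 3L * seq_len(n) - 2L
    for (hh in 1:2) {
        iH <- iO + hh
        d <- frame[iH, , drop = FALSE] - frame[iO, , drop = FALSE]
        r <- sqrt(rowSums(d^2))
        if (any(r < 1e-6)) stop("overlapping sites")
        E <- E + sum(0.5 * params$kr * (r - params$r0)^2)
        fmag <- -params$kr * (r - params$r0) / r
        fH <- d * fmag
        F[iH, ] <- F[iH, ] + fH
        F[iO, ] <- F[iO, ] - fH
    }
    u <- frame[iO + 1L, , drop = FALSE] - frame[iO, , drop = FALSE]
    v <- frame[iO + 2L, , drop = FALSE] - frame[iO, , drop = FALSE]
    ru <- sqrt(rowSums(u^2)); rv <- sqrt(rowSums(v^2))
    eu <- u / ru; ev <- v / rv
    ct <- pmin(1, pmax(-1, rowSums(eu * ev)))
    th <- acos(ct)
    st <- sqrt(pmax(1 - ct^2, 1e-12))
    E <- E + sum(0.5 * params$ktheta * (th - params$theta0)^2)
    dEdth <- params$ktheta * (th - params$theta0)
    gH1 <- -(ev - ct * eu) / (ru * st) * dEdth   # dE/dH1
    gH2 <- -(eu - ct * ev) / (rv * st) * dEdth
    F[iO + 1L, ] <- F[iO + 1L, ] + gH1 * (-1)
    F[iO + 2L, ] <- F[iO + 2L, ] + gH2 * (-1)
    F[iO, ] <- F[iO, ] - (gH1 * (-1) + gH2 * (-1))

    # --- intermolecular -----------------------------------------------------
    if (n > 1L) {
        if (is.null(pairs)) pairs <- .pairList(topology)
        d <- frame[pairs$i, , drop = FALSE] - frame[pairs$j, , drop = FALSE]
        if (!is.null(box)) d <- .minImage(d, box)
        r <- sqrt(rowSums(d^2))
        if (any(r < 1e-6)) stop("overlapping sites")
        live <- r < params$cutoff
        if (any(live)) {
            rl <- r[live]
            U <- pairs$qq[live] / rl
            dU <- -U / rl
            if (any(ooL <- pairs$oo[live])) {
                s6 <- (params$sigma / rl[ooL])^6
                U[ooL] <- U[ooL] + 4 * params$epsilon * (s6^2 - s6)
                dU[ooL] <- dU[ooL] + 4 * params$epsilon *
                    (-12 * s6^2 + 6 * s6) / rl[ooL]
            }
            tp <- .taper(rl, params$cutoff, params$taper)
            E <- E + sum(U * tp$s)
            fmag <- -(dU * tp$s + U * tp$ds) / rl
            fv <- d[live, , drop = FALSE] * fmag
            ii <- pairs$i[live]; jj <- pairs$j[live]
            acc <- rowsum(rbind(fv, -fv), c(ii, jj))
            tgt <- as.integer(rownames(acc))
            F[tgt, ] <- F[tgt, ] + acc
        }
    }
    list(forces = F, energy = E)
}
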