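# Adiabatic mixed quantum-classical dynamics: classical nuclei move under
# the combined classical water force and the Hellmann-Feynman force of
# the ground-state excess electron, integrated with velocity Verlet
# (explicit velocities are needed for kinetic temperature control).

#' Simulation configuration
#'
#' Collects every knob of the dynamics engine.  Defaults are the
#' standard protocol values: 0.5 fs time step, 16^3 dynamics grid on an
#' 18.17 A cube, microcanonical production.
#'
#' @param topology a \code{WaterTopology}.
#' @param nSteps number of integration steps.
#' @param dt time step, fs.
#' @param temperature target temperature, K (200 for clusters, 300 for
#'   bulk in the standard protocol).
#' @param box cubic box edge in A, or NULL for clusters.
#' @param dynGridL,dynGridM dynamics wavefunction cube edge (A) and
#'   points per dimension.
#' @param storeStride store every \code{storeStride}-th frame.
#' @param quantum logical; include the excess electron (FALSE gives
#'   plain classical water dynamics).
#' @param recenter "initial" (cube centered once on the water center of
#'   mass) or "centroid" (cube follows the electron centroid, snapped to
#'   whole grid spacings so the discretization is translation-consistent).
#' @param solverTol eigensolver residual tolerance during dynamics.
#' @param seed integer seed (velocity initialization, solver starts).
#' @param ffParams,ppParams force-field / pseudopotential parameter
#'   lists; defaults load the shipped files.
#' @param escapeRadius molecules whose O drifts beyond this distance
#'   from the cluster center of mass are flagged (never deleted).
#' @param rescaleEvery thermostat interval (equilibration only), steps.
#' @return a validated config list of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(topology, nSteps, dt = 0.5, temperature = 200,
                             box = NULL, dynGridL = 18.17, dynGridM = 16,
                             storeStride = 1L, quantum = TRUE,
                             recenter = c("initial", "centroid"),
                             solverTol = 1e-9, seed = 1L,
                             ffParams = loadForceField(),
                             ppParams = loadPseudopotential(),
                             escapeRadius = 25, rescaleEvery = 50L) {
    stopifnot(dt > 0, nSteps >= 0, storeStride >= 1L)
    if (!is.null(box) && box <= 2 * ffParams$cutoff)
        stop("box must exceed twice the cutoff")
    if (is.null(box) && ffParams$cutoff < 50) {
        # the tapered spherical cutoff is a bulk (periodic) device; an
        # isolated cluster interacts at full range.  Molecules wandering
        # through the taper region also degrade NVE conservation.
        ffParams$cutoff <- 50
    }
    structure(list(topology = topology, nSteps = as.integer(nSteps), dt = dt,
                   temperature = temperature, box = box,
                   dynGridL = dynGridL, dynGridM = as.integer(dynGridM),
                   storeStride = as.integer(storeStride), quantum = quantum,
                   recenter = match.arg(recenter), solverTol = solverTol,
                   seed = as.integer(seed), ffParams = ffParams,
                   ppParams = ppParams, escapeRadius = escapeRadius,
                   rescaleEvery = as.integer(rescaleEvery)),
              class = "SimulationConfig")
}

.siteMassMatrix <- function(topology)
    matrix(topology@siteMasses, nSites(topology), 3L)

.comPosition <- function(x, topology) {
    m <- topology@siteMasses
    colSums(x * m) / sum(m)
}

#' Seeded Maxwell-Boltzmann velocities
#'
#' Draws site velocities at the target temperature and removes the net
#' linear momentum (and, for clusters, the net angular momentum about
#' the center of mass).
#'
#' @param topology a \code{WaterTopology}.
#' @param temperature K.
#' @param seed integer seed.
#' @param cluster remove angular momentum too (isolated systems).
#' @return nsites x 3 velocity matrix, A/fs; needs positions for angular
#'   momentum removal, so pass \code{x}.
#' @param x nsites x 3 positions, A.
#' @export
maxwellVelocities <- function(topology, temperature, x, seed = 1L,
                              cluster = TRUE) {
    m <- topology@siteMasses
    ns <- length(m)
    v <- matrix(.especGauss(3L * ns, seed), ns, 3L) *
         sqrt(especConstants$kB * temperature / m)
    # remove net momentum
    p <- colSums(v * m)
    v <- sweep(v, 2L, p / sum(m))
    if (cluster) {
        com <- .comPosition(x, topology)
        r <- sweep(x, 2L, com)
        L <- colSums(m * cbind(r[, 2] * v[, 3] - r[, 3] * v[, 2],
                               r[, 3] * v[, 1] - r[, 1] * v[, 3],
                               r[, 1] * v[, 2] - r[, 2] * v[, 1]))
        r2 <- rowSums(r^2)
        I <- diag(sum(m * r2), 3L) - t(r * m) %*% r
        om <- solve(I + diag(1e-12, 3L), L)
        v <- v - cbind(om[2] * r[, 3] - om[3] * r[, 2],
                       om[3] * r[, 1] - om[1] * r[, 3],
                       om[1] * r[, 2] - om[2] * r[, 1])
    }
    v
}

# Deterministic standard normals via Box-Muller on the hash stream.
.especGauss <- function(n, seed) {
    m <- ceiling(n / 2)
    u1 <- pmax(.especRand(m, seed) + 0.5, 1e-12)
    u2 <- .especRand(m, seed + 31L) + 0.5
    z <- c(sqrt(-2 * log(u1)) * cos(2 * pi * u2),
           sqrt(-2 * log(u1)) * sin(2 * pi * u2))
    z[seq_len(n)]
}

#' Kinetic temperature
#'
#' @param v velocities, A/fs.
#' @param topology a \code{WaterTopology}.
#' @param dof degrees of freedom; default 3N - 6 (isolated cluster).
#' @return temperature in K.
#' @export
kineticTemperature <- function(v, topology, dof = 3L * nSites(topology) - 6L) {
    ke <- 0.5 * sum(topology@siteMasses * rowSums(v^2))
    2 * ke / (dof * especConstants$kB)
}

#' One velocity-Verlet step
#'
#' Deterministic symplectic update: half-kick, drift, force, half-kick.
#'
#' @param x,v positions (A) and velocities (A/fs).
#' @param f forces at \code{x}, eV/A.
#' @param masses site masses (eV fs^2/A^2), recycled across components.
#' @param dt time step, fs.
#' @param forceFun function(x) returning list(forces, energy).
#' @return list(x, v, f, energy) after the step.
#' @export
verletStep <- function(x, v, f, masses, dt, forceFun) {
    if (!all(is.finite(f))) stop("non-finite force")
    v <- v + f / masses * (dt / 2)
    x <- x + v * dt
    fe <- forceFun(x)
    v <- v + fe$forces / masses * (dt / 2)
    list(x = x, v = v, f = fe$forces, energy = fe$energy)
}

# Build the combined force closure and electron-state cache for a config.
.makeEngine <- function(config, x0) {
    top <- config$topology
    pairs <- if (top@nMolecules > 1L) .pairList(top) else NULL
    env <- new.env(parent = emptyenv())
    env$states <- NULL
    env$grid <- NULL
    env$ncall <- 0L
    if (config$quantum) {
        origin <- .comPosition(x0, top)
        h <- config$dynGridL / config$dynGridM
        env$grid <- gridSpec(config$dynGridL, config$dynGridM,
                             origin = round(origin / h) * h)
    }
    force <- function(x) {
        cf <- classicalForces(x, top, config$ffParams, box = config$box,
                              pairs = pairs)
        if (!config$quantum)
            return(list(forces = cf$forces, energy = cf$energy, e0 = 0))
        if (config$recenter == "centroid" && !is.null(env$states)) {
            cen <- groundStateCentroid(env$states)
            h <- env$grid@L / env$grid@M
            shift <- round((cen - env$grid@origin) / h)
            if (any(shift != 0)) {
                env$grid <- gridSpec(env$grid@L, env$grid@M,
                                     origin = env$grid@origin + shift * h)
                env$states@wfn <- .rollGrid(env$states@wfn, env$grid@M, shift)
            }
        }
        fld <- .gridSiteField(gridPoints(env$grid), x, box = config$box)
        vpot <- .potentialFromField(fld, top, config$ppParams)
        h3 <- (env$grid@L / env$grid@M)^3
        start <- if (!is.null(env$states)) env$states@wfn * sqrt(h3)
        env$ncall <- env$ncall + 1L
        # ground state only, but expand in blocks of 2 when warm-started:
        # the extra exploratory direction protects the warm start from
        # stagnating on the wrong branch at near-degeneracy crossings
        eig <- lowestEigenpairs(vpot, env$grid, nev = 1L,
            tol = config$solverTol, start = start,
            blockSize = if (is.null(start)) 4L else 2L,
            seed = config$seed + env$ncall %% 1000L)
        if (!eig$converged)
            stop("eigensolver did not converge: residuals ",
                 paste(sprintf("%.2e", eig$residuals), collapse = " "))
        env$states <- methods::new("ElectronStates",
            energies = eig$values, wfn = eig$vectors / sqrt(h3),
            grid = env$grid, deltaE = eig$values[-1] - eig$values[1],
            dipoles = matrix(0, 1L, 3L), f = 0,
            residuals = eig$residuals)
        qf <- .hfFromField(fld, env$states, top, config$ppParams)
        list(forces = cf$forces + qf, energy = cf$energy,
             e0 = env$states@energies[1])
    }
    list(force = force, env = env)
}

# Circularly shift grid wavefunction columns by integer grid steps.
.rollGrid <- function(wfn, M, shift) {
    idx <- function(s) ((seq_len(M) - 1L + s) %% M) + 1L
    for (j in seq_len(ncol(wfn))) {
        a <- array(wfn[, j], c(M, M, M))
        wfn[, j] <- as.vector(a[idx(shift[1]), idx(shift[2]), idx(shift[3])])
    }
    wfn
}

#' Run adiabatic quantum-classical dynamics
#'
#' Per step: solve the ground state of the excess electron on the
#' dynamics grid (warm-started from the previous step), add the
#' Hellmann-Feynman force to the classical forces, and advance with
#' velocity Verlet.  Microcanonical: the conserved quantity is
#' KE + classical PE + E0.
#'
#' @param config a \code{SimulationConfig}.
#' @param frame list with \code{x} (nsites x 3 positions, A) and
#'   optionally \code{v}; missing velocities are drawn Maxwell-Boltzmann
#'   at the config temperature.
#' @return list with \code{trajectory} (dense \code{Trajectory} with
#'   velocities), \code{ledger} (per stored frame: time, kinetic,
#'   classical potential, E0, total energy, temperature, evaporation
#'   flag) and \code{finalFrame}.
#' @export
runQCMD <- function(config, frame) {
    top <- config$topology
    x <- frame$x
    v <- frame$v
    if (is.null(v))
        v <- maxwellVelocities(top, config$temperature, x,
                               seed = config$seed,
                               cluster = is.null(config$box))
    eng <- .makeEngine(config, x)
    fe <- eng$force(x)
    masses <- .siteMassMatrix(top)
    nstore <- config$nSteps %/% config$storeStride + 1L
    co <- array(0, c(nSites(top), 3L, nstore))
    ve <- array(0, c(nSites(top), 3L, nstore))
    ledger <- data.frame(time = numeric(nstore), kinetic = numeric(nstore),
                         potential = numeric(nstore), e0 = numeric(nstore),
                         total = numeric(nstore),
                         temperature = numeric(nstore),
                         evaporated = logical(nstore))
    isCluster <- is.null(config$box)
    dof <- if (isCluster) 3L * nSites(top) - 6L else 3L * nSites(top) - 3L
    record <- function(slot, t, x, v, fe) {
        ke <- 0.5 * sum(masses * v^2)
        co[, , slot] <<- x
        ve[, , slot] <<- v
        ev <- FALSE
        if (isCluster) {
            com <- .comPosition(x, top)
            dO <- sqrt(rowSums(sweep(
                x[3L * seq_len(top@nMolecules) - 2L, , drop = FALSE],
                2L, com)^2))
            ev <- any(dO > config$escapeRadius)
        }
        ledger[slot, ] <<- list(t, ke, fe$energy, fe$e0,
                                ke + fe$energy + fe$e0,
                                2 * ke / (dof * especConstants$kB), ev)
    }
    record(1L, 0, x, v, fe)
    slot <- 1L
    for (step in seq_len(config$nSteps)) {
        st <- verletStep(x, v, fe$forces, masses, config$dt, eng$force)
        x <- st$x; v <- st$v
        fe <- list(forces = st$f, energy = st$energy,
                   e0 = if (config$quantum) eng$env$states@energies[1] else 0)
        if (step %% config$storeStride == 0L) {
            slot <- slot + 1L
            record(slot, step * config$dt, x, v, fe)
        }
    }
    dense <- newTrajectory(top, co[, , seq_len(slot), drop = FALSE],
                           config$dt * config$storeStride,
                           velocities = ve[, , seq_len(slot), drop = FALSE],
                           box = config$box, tag = "classical")
    list(trajectory = dense, ledger = ledger[seq_len(slot), ],
         finalFrame = list(x = x, v = v),
         states = if (config$quantum) eng$env$states else NULL)
}

#' Relax a structure on the coupled potential surface
#'
#' Damped steepest descent on the combined classical + Hellmann-Feynman
#' energy (classical PE + E0).  Starting microcanonical production from
#' a coupled-surface minimum avoids the exothermic rearrangements (and
#' near-continuum electron states) that an electron-free structure
#' undergoes once the quantum force switches on.
#'
#' @param config a \code{SimulationConfig} (grid, parameters and
#'   \code{quantum} flag are honored; time stepping is not used).
#' @param frame list with positions \code{x}.
#' @param fTol force convergence threshold, eV/A.
#' @param maxIter iteration cap.
#' @return list(x, energy, converged).
#' @export
relaxCluster <- function(config, frame, fTol = 0.05, maxIter = 400L) {
    x <- frame$x
    eng <- .makeEngine(config, x)
    fe <- eng$force(x)
    etot <- function(fe) fe$energy + fe$e0
    alpha <- 0.002
    for (it in seq_len(maxIter)) {
        fmax <- sqrt(max(rowSums(fe$forces^2)))
        if (fmax < fTol) break
        step <- alpha * fe$forces
        cap <- 0.1 / max(sqrt(rowSums(step^2)))
        if (cap < 1) step <- step * cap
        xn <- x + step
        fen <- tryCatch(eng$force(xn), error = function(e) NULL)
        if (is.null(fen) || etot(fen) > etot(fe) + 1e-12) {
            alpha <- alpha / 2
            if (alpha < 1e-8) break
        } else {
            x <- xn
            fe <- fen
            alpha <- min(alpha * 1.1, 0.02)
        }
    }
    list(x = x, energy = etot(fe),
         converged = sqrt(max(rowSums(fe$forces^2))) < fTol)
}

#' Equilibrate to a target temperature
#'
#' Velocity-rescaling thermostat: every \code{rescaleEvery} steps the
#' velocities are scaled toward the target kinetic temperature; the
#' thermostat is then released and the final frame is microcanonical-
#' ready.
#'
#' @param config a \code{SimulationConfig} (its \code{nSteps} is the
#'   thermostatted length).
#' @param frame list(x, v); missing velocities are drawn at the target
#'   temperature.
#' @param tempWindow acceptable relative deviation of the trailing mean
#'   temperature; exceeded at the end raises a warning only.
#' @return list(x, v) plus the equilibration ledger.
#' @export
equilibrate <- function(config, frame, tempWindow = 0.3) {
    top <- config$topology
    x <- frame$x
    v <- frame$v
    if (is.null(v))
        v <- maxwellVelocities(top, config$temperature, x,
                               seed = config$seed,
                               cluster = is.null(config$box))
    eng <- .makeEngine(config, x)
    fe <- eng$force(x)
    masses <- .siteMassMatrix(top)
    dof <- if (is.null(config$box)) 3L * nSites(top) - 6L else
        3L * nSites(top) - 3L
    temps <- numeric(config$nSteps)
    for (step in seq_len(config$nSteps)) {
        st <- verletStep(x, v, fe$forces, masses, config$dt, eng$force)
        x <- st$x; v <- st$v
        fe <- list(forces = st$f, energy = st$energy)
        temps[step] <- 2 * (0.5 * sum(masses * v^2)) /
            (dof * especConstants$kB)
        if (step %% config$rescaleEvery == 0L) {
            tcur <- mean(temps[max(1L, step - config$rescaleEvery + 1L):step])
            lambda <- sqrt(config$temperature / max(tcur, 1e-6))
            # damp the rescale to avoid overshoot on stiff modes
            v <- v * min(max(lambda, 0.8), 1.25)
        }
    }
    tail <- temps[max(1L, length(temps) - 4L * config$rescaleEvery):
                  length(temps)]
    if (length(tail) && abs(mean(tail) - config$temperature) >
        tempWindow * config$temperature)
        warning(sprintf("equilibration ended at %.0f K (target %.0f K)",
                        mean(tail), config$temperature))
    list(x = x, v = v, temperatures = temps)
}
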