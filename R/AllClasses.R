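# Central S4 classes. Constructors live next to the code that uses them;
# validity methods encode the structural invariants every module relies on.

#' WaterTopology: site layout of an all-water system
#'
#' Sites are ordered O,H,H within each molecule, molecules concatenated.
#' Charges must sum to zero within each molecule (neutral water; the excess
#' electron is handled separately on the grid).
#'
#' @slot nMolecules number of water molecules.
#' @slot siteElements character vector, "O"/"H", length 3n.
#' @slot siteMasses numeric, eV fs^2/A^2, length 3n.
#' @slot siteCharges numeric, units of e, length 3n.
#' @export
setClass("WaterTopology",
    representation(nMolecules = "integer", siteElements = "character",
                   siteMasses = "numeric", siteCharges = "numeric"))

setValidity("WaterTopology", function(object) {
    n <- object@nMolecules
    msg <- character()
    if (length(object@siteElements) != 3L * n ||
        length(object@siteMasses) != 3L * n ||
        length(object@siteCharges) != 3L * n)
        msg <- c(msg, "topology must have 3 sites per molecule")
    else {
        if (!all(object@siteElements == rep(c("O", "H", "H"), n)))
            msg <- c(msg, "sites must be ordered O,H,H per molecule")
        qmol <- rowSums(matrix(object@siteCharges, ncol = 3L, byrow = TRUE))
        if (any(abs(qmol) > 1e-10))
            msg <- c(msg, "per-molecule charges must sum to zero")
        m <- matrix(object@siteMasses, ncol = 3L, byrow = TRUE)
        if (any(m[, 2] >= m[, 1] | m[, 3] >= m[, 1]))
            msg <- c(msg, "H mass must be smaller than O mass")
    }
    if (length(msg)) msg else TRUE
})

#' Trajectory: time-ordered frames at uniform spacing
#'
#' Coordinates are Cartesian angstrom, stored as an nsites x 3 x nframes
#' array.  Velocities (A/fs) are optional (zero-length array when absent).
#' \code{box} holds the cubic box edge for bulk systems and is empty for
#' clusters.  Uniform time spacing is required by the moving-window
#' convolution of the quantization filter.
#'
#' @slot topology a \code{WaterTopology}.
#' @slot coords numeric array, nsites x 3 x nframes.
#' @slot velocities numeric array, same shape or zero-length.
#' @slot times numeric, fs, strictly increasing, uniform spacing.
#' @slot dtStore storage interval, fs.
#' @slot box cubic box edge in A (length 1) or numeric(0) for clusters.
#' @slot tag "classical", "quantized" or "scaled:<f>".
#' @export
setClass("Trajectory",
    representation(topology = "WaterTopology", coords = "array",
                   velocities = "array", times = "numeric",
                   dtStore = "numeric", box = "numeric", tag = "character"))

setValidity("Trajectory", function(object) {
    msg <- character()
    d <- dim(object@coords)
    ns <- 3L * object@topology@nMolecules
    if (length(d) != 3L || d[1] != ns || d[2] != 3L)
        msg <- c(msg, "coords must be nsites x 3 x nframes")
    if (length(object@times) < 1L || (length(d) == 3L && d[3] != length(object@times)))
        msg <- c(msg, "need >= 1 frame with one time stamp per frame")
    if (length(object@times) > 1L) {
        dt <- diff(object@times)
        if (any(dt <= 0) || max(abs(dt - object@dtStore)) > 1e-9 * object@dtStore)
            msg <- c(msg, "time stamps must be strictly increasing with uniform spacing dtStore")
    }
    if (length(object@velocities) && !identical(dim(object@velocities), d))
        msg <- c(msg, "velocities must match coords shape")
    if (length(object@box) && object@box[1] <= 0)
        msg <- c(msg, "box edge must be positive")
    if (length(msg)) msg else TRUE
})

#' GridSpec: cubic wavefunction grid
#'
#' @slot L cube edge, A.
#' @slot M points per dimension (a power of two; 16 for dynamics, 32 for
#'   spectra in the standard protocol).
#' @slot origin grid center, A (length 3).
#' @export
setClass("GridSpec",
    representation(L = "numeric", M = "integer", origin = "numeric"))

setValidity("GridSpec", function(object) {
    msg <- character()
    if (object@L <= 0) msg <- c(msg, "L must be positive")
    M <- object@M
    if (M < 4L || bitwAnd(M, M - 1L) != 0L)
        msg <- c(msg, "M must be a power of two >= 4")
    if (length(object@origin) != 3L) msg <- c(msg, "origin must have length 3")
    if (length(msg)) msg else TRUE
})

#' ElectronStates: grid eigenpairs of the one-electron Hamiltonian
#'
#' Real-valued wavefunctions are L2-normalized on the grid
#' (sum(psi^2) * h^3 = 1 with h the grid spacing), stored one per column.
#'
#' @slot energies eigenvalues E_0..E_K, eV, ascending.
#' @slot wfn M^3 x (K+1) matrix of grid wavefunctions.
#' @slot grid the \code{GridSpec} used.
#' @slot deltaE transition energies E_k - E_0, eV (length K).
#' @slot dipoles K x 3 matrix of transition dipoles, e A.
#' @slot f oscillator strengths, dimensionless (length K).
#' @slot residuals eigensolver residual norms per state.
#' @export
setClass("ElectronStates",
    representation(energies = "numeric", wfn = "matrix", grid = "GridSpec",
                   deltaE = "numeric", dipoles = "matrix", f = "numeric",
                   residuals = "numeric"))

setValidity("ElectronStates", function(object) {
    msg <- character()
    if (is.unsorted(object@energies, strictly = FALSE))
        msg <- c(msg, "energies must be ascending")
    if (ncol(object@wfn) != length(object@energies))
        msg <- c(msg, "one wavefunction column per energy")
    if (length(object@f) && any(object@f < -1e-12))
        msg <- c(msg, "oscillator strengths must be nonnegative")
    if (length(msg)) msg else TRUE
})

#' FilterKernel: discrete quantization filter
#'
#' Real, symmetric, unit-sum kernel whose discrete transfer gain at the
#' window's FFT frequencies equals sqrt(w(nu)) with w the
#' quantum/classical harmonic-oscillator energy ratio at temperature T.
#'
#' @slot dt sampling interval, fs.
#' @slot window nominal window length W, fs.
#' @slot temperature K.
#' @slot g numeric kernel, odd length, symmetric about its center.
#' @export
setClass("FilterKernel",
    representation(dt = "numeric", window = "numeric",
                   temperature = "numeric", g = "numeric"))

setValidity("FilterKernel", function(object) {
    msg <- character()
    n <- length(object@g)
    if (n < 9L || n %% 2L == 0L)
        msg <- c(msg, "kernel must have odd length >= 9")
    else if (max(abs(object@g - rev(object@g))) > 1e-10)
        msg <- c(msg, "kernel must be symmetric about its center")
    if (abs(sum(object@g) - 1) > 1e-10)
        msg <- c(msg, "kernel must sum to 1 (unit DC gain)")
    if (object@temperature <= 0) msg <- c(msg, "temperature must be positive")
    if (length(msg)) msg else TRUE
})

#' ExcitationTable: per-configuration transition energies and intensities
#'
#' One row per (configuration, transition k).  Either transition dipole
#' components (mux,muy,muz in e A) or precomputed oscillator strengths f
#' are present; \code{fOnly} marks tables lacking dipoles.
#'
#' @slot data data.frame with columns config, k, deltaE, (mux,muy,muz), f.
#' @slot K number of transitions per configuration.
#' @slot tag provenance tag ("classical", "quantized", "scaled:<f>", ...).
#' @slot fOnly logical, TRUE when only oscillator strengths are stored.
#' @export
setClass("ExcitationTable",
    representation(data = "data.frame", K = "integer", tag = "character",
                   fOnly = "logical"))

setValidity("ExcitationTable", function(object) {
    d <- object@data
    msg <- character()
    need <- c("config", "k", "deltaE", "f")
    if (!all(need %in% names(d)))
        msg <- c(msg, paste("missing columns:", paste(setdiff(need, names(d)), collapse = ", ")))
    else {
        if (any(d$deltaE <= 0)) msg <- c(msg, "transition energies must be positive")
        if (any(d$f < 0)) msg <- c(msg, "oscillator strengths must be nonnegative")
        if (anyDuplicated(d[, c("config", "k")]))
            msg <- c(msg, "duplicate (config, k) pairs")
        ord <- order(d$config, d$k)
        dd <- d[ord, ]
        bad <- stats::ave(dd$deltaE, dd$config, FUN = function(x) c(0, diff(x)))
        if (any(bad < -1e-12))
            msg <- c(msg, "deltaE must be nondecreasing in k within a configuration")
    }
    if (length(msg)) msg else TRUE
})

#' Spectrum: binned oscillator-strength density with sub-bands
#'
#' @slot energy bin centers, eV.
#' @slot total total intensity density (oscillator strength per eV).
#' @slot subbands nbins x K matrix, per-transition sub-band densities;
#'   total equals the row sums exactly.
#' @slot binWidth eV.
#' @slot normalization "raw" or "unit-maximum".
#' @slot meanSumF mean summed oscillator strength per configuration (the
#'   integral of the raw total).
#' @slot tag provenance tag.
#' @export
setClass("Spectrum",
    representation(energy = "numeric", total = "numeric", subbands = "matrix",
                   binWidth = "numeric", normalization = "character",
                   meanSumF = "numeric", tag = "character"))

setValidity("Spectrum", function(object) {
    msg <- character()
    if (length(object@energy) != length(object@total) ||
        nrow(object@subbands) != length(object@energy))
        msg <- c(msg, "energy grid, total and sub-bands must share length")
    if (any(object@total < -1e-12)) msg <- c(msg, "density must be nonnegative")
    if (max(abs(object@total - rowSums(object@subbands))) > 1e-10 * max(1, max(object@total)))
        msg <- c(msg, "total must equal the sum of sub-bands")
    if (length(msg)) msg else TRUE
})
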