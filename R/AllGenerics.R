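# Generics and accessors.  Slot access from user code goes through these.

#' @rdname trajectory-accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname trajectory-accessors
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @rdname trajectory-accessors
#' @export
setGeneric("nMolecules", function(x) standardGeneric("nMolecules"))

#' @rdname trajectory-accessors
#' @export
setGeneric("coords", function(x, ...) standardGeneric("coords"))

#' @rdname trajectory-accessors
#' @export
setGeneric("velocities", function(x, ...) standardGeneric("velocities"))

#' @rdname trajectory-accessors
#' @export
setGeneric("timeStamps", function(x) standardGeneric("timeStamps"))

#' @rdname trajectory-accessors
#' @export
setGeneric("boxEdge", function(x) standardGeneric("boxEdge"))

#' @rdname trajectory-accessors
#' @export
setGeneric("provenanceTag", function(x) standardGeneric("provenanceTag"))

#' Accessors for trajectories and topologies
#'
#' @param x a \code{Trajectory}, \code{WaterTopology} or related object.
#' @param ... for \code{coords}/\code{velocities}: optional \code{frame}
#'   index returning a single nsites x 3 matrix.
#' @return the requested component.
#' @name trajectory-accessors
NULL

setMethod("nMolecules", "WaterTopology", function(x) x@nMolecules)
setMethod("nSites", "WaterTopology", function(x) 3L * x@nMolecules)
setMethod("nFrames", "Trajectory", function(x) length(x@times))
setMethod("nSites", "Trajectory", function(x) dim(x@coords)[1])
setMethod("nMolecules", "Trajectory", function(x) x@topology@nMolecules)
setMethod("coords", "Trajectory", function(x, frame = NULL) {
    if (is.null(frame)) x@coords else x@coords[, , frame, drop = TRUE]
})
setMethod("velocities", "Trajectory", function(x, frame = NULL) {
    if (!length(x@velocities)) return(NULL)
    if (is.null(frame)) x@velocities else x@velocities[, , frame, drop = TRUE]
})
setMethod("timeStamps", "Trajectory", function(x) x@times)
setMethod("boxEdge", "Trajectory", function(x) if (length(x@box)) x@box else NULL)
setMethod("provenanceTag", "Trajectory", function(x) x@tag)
setMethod("provenanceTag", "ExcitationTable", function(x) x@tag)

#' @rdname states-accessors
#' @export
setGeneric("energies", function(x) standardGeneric("energies"))

#' @rdname states-accessors
#' @export
setGeneric("transitionEnergies", function(x) standardGeneric("transitionEnergies"))

#' @rdname states-accessors
#' @export
setGeneric("wavefunctions", function(x) standardGeneric("wavefunctions"))

#' @rdname states-accessors
#' @export
setGeneric("oscStrengths", function(x) standardGeneric("oscStrengths"))

#' Accessors for electron states and excitation tables
#'
#' @param x an \code{ElectronStates} or \code{ExcitationTable}.
#' @return eigenvalues (eV), transition energies (eV), grid wavefunction
#'   matrix, or oscillator strengths as appropriate.
#' @name states-accessors
NULL

setMethod("energies", "ElectronStates", function(x) x@energies)
setMethod("transitionEnergies", "ElectronStates", function(x) x@deltaE)
setMethod("wavefunctions", "ElectronStates", function(x) x@wfn)
setMethod("oscStrengths", "ElectronStates", function(x) x@f)
setMethod("transitionEnergies", "ExcitationTable", function(x) x@data$deltaE)
setMethod("oscStrengths", "ExcitationTable", function(x) x@data$f)

#' @rdname excitation-accessors
#' @export
setGeneric("excitationData", function(x) standardGeneric("excitationData"))

#' Extract the per-transition record table
#'
#' @param x an \code{ExcitationTable}.
#' @return the underlying data.frame (one row per configuration and
#'   transition).
#' @name excitation-accessors
NULL
setMethod("excitationData", "ExcitationTable", function(x) x@data)

# ---- show methods ----------------------------------------------------------

setMethod("show", "WaterTopology", function(object) {
    cat("WaterTopology:", object@nMolecules, "water molecules (",
        3L * object@nMolecules, "sites, O-H-H order )\n")
})

setMethod("show", "Trajectory", function(object) {
    cat(sprintf("Trajectory [%s]: %d molecules, %d frames, dt = %g fs%s%s\n",
        object@tag, object@topology@nMolecules, length(object@times),
        object@dtStore,
        if (length(object@box)) sprintf(", box %.2f A", object@box) else " (cluster)",
        if (length(object@velocities)) ", with velocities" else ""))
})

setMethod("show", "GridSpec", function(object) {
    cat(sprintf("GridSpec: %d^3 points, edge %.3f A, spacing %.4f A\n",
        object@M, object@L, object@L / object@M))
})

setMethod("show", "ElectronStates", function(object) {
    K <- length(object@energies) - 1L
    cat(sprintf("ElectronStates: E0 = %.4f eV, %d excited state(s)\n",
        object@energies[1], K))
    if (K > 0)
        cat("  gaps (eV):", paste(sprintf("%.4f", object@deltaE), collapse = " "), "\n")
})

setMethod("show", "FilterKernel", function(object) {
    cat(sprintf("FilterKernel: W = %g fs (%d taps), dt = %g fs, T = %g K\n",
        object@window, length(object@g), object@dt, object@temperature))
})

setMethod("show", "ExcitationTable", function(object) {
    cat(sprintf("ExcitationTable [%s]: %d configurations x K = %d transitions%s\n",
        object@tag, length(unique(object@data$config)), object@K,
        if (object@fOnly) " (f-only)" else ""))
})

setMethod("show", "Spectrum", function(object) {
    cat(sprintf("Spectrum [%s, %s]: %d bins of %g eV, integral %.4f\n",
        object@tag, object@normalization, length(object@energy),
        object@binWidth, sum(object@total) * object@binWidth))
})
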