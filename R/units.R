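#' Physical constants in the package unit system
#'
#' All interfaces exchange lengths in angstrom (A), times in femtoseconds
#' (fs), energies in electronvolts (eV) and temperatures in kelvin (K).
#' Charges are in units of the elementary charge e.  In these units the
#' Coulomb energy of two unit charges at distance r is
#' \code{coulombConstant / r} eV.
#'
#' @format A list with elements
#' \describe{
#'   \item{hbar}{reduced Planck constant, eV fs}
#'   \item{h}{Planck constant, eV fs}
#'   \item{kB}{Boltzmann constant, eV/K}
#'   \item{cLight}{speed of light, A/fs}
#'   \item{me}{electron mass, eV fs^2/A^2}
#'   \item{amu}{atomic mass unit, eV fs^2/A^2}
#'   \item{bohr}{Bohr radius, A}
#'   \item{hartree}{Hartree energy, eV}
#'   \item{coulombConstant}{e^2/(4 pi eps0), eV A}
#' }
#' @export
especConstants <- local({
    cLight <- 2997.92458               # A/fs
    hbar <- 0.6582119569               # eV fs
    bohr <- 0.529177210903             # A
    hartree <- 27.211386245988         # eV
    list(
        hbar = hbar,
        h = 2 * pi * hbar,
        kB = 8.617333262e-5,           # eV/K
        cLight = cLight,
        me = 510998.95000 / cLight^2,  # eV fs^2/A^2
        amu = 931494102.42 / cLight^2, # eV fs^2/A^2
        bohr = bohr,
        hartree = hartree,
        coulombConstant = hartree * bohr  # 14.3996... eV A
    )
})

#' Unit conversions
#'
#' Helpers converting between the interface units (A, fs, eV) and atomic
#' units, and between spectroscopic wavenumbers and linear frequency.
#' Round trips are identities to better than 1e-12 relative.
#'
#' @param x numeric vector to convert.
#' @return numeric vector in the target unit.
#' @name unitConversions
NULL

#' @rdname unitConversions
#' @export
angstromToBohr <- function(x) x / especConstants$bohr

#' @rdname unitConversions
#' @export
bohrToAngstrom <- function(x) x * especConstants$bohr

#' @rdname unitConversions
#' @export
evToHartree <- function(x) x / especConstants$hartree

#' @rdname unitConversions
#' @export
hartreeToEv <- function(x) x * especConstants$hartree

#' @rdname unitConversions
#' @export
wavenumberToFrequency <- function(x) x * especConstants$cLight * 1e-8 # cm^-1 -> fs^-1

#' @rdname unitConversions
#' @export
frequencyToWavenumber <- function(x) x / (especConstants$cLight * 1e-8)
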