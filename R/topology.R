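#' Construct a water topology
#'
#' Builds the O,H,H-ordered site layout for \code{n} water molecules with
#' uniform per-molecule masses and charges.  Defaults are the flexible
#' simple point-charge values (q_O = -0.82 e, q_H = +0.41 e) and atomic
#' masses of 15.999 and 1.008 u.
#'
#' @param n number of molecules.
#' @param massO,massH site masses in atomic mass units.
#' @param chargeO,chargeH site partial charges in units of e;
#'   \code{chargeO + 2*chargeH} must be zero.
#' @return a \code{WaterTopology}.
#' @examples
#' top <- waterTopology(2)
#' nSites(top)
#' @export
waterTopology <- function(n, massO = 15.999, massH = 1.008,
                          chargeO = -0.82, chargeH = 0.41) {
    n <- as.integer(n)
    stopifnot(n >= 1L)
    amu <- especConstants$amu
    methods::new("WaterTopology",
        nMolecules = n,
        siteElements = rep(c("O", "H", "H"), n),
        siteMasses = rep(c(massO, massH, massH) * amu, n),
        siteCharges = rep(c(chargeO, chargeH, chargeH), n))
}

#' Construct a trajectory object
#'
#' Time stamps are synthesized from \code{dtStore} (uniform spacing is a
#' structural requirement of the quantization filter, so stamps are never
#' taken from file).
#'
#' @param topology a \code{WaterTopology}.
#' @param coords nsites x 3 x nframes array (or nsites x 3 matrix for a
#'   single frame), angstrom.
#' @param dtStore frame spacing, fs.
#' @param velocities optional array matching \code{coords}, A/fs.
#' @param box optional cubic box edge, A.
#' @param tag provenance tag.
#' @param t0 time of the first frame, fs.
#' @return a \code{Trajectory}.
#' @export
newTrajectory <- function(topology, coords, dtStore,
                          velocities = NULL, box = NULL,
                          tag = "classical", t0 = 0) {
    if (is.matrix(coords)) coords <- array(coords, c(dim(coords), 1L))
    if (is.matrix(velocities)) velocities <- array(velocities, c(dim(velocities), 1L))
    nf <- dim(coords)[3]
    methods::new("Trajectory",
        topology = topology, coords = coords,
        velocities = if (is.null(velocities)) array(0, c(0, 0, 0)) else velocities,
        times = t0 + dtStore * (seq_len(nf) - 1L),
        dtStore = dtStore,
        box = if (is.null(box)) numeric(0) else box,
        tag = tag)
}

#' Construct a cubic grid specification
#'
#' @param L cube edge, A.
#' @param M points per dimension (power of two).
#' @param origin cube center, A.
#' @return a \code{GridSpec}.
#' @export
gridSpec <- function(L, M, origin = c(0, 0, 0)) {
    methods::new("GridSpec", L = L, M = as.integer(M), origin = as.numeric(origin))
}

#' Grid point coordinates
#'
#' \code{gridAxis} gives the M axis offsets relative to the cube center
#' (periodic spacing h = L/M, the center being a grid point);
#' \code{gridPoints} the full M^3 x 3 matrix of absolute grid point
#' coordinates, x index fastest -- the layout used by all grid
#' quantities in the package.
#'
#' @param grid a \code{GridSpec}.
#' @return numeric vector (axis) or M^3 x 3 matrix (points), A.
#' @export
gridAxis <- function(grid) {
    h <- grid@L / grid@M
    h * (seq_len(grid@M) - 1L - grid@M / 2L)
}

#' @rdname gridAxis
#' @export
gridPoints <- function(grid) {
    ax <- gridAxis(grid)
    M <- grid@M
    cbind(rep(ax, times = M * M) + grid@origin[1],
          rep(rep(ax, each = M), times = M) + grid@origin[2],
          rep(ax, each = M * M) + grid@origin[3])
}
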