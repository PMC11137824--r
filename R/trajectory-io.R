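#' Read an (extended-)XYZ trajectory
#'
#' Accepts plain XYZ or extended-XYZ with a constant atom count and sites
#' in topology order (O,H,H per molecule).  Velocities are picked up from
#' columns 5-7 when present.  A cubic box edge is recovered from an
#' extended-XYZ \code{Lattice="L 0 0 0 L 0 0 0 L"} entry in the comment
#' line.  Time stamps are synthesized from \code{dtStore}.
#'
#' @param path file path.
#' @param topology a \code{WaterTopology} the frames must match.
#' @param dtStore frame spacing, fs.
#' @param tag provenance tag for the returned trajectory.
#' @return a \code{Trajectory}.
#' @examples
#' top <- waterTopology(1)
#' fr <- rigidWaterFrame()
#' tf <- tempfile(fileext = ".xyz")
#' writeXYZTrajectory(newTrajectory(top, fr, 0.5), tf)
#' readXYZTrajectory(tf, top, 0.5)
#' @export
readXYZTrajectory <- function(path, topology, dtStore, tag = "classical") {
    lines <- readLines(path)
    lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0L))]
    if (!length(lines)) stop("empty XYZ file: ", path)
    ns <- nSites(topology)
    pos <- 1L
    frames <- list()
    vels <- list()
    box <- NULL
    while (pos <= length(lines)) {
        nat <- suppressWarnings(as.integer(trimws(lines[pos])))
        if (is.na(nat)) stop("malformed XYZ: expected atom count at line ", pos)
        if (nat != ns)
            stop("inconsistent atom count: frame declares ", nat,
                 " atoms, topology has ", ns)
        if (pos + 1L + nat > length(lines))
            stop("truncated XYZ frame starting at line ", pos)
        comment <- lines[pos + 1L]
        lat <- regmatches(comment, regexec('Lattice="([^"]+)"', comment))[[1]]
        if (length(lat) == 2L) {
            lv <- as.numeric(strsplit(trimws(lat[2]), "\\s+")[[1]])
            if (length(lv) == 9L) box <- lv[1]
        }
        rows <- strsplit(trimws(lines[pos + 1L + seq_len(nat)]), "\\s+")
        el <- vapply(rows, `[`, "", 1L)
        if (!all(el %in% c("O", "H")))
            stop("non-water element in XYZ: ", paste(unique(setdiff(el, c("O", "H"))), collapse = ","))
        if (!all(el == topology@siteElements))
            stop("element order does not match O,H,H topology order")
        num <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(length(rows[[1]]) - 1L)))
        frames[[length(frames) + 1L]] <- num[, 1:3, drop = FALSE]
        if (ncol(num) >= 6L) vels[[length(frames)]] <- num[, 4:6, drop = FALSE]
        pos <- pos + 2L + nat
    }
    co <- array(unlist(frames), c(ns, 3L, length(frames)))
    # frames were row-major matrices; array() fills columns, so rebuild:
    for (i in seq_along(frames)) co[, , i] <- frames[[i]]
    ve <- NULL
    if (length(vels) == length(frames) && length(frames) > 0L) {
        ve <- array(0, c(ns, 3L, length(frames)))
        for (i in seq_along(vels)) ve[, , i] <- vels[[i]]
    }
    newTrajectory(topology, co, dtStore, velocities = ve, box = box, tag = tag)
}

#' Write an (extended-)XYZ trajectory
#'
#' Emits extended-XYZ: the comment line carries \code{Time=} (fs), the
#' cubic \code{Lattice} when a box is present, and a \code{Properties}
#' descriptor.  Velocities, when stored, become columns 5-7.
#' Coordinates are written unwrapped with 1e-6 A precision.
#'
#' @param traj a \code{Trajectory}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeXYZTrajectory <- function(traj, path) {
    ns <- nSites(traj)
    el <- traj@topology@siteElements
    hasV <- length(traj@velocities) > 0L
    props <- if (hasV) "Properties=species:S:1:pos:R:3:vel:R:3" else
        "Properties=species:S:1:pos:R:3"
    lat <- if (length(traj@box))
        sprintf(' Lattice="%g 0 0 0 %g 0 0 0 %g"', traj@box, traj@box, traj@box) else ""
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nFrames(traj))) {
        writeLines(as.character(ns), con)
        writeLines(sprintf("%s%s Time=%.6f", props, lat, traj@times[i]), con)
        x <- traj@coords[, , i]
        if (hasV) {
            v <- traj@velocities[, , i]
            writeLines(sprintf("%s %.6f %.6f %.6f %.8f %.8f %.8f",
                el, x[, 1], x[, 2], x[, 3], v[, 1], v[, 2], v[, 3]), con)
        } else {
            writeLines(sprintf("%s %.6f %.6f %.6f", el, x[, 1], x[, 2], x[, 3]), con)
        }
    }
    invisible(path)
}
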