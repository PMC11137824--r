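#' Construct an excitation table
#'
#' @param data data.frame with columns \code{config}, \code{k},
#'   \code{deltaE} (eV) and either dipole components \code{mux,muy,muz}
#'   (e A) or oscillator strengths \code{f}.  When dipoles are given and
#'   \code{f} is absent, oscillator strengths are derived as
#'   f = 2 m_e dE |mu|^2 / (3 hbar^2).
#' @param tag provenance tag.
#' @return an \code{ExcitationTable}.
#' @export
excitationTable <- function(data, tag = "untagged") {
    data <- as.data.frame(data)
    hasMu <- all(c("mux", "muy", "muz") %in% names(data))
    if (!"f" %in% names(data)) {
        if (!hasMu) stop("need either dipole components mux,muy,muz or f")
        k <- especConstants
        mu2 <- data$mux^2 + data$muy^2 + data$muz^2
        data$f <- 2 * k$me * data$deltaE * mu2 / (3 * k$hbar^2)
    }
    data <- data[order(data$config, data$k), , drop = FALSE]
    rownames(data) <- NULL
    methods::new("ExcitationTable", data = data,
        K = as.integer(max(data$k)), tag = tag, fOnly = !hasMu)
}

#' Read an excitation table from delimited text
#'
#' Expects a header naming at least \code{config}, \code{k},
#' \code{deltaE} and either \code{mux,muy,muz} or \code{f}.  Tab or
#' comma delimited (autodetected).
#'
#' @param path file path.
#' @param tag provenance tag for the table.
#' @return an \code{ExcitationTable}; tables without dipole columns are
#'   flagged f-only.
#' @export
readExcitationTable <- function(path, tag = "untagged") {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
    d <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
    need <- c("config", "k", "deltaE")
    if (!all(need %in% names(d)))
        stop("missing columns: ", paste(setdiff(need, names(d)), collapse = ", "))
    if (any(d$deltaE <= 0)) stop("transition energies must be positive")
    excitationTable(d, tag = tag)
}

#' Write an excitation table as TSV
#'
#' @param table an \code{ExcitationTable}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeExcitationTable <- function(table, path) {
    utils::write.table(table@data, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
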