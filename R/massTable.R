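#' Monoisotopic mass table
#'
#' The package ships one plain-text mass asset
#' (`extdata/monoisotopic_masses.csv`) holding the monoisotopic residue
#' masses of the 20 standard amino acids, the water and proton constants,
#' the fixed carbamidomethyl modification mass applied to cysteine after
#' iodoacetamide alkylation, and the heavy-label mass shifts of
#' (13C6/15N2)-lysine and (13C6/15N4)-arginine. All mass arithmetic in the
#' package and the independent test oracles read this one source.
#'
#' @return A list with components `residues` (named numeric, Da),
#'   `water`, `proton` (numeric scalars, Da), `mods` (named numeric, Da)
#'   and `labelShifts` (named numeric, Da, names `K` and `R`).
#' @examples
#' mt <- massTable()
#' mt$residues[["G"]]
#' mt$labelShifts
#' @export
massTable <- function() {
    cached <- get0("massTable", envir = .mrmquantCache)
    if (!is.null(cached)) {
        return(cached)
    }
    path <- system.file("extdata", "monoisotopic_masses.csv",
        package = "mrmquant", mustWork = TRUE)
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    pick <- function(ty) {
        sel <- tab[tab$type == ty, , drop = FALSE]
        stats::setNames(sel$mass_da, sel$name)
    }
    mt <- list(
        residues = pick("residue"),
        water = unname(pick("constant")[["water"]]),
        proton = unname(pick("constant")[["proton"]]),
        mods = pick("modification"),
        labelShifts = pick("label_shift")
    )
    stopifnot(
        all(mt$residues > 0),
        setequal(names(mt$residues), strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]),
        setequal(names(mt$labelShifts), c("K", "R"))
    )
    assign("massTable", mt, envir = .mrmquantCache)
    mt
}

.mrmquantCache <- new.env(parent = emptyenv())

# Valid residue alphabet; I and L are distinct letters with identical mass.
.AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.checkSequence <- function(sequence, what = "sequence") {
    if (length(sequence) != 1L || is.na(sequence) || !nzchar(sequence)) {
        stop(what, " must be a single non-empty residue string", call. = FALSE)
    }
    chars <- strsplit(sequence, "")[[1]]
    bad <- which(!(chars %in% .AA_ALPHABET))
    if (length(bad)) {
        stop(sprintf("invalid residue '%s' at position %d in %s",
            chars[bad[1]], bad[1], what), call. = FALSE)
    }
    invisible(chars)
}
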