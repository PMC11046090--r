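#' Peptide monoisotopic mass
#'
#' Sum of residue monoisotopic masses plus one water, plus the fixed
#' carbamidomethyl mass for every cysteine (samples are reduced and
#' alkylated with iodoacetamide before digestion), plus the stable-isotope
#' label shift of the C-terminal residue when `label = "heavy"`.
#'
#' Heavy labelling is only meaningful for peptides ending in K or R, the
#' residues carried by (13C6/15N2)-Lys / (13C6/15N4)-Arg labelled internal
#' standards; requesting a heavy mass for any other C-terminus is an error.
#'
#' @param sequence Character vector of peptide sequences.
#' @param label `"light"` (endogenous) or `"heavy"` (internal standard).
#' @param carbamidomethyl Apply the fixed +57.02146 Da modification to
#'   every cysteine (default `TRUE`).
#' @return Numeric vector of monoisotopic masses in Da.
#' @examples
#' peptideMass("PEPTIDE")
#' peptideMass("SAMPLEK", label = "heavy") - peptideMass("SAMPLEK")
#' @export
peptideMass <- function(sequence, label = c("light", "heavy"),
                        carbamidomethyl = TRUE) {
    label <- match.arg(label)
    mt <- massTable()
    vapply(sequence, function(s) {
        chars <- .checkSequence(s, "peptide")
        m <- sum(mt$residues[chars]) + mt$water
        if (carbamidomethyl) {
            m <- m + sum(chars == "C") * mt$mods[["carbamidomethyl"]]
        }
        if (label == "heavy") {
            cterm <- chars[length(chars)]
            if (!cterm %in% c("K", "R")) {
                stop("heavy label requires a C-terminal K or R, got '",
                    cterm, "'", call. = FALSE)
            }
            m <- m + mt$labelShifts[[cterm]]
        }
        unname(m)
    }, numeric(1), USE.NAMES = FALSE)
}

#' Heavy-label mass shift for a C-terminal residue
#'
#' @param residue `"K"` or `"R"`.
#' @return Mass shift in Da (+8.014199 for K, +10.008269 for R).
#' @export
labelShift <- function(residue) {
    mt <- massTable()
    if (!all(residue %in% c("K", "R"))) {
        stop("label shifts are defined for K and R only", call. = FALSE)
    }
    unname(mt$labelShifts[residue])
}

#' Precursor m/z
#'
#' `(M + z * m_proton) / z` for the peptide's monoisotopic mass M. This is
#' the Q1 value of an MRM transition.
#'
#' @inheritParams peptideMass
#' @param charge Positive integer charge state.
#' @return Numeric vector of m/z values.
#' @examples
#' precursorMz("PEPTIDE", 2)
#' @export
precursorMz <- function(sequence, charge, label = c("light", "heavy"),
                        carbamidomethyl = TRUE) {
    if (any(charge < 1) || any(charge != as.integer(charge))) {
        stop("charge must be a positive integer", call. = FALSE)
    }
    mt <- massTable()
    (peptideMass(sequence, label, carbamidomethyl) + charge * mt$proton) /
        charge
}

#' Fragment-ion m/z
#'
#' b- and y-ion m/z values as monitored in Q3. `y_n` comprises the n
#' C-terminal residues plus water; `b_n` the n N-terminal residues; both
#' gain `charge` protons and are divided by `charge`. For a heavy peptide
#' (label on the C-terminal K/R) the label shift is carried by y-ions
#' only; b-ions are identical between light and heavy.
#'
#' @inheritParams peptideMass
#' @param ion `"y"` or `"b"`.
#' @param index Fragment index, `1 <= index <= nchar(sequence) - 1` for
#'   informative fragments; `index == nchar(sequence)` is allowed for y
#'   (the full-length ion equals the precursor at the same charge).
#' @param charge Positive integer fragment charge (default 1).
#' @return Fragment m/z.
#' @examples
#' fragmentMz("PEPTIDEK", "y", 1) # C-terminal K immonium-free y1
#' fragmentMz("PEPTIDEK", "b", 2)
#' @export
fragmentMz <- function(sequence, ion = c("y", "b"), index, charge = 1L,
                       label = c("light", "heavy"), carbamidomethyl = TRUE) {
    ion <- match.arg(ion)
    label <- match.arg(label)
    chars <- .checkSequence(sequence, "peptide")
    n <- length(chars)
    maxIndex <- if (ion == "y") n else n - 1L
    if (index < 1 || index > maxIndex) {
        stop(sprintf("%s-ion index %d out of range [1, %d] for '%s'",
            ion, index, maxIndex, sequence), call. = FALSE)
    }
    if (charge < 1 || charge != as.integer(charge)) {
        stop("charge must be a positive integer", call. = FALSE)
    }
    mt <- massTable()
    piece <- if (ion == "y") chars[(n - index + 1):n] else chars[1:index]
    m <- sum(mt$residues[piece])
    if (carbamidomethyl) {
        m <- m + sum(piece == "C") * mt$mods[["carbamidomethyl"]]
    }
    if (ion == "y") {
        m <- m + mt$water
        if (label == "heavy") {
            cterm <- chars[n]
            if (!cterm %in% c("K", "R")) {
                stop("heavy label requires a C-terminal K or R", call. = FALSE)
            }
            m <- m + mt$labelShifts[[cterm]]
        }
    }
    unname((m + charge * mt$proton) / charge)
}
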