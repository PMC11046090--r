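#' In silico proteolytic digestion
#'
#' Cleaves a protein sequence according to the rules of trypsin, lysyl
#' endopeptidase (LysC), or their sequential combination as used when a
#' sample is digested first with LysC and then with trypsin:
#'
#' * `trypsin`: cleave C-terminal to K or R, except when the next residue
#'   is P;
#' * `lysc`: cleave C-terminal to every K, including before P;
#' * `lysc_then_trypsin`: the union of both site sets — after every K, and
#'   after R unless followed by P. This reproduces the final peptide
#'   population of the sequential protocol without modelling kinetics.
#'
#' With `maxMissedCleavages > 0`, all contiguous joins of up to that many
#' adjacent fully cleaved fragments are also returned, flagged by their
#' missed-cleavage count.
#'
#' @param sequence Single protein/peptide string over the 20 standard
#'   residues.
#' @param enzyme One of `"trypsin"`, `"lysc"`, `"lysc_then_trypsin"`.
#' @param maxMissedCleavages Non-negative integer (default 0).
#' @return A data.frame with columns `peptide`, `start`, `end`,
#'   `missedCleavages`, ordered by start position then missed-cleavage
#'   count. The `missedCleavages == 0` rows concatenate to the input.
#' @examples
#' digestProtein("PEPTIDEKSEQR", "trypsin")$peptide
#' digestProtein("AKPLRGK", "lysc_then_trypsin")$peptide
#' @export
digestProtein <- function(sequence,
                          enzyme = c("lysc_then_trypsin", "trypsin", "lysc"),
                          maxMissedCleavages = 0L) {
    enzyme <- match.arg(enzyme)
    chars <- .checkSequence(sequence)
    if (maxMissedCleavages < 0) {
        stop("maxMissedCleavages must be >= 0", call. = FALSE)
    }
    sites <- cleavageSites(sequence, enzyme)
    bounds <- c(0L, sites, length(chars))
    starts <- bounds[-length(bounds)] + 1L
    ends <- bounds[-1]
    n <- length(starts)
    out <- data.frame(
        peptide = substring(sequence, starts, ends),
        start = starts, end = ends, missedCleavages = 0L,
        stringsAsFactors = FALSE
    )
    if (maxMissedCleavages > 0 && n > 1) {
        extra <- list()
        for (mc in seq_len(min(maxMissedCleavages, n - 1L))) {
            i <- seq_len(n - mc)
            extra[[mc]] <- data.frame(
                peptide = substring(sequence, starts[i], ends[i + mc]),
                start = starts[i], end = ends[i + mc], missedCleavages = mc,
                stringsAsFactors = FALSE
            )
        }
        out <- rbind(out, do.call(rbind, extra))
        out <- out[order(out$start, out$missedCleavages), , drop = FALSE]
        rownames(out) <- NULL
    }
    out
}

#' Cleavage-site positions
#'
#' Positions `i` such that the enzyme cuts between residue `i` and
#' residue `i + 1`.
#'
#' @inheritParams digestProtein
#' @return Integer vector of cut positions (possibly empty).
#' @export
cleavageSites <- function(sequence,
                          enzyme = c("lysc_then_trypsin", "trypsin", "lysc")) {
    enzyme <- match.arg(enzyme)
    chars <- .checkSequence(sequence)
    n <- length(chars)
    if (n < 2L) {
        return(integer(0))
    }
    res <- chars[-n]
    nxt <- chars[-1]
    cut <- switch(enzyme,
        trypsin = (res == "K" | res == "R") & nxt != "P",
        lysc = res == "K",
        lysc_then_trypsin = res == "K" | (res == "R" & nxt != "P")
    )
    which(cut)
}
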