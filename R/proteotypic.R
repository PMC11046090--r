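#' Peptide selection rules
#'
#' Filtering and ranking rules for proteotypic peptide candidates. A
#' candidate must be a fully cleaved digest product of its protein, fall
#' within the length bounds, end in K/R when `requireCtermKR`, match none
#' of the exclusion motifs, and occur exactly once in the whole proteome
#' digest (the proteotypic requirement). The default motifs exclude
#' methionine-containing peptides (oxidation-prone) and N-terminal
#' glutamine (pyro-Glu formation).
#'
#' @param minLength,maxLength Allowed peptide length in residues
#'   (defaults 7 and 20; bounds 5 and 30 are enforced).
#' @param requireCtermKR Require a C-terminal K or R (default `TRUE`);
#'   needed for heavy-label internal standards.
#' @param excludeMotifs Character vector of regular expressions; a
#'   candidate matching any is excluded. Default `c("M", "^Q")`.
#' @param maxPeptidesPerProtein Peptides to keep per protein (default 1).
#' @return A list of class `"SelectionRules"`.
#' @export
selectionRules <- function(minLength = 7L, maxLength = 20L,
                           requireCtermKR = TRUE,
                           excludeMotifs = c("M", "^Q"),
                           maxPeptidesPerProtein = 1L) {
    stopifnot(minLength >= 5L, maxLength <= 30L, minLength <= maxLength,
        maxPeptidesPerProtein >= 1L)
    structure(list(
        minLength = as.integer(minLength),
        maxLength = as.integer(maxLength),
        requireCtermKR = isTRUE(requireCtermKR),
        excludeMotifs = excludeMotifs,
        maxPeptidesPerProtein = as.integer(maxPeptidesPerProtein)
    ), class = "SelectionRules")
}

#' Select proteotypic peptides for target proteins
#'
#' Digests every protein of the proteome in silico, keeps for each target
#' the fully cleaved peptides that satisfy the [selectionRules()] and are
#' unique to that protein across the whole proteome, and ranks survivors
#' deterministically (length closest to 12 residues, then alphabetically).
#' Targets yielding no candidate are reported, never silently dropped.
#'
#' @param proteome A named character vector or
#'   [Biostrings::AAStringSet] of protein sequences.
#' @param targets Character vector of protein identifiers to cover; all
#'   must be present in `proteome`.
#' @param rules A [selectionRules()] list.
#' @param enzyme Digestion enzyme (default `"lysc_then_trypsin"`).
#' @return A list with `selection` (data.frame `proteinId`, `peptide`,
#'   `rank`) and `failures` (data.frame `proteinId`, `reason`).
#' @export
selectProteotypic <- function(proteome, targets, rules = selectionRules(),
                              enzyme = "lysc_then_trypsin") {
    seqs <- .asProteome(proteome)
    missing <- setdiff(targets, names(seqs))
    if (length(missing)) {
        stop("target IDs absent from proteome: ",
            paste(missing, collapse = ", "), call. = FALSE)
    }
    digests <- lapply(seqs, function(s) {
        digestProtein(s, enzyme, maxMissedCleavages = 0L)$peptide
    })
    # occurrence count of each peptide across the whole proteome digest
    allPeps <- unlist(digests, use.names = FALSE)
    occ <- table(allPeps)

    selRows <- list()
    failRows <- list()
    for (id in targets) {
        cand <- digests[[id]]
        reason <- NULL
        len <- nchar(cand)
        cand <- cand[len >= rules$minLength & len <= rules$maxLength]
        if (rules$requireCtermKR && length(cand)) {
            cand <- cand[substring(cand, nchar(cand)) %in% c("K", "R")]
        }
        if (length(cand)) {
            for (motif in rules$excludeMotifs) {
                cand <- cand[!grepl(motif, cand)]
            }
        }
        if (length(cand)) {
            cand <- unique(cand[occ[cand] == 1L])
            if (!length(cand)) reason <- "no proteome-unique peptide"
        } else {
            reason <- "no candidate passing length/terminus/motif rules"
        }
        if (is.null(reason)) {
            ord <- order(abs(nchar(cand) - 12L), cand)
            keep <- cand[ord][seq_len(min(rules$maxPeptidesPerProtein,
                length(cand)))]
            selRows[[id]] <- data.frame(proteinId = id, peptide = keep,
                rank = seq_along(keep), stringsAsFactors = FALSE)
        } else {
            failRows[[id]] <- data.frame(proteinId = id, reason = reason,
                stringsAsFactors = FALSE)
        }
    }
    list(
        selection = if (length(selRows)) {
            do.call(rbind, c(selRows, list(make.row.names = FALSE)))
        } else {
            data.frame(proteinId = character(0), peptide = character(0),
                rank = integer(0))
        },
        failures = if (length(failRows)) {
            do.call(rbind, c(failRows, list(make.row.names = FALSE)))
        } else {
            data.frame(proteinId = character(0), reason = character(0))
        }
    )
}

.asProteome <- function(proteome) {
    if (methods::is(proteome, "AAStringSet")) {
        proteome <- stats::setNames(as.character(proteome), names(proteome))
    }
    if (!is.character(proteome) || is.null(names(proteome)) ||
        any(!nzchar(names(proteome)))) {
        stop("proteome must be a named character vector or AAStringSet",
            call. = FALSE)
    }
    proteome
}

#' Read a proteome FASTA
#'
#' Thin wrapper over [Biostrings::readAAStringSet()] returning a named
#' character vector keyed by the first token of each description line.
#'
#' @param path FASTA file path.
#' @return Named character vector of protein sequences.
#' @export
readProteome <- function(path) {
    aa <- Biostrings::readAAStringSet(path)
    ids <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1L)
    stats::setNames(as.character(aa), ids)
}

#' Write sequences as FASTA
#'
#' @param sequences Named character vector.
#' @param path Output path; lines wrapped at 60 residues.
#' @export
writeFasta <- function(sequences, path) {
    aa <- Biostrings::AAStringSet(sequences)
    Biostrings::writeXStringSet(aa, path, width = 60L)
    invisible(path)
}
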