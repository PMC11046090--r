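#' Assemble QconCAT constructs from proteotypic peptides
#'
#' Packs K/R-terminated peptides into `ceiling(n / capacity)` artificial
#' concatamer constructs of at most `capacity` peptides each (the design
#' links roughly 50 proteotypic peptides per construct). Within a
#' construct, peptide order is permuted only when needed to resolve
#' junction conflicts: a peptide ending in R followed by one starting with
#' P would create an uncleavable R|P junction, so P-starting peptides are
#' greedily placed after K-ending ones. If no conflict-free order exists
#' the assembly fails hard (no silent spacer insertion by default); a
#' single `spacer` residue may be supplied to separate irreconcilable
#' junctions.
#'
#' @param peptideSeqs Character vector of peptide sequences, each ending
#'   in K or R.
#' @param capacity Maximum peptides per construct (default 50, minimum 2).
#' @param nTermTag,cTermTag Optional terminal tag sequences applied to
#'   every construct.
#' @param spacer Optional single residue inserted before a P-starting
#'   peptide when reordering cannot avoid an R|P junction. Default `""`
#'   (disabled; unresolvable conflicts are an error).
#' @param idPrefix Construct identifier prefix (default `"QC"`).
#' @return List of [QconCAT-class] objects, each passing
#'   [validateQconcat()].
#' @examples
#' qcs <- assembleQconcat(c("SAMPLEK", "PEPTIDER"))
#' fullSequence(qcs[[1]])
#' @export
assembleQconcat <- function(peptideSeqs, capacity = 50L,
                            nTermTag = "", cTermTag = "",
                            spacer = "", idPrefix = "QC") {
    if (capacity < 2L) {
        stop("capacity must be >= 2", call. = FALSE)
    }
    if (anyDuplicated(peptideSeqs)) {
        stop("duplicate peptides cannot be quantified unambiguously",
            call. = FALSE)
    }
    cterm <- substring(peptideSeqs, nchar(peptideSeqs))
    bad <- peptideSeqs[!cterm %in% c("K", "R")]
    if (length(bad)) {
        stop("peptides must end in K or R to be released by digestion: ",
            paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
    nConstructs <- ceiling(length(peptideSeqs) / capacity)
    chunkIdx <- rep(seq_len(nConstructs), each = capacity,
        length.out = length(peptideSeqs))
    fmt <- paste0(idPrefix, "%0", max(2L, nchar(nConstructs)), "d")
    lapply(seq_len(nConstructs), function(i) {
        chunk <- peptideSeqs[chunkIdx == i]
        ordered <- .orderJunctionSafe(chunk, spacer)
        QconCAT(ordered, constructId = sprintf(fmt, i),
            nTermTag = nTermTag, cTermTag = cTermTag)
    })
}

# Junction-safe ordering: after an R-terminated peptide the next peptide
# must not start with P. Input order is kept when it is already free of
# conflicts; otherwise a greedy pass places P-starters after K-enders.
# Deterministic: input order within preference classes.
.orderJunctionSafe <- function(chunk, spacer = "") {
    if (length(chunk) < 2L || !any(.junctionConflicts(chunk))) {
        return(chunk)
    }
    remaining <- chunk
    out <- character(0)
    prevEnd <- ""
    while (length(remaining)) {
        allowed <- if (prevEnd == "R") {
            which(!startsWith(remaining, "P"))
        } else {
            seq_along(remaining)
        }
        if (!length(allowed)) {
            if (nzchar(spacer)) {
                # neutral spacer residue restores a cleavable junction
                remaining[1] <- paste0(spacer, remaining[1])
                allowed <- 1L
            } else {
                stop("unresolvable R|P junction conflict in construct ",
                    "assembly (peptides starting with P exceed K-ended ",
                    "predecessors); supply a spacer residue", call. = FALSE)
            }
        }
        pStartLeft <- any(startsWith(remaining[allowed], "P"))
        pick <- if (pStartLeft) {
            p <- allowed[startsWith(remaining[allowed], "P")]
            p[1]
        } else {
            # keep K-enders in reserve while P-starters remain elsewhere
            kEnd <- allowed[substring(remaining[allowed],
                nchar(remaining[allowed])) == "K"]
            if (any(startsWith(remaining, "P")) && length(kEnd)) {
                kEnd[1]
            } else {
                allowed[1]
            }
        }
        out <- c(out, remaining[pick])
        prevEnd <- substring(remaining[pick], nchar(remaining[pick]))
        remaining <- remaining[-pick]
    }
    out
}

#' Validate that a construct releases every peptide intact
#'
#' Digests the construct's full sequence in silico and checks that every
#' designed peptide appears exactly once among the fully cleaved
#' fragments. Junctions whose cleavage is suppressed (R followed by P) are
#' reported.
#'
#' @param x A [QconCAT-class] object, or a list with elements `peptides`,
#'   `nTermTag`, `cTermTag` (used internally before validity is
#'   established).
#' @param enzyme Digestion enzyme (default `"lysc_then_trypsin"`).
#' @return List with `pass` (logical), `peptideReport` (data.frame
#'   `peptide`, `released`, `ok`) and `junctions` (data.frame `position`,
#'   `context`, `cleaved`).
#' @examples
#' validateQconcat(QconCAT(c("SAMPLEK", "PEPTIDER")))$pass
#' @export
validateQconcat <- function(x, enzyme = "lysc_then_trypsin") {
    if (methods::is(x, "QconCAT")) {
        peps <- x@peptides
        nTag <- x@nTermTag
        cTag <- x@cTermTag
    } else {
        peps <- x$peptides
        nTag <- x$nTermTag %||% ""
        cTag <- x$cTermTag %||% ""
    }
    full <- paste0(nTag, paste(peps, collapse = ""), cTag)
    released <- digestProtein(full, enzyme, maxMissedCleavages = 0L)$peptide
    counts <- vapply(peps, function(p) sum(released == p), integer(1))
    peptideReport <- data.frame(
        peptide = peps, released = unname(counts),
        ok = unname(counts == 1L), stringsAsFactors = FALSE
    )
    # junction positions: boundary after each peptide (within the core)
    ends <- nchar(nTag) + cumsum(nchar(peps))
    ends <- ends[seq_len(length(peps) - 1L)]
    if (length(peps) > 1L) {
        sites <- cleavageSites(full, enzyme)
        ctx <- paste0(substring(full, ends, ends), "|",
            substring(full, ends + 1L, ends + 1L))
        junctions <- data.frame(position = ends, context = ctx,
            cleaved = ends %in% sites, stringsAsFactors = FALSE)
    } else {
        junctions <- data.frame(position = integer(0),
            context = character(0), cleaved = logical(0))
    }
    list(pass = all(peptideReport$ok), peptideReport = peptideReport,
        junctions = junctions)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# TRUE at position i when peptide i ends in R and peptide i+1 starts in P
.junctionConflicts <- function(chunk) {
    n <- length(chunk)
    substring(chunk[-n], nchar(chunk[-n])) == "R" &
        startsWith(chunk[-1], "P")
}

#' Write a construct manifest
#'
#' One row per peptide: `protein_id` (if a selection table is given),
#' `peptide`, `construct_id`, `position`.
#'
#' @param constructs List of [QconCAT-class] objects.
#' @param path Output CSV path.
#' @param selection Optional selection data.frame (`proteinId`,
#'   `peptide`) used to annotate the source protein.
#' @return The manifest data.frame, invisibly written to `path`.
#' @export
writeConstructManifest <- function(constructs, path, selection = NULL) {
    rows <- lapply(constructs, function(qc) {
        data.frame(
            protein_id = NA_character_,
            peptide = peptides(qc),
            construct_id = constructId(qc),
            position = seq_along(peptides(qc)),
            stringsAsFactors = FALSE
        )
    })
    manifest <- do.call(rbind, rows)
    if (!is.null(selection)) {
        idx <- match(manifest$peptide, selection$peptide)
        manifest$protein_id <- selection$proteinId[idx]
    }
    utils::write.csv(manifest, path, row.names = FALSE)
    invisible(manifest)
}
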