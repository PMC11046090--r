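#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' QconCAT artificial concatamer
#'
#' An artificial protein formed by linking proteotypic peptides head to
#' tail (optionally between terminal tags, e.g. an affinity tag used for
#' Ni-resin purification). Expressed with heavy lysine/arginine and spiked
#' into samples as the internal standard: on digestion it releases one
#' labelled copy of every peptide. Validity requires that every peptide is
#' released intact exactly once by a LysC-then-trypsin digest of the full
#' sequence.
#'
#' @slot constructId Single identifier string.
#' @slot peptides Ordered character vector of peptide sequences.
#' @slot nTermTag,cTermTag Optional terminal tag sequences (may be `""`);
#'   tags are excluded from quantification.
#' @aliases QconCAT
#' @exportClass QconCAT
setClass("QconCAT",
    representation(
        constructId = "character",
        peptides = "character",
        nTermTag = "character",
        cTermTag = "character"
    ),
    prototype(nTermTag = "", cTermTag = "")
)

setValidity("QconCAT", function(object) {
    if (length(object@constructId) != 1L || !nzchar(object@constructId)) {
        return("constructId must be a single non-empty string")
    }
    if (length(object@peptides) < 1L) {
        return("a construct must contain at least one peptide")
    }
    cterm <- substring(object@peptides, nchar(object@peptides))
    if (!all(cterm %in% c("K", "R"))) {
        return("every peptide must end in K or R")
    }
    rep <- validateQconcat(object)
    if (!rep$pass) {
        return(paste0("digestion does not release every peptide exactly ",
            "once: ", paste(rep$peptideReport$peptide[!rep$peptideReport$ok],
                collapse = ", ")))
    }
    TRUE
})

#' Construct a QconCAT object
#'
#' @param peptides Ordered character vector of K/R-terminated peptides.
#' @param constructId Identifier (default `"QC01"`).
#' @param nTermTag,cTermTag Optional terminal tags.
#' @return A validated [QconCAT-class] object.
#' @examples
#' qc <- QconCAT(c("SAMPLEK", "PEPTIDER"))
#' fullSequence(qc)
#' @export
QconCAT <- function(peptides, constructId = "QC01",
                    nTermTag = "", cTermTag = "") {
    new("QconCAT", constructId = constructId, peptides = peptides,
        nTermTag = nTermTag, cTermTag = cTermTag)
}

#' @describeIn QconCAT-class peptides in construct order
#' @param object,x A `QconCAT` object.
#' @export
setGeneric("peptides", function(x) standardGeneric("peptides"))

#' @rdname QconCAT-class
#' @export
setMethod("peptides", "QconCAT", function(x) x@peptides)

#' @describeIn QconCAT-class the full artificial protein sequence
#'   (N-terminal tag, peptides in order, C-terminal tag)
#' @export
setGeneric("fullSequence", function(x) standardGeneric("fullSequence"))

#' @rdname QconCAT-class
#' @export
setMethod("fullSequence", "QconCAT", function(x) {
    paste0(x@nTermTag, paste(x@peptides, collapse = ""), x@cTermTag)
})

#' @describeIn QconCAT-class construct identifier
#' @export
setGeneric("constructId", function(x) standardGeneric("constructId"))

#' @rdname QconCAT-class
#' @export
setMethod("constructId", "QconCAT", function(x) x@constructId)

setMethod("show", "QconCAT", function(object) {
    cat("QconCAT construct", object@constructId, "\n")
    cat(" ", length(object@peptides), "peptides,",
        nchar(fullSequence(object)), "residues\n")
    if (nzchar(object@nTermTag) || nzchar(object@cTermTag)) {
        cat("  tags:", object@nTermTag, "/", object@cTermTag, "\n")
    }
})

#' Scheduled-MRM chromatogram set
#'
#' Long-format time/intensity traces for every (transition, label) pair of
#' a scheduled acquisition, together with the acquisition settings and —
#' for simulated data — the generating ground truth.
#'
#' @slot traces data.frame with columns `transition_id`, `label`
#'   (`"light"`/`"heavy"`), `time_min`, `intensity`.
#' @slot settings Acquisition settings list (see [assaySettings()]).
#' @slot truth Simulation ground truth (a [simTruth()] list) or an empty
#'   list for measured data.
#' @aliases ChromatogramSet
#' @exportClass ChromatogramSet
setClass("ChromatogramSet",
    representation(traces = "data.frame", settings = "list", truth = "list")
)

setValidity("ChromatogramSet", function(object) {
    tr <- object@traces
    need <- c("transition_id", "label", "time_min", "intensity")
    if (!all(need %in% names(tr))) {
        return(paste("traces must have columns:", paste(need, collapse = ", ")))
    }
    if (nrow(tr)) {
        if (any(tr$intensity < 0)) {
            return("intensities must be non-negative")
        }
        if (!all(tr$label %in% c("light", "heavy"))) {
            return("label must be 'light' or 'heavy'")
        }
        bad <- vapply(split(tr$time_min, paste(tr$transition_id, tr$label)),
            function(t) any(diff(t) <= 0), logical(1))
        if (any(bad)) {
            return("times must be strictly increasing within each trace")
        }
        keys <- unique(tr[, c("transition_id", "label")])
        light <- keys$transition_id[keys$label == "light"]
        heavy <- keys$transition_id[keys$label == "heavy"]
        if (!setequal(light, heavy)) {
            return("every light trace must have a heavy sibling")
        }
    }
    TRUE
})

#' @describeIn ChromatogramSet-class the long-format trace table
#' @param object,x A `ChromatogramSet`.
#' @export
setGeneric("traces", function(x) standardGeneric("traces"))

#' @rdname ChromatogramSet-class
#' @export
setMethod("traces", "ChromatogramSet", function(x) x@traces)

#' @describeIn ChromatogramSet-class the simulation ground truth (empty
#'   list for measured data)
#' @export
setGeneric("simulationTruth", function(x) standardGeneric("simulationTruth"))

#' @rdname ChromatogramSet-class
#' @export
setMethod("simulationTruth", "ChromatogramSet", function(x) x@truth)

setMethod("show", "ChromatogramSet", function(object) {
    keys <- unique(object@traces[, c("transition_id", "label")])
    cat("ChromatogramSet:", nrow(keys), "traces,",
        nrow(object@traces), "points\n")
    if (length(object@truth)) {
        cat("  simulated (seed ", object@truth$seed, ")\n", sep = "")
    }
})

#' Three-group study matrix
#'
#' An analyte-by-sample abundance matrix with per-sample group labels,
#' stored as a [SummarizedExperiment::SummarizedExperiment] with one assay
#' `"abundance"`, `colData$group`, and (for simulated studies) the planted
#' effect table in `metadata(x)$planted`. Emulates a three-genotype design
#' (e.g. wild type, hemizygous and homozygous transgenics).
#'
#' @aliases StudyMatrix
#' @exportClass StudyMatrix
setClass("StudyMatrix", contains = "SummarizedExperiment")

setValidity("StudyMatrix", function(object) {
    cd <- SummarizedExperiment::colData(object)
    if (!"group" %in% names(cd)) {
        return("colData must contain a 'group' column")
    }
    if (any(is.na(cd$group))) {
        return("no missing group labels allowed")
    }
    planted <- S4Vectors::metadata(object)$planted
    if (!is.null(planted) && nrow(planted)) {
        if (!all(planted$analyte %in% rownames(object))) {
            return("planted table references unknown analytes")
        }
        if (!all(planted$group %in% as.character(cd$group))) {
            return("planted table references unknown groups")
        }
    }
    TRUE
})

#' Construct a StudyMatrix
#'
#' @param values Numeric matrix, analytes in rows, samples in columns.
#' @param groups Group label per sample (length `ncol(values)`).
#' @param planted Optional data.frame (`analyte`, `group`, `foldChange`)
#'   recording effects planted by the simulator.
#' @return A [StudyMatrix-class] object.
#' @export
StudyMatrix <- function(values, groups, planted = NULL) {
    if (ncol(values) != length(groups)) {
        stop("one group label per sample column required", call. = FALSE)
    }
    if (is.null(rownames(values))) {
        rownames(values) <- sprintf("analyte%04d", seq_len(nrow(values)))
    }
    if (is.null(colnames(values))) {
        colnames(values) <- sprintf("%s_%d", groups,
            stats::ave(seq_along(groups), groups, FUN = seq_along))
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(abundance = values),
        colData = S4Vectors::DataFrame(group = as.character(groups))
    )
    md <- list(planted = if (is.null(planted)) {
        data.frame(analyte = character(0), group = character(0),
            foldChange = numeric(0))
    } else {
        planted
    })
    S4Vectors::metadata(se) <- md
    new("StudyMatrix", se)
}

#' @describeIn StudyMatrix-class per-sample group labels
#' @param object,x A `StudyMatrix`.
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))

#' @rdname StudyMatrix-class
#' @export
setMethod("groupLabels", "StudyMatrix", function(x) {
    as.character(SummarizedExperiment::colData(x)$group)
})

#' @describeIn StudyMatrix-class the planted-effect table
#' @export
setGeneric("plantedEffects", function(x) standardGeneric("plantedEffects"))

#' @rdname StudyMatrix-class
#' @export
setMethod("plantedEffects", "StudyMatrix", function(x) {
    S4Vectors::metadata(x)$planted
})

#' @describeIn StudyMatrix-class the abundance matrix
#' @export
abundances <- function(x) {
    SummarizedExperiment::assay(x, "abundance")
}

setMethod("show", "StudyMatrix", function(object) {
    g <- table(groupLabels(object))
    cat("StudyMatrix:", nrow(object), "analytes x", ncol(object),
        "samples\n  groups:",
        paste(sprintf("%s (n=%d)", names(g), as.integer(g)), collapse = ", "),
        "\n")
    pl <- plantedEffects(object)
    if (!is.null(pl) && nrow(pl)) {
        cat("  planted effects:", nrow(pl), "\n")
    }
})
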