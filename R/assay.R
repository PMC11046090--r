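#' Instrument parameter equations
#'
#' Per-transition voltages of the triple-quadrupole acquisition are linear
#' functions of the precursor (Q1) and fragment (Q3) m/z:
#'
#' * declustering potential: `DP = 0.049 * Q1 + 42.6`
#' * collision energy: `CE = 0.036 * Q1 + 6.9` for 2+ precursors and
#'   `CE = 0.054 * Q1 - 2.4` for 3+ precursors
#' * collision cell exit potential: `CXP = 0.0391 * Q3 - 2.23`
#' * entrance potential: constant `EP = 10`
#'
#' `collisionCellExitPotential()` goes non-positive below Q3 of about
#' 57 m/z (smaller than any plausible fragment); such values are returned
#' with a warning rather than rejected.
#'
#' @param q1,q3 Precursor / fragment m/z (must be positive).
#' @param charge Precursor charge state, 2 or 3 (the only charge states
#'   with a defined collision-energy ramp).
#' @return Voltage (numeric vector).
#' @examples
#' declusteringPotential(500) # 67.1
#' collisionEnergy(600, 2) # 28.5
#' collisionCellExitPotential(400) # 13.41
#' @name instrumentParameters
NULL

#' @rdname instrumentParameters
#' @export
declusteringPotential <- function(q1) {
    if (any(q1 <= 0)) stop("q1 must be positive", call. = FALSE)
    0.049 * q1 + 42.6
}

#' @rdname instrumentParameters
#' @export
collisionEnergy <- function(q1, charge) {
    if (any(q1 <= 0)) stop("q1 must be positive", call. = FALSE)
    if (!all(charge %in% c(2L, 3L))) {
        stop("collision energy is defined for 2+ and 3+ precursors only",
            call. = FALSE)
    }
    ifelse(charge == 2L, 0.036 * q1 + 6.9, 0.054 * q1 - 2.4)
}

#' @rdname instrumentParameters
#' @export
collisionCellExitPotential <- function(q3) {
    if (any(q3 <= 0)) stop("q3 must be positive", call. = FALSE)
    cxp <- 0.0391 * q3 - 2.23
    if (any(cxp <= 0)) {
        warning("CXP non-positive for q3 <= 57.0 m/z; value returned as-is")
    }
    cxp
}

#' Scheduled-MRM acquisition settings
#'
#' @param targetScanTime Cycle time in seconds (default 1).
#' @param detectionWindow Scheduled detection window in seconds
#'   (default 120; each transition is acquired for `predicted RT` +/-
#'   half this window).
#' @param minTransitions Minimum transitions monitored per peptide
#'   (default and floor 3).
#' @param resolution Q1/Q3 resolution label, recorded as metadata only
#'   (default `"unit (0.7 Da half-width)"`).
#' @param overheadMs Per-transition cycle overhead in milliseconds used in
#'   dwell-time accounting (default 2).
#' @param dwellFloorMs Dwell time under which a scheduling warning is
#'   raised (default 5 ms).
#' @return A list of class `"AssaySettings"`.
#' @export
assaySettings <- function(targetScanTime = 1, detectionWindow = 120,
                          minTransitions = 3L,
                          resolution = "unit (0.7 Da half-width)",
                          overheadMs = 2, dwellFloorMs = 5) {
    stopifnot(targetScanTime > 0, detectionWindow > 0, minTransitions >= 3L)
    structure(list(
        targetScanTime = targetScanTime,
        detectionWindow = detectionWindow,
        minTransitions = as.integer(minTransitions),
        resolution = resolution,
        overheadMs = overheadMs,
        dwellFloorMs = dwellFloorMs,
        ep = 10
    ), class = "AssaySettings")
}

#' Build light/heavy MRM transitions for one peptide
#'
#' Chooses `minTransitions` y-ions from the candidate series y3 ... y(L-1)
#' (highest index first: longer y-ions are more sequence-specific), at 1+
#' fragment charge. The precursor is monitored at 2+ unless its 2+ m/z
#' exceeds 1250, in which case 3+ is used. Every light transition gets a
#' heavy partner whose Q1 (and, for y-ions, Q3) is shifted by the
#' C-terminal label shift divided by the charge. DP/CE/CXP are filled from
#' the instrument parameter equations and EP is 10.
#'
#' @param sequence Peptide sequence (length >= 6 so that at least three
#'   informative y-ions exist), ending in K or R.
#' @param proteinId Optional protein identifier carried through.
#' @param rt Predicted retention time in minutes (may be `NA`; scheduling
#'   then fails until an RT table is supplied).
#' @param settings An [assaySettings()] list.
#' @return data.frame with one row per (fragment, label):
#'   `transition_id`, `protein_id`, `peptide`, `label`,
#'   `precursor_charge`, `q1`, `fragment`, `q3`, `dp`, `ce`, `cxp`, `ep`,
#'   `rt`, `window_start`, `window_end`.
#' @examples
#' tr <- buildTransitions("LVNELTEFAK", rt = 10)
#' subset(tr, label == "light")$fragment
#' @export
buildTransitions <- function(sequence, proteinId = NA_character_,
                             rt = NA_real_, settings = assaySettings()) {
    chars <- .checkSequence(sequence, "peptide")
    L <- length(chars)
    if (L < 6L) {
        stop("peptide too short for >= 3 informative y-ions (length >= 6 ",
            "required): ", sequence, call. = FALSE)
    }
    if (!chars[L] %in% c("K", "R")) {
        stop("peptide must end in K or R for heavy-label pairing: ",
            sequence, call. = FALSE)
    }
    yIdx <- seq(L - 1L, 3L)
    yIdx <- yIdx[seq_len(min(settings$minTransitions, length(yIdx)))]
    charge <- if (precursorMz(sequence, 2L, "light") > 1250) 3L else 2L
    halfWin <- settings$detectionWindow / 60 / 2
    rows <- lapply(c("light", "heavy"), function(lab) {
        q1 <- precursorMz(sequence, charge, lab)
        q3 <- vapply(yIdx, function(i) {
            fragmentMz(sequence, "y", i, 1L, lab)
        }, numeric(1))
        data.frame(
            transition_id = sprintf("%s.%d.y%d", sequence, charge, yIdx),
            protein_id = proteinId,
            peptide = sequence,
            label = lab,
            precursor_charge = charge,
            q1 = q1,
            fragment = sprintf("y%d", yIdx),
            q3 = q3,
            dp = declusteringPotential(q1),
            ce = collisionEnergy(q1, charge),
            cxp = collisionCellExitPotential(q3),
            ep = settings$ep,
            rt = rt,
            window_start = rt - halfWin,
            window_end = rt + halfWin,
            stringsAsFactors = FALSE
        )
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Build a transition table for many peptides
#'
#' @param peptideSeqs Character vector of peptide sequences.
#' @param rtTable data.frame with columns `peptide` and `rt` (minutes)
#'   supplying predicted retention times; no RT prediction model is used.
#' @param proteinIds Optional protein identifier per peptide.
#' @param settings An [assaySettings()] list.
#' @return Combined transition data.frame (see [buildTransitions()]).
#' @export
buildAssay <- function(peptideSeqs, rtTable, proteinIds = NULL,
                       settings = assaySettings()) {
    if (is.null(proteinIds)) proteinIds <- rep(NA_character_,
        length(peptideSeqs))
    rt <- rtTable$rt[match(peptideSeqs, rtTable$peptide)]
    if (any(is.na(rt))) {
        stop("missing retention times for: ",
            paste(utils::head(peptideSeqs[is.na(rt)], 5), collapse = ", "),
            call. = FALSE)
    }
    out <- do.call(rbind, Map(buildTransitions, peptideSeqs, proteinIds, rt,
        MoreArgs = list(settings = settings)))
    rownames(out) <- NULL
    out
}

#' Schedule an assay and report concurrency
#'
#' Each transition is acquired only within `rt +/- detectionWindow/2`.
#' The report sweeps the window endpoints to find the maximum number of
#' concurrently acquired transitions and the per-transition dwell time at
#' that load, `dwell = (scanTime - n * overhead) / n` (milliseconds). A
#' warning lists crowded time regions whose dwell falls below the floor.
#'
#' @param transitions Transition data.frame from [buildAssay()].
#' @param settings An [assaySettings()] list.
#' @return List with `transitions` (input, windows recomputed),
#'   `maxConcurrent`, `dwellMs` (dwell at peak load), and `profile`
#'   (data.frame `time_min`, `concurrent`, `dwell_ms` at window event
#'   points).
#' @export
scheduleAssay <- function(transitions, settings = assaySettings()) {
    if (any(is.na(transitions$rt))) {
        stop("every transition needs a predicted retention time",
            call. = FALSE)
    }
    halfWin <- settings$detectionWindow / 60 / 2
    transitions$window_start <- transitions$rt - halfWin
    transitions$window_end <- transitions$rt + halfWin
    starts <- transitions$window_start
    ends <- transitions$window_end
    evTimes <- sort(unique(starts))
    concurrent <- vapply(evTimes, function(t) {
        sum(starts <= t & ends > t)
    }, numeric(1))
    scanMs <- settings$targetScanTime * 1000
    dwell <- (scanMs - concurrent * settings$overheadMs) / concurrent
    profile <- data.frame(time_min = evTimes, concurrent = concurrent,
        dwell_ms = dwell)
    maxConcurrent <- if (length(concurrent)) max(concurrent) else 0
    dwellAtPeak <- if (maxConcurrent > 0) {
        (scanMs - maxConcurrent * settings$overheadMs) / maxConcurrent
    } else {
        NA_real_
    }
    crowded <- profile[profile$dwell_ms < settings$dwellFloorMs, ,
        drop = FALSE]
    if (nrow(crowded)) {
        warning(sprintf(
            "dwell time below %.1f ms in %d window region(s); worst: %.2f ms at %.2f min",
            settings$dwellFloorMs, nrow(crowded), min(crowded$dwell_ms),
            crowded$time_min[which.min(crowded$dwell_ms)]))
    }
    list(transitions = transitions, maxConcurrent = maxConcurrent,
        dwellMs = dwellAtPeak, profile = profile)
}

#' Acylcarnitine precursor-ion-scan parameters
#'
#' Acylcarnitines are profiled by a precursor-ion scan for the common
#' product at m/z 85.05, with the collision energy set by acyl chain
#' length: -20 V for short chains (C0-C8), -25 V for middle chains
#' (C10:1-C14:OH), -35 V for long chains (C16-C18:OH). Chain lengths 9
#' and 15, which fall between the printed class ranges, are assigned to
#' the middle and long class respectively (thresholds <= 8, <= 14,
#' <= 18).
#'
#' @param species Character vector of acylcarnitine labels such as
#'   `"C4"`, `"C12:1"`, `"C14:OH"` or `"C16-OH"` (carbon count 0-18,
#'   optional unsaturation `:n` and hydroxyl `OH` suffixes).
#' @return data.frame with columns `species`, `carbons`, `product_mz`
#'   (always 85.05) and `ce` (volts, negative ion mode).
#' @examples
#' acylcarnitineCE(c("C4", "C12:1", "C16"))
#' @export
acylcarnitineCE <- function(species) {
    m <- regmatches(species,
        regexec("^C([0-9]{1,2})(:[0-9]+)?([-:]?OH)?$", species))
    carbons <- vapply(seq_along(species), function(i) {
        if (length(m[[i]]) == 0) {
            stop("unparsable acylcarnitine label: ", species[i],
                call. = FALSE)
        }
        as.integer(m[[i]][2])
    }, integer(1))
    if (any(carbons > 18L)) {
        stop("acyl chain length outside 0-18: ",
            paste(species[carbons > 18L], collapse = ", "), call. = FALSE)
    }
    ce <- ifelse(carbons <= 8L, -20, ifelse(carbons <= 14L, -25, -35))
    data.frame(species = species, carbons = carbons, product_mz = 85.05,
        ce = ce, stringsAsFactors = FALSE)
}

.TRANSITION_COLUMNS <- c("protein_id", "peptide", "label",
    "precursor_charge", "q1", "fragment", "q3", "dp", "ce", "cxp", "ep",
    "rt", "window_start", "window_end")

#' Transition list CSV input/output
#'
#' Writes the transition table with a fixed column order
#' (`protein_id, peptide, label, precursor_charge, q1, fragment, q3, dp,
#' ce, cxp, ep, rt, window_start, window_end`) at full double precision,
#' and reads it back losslessly (the `transition_id` is reconstructed
#' from peptide, charge and fragment).
#'
#' @param transitions Transition data.frame.
#' @param path CSV path.
#' @return `writeTransitionList()` returns `path` invisibly;
#'   `readTransitionList()` returns the transition data.frame.
#' @name transitionIO
NULL

#' @rdname transitionIO
#' @export
writeTransitionList <- function(transitions, path) {
    out <- transitions[, .TRANSITION_COLUMNS]
    utils::write.csv(format(out, digits = 17, trim = TRUE,
        scientific = FALSE), path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname transitionIO
#' @export
readTransitionList <- function(path) {
    tr <- utils::read.csv(path, stringsAsFactors = FALSE,
        colClasses = c(protein_id = "character", peptide = "character",
            label = "character", fragment = "character"))
    tr$transition_id <- sprintf("%s.%d.%s", tr$peptide,
        tr$precursor_charge, tr$fragment)
    tr[, c("transition_id", .TRANSITION_COLUMNS)]
}
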