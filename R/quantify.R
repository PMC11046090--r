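#' Integrate a chromatographic peak
#'
#' Trapezoidal integral of a trace above a flat baseline estimated as the
#' mean of the first and last `k` samples inside the window. On short
#' traces `k` is shrunk (`k_eff = max(1, min(k, floor(n/3)))`) so the
#' baseline never swallows the peak itself. Negative baseline-subtracted
#' intensities are clamped at zero, so the area is never negative.
#'
#' @param time,intensity Numeric vectors of the trace (minutes, counts).
#' @param window Optional `c(start, end)` in minutes restricting the
#'   integration; default the full trace.
#' @param k Number of edge samples per side for the baseline (default 3).
#' @return Area in intensity x minutes.
#' @examples
#' integratePeak(c(0, 1, 2), c(0, 10, 0)) # 10
#' @export
integratePeak <- function(time, intensity, window = NULL, k = 3L) {
    if (!is.null(window)) {
        keep <- time >= window[1] & time <= window[2]
        time <- time[keep]
        intensity <- intensity[keep]
    }
    n <- length(time)
    if (n < 3L) {
        stop("at least 3 samples required inside the window", call. = FALSE)
    }
    kEff <- max(1L, min(as.integer(k), n %/% 3L))
    baseline <- mean(c(intensity[seq_len(kEff)],
        intensity[seq(n - kEff + 1L, n)]))
    y <- pmax(intensity - baseline, 0)
    sum(diff(time) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Ratio dot product
#'
#' Normalised dot product `(x . y) / (|x| |y|)` between the light and
#' heavy per-transition peak-area vectors. Equals 1 when the endogenous
#' peak's fragmentation pattern matches the internal standard's exactly;
#' interference on individual transitions pulls it down. A zero-norm
#' vector yields 0 (with the QC failure left to the caller).
#'
#' @param lightAreas,heavyAreas Equal-length numeric vectors (length >= 2)
#'   of non-negative per-transition areas.
#' @return Value in `[0, 1]`.
#' @examples
#' rdotp(c(3, 4), c(4, 3)) # 0.96
#' @export
rdotp <- function(lightAreas, heavyAreas) {
    if (length(lightAreas) != length(heavyAreas) ||
        length(lightAreas) < 2L) {
        stop("area vectors must have equal length >= 2", call. = FALSE)
    }
    nl <- sqrt(sum(lightAreas^2))
    nh <- sqrt(sum(heavyAreas^2))
    if (nl == 0 || nh == 0) {
        return(0)
    }
    min(1, max(0, sum(lightAreas * heavyAreas) / (nl * nh)))
}

#' Retention-time match
#'
#' Co-elution check between the light and heavy apexes: `|delta| <= tol`
#' (closed boundary).
#'
#' @param lightApex,heavyApex Apex retention times, minutes.
#' @param tol Tolerance in minutes (default 0.1).
#' @return Logical.
#' @export
rtMatch <- function(lightApex, heavyApex, tol = 0.1) {
    abs(lightApex - heavyApex) <= tol
}

#' Extract light/heavy peak groups from chromatograms
#'
#' Integrates every trace over its transition's scheduling window and
#' collects, per peptide, the per-transition light and heavy areas plus
#' the apex retention time of each label (time of maximum of the summed
#' traces).
#'
#' @param chrom A [ChromatogramSet-class] object.
#' @param assay Transition data.frame matching the chromatograms.
#' @param k Baseline edge samples (see [integratePeak()]).
#' @return Named list of peak groups; each is a list with `peptide`,
#'   `protein`, `transitionIds`, `lightAreas`, `heavyAreas`, `lightApex`,
#'   `heavyApex`.
#' @export
extractPeakGroups <- function(chrom, assay, k = 3L) {
    tr <- traces(chrom)
    light <- assay[assay$label == "light", , drop = FALSE]
    out <- lapply(split(light, light$peptide), function(blk) {
        ids <- blk$transition_id
        areas <- function(lab) {
            vapply(ids, function(id) {
                t0 <- tr[tr$transition_id == id & tr$label == lab, ,
                    drop = FALSE]
                integratePeak(t0$time_min, t0$intensity, k = k)
            }, numeric(1))
        }
        apex <- function(lab) {
            t0 <- tr[tr$transition_id %in% ids & tr$label == lab, ,
                drop = FALSE]
            tot <- tapply(t0$intensity, t0$time_min, sum)
            as.numeric(names(tot)[which.max(tot)])
        }
        list(peptide = blk$peptide[1], protein = blk$protein_id[1],
            transitionIds = ids, lightAreas = areas("light"),
            heavyAreas = areas("heavy"), lightApex = apex("light"),
            heavyApex = apex("heavy"))
    })
    out
}

#' Remove interfered transitions from a peak group
#'
#' Transitions where foreign material overlaps the light trace show a
#' light/heavy area ratio inconsistent with the peptide's other
#' transitions. Ratios deviating from the median by more than
#' `kMad * MAD` *and* by more than `minRelDev` times the median ratio are
#' eliminated; the relative floor keeps the rule stable when only three
#' ratios are available and the MAD is itself a noisy scale estimate. At
#' least three transitions must remain; otherwise the group is flagged
#' `fail_min_transitions` and must not be quantified.
#'
#' @param pg A peak group (see [extractPeakGroups()]).
#' @param kMad MAD multiplier (default 5).
#' @param minRelDev Minimum relative deviation from the median ratio for
#'   a transition to count as interfered (default 0.2).
#' @param minTransitions Retention floor (default 3).
#' @return The peak group with `lightAreas`/`heavyAreas` subset to the
#'   retained transitions, plus fields `nMeasured`, `nRetained`,
#'   `droppedTransitions` and `minTransitionsOk`.
#' @export
dropInterfered <- function(pg, kMad = 5, minRelDev = 0.2,
                           minTransitions = 3L) {
    n <- length(pg$lightAreas)
    if (n < minTransitions) {
        stop("peak group has fewer transitions than the quantification ",
            "floor", call. = FALSE)
    }
    ratio <- ifelse(pg$heavyAreas > 0, pg$lightAreas / pg$heavyAreas, NA)
    med <- stats::median(ratio, na.rm = TRUE)
    madv <- stats::mad(ratio, na.rm = TRUE)
    dev <- abs(ratio - med)
    cut <- max(kMad * madv, minRelDev * abs(med))
    drop <- is.na(ratio) | (dev > cut)
    if (sum(!drop) < minTransitions) {
        # cannot eliminate without falling below the floor: flag, keep all
        pg$nMeasured <- n
        pg$nRetained <- sum(!drop)
        pg$droppedTransitions <- pg$transitionIds[drop]
        pg$minTransitionsOk <- FALSE
        return(pg)
    }
    pg$nMeasured <- n
    pg$droppedTransitions <- pg$transitionIds[drop]
    pg$transitionIds <- pg$transitionIds[!drop]
    pg$lightAreas <- pg$lightAreas[!drop]
    pg$heavyAreas <- pg$heavyAreas[!drop]
    pg$nRetained <- length(pg$lightAreas)
    pg$minTransitionsOk <- TRUE
    pg
}

#' Quantification QC thresholds
#'
#' @param rdotpMin Ratio-dot-product gate; quantification requires
#'   `rdotp > rdotpMin` (default 0.9, strict).
#' @param rtTol Retention-time co-elution tolerance in minutes
#'   (default 0.1).
#' @param minTransitions Minimum retained transitions (default 3).
#' @param kMad MAD multiplier for interference elimination (default 5).
#' @param minRelDev Relative-deviation floor for interference
#'   elimination (default 0.2; see [dropInterfered()]).
#' @return A list of class `"QuantThresholds"`.
#' @export
quantThresholds <- function(rdotpMin = 0.9, rtTol = 0.1,
                            minTransitions = 3L, kMad = 5,
                            minRelDev = 0.2) {
    structure(list(rdotpMin = rdotpMin, rtTol = rtTol,
        minTransitions = as.integer(minTransitions), kMad = kMad,
        minRelDev = minRelDev),
        class = "QuantThresholds")
}

#' Quantify one peptide from its peak group
#'
#' After interference elimination, the light/heavy ratio is the sum of
#' retained light areas over the sum of retained heavy areas (summing
#' weights transitions by signal), and the absolute concentration is
#' `ratio x spiked` in fmol/ug. Quantification passes QC only if the
#' ratio dot product exceeds the gate, the light and heavy apexes
#' co-elute within tolerance, and at least three transitions remain;
#' failures carry no concentration.
#'
#' @param pg A peak group (see [extractPeakGroups()]).
#' @param spiked Spiked heavy amount, fmol/ug.
#' @param thresholds A [quantThresholds()] list.
#' @param ratioMethod `"sum"` (default; summed areas, weighting
#'   transitions by signal) or `"mean"` (mean of per-transition ratios).
#' @return One-row data.frame: `protein`, `peptide`, `rdotp`, `rt_delta`,
#'   `ratio`, `fmol_per_ug`, `n_retained`, `qc_status`.
#' @export
quantifyPeptide <- function(pg, spiked, thresholds = quantThresholds(),
                            ratioMethod = c("sum", "mean")) {
    ratioMethod <- match.arg(ratioMethod)
    pg <- dropInterfered(pg, kMad = thresholds$kMad,
        minRelDev = thresholds$minRelDev,
        minTransitions = thresholds$minTransitions)
    res <- data.frame(protein = pg$protein %||% NA_character_,
        peptide = pg$peptide, rdotp = NA_real_, rt_delta = NA_real_,
        ratio = NA_real_, fmol_per_ug = NA_real_,
        n_retained = pg$nRetained, qc_status = NA_character_,
        stringsAsFactors = FALSE)
    if (!pg$minTransitionsOk) {
        res$qc_status <- "fail_min_transitions"
        return(res)
    }
    r <- rdotp(pg$lightAreas, pg$heavyAreas)
    delta <- pg$lightApex - pg$heavyApex
    res$rdotp <- r
    res$rt_delta <- delta
    heavySum <- sum(pg$heavyAreas)
    # an absent internal standard (zero heavy signal) gives rdotp = 0 and
    # is rejected by the gate below
    if (!(r > thresholds$rdotpMin)) {
        res$qc_status <- "fail_rdotp"
        return(res)
    }
    if (!rtMatch(pg$lightApex, pg$heavyApex, thresholds$rtTol)) {
        res$qc_status <- "fail_rt"
        return(res)
    }
    res$ratio <- if (ratioMethod == "sum") {
        sum(pg$lightAreas) / heavySum
    } else {
        mean(pg$lightAreas / pg$heavyAreas)
    }
    res$fmol_per_ug <- res$ratio * spiked
    res$qc_status <- "pass"
    res
}

#' Quantify all peptides of a chromatogram set
#'
#' @param chrom A [ChromatogramSet-class] object.
#' @param assay Matching transition data.frame.
#' @param spikes Spiked heavy amount: a single value, or a data.frame
#'   with columns `peptide` and `spiked_fmol_per_ug`.
#' @param thresholds A [quantThresholds()] list.
#' @param ratioMethod Ratio estimator, see [quantifyPeptide()].
#' @return data.frame of per-peptide quantification results.
#' @export
quantifyChromatograms <- function(chrom, assay, spikes,
                                  thresholds = quantThresholds(),
                                  ratioMethod = c("sum", "mean")) {
    ratioMethod <- match.arg(ratioMethod)
    pgs <- extractPeakGroups(chrom, assay)
    spikeOf <- function(pep) {
        if (is.data.frame(spikes)) {
            s <- spikes$spiked_fmol_per_ug[match(pep, spikes$peptide)]
            if (is.na(s)) stop("no spike amount for ", pep, call. = FALSE)
            s
        } else {
            spikes
        }
    }
    out <- do.call(rbind, lapply(pgs, function(pg) {
        quantifyPeptide(pg, spikeOf(pg$peptide), thresholds, ratioMethod)
    }))
    rownames(out) <- NULL
    out
}

#' Roll peptide results up to proteins
#'
#' Protein concentration is the mean of its passing peptides'
#' concentrations; the peptide count and coefficient of variation are
#' reported. Proteins with no passing peptide are flagged, never silently
#' dropped.
#'
#' @param quant Per-peptide results from [quantifyChromatograms()].
#' @return data.frame: `protein`, `fmol_per_ug`, `n_peptides`, `cv`,
#'   `quantified`.
#' @export
rollUpProteins <- function(quant) {
    out <- lapply(split(quant, quant$protein), function(q) {
        ok <- q[q$qc_status == "pass", , drop = FALSE]
        if (nrow(ok)) {
            v <- ok$fmol_per_ug
            data.frame(protein = q$protein[1], fmol_per_ug = mean(v),
                n_peptides = nrow(ok),
                cv = if (nrow(ok) > 1) stats::sd(v) / mean(v) else NA_real_,
                quantified = TRUE, stringsAsFactors = FALSE)
        } else {
            data.frame(protein = q$protein[1], fmol_per_ug = NA_real_,
                n_peptides = 0L, cv = NA_real_, quantified = FALSE,
                stringsAsFactors = FALSE)
        }
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
}
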