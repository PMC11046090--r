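#' Simulation ground truth
#'
#' Describes the hidden state behind a simulated scheduled-MRM run: true
#' endogenous concentrations, the spiked heavy-standard amount, the
#' relative transition intensities shared by the co-eluting light and
#' heavy peaks, retention times, Gaussian peak width, multiplicative noise
#' level, an optional interference plan, and the seed reproducing it all.
#'
#' @param peptideSeqs Character vector of peptide sequences.
#' @param concentrations True endogenous concentration per peptide,
#'   fmol/ug (non-negative).
#' @param spike Spiked heavy amount per peptide, fmol/ug (scalar or
#'   vector).
#' @param relIntensities List (one numeric vector per peptide) of relative
#'   transition intensities; each vector is normalised to sum to 1.
#' @param rt True retention time per peptide, minutes.
#' @param peakSigma Gaussian peak sigma, minutes (default 0.05).
#' @param noiseCv Coefficient of variation of the multiplicative intensity
#'   noise (default 0.05; 0 gives a noiseless run).
#' @param baseline Flat additive baseline in counts (default 1).
#' @param interference Optional data.frame (`transition_id`, `rt_offset`,
#'   `amplitude_factor`) adding an interfering Gaussian to the listed
#'   *light* transitions; the factor scales that transition's light
#'   amplitude.
#' @param seed Integer seed recorded in every output.
#' @return A list of class `"SimTruth"`.
#' @export
simTruth <- function(peptideSeqs, concentrations, spike = 10,
                     relIntensities, rt, peakSigma = 0.05,
                     noiseCv = 0.05, baseline = 1,
                     interference = NULL, seed = 1L) {
    n <- length(peptideSeqs)
    stopifnot(length(concentrations) == n, length(rt) == n,
        length(relIntensities) == n, all(concentrations >= 0),
        all(spike > 0), peakSigma > 0, noiseCv >= 0)
    spike <- rep_len(spike, n)
    relIntensities <- lapply(relIntensities, function(ri) {
        stopifnot(all(ri > 0))
        ri / sum(ri)
    })
    names(relIntensities) <- peptideSeqs
    structure(list(
        peptides = peptideSeqs,
        concentrations = stats::setNames(concentrations, peptideSeqs),
        spike = stats::setNames(spike, peptideSeqs),
        relIntensities = relIntensities,
        rt = stats::setNames(rt, peptideSeqs),
        peakSigma = peakSigma,
        noiseCv = noiseCv,
        baseline = baseline,
        interference = interference,
        seed = as.integer(seed)
    ), class = "SimTruth")
}

# counts emitted per fmol/ug of analyte at relative intensity 1
.RESPONSE_FACTOR <- 1000

#' Simulate scheduled-MRM chromatograms
#'
#' For every transition of the assay, samples a Gaussian elution peak
#' `A * exp(-(t - rt)^2 / (2 * sigma^2))` on the acquisition grid (one
#' point per target scan time) restricted to the transition's scheduling
#' window. The light amplitude is proportional to the true concentration
#' times the transition's relative intensity; the heavy amplitude to the
#' spiked amount times the *same* relative intensity — the shared
#' fragmentation pattern that drives the ratio dot product towards 1.
#' Intensities receive mean-one multiplicative log-normal noise at the
#' stated CV plus a flat additive baseline; interference (if planned)
#' adds an extra Gaussian to the listed light transitions. Fully
#' reproducible from the recorded seed.
#'
#' @param assay Transition data.frame from [buildAssay()] (must contain
#'   every truth peptide, with scheduling windows).
#' @param truth A [simTruth()] object.
#' @param settings An [assaySettings()] list (grid spacing = target scan
#'   time).
#' @return A [ChromatogramSet-class] object.
#' @export
simulateChromatograms <- function(assay, truth,
                                  settings = assaySettings()) {
    missing <- setdiff(truth$peptides, assay$peptide)
    if (length(missing)) {
        stop("truth peptides missing from assay: ",
            paste(missing, collapse = ", "), call. = FALSE)
    }
    set.seed(truth$seed)
    dt <- settings$targetScanTime / 60
    sdlog <- sqrt(log(1 + truth$noiseCv^2))
    rows <- vector("list", nrow(assay))
    for (i in seq_len(nrow(assay))) {
        tr <- assay[i, ]
        pep <- tr$peptide
        ri <- truth$relIntensities[[pep]]
        # fragment rank within this peptide/label block orders intensities
        block <- assay$transition_id[assay$peptide == pep &
            assay$label == tr$label]
        k <- match(tr$transition_id, block)
        amount <- if (tr$label == "light") {
            truth$concentrations[[pep]]
        } else {
            truth$spike[[pep]]
        }
        A <- .RESPONSE_FACTOR * amount * ri[k]
        tgrid <- seq(tr$window_start, tr$window_end, by = dt)
        mu <- truth$rt[[pep]]
        sig <- truth$peakSigma
        signal <- A * exp(-(tgrid - mu)^2 / (2 * sig^2))
        if (tr$label == "light" && !is.null(truth$interference)) {
            hit <- truth$interference[
                truth$interference$transition_id == tr$transition_id, ,
                drop = FALSE]
            for (j in seq_len(nrow(hit))) {
                signal <- signal + hit$amplitude_factor[j] * A *
                    exp(-(tgrid - mu - hit$rt_offset[j])^2 / (2 * sig^2))
            }
        }
        noise <- if (sdlog > 0) {
            exp(stats::rnorm(length(tgrid), 0, sdlog) - sdlog^2 / 2)
        } else {
            1
        }
        rows[[i]] <- data.frame(
            transition_id = tr$transition_id,
            label = tr$label,
            time_min = tgrid,
            intensity = signal * noise + truth$baseline,
            stringsAsFactors = FALSE
        )
    }
    tracesDf <- do.call(rbind, rows)
    rownames(tracesDf) <- NULL
    new("ChromatogramSet", traces = tracesDf,
        settings = unclass(settings), truth = unclass(truth))
}

#' Simulate a three-group study matrix
#'
#' Emulates the measured analyte-by-sample matrices of a three-genotype
#' comparison (wild type, hemizygous, homozygous): per-analyte baseline
#' abundances are log-normal, within-group replicate variation is
#' mean-one multiplicative log-normal noise at the stated CV, and planted
#' analytes are multiplied by their fold change in the stated group. The
#' planted table is embedded as ground truth.
#'
#' @param nAnalytes Number of analytes.
#' @param groups Three group labels (default `c("WT", "Tg", "TgTg")`).
#' @param nPerGroup Samples per group (>= 2; the study design uses 5 for
#'   proteins and 10 for metabolites).
#' @param planted Optional data.frame (`analyte`, `group`, `foldChange`
#'   all > 0); analytes may be given as integer indices or IDs.
#' @param cv Within-group coefficient of variation (default 0.1).
#' @param seed Integer seed.
#' @param baselineMeanlog,baselineSdlog Log-normal baseline parameters
#'   (defaults `log(50)` and 1, spanning roughly 2-3 decades of
#'   abundance).
#' @return A [StudyMatrix-class] object.
#' @export
simulateStudy <- function(nAnalytes, groups = c("WT", "Tg", "TgTg"),
                          nPerGroup = 5L, planted = NULL, cv = 0.1,
                          seed = 1L, baselineMeanlog = log(50),
                          baselineSdlog = 1) {
    if (nPerGroup < 2L) {
        stop("nPerGroup must be >= 2 (no variance estimate otherwise)",
            call. = FALSE)
    }
    stopifnot(length(groups) == 3L, cv >= 0)
    set.seed(as.integer(seed))
    analytes <- sprintf("analyte%04d", seq_len(nAnalytes))
    if (!is.null(planted)) {
        if (is.numeric(planted$analyte)) {
            planted$analyte <- analytes[planted$analyte]
        }
        if (any(planted$foldChange <= 0)) {
            stop("planted fold changes must be > 0", call. = FALSE)
        }
    }
    groupOf <- rep(groups, each = nPerGroup)
    sampleIds <- sprintf("%s_%d", groupOf, rep(seq_len(nPerGroup),
        times = length(groups)))
    baseline <- stats::rlnorm(nAnalytes, baselineMeanlog, baselineSdlog)
    expected <- matrix(baseline, nrow = nAnalytes,
        ncol = length(sampleIds))
    if (!is.null(planted)) {
        for (j in seq_len(nrow(planted))) {
            r <- match(planted$analyte[j], analytes)
            expected[r, groupOf == planted$group[j]] <-
                expected[r, groupOf == planted$group[j]] *
                planted$foldChange[j]
        }
    }
    sdlog <- sqrt(log(1 + cv^2))
    noise <- if (sdlog > 0) {
        matrix(exp(stats::rnorm(length(expected), 0, sdlog) - sdlog^2 / 2),
            nrow = nAnalytes)
    } else {
        1
    }
    values <- expected * noise
    dimnames(values) <- list(analytes, sampleIds)
    StudyMatrix(values, groupOf, planted)
}

#' Generate a synthetic fixture proteome
#'
#' Random protein sequences over the 20 standard residues with natural
#' lysine/arginine frequencies, usable as a stand-in proteome for assay
#' design demonstrations and tests. Purely synthetic: no homology, no
#' domain structure.
#'
#' @param nProteins Number of proteins.
#' @param minLength,maxLength Protein length range (defaults 150-400).
#' @param seed Integer seed.
#' @return Named character vector (`PROT0001`, ...).
#' @export
syntheticProteome <- function(nProteins = 12L, minLength = 150L,
                              maxLength = 400L, seed = 1L) {
    set.seed(as.integer(seed))
    # rough natural amino-acid frequencies (vertebrate average)
    freq <- c(A = 7.4, C = 2.5, D = 5.9, E = 5.8, F = 4.0, G = 7.4,
        H = 2.9, I = 3.8, K = 7.2, L = 7.6, M = 1.8, N = 4.4, P = 5.0,
        Q = 3.7, R = 4.2, S = 8.1, T = 6.2, V = 6.8, W = 1.3, Y = 3.3)
    lens <- sample(minLength:maxLength, nProteins, replace = TRUE)
    seqs <- vapply(lens, function(L) {
        paste(sample(names(freq), L, replace = TRUE, prob = freq),
            collapse = "")
    }, character(1))
    stats::setNames(seqs, sprintf("PROT%04d", seq_len(nProteins)))
}

#' Chromatogram TSV input/output
#'
#' Long-format TSV with columns `transition_id`, `label`, `time_min`,
#' `intensity`.
#'
#' @param x A [ChromatogramSet-class] object.
#' @param path TSV path.
#' @return `writeChromatograms()` returns `path` invisibly;
#'   `readChromatograms()` returns a [ChromatogramSet-class] (without
#'   truth).
#' @name chromatogramIO
NULL

#' @rdname chromatogramIO
#' @export
writeChromatograms <- function(x, path) {
    utils::write.table(traces(x), path, sep = "\t", row.names = FALSE,
        quote = FALSE)
    invisible(path)
}

#' @rdname chromatogramIO
#' @param settings Acquisition settings to attach on read.
#' @export
readChromatograms <- function(path, settings = assaySettings()) {
    tr <- utils::read.delim(path, stringsAsFactors = FALSE)
    new("ChromatogramSet", traces = tr, settings = unclass(settings),
        truth = list())
}
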