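#' Study matrix CSV input/output
#'
#' The matrix CSV has the analyte identifier in the first column and one
#' column per sample; the groups CSV maps `sample` to `group`.
#'
#' @param sm A [StudyMatrix-class] object.
#' @param matrixPath,groupsPath Output/input CSV paths.
#' @return `writeStudyMatrix()` returns the paths invisibly;
#'   `readStudyMatrix()` returns a [StudyMatrix-class] object (without a
#'   planted-effect table).
#' @name studyIO
NULL

#' @rdname studyIO
#' @export
writeStudyMatrix <- function(sm, matrixPath, groupsPath) {
    x <- abundances(sm)
    out <- data.frame(analyte = rownames(x), x, check.names = FALSE,
        stringsAsFactors = FALSE)
    utils::write.csv(out, matrixPath, row.names = FALSE)
    utils::write.csv(data.frame(sample = colnames(x),
        group = groupLabels(sm)), groupsPath, row.names = FALSE)
    invisible(c(matrixPath, groupsPath))
}

#' @rdname studyIO
#' @export
readStudyMatrix <- function(matrixPath, groupsPath) {
    tab <- utils::read.csv(matrixPath, check.names = FALSE,
        stringsAsFactors = FALSE)
    groups <- utils::read.csv(groupsPath, stringsAsFactors = FALSE)
    x <- as.matrix(tab[, -1, drop = FALSE])
    rownames(x) <- tab[[1]]
    StudyMatrix(x, groups$group[match(colnames(x), groups$sample)])
}

#' Run the whole workflow end to end
#'
#' Demonstration pipeline exercising every stage on synthetic inputs,
#' deterministic from one seed:
#'
#' 1. generate a synthetic fixture proteome and select proteotypic
#'    peptides ([selectProteotypic()]);
#' 2. assemble QconCAT internal-standard constructs
#'    ([assembleQconcat()]);
#' 3. build the scheduled MRM assay with instrument parameters
#'    ([buildAssay()], [scheduleAssay()]);
#' 4. simulate chromatograms with known concentrations
#'    ([simulateChromatograms()]) and quantify them
#'    ([quantifyChromatograms()], [rollUpProteins()]);
#' 5. simulate a three-group study matrix with planted effects and run
#'    the differential layer ([volcanoTable()], [anovaSidak()],
#'    [studyPca()], [heatmapMatrix()]).
#'
#' All tables are written as CSV/TSV under `outDir`.
#'
#' @param outDir Output directory (created if needed).
#' @param seed Integer master seed; every stochastic stage derives its
#'   seed from it.
#' @param nProteins Synthetic proteome size (default 12).
#' @param nAnalytes,nPlanted,plantedFC Study-simulation design: number of
#'   analytes (default 247, the protein panel size of the motivating
#'   three-genotype study), planted differential analytes (default 30)
#'   and their fold change (default 2).
#' @param nPerGroup Samples per group (default 5).
#' @param cv Study within-group CV (default 0.1).
#' @return Invisible list with the main intermediate objects
#'   (`selection`, `constructs`, `assay`, `schedule`, `quant`, `proteins`,
#'   `study`, `volcano`, `anova`, `pca`, `heatmap`, `files`).
#' @export
runPipeline <- function(outDir = tempfile("mrmquant"), seed = 1L,
                        nProteins = 12L, nAnalytes = 247L,
                        nPlanted = 30L, plantedFC = 2,
                        nPerGroup = 5L, cv = 0.1) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    seed <- as.integer(seed)
    paths <- list()

    # 1. proteome and proteotypic selection
    proteome <- syntheticProteome(nProteins, seed = seed)
    writeFasta(proteome, file.path(outDir, "proteome.fasta"))
    sel <- selectProteotypic(proteome, names(proteome))
    utils::write.csv(sel$selection,
        file.path(outDir, "selection.csv"), row.names = FALSE)
    if (nrow(sel$failures)) {
        utils::write.csv(sel$failures,
            file.path(outDir, "selection_failures.csv"), row.names = FALSE)
    }
    peps <- sel$selection$peptide

    # 2. internal-standard constructs
    constructs <- assembleQconcat(peps, capacity = 50L)
    writeConstructManifest(constructs,
        file.path(outDir, "constructs.csv"), sel$selection)
    writeFasta(stats::setNames(
        vapply(constructs, fullSequence, character(1)),
        vapply(constructs, constructId, character(1))),
        file.path(outDir, "constructs.fasta"))

    # 3. scheduled assay (RTs drawn uniformly over the gradient)
    set.seed(seed + 1L)
    rtTable <- data.frame(peptide = peps,
        rt = stats::runif(length(peps), 5, 25))
    settings <- assaySettings()
    assay <- buildAssay(peps, rtTable, sel$selection$proteinId, settings)
    sched <- scheduleAssay(assay, settings)
    writeTransitionList(sched$transitions,
        file.path(outDir, "transitions.csv"))

    # 4. simulate and quantify
    set.seed(seed + 2L)
    truth <- simTruth(
        peptideSeqs = peps,
        concentrations = stats::rlnorm(length(peps), log(10), 0.8),
        spike = 10,
        relIntensities = replicate(length(peps),
            stats::runif(settings$minTransitions, 0.2, 1),
            simplify = FALSE),
        rt = rtTable$rt,
        noiseCv = 0.05,
        seed = seed + 3L
    )
    chrom <- simulateChromatograms(sched$transitions, truth, settings)
    writeChromatograms(chrom, file.path(outDir, "chromatograms.tsv"))
    quant <- quantifyChromatograms(chrom, sched$transitions, spikes = 10)
    utils::write.csv(quant, file.path(outDir, "quant.csv"),
        row.names = FALSE)
    proteins <- rollUpProteins(quant)
    utils::write.csv(proteins, file.path(outDir, "proteins.csv"),
        row.names = FALSE)

    # 5. three-group study and differential layer
    planted <- data.frame(
        analyte = seq_len(min(nPlanted, nAnalytes)),
        group = "TgTg", foldChange = plantedFC)
    study <- simulateStudy(nAnalytes, nPerGroup = nPerGroup,
        planted = planted, cv = cv, seed = seed + 4L)
    writeStudyMatrix(study, file.path(outDir, "study_matrix.csv"),
        file.path(outDir, "study_groups.csv"))
    volcano <- volcanoTable(study, "WT", "TgTg")
    utils::write.csv(volcano, file.path(outDir, "volcano.csv"),
        row.names = FALSE)
    aov <- anovaSidak(study, referenceGroup = "TgTg")
    utils::write.csv(aov$anova, file.path(outDir, "anova.csv"),
        row.names = FALSE)
    utils::write.csv(aov$pairwise, file.path(outDir, "anova_pairwise.csv"),
        row.names = FALSE)
    pca <- studyPca(study)
    utils::write.csv(data.frame(sample = rownames(pca$scores),
        group = groupLabels(study), pca$scores[, 1:3]),
        file.path(outDir, "pca_scores.csv"), row.names = FALSE)
    hmSubset <- volcano$analyte[volcano$p_value < 0.05]
    hm <- heatmapMatrix(study,
        if (length(hmSubset)) hmSubset else NULL)
    utils::write.csv(data.frame(analyte = rownames(hm$z)[hm$rowOrder],
        hm$z[hm$rowOrder, , drop = FALSE], check.names = FALSE),
        file.path(outDir, "heatmap_matrix.csv"), row.names = FALSE)

    invisible(list(selection = sel, constructs = constructs,
        assay = assay, schedule = sched, truth = truth, quant = quant,
        proteins = proteins, study = study, volcano = volcano,
        anova = aov, pca = pca, heatmap = hm, outDir = outDir))
}
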