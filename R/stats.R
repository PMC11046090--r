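#' Per-analyte fold change between two groups
#'
#' Ratio of arithmetic group means, `groupB / groupA`.
#'
#' @param sm A [StudyMatrix-class] object.
#' @param groupA,groupB Group labels (denominator, numerator).
#' @return Named numeric vector; analytes whose `groupA` mean is zero get
#'   `Inf`/`NaN` with a warning.
#' @export
foldChange <- function(sm, groupA, groupB) {
    g <- groupLabels(sm)
    .checkGroups(g, c(groupA, groupB))
    x <- abundances(sm)
    mA <- rowMeans(x[, g == groupA, drop = FALSE])
    mB <- rowMeans(x[, g == groupB, drop = FALSE])
    if (any(mA == 0)) {
        warning(sum(mA == 0), " analyte(s) with zero denominator mean")
    }
    mB / mA
}

.checkGroups <- function(g, wanted) {
    unknown <- setdiff(wanted, g)
    if (length(unknown)) {
        stop("unknown group label(s): ", paste(unknown, collapse = ", "),
            call. = FALSE)
    }
}

#' Per-analyte two-sample t test
#'
#' Two-sided p-values comparing two groups for every analyte. Welch's
#' unequal-variance test is the default; the pooled-variance Student test
#' is available. Analytes with zero variance in both groups get `p = 1`
#' when the means are equal and `p = 0` otherwise (degenerate-input
#' convention).
#'
#' @param sm A [StudyMatrix-class] object.
#' @param groupA,groupB Group labels.
#' @param flavor `"welch"` (default) or `"student"`.
#' @return Named numeric vector of p-values.
#' @export
groupTTest <- function(sm, groupA, groupB,
                       flavor = c("welch", "student")) {
    flavor <- match.arg(flavor)
    g <- groupLabels(sm)
    .checkGroups(g, c(groupA, groupB))
    x <- abundances(sm)
    a <- x[, g == groupA, drop = FALSE]
    b <- x[, g == groupB, drop = FALSE]
    if (ncol(a) < 2L || ncol(b) < 2L) {
        stop("n >= 2 per group required", call. = FALSE)
    }
    p <- vapply(seq_len(nrow(x)), function(i) {
        ai <- a[i, ]
        bi <- b[i, ]
        if (stats::sd(ai) == 0 && stats::sd(bi) == 0) {
            return(if (mean(ai) == mean(bi)) 1 else 0)
        }
        stats::t.test(bi, ai, var.equal = (flavor == "student"))$p.value
    }, numeric(1))
    stats::setNames(p, rownames(x))
}

#' Volcano table and selection
#'
#' `volcanoTable()` assembles per-analyte differential records for one
#' group pair; `volcanoSelect()` applies the selection rule: an analyte is
#' differential when `FC > 1.5` or `FC < 1/1.5` (the symmetric
#' interpretation of |fold change| > 1.5 on the log scale, strict) *and*
#' its t-test `p < 0.05` (strict). Direction (`"up"`/`"down"`) follows the
#' sign of the log2 fold change. An adjusted p-value column
#' (Benjamini-Hochberg, tagged in the `p_adjust_method` attribute) is
#' carried for reporting; the selection gate itself uses the raw p-value.
#'
#' @param sm A [StudyMatrix-class] object.
#' @param groupA,groupB Group labels (fold change is `groupB / groupA`).
#' @param flavor t-test flavor, see [groupTTest()].
#' @param fcThreshold Fold-change gate (default 1.5).
#' @param alpha p-value gate (default 0.05).
#' @return data.frame: `analyte`, `group_pair`, `fold_change`, `log2_fc`,
#'   `p_value`, `p_adjusted`, `selected`, `direction`.
#' @name volcano
NULL

#' @rdname volcano
#' @export
volcanoTable <- function(sm, groupA, groupB,
                         flavor = c("welch", "student"),
                         fcThreshold = 1.5, alpha = 0.05) {
    fc <- foldChange(sm, groupA, groupB)
    p <- groupTTest(sm, groupA, groupB, flavor)
    rec <- data.frame(
        analyte = names(fc),
        group_pair = paste(groupA, "vs", groupB),
        fold_change = unname(fc),
        log2_fc = unname(log2(fc)),
        p_value = unname(p),
        p_adjusted = unname(stats::p.adjust(p, "BH")),
        stringsAsFactors = FALSE
    )
    attr(rec, "p_adjust_method") <- "BH"
    volcanoSelect(rec, fcThreshold = fcThreshold, alpha = alpha)
}

#' @rdname volcano
#' @param records A volcano data.frame with `fold_change` and `p_value`.
#' @export
volcanoSelect <- function(records, fcThreshold = 1.5, alpha = 0.05) {
    fc <- records$fold_change
    fcGate <- fc > fcThreshold | fc < 1 / fcThreshold
    records$selected <- fcGate & records$p_value < alpha
    records$direction <- ifelse(!records$selected, NA_character_,
        ifelse(fc > 1, "up", "down"))
    records
}

#' Sidak adjustment
#'
#' `p_adj = 1 - (1 - p)^m` for `m` comparisons; monotone in `p` and
#' bounded in `[0, 1]`.
#'
#' @param p Numeric vector of p-values.
#' @param m Number of comparisons.
#' @return Adjusted p-values.
#' @examples
#' sidakAdjust(0.01, 3) # 0.029701
#' @export
sidakAdjust <- function(p, m) {
    stopifnot(all(p >= 0 & p <= 1), m >= 1)
    1 - (1 - p)^m
}

#' One-way ANOVA with Sidak-adjusted pairwise comparisons
#'
#' For every analyte: the one-way ANOVA F statistic and p-value across
#' all groups, plus pairwise two-sample comparisons of each non-reference
#' group against the reference, Sidak-adjusted over the `m = nGroups - 1`
#' comparisons made per analyte (mirroring "versus reference" figure
#' annotations; no adjustment across analytes).
#'
#' @param sm A [StudyMatrix-class] object.
#' @param referenceGroup Group every other group is compared against.
#' @param flavor Pairwise t-test flavor (default `"student"`, matching
#'   classic post-hoc usage).
#' @return List with `anova` (data.frame `analyte`, `F`, `df1`, `df2`,
#'   `p_value`) and `pairwise` (data.frame `analyte`, `comparison`,
#'   `p_value`, `p_sidak`).
#' @export
anovaSidak <- function(sm, referenceGroup,
                       flavor = c("student", "welch")) {
    flavor <- match.arg(flavor)
    g <- groupLabels(sm)
    .checkGroups(g, referenceGroup)
    lev <- unique(g)
    if (length(lev) < 2L) {
        stop("at least 2 groups required", call. = FALSE)
    }
    if (any(table(g) < 2L)) {
        stop("n >= 2 per group required", call. = FALSE)
    }
    x <- abundances(sm)
    gf <- factor(g, levels = lev)
    others <- setdiff(lev, referenceGroup)
    m <- length(others)
    anovaRows <- vector("list", nrow(x))
    pairRows <- vector("list", nrow(x))
    for (i in seq_len(nrow(x))) {
        v <- x[i, ]
        fit <- stats::oneway.test(v ~ gf, var.equal = TRUE)
        anovaRows[[i]] <- data.frame(
            analyte = rownames(x)[i],
            F = unname(fit$statistic),
            df1 = unname(fit$parameter[1]),
            df2 = unname(fit$parameter[2]),
            p_value = fit$p.value,
            stringsAsFactors = FALSE
        )
        pw <- vapply(others, function(go) {
            stats::t.test(v[g == go], v[g == referenceGroup],
                var.equal = (flavor == "student"))$p.value
        }, numeric(1))
        pairRows[[i]] <- data.frame(
            analyte = rownames(x)[i],
            comparison = paste(others, "vs", referenceGroup),
            p_value = unname(pw),
            p_sidak = unname(sidakAdjust(pw, m)),
            stringsAsFactors = FALSE
        )
    }
    list(anova = do.call(rbind, anovaRows),
        pairwise = do.call(rbind, pairRows))
}

#' Principal component analysis of a study matrix
#'
#' Singular-value decomposition of the sample-by-analyte matrix after
#' centering (and optional unit scaling) of each analyte. Constant
#' analytes are dropped with a warning when scaling. The sign of each
#' component is fixed deterministically: the largest-magnitude loading is
#' made positive.
#'
#' @param sm A [StudyMatrix-class] object (no missing values).
#' @param scale Unit-scale analytes (default `FALSE`).
#' @return List of class `"PcaResult"`: `scores` (samples x components),
#'   `loadings` (analytes x components, orthonormal columns),
#'   `explainedVariance` (fractions, non-increasing, summing to <= 1).
#' @export
studyPca <- function(sm, scale = FALSE) {
    x <- abundances(sm)
    if (anyNA(x)) {
        stop("missing values are the caller's problem: impute first",
            call. = FALSE)
    }
    if (scale) {
        constant <- apply(x, 1, stats::sd) == 0
        if (any(constant)) {
            warning(sum(constant),
                " constant analyte(s) dropped before scaling")
            x <- x[!constant, , drop = FALSE]
        }
    }
    pc <- stats::prcomp(t(x), center = TRUE, scale. = scale)
    for (j in seq_len(ncol(pc$rotation))) {
        if (pc$rotation[which.max(abs(pc$rotation[, j])), j] < 0) {
            pc$rotation[, j] <- -pc$rotation[, j]
            pc$x[, j] <- -pc$x[, j]
        }
    }
    structure(list(
        scores = pc$x,
        loadings = pc$rotation,
        explainedVariance = pc$sdev^2 / sum(pc$sdev^2)
    ), class = "PcaResult")
}

#' Z-scored matrix with hierarchical clustering order
#'
#' Per-analyte z-scores across samples (zero-variance analytes are set to
#' 0 with a warning) and a deterministic average-linkage clustering of the
#' analytes on Euclidean distance; ties are broken by input order, as in
#' [stats::hclust()].
#'
#' @param sm A [StudyMatrix-class] object.
#' @param analytes Optional character vector restricting the rows (must be
#'   non-empty).
#' @return List with `z` (z-scored matrix), `rowOrder` (leaf order),
#'   `hclust` (the [stats::hclust] object, `NULL` for a single analyte).
#' @export
heatmapMatrix <- function(sm, analytes = NULL) {
    x <- abundances(sm)
    if (!is.null(analytes)) {
        if (!length(analytes)) {
            stop("analyte subset must be non-empty", call. = FALSE)
        }
        missing <- setdiff(analytes, rownames(x))
        if (length(missing)) {
            stop("unknown analytes: ", paste(missing, collapse = ", "),
                call. = FALSE)
        }
        x <- x[analytes, , drop = FALSE]
    }
    mu <- rowMeans(x)
    sdv <- apply(x, 1, stats::sd)
    if (any(sdv == 0)) {
        warning(sum(sdv == 0), " zero-variance analyte(s); z-scores set to 0")
    }
    z <- (x - mu) / ifelse(sdv == 0, 1, sdv)
    z[sdv == 0, ] <- 0
    if (nrow(z) > 1L) {
        hc <- stats::hclust(stats::dist(z, "euclidean"), "average")
        rowOrder <- hc$order
    } else {
        hc <- NULL
        rowOrder <- 1L
    }
    list(z = z, rowOrder = rowOrder, hclust = hc)
}
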