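threeGroupMatrix <- function(values, nPerGroup = 5) {
    StudyMatrix(values, rep(c("WT", "Tg", "TgTg"),
        each = nPerGroup)[seq_len(ncol(values))])
}

test_that("fold change is the ratio of arithmetic group means", {
    x <- rbind(c(rep(10, 5), rep(15, 5), rep(20, 5)),
        c(rep(3, 5), rep(3, 5), rep(3, 5)))
    sm <- threeGroupMatrix(x)
    fc <- foldChange(sm, "WT", "TgTg")
    expect_equal(unname(fc), c(2, 1))
    expect_error(foldChange(sm, "WT", "nope"), "unknown group")
})

test_that("t tests match hand computation and handle degeneracy", {
    # identical groups: t = 0, p = 1
    smEq <- StudyMatrix(matrix(c(1, 2, 3, 1, 2, 3), nrow = 1),
        rep(c("a", "b"), each = 3))
    expect_equal(unname(groupTTest(smEq, "a", "b", "student")), 1)
    # pooled-variance example: t = 10, df = 8
    smT <- StudyMatrix(matrix(c(10:14, 20:24), nrow = 1),
        rep(c("a", "b"), each = 5))
    p <- unname(groupTTest(smT, "a", "b", "student"))
    expect_equal(p, 2 * pt(-10, 8), tolerance = 1e-9)
    expect_equal(p, 8.5e-6, tolerance = 0.01)
    # zero variance in both groups, equal means
    smC <- StudyMatrix(matrix(rep(5, 6), nrow = 1),
        rep(c("a", "b"), each = 3))
    expect_equal(unname(groupTTest(smC, "a", "b")), 1)
})

test_that("volcano selection needs both the FC and the p gate", {
    rec <- data.frame(
        analyte = c("up", "flat", "down", "weakp"),
        fold_change = c(1.6, 1.4, 0.6, 1.8),
        p_value = c(0.04, 0.001, 0.01, 0.2))
    out <- volcanoSelect(rec)
    expect_identical(out$selected, c(TRUE, FALSE, TRUE, FALSE))
    expect_identical(out$direction, c("up", NA, "down", NA))
    # strict boundaries: FC exactly 1.5 or p exactly 0.05 do not select
    bound <- volcanoSelect(data.frame(analyte = c("f", "p"),
        fold_change = c(1.5, 2), p_value = c(0.01, 0.05)))
    expect_false(any(bound$selected))
})

test_that("Sidak adjustment is the closed form, monotone and bounded", {
    expect_equal(sidakAdjust(0.01, 3), 0.029701, tolerance = 1e-9)
    expect_equal(sidakAdjust(0, 5), 0)
    expect_equal(sidakAdjust(1, 5), 1)
    p <- seq(0, 1, 0.01)
    adj <- sidakAdjust(p, 4)
    expect_true(all(diff(adj) >= 0))
    expect_true(all(adj >= 0 & adj <= 1))
    expect_true(all(adj >= p))
})

test_that("one-way ANOVA F matches the hand decomposition", {
    sm <- StudyMatrix(matrix(c(1, 2, 3, 2, 3, 4, 3, 4, 5), nrow = 1),
        rep(c("g1", "g2", "g3"), each = 3))
    a <- anovaSidak(sm, "g1")
    expect_equal(a$anova$F, 3, tolerance = 1e-9) # SSB = 6, SSW = 6
    expect_equal(a$anova$df1, 2)
    expect_equal(a$anova$df2, 6)
    expect_equal(a$anova$p_value, pf(3, 2, 6, lower.tail = FALSE),
        tolerance = 1e-9)
    expect_identical(a$pairwise$comparison, c("g2 vs g1", "g3 vs g1"))
    expect_equal(a$pairwise$p_sidak,
        sidakAdjust(a$pairwise$p_value, 2), tolerance = 1e-12)
    expect_error(anovaSidak(StudyMatrix(matrix(1:4, nrow = 1),
        rep("a", 4)), "a"), "2 groups")
})

test_that("PCA matches an independent eigen-decomposition", {
    # two samples on one axis: PC1 explains everything
    smAx <- StudyMatrix(t(matrix(c(1, 0, -1, 0), nrow = 2, byrow = TRUE)),
        c("a", "a"))
    expect_equal(studyPca(smAx)$explainedVariance[1], 1)
    set.seed(41)
    x <- matrix(rnorm(15), nrow = 3,
        dimnames = list(sprintf("an%d", 1:3), sprintf("s%d", 1:5)))
    sm <- StudyMatrix(x, rep("g", 5))
    pc <- studyPca(sm)
    # oracle: eigen-decomposition of the covariance of centered samples
    cen <- scale(t(x), center = TRUE, scale = FALSE)
    ev <- eigen(cov(cen))$values
    expect_equal(pc$explainedVariance, ev / sum(ev), tolerance = 1e-10)
    # loadings orthonormal, scores reconstruct the centered matrix
    expect_equal(crossprod(pc$loadings), diag(ncol(pc$loadings)),
        tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(pc$scores %*% t(pc$loadings), unclass(cen),
        tolerance = 1e-10, ignore_attr = TRUE)
    # explained fractions non-increasing and summing to <= 1
    expect_true(all(diff(pc$explainedVariance) <= 1e-12))
    expect_lte(sum(pc$explainedVariance), 1 + 1e-12)
    # deterministic sign: largest-magnitude loading positive
    for (j in seq_len(ncol(pc$loadings))) {
        expect_gte(pc$loadings[which.max(abs(pc$loadings[, j])), j], 0)
    }
})

test_that("constant analytes are dropped before unit scaling", {
    x <- rbind(matrix(rnorm(10), nrow = 2), rep(4, 5))
    rownames(x) <- c("a", "b", "flat")
    sm <- StudyMatrix(x, rep("g", 5))
    expect_warning(pc <- studyPca(sm, scale = TRUE), "constant")
    expect_identical(nrow(pc$loadings), 2L)
})

test_that("heat-map rows are z-scored and clustered deterministically", {
    set.seed(43)
    base <- rnorm(6)
    x <- rbind(a1 = base + rnorm(6, sd = 0.01),
        a2 = base + rnorm(6, sd = 0.01),
        b1 = -base + rnorm(6, sd = 0.01),
        b2 = -base + rnorm(6, sd = 0.01))
    sm <- StudyMatrix(x, rep("g", 6))
    hm <- heatmapMatrix(sm)
    expect_equal(unname(rowMeans(hm$z)), rep(0, 4), tolerance = 1e-12)
    expect_equal(unname(apply(hm$z, 1, sd)), rep(1, 4), tolerance = 1e-12)
    # planted two-cluster structure: a's and b's are adjacent leaves
    ord <- rownames(hm$z)[hm$rowOrder]
    aPos <- which(startsWith(ord, "a"))
    bPos <- which(startsWith(ord, "b"))
    expect_equal(abs(diff(aPos)), 1)
    expect_equal(abs(diff(bPos)), 1)
    # identical analytes merge first (distance 0)
    x2 <- rbind(p = 1:6, q = 1:6, r = c(9, 1, 4, 2, 8, 5))
    hm2 <- heatmapMatrix(StudyMatrix(x2, rep("g", 6)))
    expect_identical(sort(hm2$hclust$merge[1, ]), c(-2L, -1L))
    # zero-variance analyte: z set to 0 with a warning
    x3 <- rbind(s = rep(3, 5), t = rnorm(5))
    expect_warning(hm3 <- heatmapMatrix(StudyMatrix(x3, rep("g", 5))),
        "zero-variance")
    expect_equal(unname(hm3$z["s", ]), rep(0, 5))
})

test_that("null volcano selects about alpha or fewer analytes", {
    sm <- simulateStudy(400, nPerGroup = 5, cv = 0.1, seed = 3)
    v <- volcanoTable(sm, "WT", "TgTg")
    # p gate alone rejects ~5%; the FC gate prunes further
    expect_lte(mean(v$selected), 0.05)
    expect_gte(mean(v$p_value < 0.05), 0.02)
    expect_lte(mean(v$p_value < 0.05), 0.09)
})
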