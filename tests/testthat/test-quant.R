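test_that("trapezoidal integration subtracts the edge baseline", {
    # triangle on zero baseline
    expect_equal(integratePeak(c(0, 1, 2), c(0, 10, 0)), 10)
    # constant trace equals its own baseline
    expect_equal(integratePeak(seq(0, 2, 0.1), rep(7, 21)), 0)
    # Gaussian closed form A * sigma * sqrt(2*pi)
    t <- seq(9, 11, by = 1 / 60)
    y <- 100 * exp(-(t - 10)^2 / (2 * 0.05^2))
    expect_equal(integratePeak(t, y), 100 * 0.05 * sqrt(2 * pi),
        tolerance = 1e-3)
    # window restriction and sample floor
    expect_equal(integratePeak(c(t, 20), c(y, 5), window = c(9, 11)),
        100 * 0.05 * sqrt(2 * pi), tolerance = 1e-3)
    expect_error(integratePeak(c(0, 1), c(1, 1)), "3 samples")
    # area is clamped non-negative even for a concave-up trace
    expect_gte(integratePeak(c(0, 1, 2, 3), c(10, 0, 0, 10)), 0)
})

test_that("ratio dot product measures pattern similarity", {
    expect_equal(rdotp(c(5, 2, 8), c(5, 2, 8)), 1)
    expect_equal(rdotp(c(1, 0), c(0, 1)), 0)
    expect_equal(rdotp(c(3, 4), c(4, 3)), 0.96)
    expect_equal(rdotp(c(0, 0), c(1, 2)), 0)
    expect_error(rdotp(1, 1), "length")
    # scale invariance over random positive vectors
    set.seed(17)
    for (i in 1:50) {
        x <- runif(4, 0.1, 10)
        y <- runif(4, 0.1, 10)
        r <- rdotp(x, y)
        expect_gte(r, 0)
        expect_lte(r, 1)
        expect_equal(rdotp(37.5 * x, 0.004 * y), r, tolerance = 1e-12)
    }
})

test_that("retention-time match uses a closed boundary", {
    expect_true(rtMatch(10.00, 10.02, tol = 0.10))
    expect_false(rtMatch(10.0, 10.5, tol = 0.10))
    expect_true(rtMatch(10.0, 10.1, tol = 0.10))
})

test_that("interference elimination follows the median/MAD rule", {
    pg <- list(peptide = "X", protein = "P",
        transitionIds = sprintf("t%d", 1:4),
        lightAreas = c(0.50, 0.51, 0.49, 1.50),
        heavyAreas = rep(1, 4),
        lightApex = 10, heavyApex = 10)
    out <- dropInterfered(pg, kMad = 5)
    expect_identical(out$droppedTransitions, "t4")
    expect_identical(out$nRetained, 3L)
    expect_true(out$minTransitionsOk)
    # equal ratios: nothing removed
    pgEq <- pg
    pgEq$lightAreas <- rep(0.5, 4)
    outEq <- dropInterfered(pgEq)
    expect_length(outEq$droppedTransitions, 0)
    expect_identical(outEq$nRetained, 4L)
    # 3 transitions with one interfered cannot drop below the floor
    pg3 <- list(peptide = "X", protein = "P",
        transitionIds = sprintf("t%d", 1:3),
        lightAreas = c(0.50, 0.51, 1.60), heavyAreas = rep(1, 3),
        lightApex = 10, heavyApex = 10)
    out3 <- dropInterfered(pg3)
    expect_false(out3$minTransitionsOk)
})

test_that("quantification gates on rdotp, RT and transition count", {
    mkpg <- function(light, heavy, dApex = 0) {
        list(peptide = "X", protein = "P",
            transitionIds = sprintf("t%d", seq_along(light)),
            lightAreas = light, heavyAreas = heavy,
            lightApex = 10 + dApex, heavyApex = 10)
    }
    # clean: ratio x spike
    q <- quantifyPeptide(mkpg(c(250, 150, 100), c(500, 300, 200)), 10)
    expect_identical(q$qc_status, "pass")
    expect_equal(q$ratio, 0.5, tolerance = 1e-12)
    expect_equal(q$fmol_per_ug, 5, tolerance = 1e-12)
    # no light signal: rdotp is 0 and the gate fails with no value
    qBad <- quantifyPeptide(mkpg(c(0, 0, 0), c(500, 300, 200)), 10)
    expect_identical(qBad$qc_status, "fail_rdotp")
    expect_equal(qBad$rdotp, 0)
    expect_true(is.na(qBad$fmol_per_ug))
    # retention-time mismatch
    qRt <- quantifyPeptide(mkpg(c(250, 150, 100), c(500, 300, 200),
        dApex = 0.5), 10)
    expect_identical(qRt$qc_status, "fail_rt")
    expect_true(is.na(qRt$fmol_per_ug))
    # absent internal standard cannot pass
    qH0 <- quantifyPeptide(mkpg(c(250, 150, 100), c(0, 0, 0)), 10)
    expect_false(qH0$qc_status == "pass")
    expect_true(is.na(qH0$fmol_per_ug))
    # interference on one of three flags, never silently quantifies
    qI <- quantifyPeptide(mkpg(c(250, 150, 320), c(500, 300, 200)), 10)
    expect_identical(qI$qc_status, "fail_min_transitions")
    expect_true(is.na(qI$fmol_per_ug))
})

test_that("sum and mean ratio estimators agree on proportional areas", {
    pg <- list(peptide = "X", protein = "P",
        transitionIds = sprintf("t%d", 1:3),
        lightAreas = c(250, 150, 100), heavyAreas = c(500, 300, 200),
        lightApex = 10, heavyApex = 10)
    qSum <- quantifyPeptide(pg, 10)
    qMean <- quantifyPeptide(pg, 10, ratioMethod = "mean")
    expect_equal(qSum$ratio, qMean$ratio, tolerance = 1e-12)
    # with unequal per-transition ratios the estimators differ:
    # sum weights by area (0.55), mean treats transitions equally (0.533)
    pg2 <- pg
    pg2$lightAreas <- c(300, 150, 100)
    expect_equal(quantifyPeptide(pg2, 10)$ratio, 0.55,
        tolerance = 1e-12)
    expect_equal(quantifyPeptide(pg2, 10, ratioMethod = "mean")$ratio,
        mean(c(0.6, 0.5, 0.5)), tolerance = 1e-12)
})

test_that("protein roll-up averages passing peptides and flags failures", {
    quant <- data.frame(
        protein = c("P1", "P1", "P2"),
        peptide = c("a", "b", "c"),
        rdotp = c(0.99, 0.99, 0.5), rt_delta = 0,
        ratio = c(0.4, 0.6, NA), fmol_per_ug = c(4, 6, NA),
        n_retained = 3L,
        qc_status = c("pass", "pass", "fail_rdotp"),
        stringsAsFactors = FALSE)
    ru <- rollUpProteins(quant)
    p1 <- ru[ru$protein == "P1", ]
    expect_equal(p1$fmol_per_ug, 5)
    expect_identical(p1$n_peptides, 2L)
    expect_equal(p1$cv, sd(c(4, 6)) / 5, tolerance = 1e-12)
    p2 <- ru[ru$protein == "P2", ]
    expect_false(p2$quantified)
    expect_true(is.na(p2$fmol_per_ug))
    # single passing peptide: protein value equals it
    one <- rollUpProteins(quant[1, , drop = FALSE])
    expect_equal(one$fmol_per_ug, 4)
})
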