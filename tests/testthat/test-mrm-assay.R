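test_that("instrument parameter equations match hand arithmetic", {
    expect_equal(declusteringPotential(500), 67.1, tolerance = 1e-9)
    expect_equal(declusteringPotential(1000), 91.6, tolerance = 1e-9)
    expect_equal(collisionEnergy(600, 2), 28.5, tolerance = 1e-9)
    expect_equal(collisionEnergy(500, 3), 24.6, tolerance = 1e-9)
    expect_equal(collisionCellExitPotential(400), 13.41, tolerance = 1e-9)
    # the two CE ramps agree at their crossover precursor m/z
    q <- 9.3 / 0.018
    expect_equal(collisionEnergy(q, 2), collisionEnergy(q, 3),
        tolerance = 1e-9)
    expect_equal(collisionEnergy(q, 2), 25.5, tolerance = 1e-9)
    expect_error(collisionEnergy(500, 1), "2\\+ and 3\\+")
    expect_error(declusteringPotential(-1), "positive")
    expect_warning(collisionCellExitPotential(50), "non-positive")
})

test_that("transition building pairs light and heavy by label shift", {
    tr <- buildTransitions("LVNELTEFAK", rt = 10)
    light <- tr[tr$label == "light", ]
    heavy <- tr[tr$label == "heavy", ]
    # candidates y3..y9, highest-index three retained
    expect_identical(light$fragment, c("y9", "y8", "y7"))
    expect_gte(nrow(light), 3L)
    expect_identical(light$transition_id, heavy$transition_id)
    expect_equal(unique(heavy$q1 - light$q1), labelShift("K") / 2,
        tolerance = 1e-9)
    expect_equal(heavy$q3 - light$q3, rep(labelShift("K"), 3),
        tolerance = 1e-9)
    expect_true(all(tr$ep == 10))
    expect_error(buildTransitions("SHRTK"), "too short")
})

test_that("stored voltages reproduce the formulas bit for bit", {
    set.seed(31)
    peps <- vapply(1:10, function(i) randomPeptide(sample(7:18, 1)),
        character(1))
    rtTable <- data.frame(peptide = peps, rt = runif(10, 5, 25))
    tr <- buildAssay(peps, rtTable)
    expect_identical(tr$dp, declusteringPotential(tr$q1))
    expect_identical(tr$ce, collisionEnergy(tr$q1, tr$precursor_charge))
    expect_identical(tr$cxp, collisionCellExitPotential(tr$q3))
    # co-elution: light and heavy share predicted RT and window
    byId <- split(tr, tr$transition_id)
    expect_true(all(vapply(byId, function(b) {
        length(unique(b$rt)) == 1 && length(unique(b$window_start)) == 1
    }, logical(1))))
    # symmetric equal-width windows
    expect_equal(unique(round(tr$window_end - tr$window_start, 9)), 2)
    expect_equal(tr$rt - tr$window_start, tr$window_end - tr$rt,
        tolerance = 1e-12)
})

test_that("2+ precursors switch to 3+ above the m/z ceiling", {
    long <- paste0(paste(rep("W", 14), collapse = ""), "K") # heavy peptide
    expect_true(precursorMz(long, 2) > 1250)
    tr <- buildTransitions(long, rt = 10)
    expect_true(all(tr$precursor_charge == 3L))
    expect_identical(unique(buildTransitions("LVNELTEFAK",
        rt = 10)$precursor_charge), 2L)
})

test_that("scheduling windows, concurrency and dwell are reported", {
    peps <- c("LVNELTEFAK", "SAMPLEPTIDER", "TTDLNEAGIK")
    rtTable <- data.frame(peptide = peps, rt = c(10, 10.5, 20))
    tr <- buildAssay(peps, rtTable)
    sched <- scheduleAssay(tr)
    w <- sched$transitions[sched$transitions$peptide == "LVNELTEFAK", ]
    expect_equal(unique(w$window_start), 9)
    expect_equal(unique(w$window_end), 11)
    # 2 peptides x 6 transitions overlap in [9.5, 11.0]
    expect_equal(sched$maxConcurrent, 12)
    expect_equal(sched$dwellMs, (1000 - 12 * 2) / 12, tolerance = 1e-9)
    # crowding warning when dwell drops below the floor
    many <- data.frame(peptide = sprintf("PEP%d", 1:200),
        rt = rep(15, 200))
    crowded <- do.call(rbind, lapply(seq_len(200), function(i) {
        t1 <- buildTransitions("LVNELTEFAK", rt = 15)
        t1$transition_id <- paste0(t1$transition_id, ".", i)
        t1
    }))
    expect_warning(scheduleAssay(crowded), "dwell")
})

test_that("dwell arithmetic matches the cycle-time budget", {
    # 100 concurrent transitions, 1-s scan, 2-ms overhead -> 8 ms each
    st <- assaySettings()
    n <- 100
    expect_equal((st$targetScanTime * 1000 - n * st$overheadMs) / n, 8)
})

test_that("acylcarnitine precursor-ion-scan CE follows chain length", {
    expect_equal(acylcarnitineCE("C4")$ce, -20)
    expect_equal(acylcarnitineCE("C4")$product_mz, 85.05)
    expect_equal(acylcarnitineCE("C12:1")$ce, -25)
    expect_equal(acylcarnitineCE("C16")$ce, -35)
    expect_equal(acylcarnitineCE(c("C0", "C8", "C10:1", "C14:OH",
        "C16-OH", "C18:OH"))$ce, c(-20, -20, -25, -25, -35, -35))
    expect_error(acylcarnitineCE("C20"), "0-18")
    expect_error(acylcarnitineCE("X4"), "unparsable")
})

test_that("transition lists round-trip through CSV", {
    peps <- c("LVNELTEFAK", "SAMPLEPTIDER")
    rtTable <- data.frame(peptide = peps, rt = c(10, 14))
    tr <- buildAssay(peps, rtTable, proteinIds = c("P1", "P2"))
    path <- tempfile(fileext = ".csv")
    writeTransitionList(tr, path)
    expect_identical(readLines(path, n = 1),
        paste("protein_id,peptide,label,precursor_charge,q1,fragment,q3",
            "dp,ce,cxp,ep,rt,window_start,window_end", sep = ","))
    back <- readTransitionList(path)
    expect_identical(back$transition_id, tr$transition_id)
    expect_equal(back$q1, tr$q1, tolerance = 1e-12)
    expect_equal(back$q3, tr$q3, tolerance = 1e-12)
    expect_equal(back$ce, tr$ce, tolerance = 1e-12)
    expect_identical(back$protein_id, tr$protein_id)
})
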