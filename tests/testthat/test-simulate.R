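test_that("simulators are pure functions of (scenario, seed)", {
    sc <- smallScenario(seed = 5)
    expect_identical(simulateReferenceCohort(sc)@.Data,
                     simulateReferenceCohort(sc)@.Data)
    a <- simulateTumorCohort(sc); b <- simulateTumorCohort(sc)
    expect_identical(a$expression@.Data, b$expression@.Data)
    expect_identical(a$mutations, b$mutations)
    other <- simulateReferenceCohort(smallScenario(seed = 6))
    expect_false(identical(other@.Data, simulateReferenceCohort(sc)@.Data))
})

test_that("reference cohort means respect the NB model (CLT bound)", {
    sc <- simulationScenario(nGenes = 5, nNormals = 2000,
                             nbMeanRange = c(50, 50), nbDispersion = 10,
                             seed = 3)
    ref <- simulateReferenceCohort(sc)
    se <- sqrt((50 + 50^2 / 10) / 2000)
    expect_true(all(abs(rowMeans(ref@.Data) - 50) < 3 * se))
})

test_that("large NB size approaches the Poisson variance limit", {
    sc <- simulationScenario(nGenes = 1, nNormals = 5000,
                             nbMeanRange = c(40, 40), nbDispersion = 1e6,
                             seed = 9)
    x <- as.vector(simulateReferenceCohort(sc)@.Data)
    expect_lt(abs(var(x) / mean(x) - 1), 0.1)
})

test_that("mutated fraction matches the binomial bound", {
    sc <- simulationScenario(nGenes = 10, nNormals = 5, nTumors = 1000,
        drivers = list(driverSpec("D1", 0.3, 1:3, 1)), seed = 21)
    tum <- simulateTumorCohort(sc)
    frac <- mean(tum$mutations[, "D1"])
    expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / 1000))
})

test_that("zero effect leaves the tumor marginal at the reference (KS)", {
    sc <- simulationScenario(nGenes = 1, nNormals = 5000, nTumors = 5000,
        nbMeanRange = c(100, 100), nbDispersion = 10,
        drivers = list(driverSpec("D1", 0.5, 1L, 0)), seed = 13)
    ref <- as.vector(simulateReferenceCohort(sc)@.Data)
    tum <- as.vector(simulateTumorCohort(sc)$expression@.Data)
    p <- suppressWarnings(ks.test(ref, tum)$p.value)
    expect_gt(p, 0.01)
})

test_that("subtype forcing guarantees active-driver mutations", {
    sc <- simulationScenario(nGenes = 10, nTumors = 300, nNormals = 5,
        drivers = list(driverSpec("D1", 0.1, 1:2, 1)),
        subtypes = list(subtypeSpec("A", 0.5, "D1", 2),
                        subtypeSpec("B", 0.5, character(), 1)),
        seed = 2)
    tum <- simulateTumorCohort(sc)
    inA <- names(tum$subtypes)[tum$subtypes == "A"]
    expect_true(all(tum$mutations[inA, "D1"] == 1))
})

test_that("survival generator respects hazards, censoring and errors", {
    sc <- simulationScenario(nGenes = 10, nNormals = 5, nTumors = 600,
        drivers = list(driverSpec("D1", 0.3, 1:2, 1)),
        subtypes = list(subtypeSpec("hi", 0.5, character(), 4),
                        subtypeSpec("lo", 0.5, character(), 1)),
        survival = survivalSpec(baselineHazard = 1e-3, censoringRate = 0,
                                maxFollowup = Inf),
        seed = 31)
    labels <- setNames(rep(c("hi", "lo"), 300), sprintf("t%03d", 1:600))
    clin <- simulateSurvival(labels, sc)
    expect_true(all(clin$event == 1))  # no censoring in this limit
    medHi <- median(clin$time[clin$subtype == "hi"])
    medLo <- median(clin$time[clin$subtype == "lo"])
    expect_lt(medHi, medLo)
    expect_error(simulateSurvival(c(x = "unknown"), sc), "unknown")
})

test_that("equal hazards give a calibrated (null) log-rank test", {
    rejections <- vapply(1:100, function(s) {
        sc <- simulationScenario(nGenes = 2, nNormals = 5, nTumors = 200,
            drivers = list(driverSpec("D1", 0.3, 1L, 1)),
            subtypes = list(subtypeSpec("A", 0.5, character(), 1),
                            subtypeSpec("B", 0.5, character(), 1)),
            survival = survivalSpec(baselineHazard = 1e-3,
                                    censoringRate = 2e-4),
            seed = 5000 + s)
        labels <- setNames(rep(c("A", "B"), 100), sprintf("s%03d", 1:200))
        clin <- simulateSurvival(labels, sc)
        logrankTest(clin, setNames(clin$subtype, clin$sample_id))$p_value < 0.05
    }, logical(1))
    expect_gte(mean(!rejections), 0.9)
})

test_that("4x hazard arm has the lower KM median, seed over seed", {
    lower <- vapply(1:100, function(s) {
        sc <- simulationScenario(nGenes = 2, nNormals = 5, nTumors = 600,
            drivers = list(driverSpec("D1", 0.3, 1L, 1)),
            subtypes = list(subtypeSpec("hi", 0.5, character(), 4),
                            subtypeSpec("lo", 0.5, character(), 1)),
            survival = survivalSpec(baselineHazard = 5e-4, censoringRate = 0,
                                    maxFollowup = Inf),
            seed = 7000 + s)
        labels <- setNames(rep(c("hi", "lo"), 300), sprintf("s%03d", 1:600))
        clin <- simulateSurvival(labels, sc)
        median(clin$time[clin$subtype == "hi"]) <
            median(clin$time[clin$subtype == "lo"])
    }, logical(1))
    expect_gte(mean(lower), 0.99)
})

test_that("promoter simulation plants recoverable motifs deterministically", {
    pwm <- consensusPwm("ACGTACGTACGT")
    plants <- list(`1` = data.frame(position = 10, strand = "+"),
                   `3` = data.frame(position = c(0, 40), strand = c("-", "+")))
    seqs <- simulatePromoters(3, 80, pwm, plants, seed = 17)
    expect_identical(seqs, simulatePromoters(3, 80, pwm, plants, seed = 17))
    expect_identical(substr(as.character(seqs[[1]]), 11, 22), "ACGTACGTACGT")
    hits3 <- scanPwm(as.character(seqs[[3]]), pwm, 1.0)
    expect_true(all(c(0, 40) %in% hits3$position))
    expect_error(simulatePromoters(1, 80, pwm,
        list(`1` = data.frame(position = c(0, 5), strand = "+")), seed = 1),
        "overlapping")
    expect_error(simulatePromoters(1, 20, pwm,
        list(`1` = data.frame(position = 15, strand = "+")), seed = 1),
        "out of bounds")
})

test_that("scenario fixtures round-trip through the readers", {
    sc <- simulationScenario(nGenes = 30, nNormals = 10, nTumors = 20,
        drivers = list(driverSpec("D1", 0.4, 1:5, 1.5)),
        subtypes = list(subtypeSpec("A", 0.5, "D1", 2),
                        subtypeSpec("B", 0.5, character(), 1)),
        seed = 8)
    dir <- withr::local_tempdir()
    paths <- writeScenarioFixtures(sc, dir)
    expect_true(all(file.exists(paths)))
    back <- readExpressionMatrix(paths[["tumors"]], "raw_counts")
    expect_identical(back@.Data, simulateTumorCohort(sc)$expression@.Data)
})
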