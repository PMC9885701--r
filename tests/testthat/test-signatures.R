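test_that("support counts and majority directions follow the hand example", {
    deg <- BinaryDEGMatrix(matrix(
        c( 1, 1, 1, 0, 0,    # gene A: flags in 3 of 4 mutated
           1, 0, 0, 0, 1,    # gene B: 1 of 4 mutated (s5 not mutated)
           0, 0, 0, 0, 0,    # gene C: none
           1, 1,-1,-1, 0),   # gene D: tie 2 up / 2 down
        nrow = 4, byrow = TRUE,
        dimnames = list(c("A", "B", "C", "D"), paste0("s", 1:5))))
    mut <- matrix(c(1, 1, 1, 1, 0), 5, 1,
                  dimnames = list(paste0("s", 1:5), "DRV"))
    sup <- countDegSupport(deg, mut, "DRV")
    expect_identical(sup$count, c(3L, 1L, 0L, 4L))
    expect_identical(sup$direction, c(1L, 1L, 0L, 0L))
    expect_identical(attr(sup, "nMut"), 4L)

    expect_error(countDegSupport(deg, mut * 0, "DRV"), "no mutated samples")
    expect_error(countDegSupport(deg, mut, "OTHER"), "not in mutation table")
})

test_that("quantile selection uses strict > on the type-7 quantile", {
    counts <- data.frame(gene = sprintf("g%03d", 1:100),
                         count = c(rep(0L, 97), 5L, 6L, 7L))
    sel <- selectAboveQuantile(counts, 0.98)
    expect_equal(attr(sel, "threshold"), 5.02)  # h = 0.98*99 + 1 = 98.02
    expect_setequal(as.character(sel), c("g099", "g100"))

    allEqual <- data.frame(gene = paste0("g", 1:10), count = rep(3L, 10))
    expect_length(selectAboveQuantile(allEqual, 0.98), 0)

    one <- data.frame(gene = "g1", count = 5L)
    expect_length(selectAboveQuantile(one, 0.98), 0)
})

test_that("unique-marker assignment removes shared genes then filters", {
    out <- assignUniqueMarkers(list(
        sig1 = c("A", "B", "C"),
        sig2 = c("B", "C", "D", "E", "F", "G", "H")), minMarkers = 5)
    expect_length(out, 1)
    expect_setequal(markers(out[["sig2"]]), c("D", "E", "F", "G", "H"))

    disjoint <- assignUniqueMarkers(list(
        s1 = paste0("a", 1:5), s2 = paste0("b", 1:6)), minMarkers = 5)
    expect_length(disjoint, 2)
    expect_identical(markers(disjoint[["s1"]]), paste0("a", 1:5))

    same <- assignUniqueMarkers(list(s1 = c("x", "y"), s2 = c("x", "y")),
                                minMarkers = 1)
    expect_length(same, 0)
})

test_that("derivation recovers a planted single-driver signature", {
    sc <- simulationScenario(nGenes = 500, nNormals = 100, nTumors = 200,
        drivers = list(driverSpec("D1", 0.3, 1:10, 2)), seed = 42)
    co <- simulateCohort(sc)
    deg <- binarizeMatrix(co$tumors, fitReferenceModel(co$normals), 0.05)
    sigs <- deriveSignatures(deg, co$mutations,
                             oncoConfig(supportQuantile = 0.98, minMarkers = 5))
    expect_length(sigs, 1)
    expect_gte(mean(co$truth$targets$D1 %in% markers(sigs[["D1"]])), 0.8)
    # planted up-regulation should be recorded as +1 directions
    expect_true(all(markerDirections(sigs[["D1"]])[
        intersect(markers(sigs[["D1"]]), co$truth$targets$D1)] == 1L))
})

test_that("minMarkers = 1 keeps a single-gene signature", {
    deg <- BinaryDEGMatrix(matrix(
        c(rep(1L, 8), rep(0L, 72)), nrow = 10, byrow = TRUE,
        dimnames = list(paste0("g", 1:10), paste0("s", 1:8))))
    mut <- matrix(1L, 8, 1, dimnames = list(paste0("s", 1:8), "D"))
    sigs <- deriveSignatures(deg, mut, oncoConfig(minMarkers = 1))
    expect_length(sigs, 1)
    expect_identical(markers(sigs[["D"]]), "g1")
})

test_that("retained signatures are disjoint and selection is order-invariant", {
    sc <- defaultScenario(seed = 3)
    co <- simulateCohort(sc)
    deg <- binarizeMatrix(co$tumors, fitReferenceModel(co$normals), 0.05)
    sigs <- deriveSignatures(deg, co$mutations, oncoConfig())
    allMarkers <- unlist(lapply(sigs@.Data, markers))
    expect_identical(anyDuplicated(allMarkers), 0L)

    # permute genes and samples: same signatures
    v <- deg@.Data
    set.seed(1)
    perm <- BinaryDEGMatrix(v[sample(nrow(v)), sample(ncol(v))])
    sigs2 <- deriveSignatures(perm, co$mutations, oncoConfig())
    expect_identical(lapply(sigs@.Data, function(s) sort(markers(s))),
                     lapply(sigs2@.Data, function(s) sort(markers(s))))
})

test_that("raising the support quantile never grows a signature", {
    sc <- smallScenario(seed = 12)
    co <- simulateCohort(sc)
    deg <- binarizeMatrix(co$tumors, fitReferenceModel(co$normals), 0.05)
    sizes <- vapply(c(0.90, 0.98, 0.999), function(q) {
        s <- deriveSignatures(deg, co$mutations,
                              oncoConfig(supportQuantile = q, minMarkers = 1))
        if (length(s)) length(markers(s[[1]])) else 0L
    }, integer(1))
    expect_true(all(diff(sizes) <= 0))
})
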