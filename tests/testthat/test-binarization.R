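test_that("method-of-moments reference fit matches hand formulas", {
    m <- ExpressionMatrix(matrix(c(5, 10, 15, 10, 10), 1, 5,
        dimnames = list("g1", paste0("n", 1:5))), "raw_counts")
    fit <- modelParameters(fitReferenceModel(m))
    expect_equal(fit$mean, 10)
    expect_identical(fit$family, "negative_binomial")
    expect_equal(fit$dispersion_or_sd, 100 / 2.5)  # size = mean^2/(var - mean)

    const <- ExpressionMatrix(matrix(7, 1, 4,
        dimnames = list("g1", paste0("n", 1:4))), "raw_counts")
    cf <- modelParameters(fitReferenceModel(const))
    expect_identical(cf$family, "poisson")
    expect_equal(cf$mean, 7)

    single <- ExpressionMatrix(matrix(5, 1, 1,
        dimnames = list("g1", "n1")), "raw_counts")
    expect_error(fitReferenceModel(single), "at least 2")

    norm <- ExpressionMatrix(matrix(c(1.5, 2.5, 3.5), 1, 3,
        dimnames = list("g1", paste0("n", 1:3))), "normalized")
    nf <- modelParameters(fitReferenceModel(norm))
    expect_identical(nf$family, "gaussian")
    expect_equal(nf$dispersion_or_sd, 1)
})

test_that("tail probabilities match pmf summation and closed forms", {
    const2 <- ExpressionMatrix(matrix(2, 1, 4,
        dimnames = list("g1", paste0("n", 1:4))), "raw_counts")
    mod <- fitReferenceModel(const2)  # Poisson(2)
    t5 <- tailProbabilities(mod, "g1", 5)
    expect_equal(t5$p_upper, pmfUpperTail(5, function(k) dpois(k, 2)),
                 tolerance = 1e-12)
    expect_equal(t5$p_upper, 0.0527, tolerance = 1e-3)
    t0 <- tailProbabilities(mod, "g1", 0)
    expect_equal(t0$p_upper, 1)           # full mass at x = 0
    expect_equal(t0$p_lower, exp(-2), tolerance = 1e-12)
    expect_error(tailProbabilities(mod, "g1", 2.5), "integer")
    expect_error(tailProbabilities(mod, "nope", 1), "not in reference")
})

test_that("discrete tails satisfy p_upper + p_lower = 1 + P(X = x)", {
    m <- ExpressionMatrix(matrix(rnbinom(200, mu = 30, size = 5), 1, 200,
        dimnames = list("g1", paste0("n", 1:200))), "raw_counts")
    mod <- fitReferenceModel(m)
    pars <- modelParameters(mod)
    for (x in c(0, 5, 30, 80)) {
        t <- tailProbabilities(mod, "g1", x)
        pmfx <- if (pars$family == "negative_binomial")
            dnbinom(x, mu = pars$mean, size = pars$dispersion_or_sd)
        else dpois(x, pars$mean)
        expect_equal(t$p_upper + t$p_lower, 1 + pmfx, tolerance = 1e-12)
    }
})

test_that("binarization assigns -1/0/+1 by per-tail alpha", {
    const2 <- ExpressionMatrix(matrix(2, 1, 4,
        dimnames = list("g1", paste0("n", 1:4))), "raw_counts")
    mod2 <- fitReferenceModel(const2)
    tum <- function(x) ExpressionMatrix(matrix(x, 1, 1,
        dimnames = list("g1", "t1")), "raw_counts")
    expect_equal(as.vector(binarizeMatrix(tum(6), mod2, 0.05)@.Data), 1)
    expect_equal(as.vector(binarizeMatrix(tum(5), mod2, 0.05)@.Data), 0)

    const10 <- ExpressionMatrix(matrix(10, 1, 4,
        dimnames = list("g1", paste0("n", 1:4))), "raw_counts")
    mod10 <- fitReferenceModel(const10)
    expect_equal(as.vector(binarizeMatrix(tum(0), mod10, 0.05)@.Data), -1)

    expect_error(binarizeMatrix(
        ExpressionMatrix(matrix(1, 1, 1, dimnames = list("gX", "t1")),
                         "raw_counts"), mod2, 0.05), "missing from reference")
    expect_error(binarizeMatrix(tum(1), mod2, 0.7), "alpha")
})

test_that("zero-mean reference genes flag any positive count up, never down", {
    zeros <- ExpressionMatrix(matrix(0, 1, 5,
        dimnames = list("g1", paste0("n", 1:5))), "raw_counts")
    mod <- fitReferenceModel(zeros)
    tum <- ExpressionMatrix(matrix(c(0, 1, 4), 1, 3,
        dimnames = list("g1", c("t1", "t2", "t3"))), "raw_counts")
    deg <- binarizeMatrix(tum, mod, 0.05)
    expect_equal(as.vector(deg@.Data), c(0, 1, 1))
})

test_that("binary calls are monotone non-decreasing in the observed value", {
    set.seed(4)
    m <- ExpressionMatrix(matrix(rnbinom(5 * 100, mu = rep(c(3, 12, 50, 200, 800), 100),
        size = 8), 5, 100, dimnames = list(paste0("g", 1:5), paste0("n", 1:100))),
        "raw_counts")
    mod <- fitReferenceModel(m)
    grid <- 0:1500
    for (g in paste0("g", 1:5)) {
        tum <- ExpressionMatrix(matrix(grid, 1, length(grid),
            dimnames = list(g, paste0("t", grid))), "raw_counts")
        calls <- as.vector(binarizeMatrix(tum, mod, 0.05)@.Data)
        expect_true(all(diff(calls) >= 0))
    }
})
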