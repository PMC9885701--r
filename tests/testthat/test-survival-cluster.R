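makeNes <- function(v) NESMatrix(v)

test_that("Cox screen selects by raw Wald p and flags degenerate covariates", {
    set.seed(20)
    n <- 300
    z <- runif(n)
    haz <- 1e-3 * exp(2.5 * scale(z)[, 1])
    evt <- rexp(n, haz); cens <- rexp(n, 4e-4)
    clin <- data.frame(sample_id = paste0("s", 1:n),
                       time = pmin(evt, cens),
                       event = as.integer(evt <= cens))
    v <- rbind(signal = z, flat = rep(0.5, n), noise = runif(n))
    colnames(v) <- clin$sample_id
    nes <- makeNes(v)
    res <- coxScreen(nes, clin, 0.05)
    expect_true(res$selected[res$signature == "signal"])
    expect_false(res$estimable[res$signature == "flat"])
    expect_false(res$selected[res$signature == "flat"])
    expect_gt(res$log_hazard_ratio[res$signature == "signal"], 0)
    expect_true(all(res$q_value >= res$p_value - 1e-12, na.rm = TRUE))
})

test_that("well-separated NES blobs are perfectly recovered at k = 2", {
    set.seed(5)
    n <- 60
    v <- cbind(matrix(rnorm(2 * n, 0.2, 0.01), 2),
               matrix(rnorm(2 * n, 0.8, 0.01), 2))
    dimnames(v) <- list(c("sig1", "sig2"), paste0("s", 1:(2 * n)))
    cl <- wardCluster(makeNes(v), 2)
    truth <- rep(1:2, each = n)
    lab <- clusterLabels(cl)
    expect_equal(length(unique(lab)), 2)
    expect_true(all(table(lab[truth == 1]) == n) ||
                all(table(lab[truth == 2]) == n))
    # duplicated columns always co-cluster
    dup <- v; dup[, 2] <- dup[, 1]
    cl2 <- wardCluster(makeNes(dup), 2)
    expect_equal(clusterLabels(cl2)[1], clusterLabels(cl2)[2],
                 ignore_attr = TRUE)
})

test_that("cluster labelling is deterministic and order-invariant", {
    set.seed(8)
    v <- matrix(runif(3 * 50), 3, 50,
                dimnames = list(paste0("sig", 1:3), paste0("s", 1:50)))
    nes <- makeNes(v)
    cl <- wardCluster(nes, 4)
    sizes <- table(clusterLabels(cl))
    expect_true(all(diff(as.integer(sizes)) <= 0))  # renumbered by size

    perm <- sample(50)
    cl2 <- wardCluster(makeNes(v[, perm]), 4)
    expect_identical(clusterLabels(cl2)[colnames(v)], clusterLabels(cl))

    expect_identical(unique(clusterLabels(wardCluster(nes, 1))), 1L)
    expect_error(wardCluster(makeNes(v[, 1:3]), 4), "at least k")
})

test_that("KM estimator matches the hand product-limit and empirical cases", {
    clin <- data.frame(sample_id = c("a", "b", "c"),
                       time = c(1, 2, 3), event = c(1, 0, 1))
    km <- kmEstimate(clin)
    expect_equal(km$survival[km$time == 1], 2 / 3)
    expect_equal(km$survival[km$time == 3], 0)
    expect_true(all(diff(km$survival) <= 0))

    censOnly <- data.frame(sample_id = c("a", "b"), time = c(5, 9),
                           event = c(0, 0))
    expect_true(all(kmEstimate(censOnly)$survival == 1))

    # all events, distinct times, no censoring: S(t_(i)) = (n - i)/n
    n <- 7
    ev <- data.frame(sample_id = paste0("s", 1:n), time = 1:n,
                     event = rep(1, n))
    expect_equal(kmEstimate(ev)$survival, (n - 1:n) / n)

    expect_error(kmEstimate(transform(ev, time = -time)), "time")
})

test_that("log-rank statistic matches a 4-time-point hand calculation", {
    clin <- data.frame(sample_id = paste0("s", 1:4),
                       time = c(1, 2, 3, 4), event = rep(1, 4))
    labels <- setNames(c("A", "A", "B", "B"), clin$sample_id)
    lr <- logrankTest(clin, labels)
    # O_A = 2, E_A = 1/2 + 1/3, V = 1/4 + 2/9 => chisq = 49/17
    expect_equal(lr$statistic, 49 / 17, tolerance = 1e-10)
    expect_identical(lr$df, 1L)

    dupl <- data.frame(sample_id = paste0("s", 1:8),
                       time = rep(c(1, 3, 5, 7), 2), event = rep(1, 8))
    same <- setNames(rep(c("A", "B"), each = 4), dupl$sample_id)
    expect_equal(logrankTest(dupl, same)$statistic, 0, tolerance = 1e-12)

    expect_error(logrankTest(clin, setNames(rep("A", 4), clin$sample_id)),
                 "two groups")
})

test_that("log-rank detects a 4-fold hazard ratio with high power", {
    hits <- vapply(1:50, function(s) {
        set.seed(900 + s)
        n <- 300
        tA <- rexp(n, 4e-3); tB <- rexp(n, 1e-3)
        clin <- data.frame(sample_id = paste0("s", 1:(2 * n)),
                           time = c(tA, tB), event = rep(1, 2 * n))
        labels <- setNames(rep(c("A", "B"), each = n), clin$sample_id)
        logrankTest(clin, labels)$p_value < 0.05
    }, logical(1))
    expect_gte(mean(hits), 0.99)
})
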