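# Shared fixtures and independent oracles used across test files.

toyExpression <- function(scale = "raw_counts") {
    m <- matrix(c(5, 1, 9, 10, 2, 18), nrow = 3,
                dimnames = list(c("gA", "gB", "gC"), c("s1", "s2")))
    ExpressionMatrix(m, scale)
}

# Brute-force pairwise MWW probability: fraction of (in, out) pairs where
# the in-set gene's expression is greater, ties counting one half.
pairwiseNesOracle <- function(profile, geneSet) {
    inVals <- profile[names(profile) %in% geneSet]
    outVals <- profile[!names(profile) %in% geneSet]
    cmp <- outer(inVals, outVals, function(a, b)
        (a > b) + 0.5 * (a == b))
    mean(cmp)
}

# Brute-force BH step-up, written from the definition: adjusted p at rank k
# is min(1, min_{j >= k} (m/j) p_(j)).
bhOracle <- function(p) {
    m <- length(p)
    o <- order(p)
    s <- p[o]
    adj <- numeric(m)
    for (k in m:1) {
        val <- (m / k) * s[k]
        adj[k] <- if (k == m) min(1, val) else min(adj[k + 1L], val, 1)
    }
    out <- numeric(m)
    out[o] <- adj
    out
}

# Discrete upper tail P(X >= x) by pmf summation from zero.
pmfUpperTail <- function(x, pmf, upTo = 10000) {
    if (x <= 0) return(1)
    1 - sum(pmf(0:(x - 1)))
}

randomMutationTable <- function(samples, drivers, prob = 0.4, seed = 1) {
    withr::with_seed(seed, {
        m <- matrix(rbinom(length(samples) * length(drivers), 1, prob),
                    nrow = length(samples),
                    dimnames = list(samples, drivers))
        m
    })
}

smallScenario <- function(seed = 1, ...) {
    simulationScenario(nGenes = 60, nNormals = 30, nTumors = 40,
                       drivers = list(driverSpec("D1", 0.4, 1:10, 2)),
                       seed = seed, ...)
}
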