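#' @include AllClasses.R
NULL

#' Midranks of one expression profile
#'
#' Ascending ranks with ties sharing the average rank, so ranks always sum
#' to N(N+1)/2.
#'
#' @param profile named numeric vector of one sample's expression; all
#'   values finite, length >= 2.
#' @return numeric vector of midranks, same names.
#' @examples
#' rankSample(c(a = 1, b = 2, c = 2, d = 3))  # 1, 2.5, 2.5, 4
#' @export
rankSample <- function(profile) {
    if (length(profile) < 2L) stop("profile needs at least 2 genes")
    if (any(!is.finite(profile))) stop("profile contains non-finite values")
    rank(profile, ties.method = "average")
}

#' Single-sample Mann-Whitney-Wilcoxon enrichment score
#'
#' Competitive gene-set test on one expression profile. With m genes in the
#' set, n outside, and T the sum of the in-set midranks,
#' U = mn + m(m+1)/2 - T and NES = 1 - U/(mn): the probability that a gene
#' inside the set is expressed above a gene outside it (ties count 1/2).
#'
#' @param profile named numeric expression vector of one sample.
#' @param geneSet character vector of gene ids; its intersection with the
#'   profile must be non-empty and proper.
#' @return list with `nes` and `summary` (m, n, T, U).
#' @examples
#' p <- c(g1 = 10, g2 = 9, g3 = 3, g4 = 2, g5 = 1)
#' mwwNes(p, c("g1", "g2"))$nes  # 1: maximal enrichment
#' @export
mwwNes <- function(profile, geneSet) {
    r <- rankSample(profile)
    inSet <- names(profile) %in% geneSet
    m <- sum(inSet); n <- sum(!inSet)
    if (m == 0L) stop("gene set does not intersect the profile")
    if (n == 0L) stop("gene set covers the whole profile")
    T <- sum(r[inSet])
    U <- m * n + m * (m + 1) / 2 - T
    list(nes = 1 - U / (m * n),
         summary = list(m = m, n = n, T = T, U = U))
}

#' NES matrix of a signature collection over a cohort
#'
#' Applies [mwwNes()] to every sample with every signature's marker genes.
#' Signatures with no profiled marker are dropped with a warning; marker
#' directions are ignored (the test is competitive on the plain set).
#'
#' @param expr an [ExpressionMatrix-class].
#' @param signatures an [OncoSignatureSet-class], or a named list of
#'   character gene sets.
#' @return An [NESMatrix-class], signatures x samples.
#' @examples
#' sc <- defaultScenario(seed = 7)
#' tum <- simulateTumorCohort(sc)
#' nes <- nesMatrix(tum$expression,
#'     list(set1 = rownames(tum$expression)[1:40]))
#' @export
nesMatrix <- function(expr, signatures) {
    stopifnot(is(expr, "ExpressionMatrix"))
    sets <- if (is(signatures, "OncoSignatureSet"))
        lapply(signatures@.Data, function(s) s@markers)
    else signatures
    if (is.null(names(sets)) && is(signatures, "OncoSignatureSet"))
        names(sets) <- vapply(signatures@.Data, function(s) s@driver,
                              character(1))
    v <- expr@.Data
    genes <- rownames(v)
    N <- length(genes)
    keep <- vapply(sets, function(s) {
        m <- sum(genes %in% s)
        m >= 1L && m < N
    }, logical(1))
    if (any(!keep))
        warning("signatures dropped (empty or full profile intersection): ",
                paste(names(sets)[!keep], collapse = ", "))
    sets <- sets[keep]
    if (length(sets) == 0L) stop("no signature intersects the profiled genes")
    ranks <- apply(v, 2L, rank, ties.method = "average")
    out <- matrix(NA_real_, nrow = length(sets), ncol = ncol(v),
                  dimnames = list(names(sets), colnames(v)))
    for (i in seq_along(sets)) {
        inSet <- genes %in% sets[[i]]
        m <- sum(inSet); n <- N - m
        T <- colSums(ranks[inSet, , drop = FALSE])
        U <- m * n + m * (m + 1) / 2 - T
        out[i, ] <- 1 - U / (m * n)
    }
    NESMatrix(out)
}
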