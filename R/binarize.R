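#' @include AllClasses.R
NULL

#' Fit per-gene reference distributions on normal samples
#'
#' For raw counts each gene gets a method-of-moments negative-binomial fit:
#' mean = sample mean, size = mean^2 / (variance - mean). Genes whose sample
#' variance does not exceed the mean (where the NB size is undefined) fall
#' back to Poisson. For normalized data each gene gets a Gaussian
#' (mean, sd) fit.
#'
#' @param normals an [ExpressionMatrix-class] of at least two normal
#'   samples; integer-valued when scale is \code{"raw_counts"}.
#' @return A [ReferenceModel-class].
#' @examples
#' m <- ExpressionMatrix(matrix(c(5, 10, 15, 10, 10), 1, 5,
#'     dimnames = list("g1", paste0("n", 1:5))), "raw_counts")
#' modelParameters(fitReferenceModel(m))  # mean 10, NB size 40
#' @export
fitReferenceModel <- function(normals) {
    stopifnot(is(normals, "ExpressionMatrix"))
    v <- normals@.Data
    if (ncol(v) < 2L)
        stop("at least 2 normal samples are required to fit the reference")
    counts <- exprScale(normals) == "raw_counts"
    if (counts && any(v != round(v)))
        stop("raw_counts reference requires integer-valued data")
    mu <- rowMeans(v)
    s2 <- apply(v, 1L, stats::var)
    if (counts) {
        overdispersed <- s2 > mu
        family <- ifelse(overdispersed, "negative_binomial", "poisson")
        disp <- ifelse(overdispersed, mu^2 / (s2 - mu), NA_real_)
    } else {
        family <- rep("gaussian", nrow(v))
        disp <- sqrt(s2)
    }
    new("ReferenceModel", genes = rownames(v), family = family,
        mean = unname(mu), dispersion = unname(disp))
}

# Vectorized tails for one gene's family/parameters over observations x:
# upper = P(X >= x), lower = P(X <= x). Discrete families compute the upper
# tail as the survival function at x - 1, honoring "equal or greater".
.tails <- function(family, mean, dispersion, x) {
    switch(family,
        negative_binomial = list(
            upper = stats::pnbinom(x - 1, size = dispersion, mu = mean,
                                   lower.tail = FALSE),
            lower = stats::pnbinom(x, size = dispersion, mu = mean)),
        poisson = if (mean == 0) {
            # degenerate reference: all mass at zero
            list(upper = as.numeric(x <= 0), lower = rep(1, length(x)))
        } else {
            list(upper = stats::ppois(x - 1, lambda = mean, lower.tail = FALSE),
                 lower = stats::ppois(x, lambda = mean))
        },
        gaussian = if (dispersion == 0) {
            list(upper = as.numeric(x <= mean), lower = as.numeric(x >= mean))
        } else {
            list(upper = stats::pnorm(x, mean, dispersion, lower.tail = FALSE),
                 lower = stats::pnorm(x, mean, dispersion))
        },
        stop("unknown family: ", family))
}

#' Tail probabilities of an observation under a gene's reference model
#'
#' Returns `p_upper` = P(X >= x) and `p_lower` = P(X <= x) under the fitted
#' distribution of one gene. For discrete families the two tails sum to
#' 1 + P(X = x).
#'
#' @param model a [ReferenceModel-class].
#' @param gene gene id present in the model.
#' @param x observed value(s); must be integer-valued for count families.
#' @return named list with numeric vectors `p_upper` and `p_lower`.
#' @examples
#' m <- ExpressionMatrix(matrix(c(2, 2, 2, 2), 1, 4,
#'     dimnames = list("g1", paste0("n", 1:4))), "raw_counts")
#' mod <- fitReferenceModel(m)              # Poisson(2) fallback
#' tailProbabilities(mod, "g1", 5)$p_upper  # ~0.0527
#' @export
tailProbabilities <- function(model, gene, x) {
    stopifnot(is(model, "ReferenceModel"))
    i <- match(gene, model@genes)
    if (is.na(i)) stop("gene not in reference model: ", gene)
    fam <- model@family[i]
    if (fam %in% c("negative_binomial", "poisson") && any(x != round(x)))
        stop("count-family tail probabilities require integer x")
    t <- .tails(fam, model@mean[i], model@dispersion[i], x)
    list(p_upper = t$upper, p_lower = t$lower)
}

#' Binarize a tumor expression matrix against the reference
#'
#' Converts tumor expression into a \{-1, 0, +1\} matrix: +1 where the
#' upper-tail probability P(X >= x) under the gene's reference distribution
#' falls below `alpha`, -1 where the lower tail P(X <= x) does, 0
#' otherwise. With `alpha` < 0.5 the two calls are mutually exclusive.
#'
#' @param tumors an [ExpressionMatrix-class]; its genes must all be in the
#'   model.
#' @param model a [ReferenceModel-class] fitted on normals.
#' @param alpha per-tail p-value cutoff, in (0, 0.5).
#' @return A [BinaryDEGMatrix-class] with the tumor dimnames.
#' @examples
#' normals <- simulateReferenceCohort(defaultScenario(seed = 7))
#' tum <- simulateTumorCohort(defaultScenario(seed = 7))
#' deg <- binarizeMatrix(tum$expression, fitReferenceModel(normals), 0.05)
#' @export
binarizeMatrix <- function(tumors, model, alpha = 0.05) {
    stopifnot(is(tumors, "ExpressionMatrix"), is(model, "ReferenceModel"))
    if (!(alpha > 0 && alpha < 0.5)) stop("alpha must be in (0, 0.5)")
    v <- tumors@.Data
    idx <- match(rownames(v), model@genes)
    if (anyNA(idx))
        stop("genes missing from reference model: ",
             paste(rownames(v)[is.na(idx)], collapse = ", "))
    counts <- any(model@family[idx] %in% c("negative_binomial", "poisson"))
    if (counts && any(v != round(v)))
        stop("count-family binarization requires integer tumor values")
    out <- matrix(0, nrow = nrow(v), ncol = ncol(v), dimnames = dimnames(v))
    for (g in seq_len(nrow(v))) {
        i <- idx[g]
        t <- .tails(model@family[i], model@mean[i], model@dispersion[i], v[g, ])
        out[g, t$upper < alpha] <- 1
        out[g, t$lower < alpha] <- -1
    }
    BinaryDEGMatrix(out)
}
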