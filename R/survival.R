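#' @include AllClasses.R
NULL

.alignClinical <- function(clinical, sampleIds) {
    clinical <- validateClinicalTable(clinical)
    idx <- match(sampleIds, clinical$sample_id)
    if (anyNA(idx))
        stop("samples missing from clinical table: ",
             paste(sampleIds[is.na(idx)], collapse = ", "))
    clinical[idx, , drop = FALSE]
}

#' Screen signatures for survival association with univariate Cox models
#'
#' Fits one proportional-hazards regression per signature with its NES as
#' the sole covariate (Efron ties) and reports the Wald p-value. A
#' signature is selected iff p < `alpha`, unadjusted; a BH-adjusted column
#' is included for transparency but not used for selection. Signatures with
#' a constant NES, or fits that fail, are flagged non-estimable and never
#' selected.
#'
#' @param nes an [NESMatrix-class] (signatures x samples).
#' @param clinical clinical data.frame covering the NES samples.
#' @param alpha selection cutoff on the raw Wald p (default 0.05).
#' @return data.frame with columns `signature`, `log_hazard_ratio`,
#'   `p_value`, `q_value`, `estimable`, `selected`.
#' @examples
#' sc <- defaultScenario(seed = 7)
#' sim <- simulateSubtypeNes(sc)
#' clin <- simulateSurvival(sim$labels, sc)
#' coxScreen(sim$nes, clin)
#' @export
coxScreen <- function(nes, clinical, alpha = 0.05) {
    stopifnot(is(nes, "NESMatrix"))
    if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
    clin <- .alignClinical(clinical, colnames(nes))
    if (sum(clin$event) < 1L) stop("at least one event is required")
    surv <- survival::Surv(clin$time, clin$event)
    fitOne <- function(x) {
        if (length(unique(x)) < 2L)
            return(c(NA_real_, NA_real_))
        fit <- tryCatch(
            suppressWarnings(survival::coxph(surv ~ x, ties = "efron")),
            error = function(e) NULL)
        if (is.null(fit) || is.na(stats::coef(fit)))
            return(c(NA_real_, NA_real_))
        s <- summary(fit)
        c(unname(stats::coef(fit)), s$coefficients[1L, "Pr(>|z|)"])
    }
    res <- t(apply(nes@.Data, 1L, fitOne))
    estimable <- is.finite(res[, 2L])
    q <- rep(NA_real_, nrow(res))
    q[estimable] <- stats::p.adjust(res[estimable, 2L], method = "BH")
    data.frame(signature = rownames(nes),
               log_hazard_ratio = res[, 1L],
               p_value = res[, 2L],
               q_value = q,
               estimable = estimable,
               selected = estimable & res[, 2L] < alpha,
               row.names = NULL)
}

#' Ward.D2 clustering of samples on the NES matrix
#'
#' Agglomerative clustering of the sample columns under Euclidean distance
#' with Ward.D2 linkage (the unsquared-distance Ward convention), cut at
#' `k`. Cluster labels are renumbered 1..k by decreasing size (ties broken
#' by the original cutree label), making the labelling deterministic.
#'
#' @param nes an [NESMatrix-class].
#' @param k number of clusters; requires at least `k` samples.
#' @return A [ClusterAssignment-class].
#' @examples
#' sc <- defaultScenario(seed = 7)
#' sim <- simulateSubtypeNes(sc)
#' wardCluster(sim$nes, 4)
#' @export
wardCluster <- function(nes, k) {
    stopifnot(is(nes, "NESMatrix"))
    k <- as.integer(k)
    if (ncol(nes) < k)
        stop("need at least k samples to form k clusters")
    tree <- stats::hclust(stats::dist(t(nes@.Data)), method = "ward.D2")
    raw <- stats::cutree(tree, k = k)
    sizes <- table(raw)
    newOrder <- order(-as.integer(sizes), as.integer(names(sizes)))
    relabel <- integer(length(sizes))
    relabel[as.integer(names(sizes))[newOrder]] <- seq_along(sizes)
    labels <- stats::setNames(relabel[raw], colnames(nes))
    new("ClusterAssignment", labels = labels, k = k, tree = tree)
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator with right censoring for one group of samples.
#'
#' @param clinical clinical data.frame (`sample_id`, `time`, `event`).
#' @return data.frame with `time`, `n_risk`, `n_event`, `survival`: the
#'   step function starts at 1 and is non-increasing.
#' @examples
#' kmEstimate(data.frame(sample_id = c("a", "b", "c"),
#'     time = c(1, 2, 3), event = c(1, 0, 1)))
#' @export
kmEstimate <- function(clinical) {
    clinical <- validateClinicalTable(clinical)
    fit <- survival::survfit(
        survival::Surv(clinical$time, clinical$event) ~ 1)
    data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
               survival = fit$surv)
}

#' k-group log-rank test
#'
#' Standard log-rank comparison of event-time distributions across groups,
#' with k - 1 degrees of freedom.
#'
#' @param clinical clinical data.frame covering all labelled samples.
#' @param labels named vector, sample -> group; at least two groups.
#' @return list with `statistic`, `df`, `p_value`.
#' @examples
#' clin <- data.frame(sample_id = paste0("s", 1:6),
#'     time = c(1, 2, 3, 4, 5, 6), event = rep(1, 6))
#' logrankTest(clin, setNames(rep(c("a", "b"), 3), clin$sample_id))
#' @export
logrankTest <- function(clinical, labels) {
    if (is.null(names(labels)))
        stop("labels must be named by sample id")
    groups <- factor(labels)
    if (nlevels(groups) < 2L) stop("at least two groups are required")
    clin <- .alignClinical(clinical, names(labels))
    if (sum(clin$event) < 1L) stop("at least one event is required")
    sd <- survival::survdiff(
        survival::Surv(clin$time, clin$event) ~ groups)
    df <- nlevels(groups) - 1L
    list(statistic = unname(sd$chisq), df = df,
         p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}
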