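#' @include AllClasses.R
NULL

#' Count dysregulation support across mutated samples
#'
#' For one driver gene, counts per gene how many mutated samples show a
#' nonzero binary call (-1 or +1), and records the majority sign of those
#' calls (ties give direction 0).
#'
#' @param deg a [BinaryDEGMatrix-class] over the tumor cohort.
#' @param mut samples x drivers 0/1 mutation matrix; rownames must cover
#'   the deg sample ids used.
#' @param driver driver gene (a column of `mut`).
#' @return data.frame with columns `gene`, `count`, `direction`, plus
#'   attributes `driver` and `nMut`.
#' @examples
#' deg <- BinaryDEGMatrix(matrix(c(1, 0, 1, 0, 1, 0), 2, 3,
#'     dimnames = list(c("gA", "gB"), c("s1", "s2", "s3"))))
#' mut <- matrix(c(1, 1, 0), 3, 1, dimnames = list(c("s1", "s2", "s3"), "TP53"))
#' countDegSupport(deg, mut, "TP53")
#' @export
countDegSupport <- function(deg, mut, driver) {
    stopifnot(is(deg, "BinaryDEGMatrix"))
    if (!driver %in% colnames(mut))
        stop("driver not in mutation table: ", driver)
    mutated <- rownames(mut)[mut[, driver] == 1]
    mutated <- intersect(mutated, colnames(deg@.Data))
    if (length(mutated) == 0L)
        stop("no mutated samples for driver ", driver)
    sub <- deg@.Data[, mutated, drop = FALSE]
    count <- rowSums(sub != 0)
    direction <- sign(rowSums(sub))
    out <- data.frame(gene = rownames(sub), count = as.integer(count),
                      direction = as.integer(direction), row.names = NULL)
    attr(out, "driver") <- driver
    attr(out, "nMut") <- length(mutated)
    out
}

#' Select genes above a support-count quantile
#'
#' Returns the genes whose support count is strictly greater than the
#' type-7 `q`-quantile of the full count vector (the "falling above the
#' 98th percentile" rule at the default q = 0.98).
#'
#' @param counts a support table from [countDegSupport()] (or any
#'   data.frame with `gene` and `count`).
#' @param q quantile in (0, 1).
#' @return character vector of selected genes; the quantile cutoff is
#'   attached as attribute `threshold`.
#' @export
selectAboveQuantile <- function(counts, q = 0.98) {
    if (!(q > 0 && q < 1)) stop("q must be in (0, 1)")
    thr <- stats::quantile(counts$count, q, type = 7, names = FALSE)
    genes <- counts$gene[counts$count > thr]
    attr(genes, "threshold") <- thr
    genes
}

#' Keep markers unique to one signature and apply the size filter
#'
#' A gene appearing in two or more candidate sets is removed from all of
#' them; candidate signatures left with fewer than `minMarkers` genes are
#' dropped. The result is ordered by driver name.
#'
#' @param candidates named list (driver -> character vector of candidate
#'   marker genes).
#' @param minMarkers minimum number of unique markers to retain a
#'   signature (default 5).
#' @param directions optional named list parallel to `candidates`, each a
#'   named integer vector gene -> direction.
#' @param thresholds optional named numeric vector of support cutoffs.
#' @param nMut optional named integer vector of mutated-sample counts.
#' @return An [OncoSignatureSet-class]; empty if nothing survives.
#' @examples
#' assignUniqueMarkers(list(
#'     sig1 = c("A", "B", "C"),
#'     sig2 = c("B", "C", "D", "E", "F", "G", "H")), minMarkers = 5)
#' @export
assignUniqueMarkers <- function(candidates, minMarkers = 5,
                                directions = NULL, thresholds = NULL,
                                nMut = NULL) {
    stopifnot(minMarkers >= 1)
    all <- unlist(candidates, use.names = FALSE)
    shared <- unique(all[duplicated(all)])
    unique_sets <- lapply(candidates, setdiff, y = shared)
    keep <- names(unique_sets)[lengths(unique_sets) >= minMarkers]
    keep <- keep[order(keep, method = "radix")]
    sigs <- lapply(keep, function(drv) {
        genes <- unique_sets[[drv]]
        dir <- if (is.null(directions)) rep(0L, length(genes))
               else as.integer(directions[[drv]][genes])
        OncoSignature(drv, genes, dir,
            supportThreshold = if (is.null(thresholds)) NA_real_
                               else thresholds[[drv]],
            nMut = if (is.null(nMut)) NA_integer_ else nMut[[drv]])
    })
    OncoSignatureSet(sigs)
}

#' Derive onco-signatures from a binarized cohort
#'
#' Full derivation for every driver in the mutation table: support counts
#' over that driver's mutated samples, selection of genes strictly above
#' the support quantile, cross-driver unique-marker assignment, and the
#' minimum-marker filter. Drivers with no mutated samples are skipped with
#' a warning.
#'
#' @param deg a [BinaryDEGMatrix-class] of the tumor cohort against the
#'   normal reference.
#' @param mut samples x drivers 0/1 mutation matrix.
#' @param config a [PipelineConfig-class] supplying `supportQuantile` and
#'   `minMarkers`.
#' @return An [OncoSignatureSet-class] of the retained signatures.
#' @examples
#' sc <- defaultScenario(seed = 7)
#' cohort <- simulateCohort(sc)
#' model <- fitReferenceModel(cohort$normals)
#' deg <- binarizeMatrix(cohort$tumors, model, 0.05)
#' deriveSignatures(deg, cohort$mutations, oncoConfig())
#' @export
deriveSignatures <- function(deg, mut, config = oncoConfig()) {
    stopifnot(is(deg, "BinaryDEGMatrix"), is(config, "PipelineConfig"))
    drivers <- colnames(mut)
    candidates <- list(); directions <- list()
    thresholds <- numeric(); nMut <- integer()
    for (drv in drivers) {
        if (sum(mut[, drv] == 1) == 0L) {
            warning("driver skipped (no mutated samples): ", drv)
            next
        }
        support <- countDegSupport(deg, mut, drv)
        sel <- selectAboveQuantile(support, config@supportQuantile)
        candidates[[drv]] <- as.character(sel)
        directions[[drv]] <- stats::setNames(support$direction, support$gene)
        thresholds[[drv]] <- attr(sel, "threshold")
        nMut[[drv]] <- attr(support, "nMut")
    }
    assignUniqueMarkers(candidates, config@minMarkers, directions,
                        thresholds, nMut)
}
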