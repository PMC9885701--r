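#' @include AllClasses.R
NULL

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, monotone-enforced and capped at 1.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same length.
#' @examples
#' bhFdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhFdr <- function(p) {
    if (length(p) == 0L) return(numeric())
    if (any(!is.finite(p)) || any(p < 0 | p > 1))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Two-group differential expression between sample sets
#'
#' Per gene, a two-sided Wilcoxon rank-sum test between the two groups and
#' a pseudocount log2 fold-change log2((meanA + 1)/(meanB + 1)), with BH
#' adjustment across all tested genes. Status is `up` when log2FC >=
#' `lfcMin` and FDR < `fdrMax`, `down` when log2FC <= -`lfcMin` and FDR <
#' `fdrMax`, otherwise `ns`. The study cutoffs are |log2FC| >= 1.5 for
#' genes and >= 1.0 for miRNA, both at FDR < 0.05.
#'
#' @param expr a normalized [ExpressionMatrix-class].
#' @param groupA,groupB disjoint sample-id sets, each of size >= 3.
#' @param lfcMin absolute log2 fold-change cutoff (default 1.5).
#' @param fdrMax BH FDR cutoff (default 0.05).
#' @return data.frame with `gene`, `log2fc` (A over B), `p_value`, `fdr`,
#'   `status`.
#' @export
differentialExpression <- function(expr, groupA, groupB, lfcMin = 1.5,
                                   fdrMax = 0.05) {
    stopifnot(is(expr, "ExpressionMatrix"))
    if (length(intersect(groupA, groupB)))
        stop("groups overlap")
    if (length(groupA) < 3L || length(groupB) < 3L)
        stop("each group needs at least 3 samples")
    v <- expr@.Data
    missing <- setdiff(c(groupA, groupB), colnames(v))
    if (length(missing))
        stop("samples not in expression matrix: ",
             paste(missing, collapse = ", "))
    a <- v[, groupA, drop = FALSE]
    b <- v[, groupB, drop = FALSE]
    log2fc <- log2((rowMeans(a) + 1) / (rowMeans(b) + 1))
    p <- vapply(seq_len(nrow(v)), function(g)
        suppressWarnings(stats::wilcox.test(a[g, ], b[g, ],
            alternative = "two.sided", exact = FALSE)$p.value),
        numeric(1))
    p[is.na(p)] <- 1  # constant genes carry no evidence
    fdr <- bhFdr(p)
    status <- rep("ns", nrow(v))
    status[log2fc >= lfcMin & fdr < fdrMax] <- "up"
    status[log2fc <= -lfcMin & fdr < fdrMax] <- "down"
    data.frame(gene = rownames(v), log2fc = unname(log2fc),
               p_value = p, fdr = fdr, status = status, row.names = NULL)
}

#' Intersect promoter-hit transcription factors with DE calls
#'
#' Keeps the transcription factors that have at least one promoter PWM hit
#' and whose own gene is differentially expressed (status not `ns`),
#' reporting the direction.
#'
#' @param hits data.frame of PWM hits with a `tf` column (e.g. rbind of
#'   [scanPwm()] results with the TF name attached).
#' @param de a [differentialExpression()] result.
#' @param tfGeneMap optional named character vector TF name -> gene id
#'   (default: TF names are gene ids).
#' @return data.frame with `tf`, `gene`, `n_hits`, `direction`.
#' @export
intersectTfCandidates <- function(hits, de, tfGeneMap = NULL) {
    empty <- data.frame(tf = character(), gene = character(),
                        n_hits = integer(), direction = character())
    if (is.null(hits) || nrow(hits) == 0L) return(empty)
    if (!"tf" %in% colnames(hits)) stop("hits need a 'tf' column")
    tfs <- sort(unique(hits$tf))
    genes <- if (is.null(tfGeneMap)) stats::setNames(tfs, tfs)
             else tfGeneMap[tfs]
    status <- de$status[match(genes, de$gene)]
    keep <- !is.na(status) & status != "ns"
    if (!any(keep)) return(empty)
    data.frame(tf = tfs[keep], gene = unname(genes[keep]),
               n_hits = as.integer(table(factor(hits$tf, levels = tfs))[keep]),
               direction = status[keep], row.names = NULL)
}
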