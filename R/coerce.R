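#' @include AllClasses.R
NULL

#' Interoperate with SummarizedExperiment
#'
#' `asSummarizedExperiment` wraps an [ExpressionMatrix-class] as a
#' single-assay `SummarizedExperiment` (assay name `"expr"`, the scale kept
#' in its metadata); `asExpressionMatrix` converts back, taking the scale
#' from the metadata unless given explicitly.
#'
#' @param x an [ExpressionMatrix-class].
#' @return `asSummarizedExperiment` a `SummarizedExperiment`;
#'   `asExpressionMatrix` an [ExpressionMatrix-class].
#' @examples
#' if (requireNamespace("SummarizedExperiment", quietly = TRUE)) {
#'     m <- ExpressionMatrix(matrix(1:6, 3, 2,
#'         dimnames = list(paste0("g", 1:3), c("s1", "s2"))), "raw_counts")
#'     se <- asSummarizedExperiment(m)
#'     asExpressionMatrix(se)
#' }
#' @export
asSummarizedExperiment <- function(x) {
    stopifnot(is(x, "ExpressionMatrix"))
    if (!requireNamespace("SummarizedExperiment", quietly = TRUE))
        stop("the SummarizedExperiment package is required for this coercion")
    SummarizedExperiment::SummarizedExperiment(
        assays = list(expr = x@.Data),
        metadata = list(scale = x@scale))
}

#' @rdname asSummarizedExperiment
#' @param se a `SummarizedExperiment` with one expression assay.
#' @param scale overrides the scale stored in `metadata(se)$scale`
#'   (defaults to `"raw_counts"` when neither is present).
#' @export
asExpressionMatrix <- function(se, scale = NULL) {
    if (!requireNamespace("SummarizedExperiment", quietly = TRUE))
        stop("the SummarizedExperiment package is required for this coercion")
    if (is.null(scale)) {
        scale <- S4Vectors::metadata(se)$scale
        if (is.null(scale)) scale <- "raw_counts"
    }
    ExpressionMatrix(SummarizedExperiment::assay(se, 1L), scale)
}
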