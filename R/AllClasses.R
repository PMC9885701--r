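#' @import methods
NULL

.EXPR_SCALES <- c("raw_counts", "normalized")

#' Gene-by-sample expression matrix
#'
#' A numeric genes x samples matrix with unique, non-empty dimnames and a
#' declared scale: \code{"raw_counts"} for untransformed RNA-seq counts or
#' \code{"normalized"} for continuous normalized expression. All entries must
#' be finite and non-negative.
#'
#' @slot scale character(1), one of \code{"raw_counts"} or \code{"normalized"}.
#' @seealso [ExpressionMatrix()], [readExpressionMatrix()],
#'   [upperQuartileNormalize()]
#' @exportClass ExpressionMatrix
setClass("ExpressionMatrix",
    contains = "matrix",
    representation(scale = "character"))

setValidity("ExpressionMatrix", function(object) {
    msg <- character()
    if (length(object@scale) != 1L || !object@scale %in% .EXPR_SCALES)
        msg <- c(msg, sprintf("scale must be one of: %s",
                              paste(.EXPR_SCALES, collapse = ", ")))
    v <- object@.Data
    if (!is.numeric(v))
        msg <- c(msg, "values must be numeric")
    if (is.null(rownames(v)) || is.null(colnames(v)))
        msg <- c(msg, "gene (row) and sample (column) names are required")
    if (anyDuplicated(rownames(v)))
        msg <- c(msg, sprintf("duplicated gene ids: %s",
            paste(unique(rownames(v)[duplicated(rownames(v))]), collapse = ", ")))
    if (anyDuplicated(colnames(v)))
        msg <- c(msg, sprintf("duplicated sample ids: %s",
            paste(unique(colnames(v)[duplicated(colnames(v))]), collapse = ", ")))
    if (is.numeric(v) && (any(!is.finite(v)) || any(v < 0)))
        msg <- c(msg, "all values must be finite and >= 0")
    if (length(msg)) msg else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   unique dimnames.
#' @param scale \code{"raw_counts"} or \code{"normalized"}.
#' @return An [ExpressionMatrix-class] object.
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' ExpressionMatrix(m, "raw_counts")
#' @export
ExpressionMatrix <- function(values, scale = c("raw_counts", "normalized")) {
    scale <- match.arg(scale)
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    new("ExpressionMatrix", values, scale = scale)
}

#' Binary differential-expression matrix
#'
#' Genes x samples matrix with entries in \{-1, 0, +1\} marking
#' down-regulation, no change and up-regulation of each tumor sample
#' relative to the normal reference model.
#'
#' @seealso [binarizeMatrix()]
#' @exportClass BinaryDEGMatrix
setClass("BinaryDEGMatrix", contains = "matrix")

setValidity("BinaryDEGMatrix", function(object) {
    v <- object@.Data
    msg <- character()
    if (is.null(rownames(v)) || is.null(colnames(v)))
        msg <- c(msg, "gene and sample names are required")
    if (!all(v %in% c(-1, 0, 1)))
        msg <- c(msg, "entries must be -1, 0 or 1")
    if (length(msg)) msg else TRUE
})

#' @rdname BinaryDEGMatrix-class
#' @param values numeric matrix with entries in \{-1, 0, 1\} and full
#'   dimnames.
#' @export
BinaryDEGMatrix <- function(values) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    new("BinaryDEGMatrix", values)
}

#' Per-gene reference expression model
#'
#' Null distribution for each gene, fitted on normal samples: a
#' negative-binomial (mean + size) or Poisson (mean) model for raw counts,
#' or a Gaussian (mean + sd) model for normalized data. Genes whose sample
#' variance does not exceed the mean fall back to Poisson, where the NB size
#' parameter is undefined.
#'
#' @slot genes character vector of gene ids.
#' @slot family per-gene distribution family: \code{"negative_binomial"},
#'   \code{"poisson"} or \code{"gaussian"}.
#' @slot mean per-gene reference mean.
#' @slot dispersion per-gene NB size or Gaussian sd (NA for Poisson).
#' @seealso [fitReferenceModel()], [tailProbabilities()]
#' @exportClass ReferenceModel
setClass("ReferenceModel",
    representation(genes = "character", family = "character",
                   mean = "numeric", dispersion = "numeric"))

setValidity("ReferenceModel", function(object) {
    n <- length(object@genes)
    msg <- character()
    if (anyDuplicated(object@genes))
        msg <- c(msg, "duplicated gene ids")
    if (length(object@family) != n || length(object@mean) != n ||
        length(object@dispersion) != n)
        msg <- c(msg, "genes, family, mean and dispersion must be parallel")
    if (!all(object@family %in% c("negative_binomial", "poisson", "gaussian")))
        msg <- c(msg, "unknown family")
    if (any(object@mean < 0))
        msg <- c(msg, "means must be >= 0")
    nb <- object@family == "negative_binomial"
    if (any(nb & !(object@dispersion > 0)))
        msg <- c(msg, "NB size must be > 0")
    ga <- object@family == "gaussian"
    if (any(ga & object@dispersion < 0))
        msg <- c(msg, "Gaussian sd must be >= 0")
    if (length(msg)) msg else TRUE
})

#' A mutation-anchored expression signature
#'
#' The unique marker genes recurrently dysregulated across tumors mutated in
#' one driver gene, with per-marker direction (+1 up, -1 down, 0 mixed), the
#' support-count threshold that selected them, and the number of mutated
#' samples the counts were taken over.
#'
#' @slot driver driver gene the signature is anchored to.
#' @slot markers marker gene ids.
#' @slot direction integer vector parallel to markers, in \{-1, 0, 1\}.
#' @slot supportThreshold the support-quantile cutoff used for selection.
#' @slot nMut number of mutated samples.
#' @seealso [deriveSignatures()]
#' @exportClass OncoSignature
setClass("OncoSignature",
    representation(driver = "character", markers = "character",
                   direction = "integer", supportThreshold = "numeric",
                   nMut = "integer"))

setValidity("OncoSignature", function(object) {
    msg <- character()
    if (length(object@driver) != 1L) msg <- c(msg, "driver must be length 1")
    if (length(object@markers) < 1L) msg <- c(msg, "markers must be non-empty")
    if (anyDuplicated(object@markers)) msg <- c(msg, "duplicated markers")
    if (length(object@direction) != length(object@markers))
        msg <- c(msg, "direction must be parallel to markers")
    if (!all(object@direction %in% c(-1L, 0L, 1L)))
        msg <- c(msg, "direction entries must be -1, 0 or 1")
    if (length(msg)) msg else TRUE
})

#' @rdname OncoSignature-class
#' @param driver,markers,direction,supportThreshold,nMut slot values; see
#'   the class description.
#' @export
OncoSignature <- function(driver, markers, direction = rep(0L, length(markers)),
                          supportThreshold = NA_real_, nMut = NA_integer_) {
    new("OncoSignature", driver = driver, markers = as.character(markers),
        direction = as.integer(direction),
        supportThreshold = as.numeric(supportThreshold),
        nMut = as.integer(nMut))
}

#' A collection of onco-signatures
#'
#' List of [OncoSignature-class] objects, named by driver. Retained
#' signatures are pairwise disjoint in markers by construction.
#'
#' @seealso [deriveSignatures()], [assignUniqueMarkers()]
#' @exportClass OncoSignatureSet
setClass("OncoSignatureSet", contains = "list")

setValidity("OncoSignatureSet", function(object) {
    msg <- character()
    if (!all(vapply(object@.Data, is, logical(1), "OncoSignature")))
        msg <- c(msg, "all elements must be OncoSignature objects")
    if (length(msg)) msg else TRUE
})

#' @rdname OncoSignatureSet-class
#' @param sigs list of [OncoSignature-class] objects.
#' @export
OncoSignatureSet <- function(sigs = list()) {
    names(sigs) <- vapply(sigs, function(s) s@driver, character(1))
    new("OncoSignatureSet", sigs)
}

#' Signatures-by-samples matrix of normalized enrichment scores
#'
#' Every entry lies in [0, 1]: the per-sample probability that a gene inside
#' the signature is expressed above a gene outside it, from the
#' Mann-Whitney U statistic.
#'
#' @seealso [nesMatrix()], [mwwNes()]
#' @exportClass NESMatrix
setClass("NESMatrix", contains = "matrix")

setValidity("NESMatrix", function(object) {
    v <- object@.Data
    msg <- character()
    if (is.null(rownames(v)) || is.null(colnames(v)))
        msg <- c(msg, "signature and sample names are required")
    if (any(!is.finite(v)) || any(v < 0 | v > 1))
        msg <- c(msg, "NES entries must be finite and in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' @rdname NESMatrix-class
#' @param values numeric matrix in [0, 1] with signature rownames and
#'   sample colnames.
#' @export
NESMatrix <- function(values) new("NESMatrix", as.matrix(values))

#' Sample cluster assignment with its dendrogram
#'
#' @slot labels named integer vector, sample -> cluster in 1..k, clusters
#'   renumbered by decreasing size.
#' @slot k number of clusters.
#' @slot tree the \code{hclust} tree the cut was taken from.
#' @seealso [wardCluster()]
#' @exportClass ClusterAssignment
setClass("ClusterAssignment",
    representation(labels = "integer", k = "integer", tree = "ANY"))

setValidity("ClusterAssignment", function(object) {
    msg <- character()
    if (is.null(names(object@labels)))
        msg <- c(msg, "labels must be named by sample")
    if (length(object@labels) >= object@k &&
        length(unique(object@labels)) != object@k)
        msg <- c(msg, "expected exactly k non-empty clusters")
    if (length(msg)) msg else TRUE
})

#' Pipeline configuration
#'
#' Holds every tunable threshold of the onco-signature pipeline. Defaults
#' are the study settings: per-tail binarization p-value cutoff 0.05,
#' support quantile 0.98, at least 5 unique markers per retained signature,
#' Cox screening at raw p < 0.05, k = 4 NES clusters, and differential
#' expression at |log2FC| >= 1.5 (1.0 for miRNA) with BH FDR < 0.05.
#'
#' @slot binarizationAlpha per-tail p-value cutoff for the -1/0/+1 calls.
#' @slot supportQuantile support-count quantile above which genes are
#'   selected (strictly greater, type-7 quantile).
#' @slot minMarkers minimum unique markers for a signature to be retained.
#' @slot coxAlpha Wald p-value cutoff of the Cox screen (unadjusted).
#' @slot nClusters number of Ward.D2 clusters cut from the NES dendrogram.
#' @slot degLfc absolute log2 fold-change cutoff for gene DE calls.
#' @slot degFdr BH FDR cutoff for DE calls.
#' @slot mirnaLfc absolute log2 fold-change cutoff for miRNA DE calls.
#' @slot seed integer seed controlling all randomness of a run.
#' @seealso [oncoConfig()], [runPipeline()]
#' @exportClass PipelineConfig
setClass("PipelineConfig",
    representation(binarizationAlpha = "numeric", supportQuantile = "numeric",
                   minMarkers = "integer", coxAlpha = "numeric",
                   nClusters = "integer", degLfc = "numeric",
                   degFdr = "numeric", mirnaLfc = "numeric", seed = "integer"),
    prototype(binarizationAlpha = 0.05, supportQuantile = 0.98,
              minMarkers = 5L, coxAlpha = 0.05, nClusters = 4L,
              degLfc = 1.5, degFdr = 0.05, mirnaLfc = 1.0, seed = 1L))

setValidity("PipelineConfig", function(object) {
    msg <- character()
    inProb <- function(x) length(x) == 1L && is.finite(x) && x > 0 && x < 1
    if (!inProb(object@binarizationAlpha))
        msg <- c(msg, "binarizationAlpha must be in (0, 1)")
    if (!inProb(object@supportQuantile))
        msg <- c(msg, "supportQuantile must be in (0, 1)")
    if (!inProb(object@coxAlpha)) msg <- c(msg, "coxAlpha must be in (0, 1)")
    if (!inProb(object@degFdr)) msg <- c(msg, "degFdr must be in (0, 1)")
    if (object@minMarkers < 1L) msg <- c(msg, "minMarkers must be >= 1")
    if (object@nClusters < 1L) msg <- c(msg, "nClusters must be >= 1")
    if (length(msg)) msg else TRUE
})

#' Create a pipeline configuration
#'
#' @param binarizationAlpha,supportQuantile,minMarkers,coxAlpha,nClusters
#'   see [PipelineConfig-class].
#' @param degLfc,degFdr,mirnaLfc,seed see [PipelineConfig-class].
#' @return A validated [PipelineConfig-class] object.
#' @examples
#' oncoConfig(seed = 42)
#' @export
oncoConfig <- function(binarizationAlpha = 0.05, supportQuantile = 0.98,
                       minMarkers = 5, coxAlpha = 0.05, nClusters = 4,
                       degLfc = 1.5, degFdr = 0.05, mirnaLfc = 1.0,
                       seed = 1) {
    new("PipelineConfig", binarizationAlpha = binarizationAlpha,
        supportQuantile = supportQuantile, minMarkers = as.integer(minMarkers),
        coxAlpha = coxAlpha, nClusters = as.integer(nClusters),
        degLfc = degLfc, degFdr = degFdr, mirnaLfc = mirnaLfc,
        seed = as.integer(seed))
}

#' Promoter window around a transcription start site
#'
#' @slot gene gene id the window belongs to.
#' @slot sequence the window sequence, 5' to 3' on the gene's strand.
#' @slot tssOffset 0-based position of the TSS within the window.
#' @seealso [extractPromoter()], [scanPwm()]
#' @exportClass PromoterWindow
setClass("PromoterWindow",
    representation(gene = "character", sequence = "character",
                   tssOffset = "integer"))

setValidity("PromoterWindow", function(object) {
    msg <- character()
    seqchars <- strsplit(object@sequence, "")[[1]]
    if (!all(seqchars %in% c("A", "C", "G", "T", "N")))
        msg <- c(msg, "sequence alphabet must be A, C, G, T or N")
    if (object@tssOffset < 0L || object@tssOffset > nchar(object@sequence))
        msg <- c(msg, "tssOffset must fall within the window")
    if (length(msg)) msg else TRUE
})
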