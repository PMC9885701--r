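#' @include AllClasses.R
NULL

#' Accessors for oncosig classes
#'
#' Small accessor generics: \code{exprScale} returns the declared scale of an
#' [ExpressionMatrix-class]; \code{driverGene}, \code{markers},
#' \code{markerDirections}, \code{supportThreshold} and \code{nMutated}
#' expose the slots of an [OncoSignature-class]; \code{clusterLabels} returns
#' the named sample-to-cluster vector of a [ClusterAssignment-class].
#'
#' @param x an oncosig object.
#' @return the slot value (see details per generic above).
#' @name accessors
#' @examples
#' sig <- OncoSignature("TP53", c("g1", "g2"), c(1L, -1L))
#' driverGene(sig)
#' markers(sig)
NULL

#' @rdname accessors
#' @export
setGeneric("exprScale", function(x) standardGeneric("exprScale"))

#' @rdname accessors
#' @export
setMethod("exprScale", "ExpressionMatrix", function(x) x@scale)

#' @rdname accessors
#' @export
setGeneric("driverGene", function(x) standardGeneric("driverGene"))

#' @rdname accessors
#' @export
setMethod("driverGene", "OncoSignature", function(x) x@driver)

#' @rdname accessors
#' @export
setGeneric("markers", function(x) standardGeneric("markers"))

#' @rdname accessors
#' @export
setMethod("markers", "OncoSignature", function(x) x@markers)

#' @rdname accessors
#' @export
setGeneric("markerDirections", function(x) standardGeneric("markerDirections"))

#' @rdname accessors
#' @export
setMethod("markerDirections", "OncoSignature",
    function(x) stats::setNames(x@direction, x@markers))

#' @rdname accessors
#' @export
setGeneric("supportThreshold", function(x) standardGeneric("supportThreshold"))

#' @rdname accessors
#' @export
setMethod("supportThreshold", "OncoSignature", function(x) x@supportThreshold)

#' @rdname accessors
#' @export
setGeneric("nMutated", function(x) standardGeneric("nMutated"))

#' @rdname accessors
#' @export
setMethod("nMutated", "OncoSignature", function(x) x@nMut)

#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname accessors
#' @export
setMethod("clusterLabels", "ClusterAssignment", function(x) x@labels)

#' @describeIn ReferenceModel-class gene ids of the model.
#' @param x,object a \code{ReferenceModel}.
#' @export
setGeneric("modelGenes", function(x) standardGeneric("modelGenes"))

#' @rdname ReferenceModel-class
#' @export
setMethod("modelGenes", "ReferenceModel", function(x) x@genes)

#' @describeIn ReferenceModel-class per-gene family, mean and dispersion as
#'   a data.frame.
#' @export
setGeneric("modelParameters", function(x) standardGeneric("modelParameters"))

#' @rdname ReferenceModel-class
#' @export
setMethod("modelParameters", "ReferenceModel", function(x)
    data.frame(gene = x@genes, family = x@family, mean = x@mean,
               dispersion_or_sd = x@dispersion, row.names = NULL))

setMethod("show", "ExpressionMatrix", function(object) {
    cat(sprintf("ExpressionMatrix: %d genes x %d samples (%s)\n",
                nrow(object), ncol(object), object@scale))
})

setMethod("show", "BinaryDEGMatrix", function(object) {
    v <- object@.Data
    cat(sprintf("BinaryDEGMatrix: %d genes x %d samples (+1: %d, -1: %d, 0: %d)\n",
                nrow(v), ncol(v), sum(v == 1), sum(v == -1), sum(v == 0)))
})

setMethod("show", "ReferenceModel", function(object) {
    tab <- table(factor(object@family,
        levels = c("negative_binomial", "poisson", "gaussian")))
    cat(sprintf("ReferenceModel: %d genes (NB: %d, Poisson: %d, Gaussian: %d)\n",
                length(object@genes), tab[[1]], tab[[2]], tab[[3]]))
})

setMethod("show", "OncoSignature", function(object) {
    cat(sprintf("OncoSignature '%s': %d markers (up %d / down %d / mixed %d), support threshold %.3g, n_mut %d\n",
                object@driver, length(object@markers),
                sum(object@direction == 1L), sum(object@direction == -1L),
                sum(object@direction == 0L), object@supportThreshold,
                object@nMut))
})

setMethod("show", "OncoSignatureSet", function(object) {
    cat(sprintf("OncoSignatureSet with %d signatures\n", length(object)))
    for (s in object@.Data)
        cat(sprintf("  %s: %d markers\n", s@driver, length(s@markers)))
})

setMethod("show", "NESMatrix", function(object) {
    cat(sprintf("NESMatrix: %d signatures x %d samples, range [%.3f, %.3f]\n",
                nrow(object), ncol(object), min(object), max(object)))
})

setMethod("show", "ClusterAssignment", function(object) {
    sizes <- table(object@labels)
    cat(sprintf("ClusterAssignment: %d samples in %d clusters (sizes: %s)\n",
                length(object@labels), object@k,
                paste(as.integer(sizes), collapse = ", ")))
})

setMethod("show", "PipelineConfig", function(object) {
    cat("PipelineConfig:\n")
    cat(sprintf("  binarization alpha: %g | support quantile: %g | min markers: %d\n",
                object@binarizationAlpha, object@supportQuantile,
                object@minMarkers))
    cat(sprintf("  cox alpha: %g | clusters: %d | DE |log2FC| >= %g (miRNA %g), FDR < %g\n",
                object@coxAlpha, object@nClusters, object@degLfc,
                object@mirnaLfc, object@degFdr))
    cat(sprintf("  seed: %d\n", object@seed))
})

setMethod("show", "PromoterWindow", function(object) {
    cat(sprintf("PromoterWindow '%s': %d nt, TSS at offset %d\n",
                object@gene, nchar(object@sequence), object@tssOffset))
})
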