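#' @include AllClasses.R
NULL

.readTsvMatrix <- function(path, what = "matrix") {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE,
                            quote = "", comment.char = "")
    if (ncol(df) < 2L)
        stop("expected a header of sample ids and a first column of row ids in ",
             path)
    ids <- as.character(df[[1L]])
    vals <- df[, -1L, drop = FALSE]
    for (j in seq_along(vals)) {
        col <- vals[[j]]
        if (!is.numeric(col)) {
            bad <- which(is.na(suppressWarnings(as.numeric(col))) & !is.na(col))
            stop(sprintf("malformed numeric cell in %s: row '%s', column '%s'",
                         path, ids[bad[1L]], colnames(vals)[j]))
        }
    }
    m <- as.matrix(vals)
    rownames(m) <- ids
    m
}

#' Read / write a gene-by-sample expression matrix
#'
#' The on-disk format is TSV with a header row of sample ids and a first
#' column of gene ids. `readExpressionMatrix` validates the result
#' (unique ids, finite non-negative values); `writeExpressionMatrix` is its
#' lossless inverse.
#'
#' @param path TSV file path.
#' @param scale declared scale of the values, \code{"raw_counts"} or
#'   \code{"normalized"}.
#' @return `readExpressionMatrix` an [ExpressionMatrix-class];
#'   `writeExpressionMatrix` the path, invisibly.
#' @examples
#' m <- ExpressionMatrix(matrix(1:6, 3, 2,
#'     dimnames = list(paste0("g", 1:3), c("s1", "s2"))), "raw_counts")
#' f <- tempfile(fileext = ".tsv")
#' writeExpressionMatrix(m, f)
#' readExpressionMatrix(f, "raw_counts")
#' @export
readExpressionMatrix <- function(path, scale = c("raw_counts", "normalized")) {
    scale <- match.arg(scale)
    ExpressionMatrix(.readTsvMatrix(path), scale)
}

#' @rdname readExpressionMatrix
#' @param x an [ExpressionMatrix-class].
#' @export
writeExpressionMatrix <- function(x, path) {
    stopifnot(is(x, "ExpressionMatrix"))
    .writeTsvMatrix(x@.Data, path, idColumn = "gene_id")
}

.writeTsvMatrix <- function(m, path, idColumn = "id") {
    df <- data.frame(rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df)[1L] <- idColumn
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read / write a binary mutation table
#'
#' TSV with samples in rows (first column \code{sample_id}) and driver genes
#' in columns; entries are 0 (wild-type) or 1 (mutated).
#'
#' @param path TSV file path.
#' @return `readMutationTable` a samples x drivers 0/1 matrix with unique
#'   sample rownames.
#' @export
readMutationTable <- function(path) {
    m <- .readTsvMatrix(path)
    if (anyDuplicated(rownames(m)))
        stop("duplicated sample ids in mutation table")
    if (!all(m %in% c(0, 1)))
        stop("mutation status entries must be 0 or 1")
    m
}

#' @rdname readMutationTable
#' @param x samples x drivers 0/1 matrix.
#' @export
writeMutationTable <- function(x, path) {
    .writeTsvMatrix(x, path, idColumn = "sample_id")
}

#' Read / write a clinical table
#'
#' TSV with columns \code{sample_id}, \code{time} (non-negative days),
#' \code{event} (1 = death observed, 0 = censored) and an optional
#' \code{subtype} label.
#'
#' @param path TSV file path.
#' @return `readClinicalTable` a validated data.frame.
#' @export
readClinicalTable <- function(path) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, quote = "")
    validateClinicalTable(df)
}

#' @rdname readClinicalTable
#' @param x clinical data.frame.
#' @export
writeClinicalTable <- function(x, path) {
    utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Validate a clinical table
#'
#' @param df data.frame with \code{sample_id}, \code{time}, \code{event} and
#'   optionally \code{subtype}.
#' @return the data.frame, invisibly validated (errors otherwise).
#' @export
validateClinicalTable <- function(df) {
    need <- c("sample_id", "time", "event")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("clinical table missing columns: ", paste(miss, collapse = ", "))
    if (anyDuplicated(df$sample_id)) stop("duplicated sample ids")
    if (any(!is.finite(df$time)) || any(df$time < 0))
        stop("time must be finite and >= 0")
    if (!all(df$event %in% c(0, 1))) stop("event must be 0 or 1")
    df
}

#' Read / write GMT gene-set files
#'
#' Standard GMT: one set per line, tab-separated name, description, then
#' gene ids. `writeSignatureGmt` writes an [OncoSignatureSet-class] with the
#' description encoding the support threshold and mutated-sample count, and
#' markers suffixed \code{+} / \code{-} / \code{.} by direction;
#' `readSignatureGmt` inverts that encoding.
#'
#' @param path GMT file path.
#' @return `readGmt` a named list with elements \code{description} and
#'   \code{genes} per set; `readSignatureGmt` an [OncoSignatureSet-class].
#' @examples
#' sigs <- OncoSignatureSet(list(OncoSignature("TP53", c("a", "b"),
#'     c(1L, -1L), 3, 10L)))
#' f <- tempfile(fileext = ".gmt")
#' writeSignatureGmt(sigs, f)
#' readSignatureGmt(f)
#' @export
readGmt <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    out <- lapply(lines, function(l) {
        parts <- strsplit(l, "\t", fixed = TRUE)[[1L]]
        if (length(parts) < 3L)
            stop("malformed GMT line (need name, description, >=1 gene): ", l)
        list(description = parts[2L], genes = parts[-(1:2)])
    })
    names(out) <- vapply(lines, function(l)
        strsplit(l, "\t", fixed = TRUE)[[1L]][1L], character(1),
        USE.NAMES = FALSE)
    out
}

#' @rdname readGmt
#' @param sets named list of character vectors (gene sets), or for
#'   `writeSignatureGmt` an [OncoSignatureSet-class].
#' @param descriptions optional character vector parallel to `sets`.
#' @export
writeGmt <- function(sets, path, descriptions = NULL) {
    if (is.null(descriptions)) descriptions <- rep("na", length(sets))
    lines <- mapply(function(nm, desc, genes)
        paste(c(nm, desc, genes), collapse = "\t"),
        names(sets), descriptions, sets)
    writeLines(unname(lines), path)
    invisible(path)
}

.DIR_SUFFIX <- c(`1` = "+", `-1` = "-", `0` = ".")

#' @rdname readGmt
#' @param sigs an [OncoSignatureSet-class].
#' @export
writeSignatureGmt <- function(sigs, path) {
    stopifnot(is(sigs, "OncoSignatureSet"))
    lines <- vapply(sigs@.Data, function(s) {
        desc <- sprintf("support_threshold=%.6g;n_mut=%d",
                        s@supportThreshold, s@nMut)
        genes <- paste0(s@markers, .DIR_SUFFIX[as.character(s@direction)])
        paste(c(s@driver, desc, genes), collapse = "\t")
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}

#' @rdname readGmt
#' @export
readSignatureGmt <- function(path) {
    raw <- readGmt(path)
    sigs <- lapply(names(raw), function(nm) {
        genes <- raw[[nm]]$genes
        suffix <- substring(genes, nchar(genes))
        dir <- c(`+` = 1L, `-` = -1L, `.` = 0L)[suffix]
        if (any(is.na(dir)))
            stop("marker without direction suffix in signature ", nm)
        desc <- raw[[nm]]$description
        fields <- strsplit(strsplit(desc, ";")[[1L]], "=")
        vals <- stats::setNames(vapply(fields, `[`, character(1), 2L),
                                vapply(fields, `[`, character(1), 1L))
        OncoSignature(nm, substring(genes, 1L, nchar(genes) - 1L),
                      unname(dir),
                      as.numeric(vals[["support_threshold"]]),
                      as.integer(vals[["n_mut"]]))
    })
    OncoSignatureSet(sigs)
}

#' Read a JASPAR-style position frequency matrix
#'
#' Accepts the JASPAR text format: a header line starting with \code{>}
#' (motif id and name), then four rows \code{A [ counts ]},
#' \code{C [ ... ]}, \code{G [ ... ]}, \code{T [ ... ]}; brackets and row
#' labels are optional.
#'
#' @param path PFM text file.
#' @return numeric 4 x L count matrix with rownames A, C, G, T and a
#'   \code{"name"} attribute from the header (if any).
#' @seealso [pfmToPwm()], [scanPwm()]
#' @examples
#' pfm <- readJasparPfm(system.file("extdata", "synthetic_motif.pfm",
#'                                  package = "oncosig"))
#' pfmToPwm(pfm)
#' @export
readJasparPfm <- function(path) {
    lines <- trimws(readLines(path))
    lines <- lines[nzchar(lines)]
    name <- NA_character_
    if (startsWith(lines[1L], ">")) {
        name <- sub("^>\\s*", "", lines[1L])
        lines <- lines[-1L]
    }
    if (length(lines) != 4L)
        stop("expected 4 base rows (A, C, G, T) in ", path)
    parseRow <- function(l) {
        l <- gsub("^[ACGTacgt]\\s*", "", l)
        l <- gsub("\\[|\\]", " ", l)
        as.numeric(strsplit(trimws(l), "\\s+")[[1L]])
    }
    rows <- lapply(lines, parseRow)
    if (length(unique(lengths(rows))) != 1L)
        stop("ragged PFM rows in ", path)
    pfm <- do.call(rbind, rows)
    rownames(pfm) <- c("A", "C", "G", "T")
    if (any(pfm < 0)) stop("negative PFM counts in ", path)
    attr(pfm, "name") <- name
    pfm
}

#' Convert a position frequency matrix to a log-odds PWM
#'
#' Columns are smoothed with a pseudocount, normalized to probabilities and
#' converted to log2 odds against the background.
#'
#' @param pfm 4 x L count (or probability) matrix, rows A, C, G, T.
#' @param background background base probabilities (default uniform).
#' @param pseudocount added to every cell before normalization.
#' @return 4 x L log2-odds PWM with the same dimnames.
#' @examples
#' pfm <- matrix(c(10, 0, 0, 0, 0, 10, 0, 0), 4, 2,
#'     dimnames = list(c("A", "C", "G", "T"), NULL))
#' pfmToPwm(pfm)
#' @export
pfmToPwm <- function(pfm, background = rep(0.25, 4), pseudocount = 0.25) {
    stopifnot(nrow(pfm) == 4L, all(pfm >= 0), length(background) == 4L,
              all(background > 0), pseudocount >= 0)
    sm <- pfm + pseudocount
    probs <- sweep(sm, 2L, colSums(sm), "/")
    pwm <- log2(probs / background)
    rownames(pwm) <- c("A", "C", "G", "T")
    attr(pwm, "name") <- attr(pfm, "name")
    pwm
}

#' Aggregate isoform counts to their parent identifier
#'
#' Sums the counts of all isoforms mapping to the same group id (e.g. all
#' small-RNA isoforms of one mature miRNA MIMAT accession). The result has
#' one row per group, in lexicographic group order.
#'
#' @param isoforms data.frame with columns \code{isoform_id},
#'   \code{group_id} and \code{count} (all counts >= 0).
#' @return data.frame with columns \code{group_id}, \code{count}.
#' @examples
#' aggregateIsoformCounts(data.frame(
#'     isoform_id = c("iso1", "iso2"),
#'     group_id = c("MIMAT0000428", "MIMAT0000428"),
#'     count = c(3, 7)))
#' @export
aggregateIsoformCounts <- function(isoforms) {
    need <- c("isoform_id", "group_id", "count")
    miss <- setdiff(need, colnames(isoforms))
    if (length(miss))
        stop("isoform table missing columns: ", paste(miss, collapse = ", "))
    if (nrow(isoforms) == 0L)
        return(data.frame(group_id = character(), count = numeric()))
    if (any(!is.finite(isoforms$count)) || any(isoforms$count < 0))
        stop("isoform counts must be finite and >= 0")
    agg <- tapply(isoforms$count, isoforms$group_id, sum)
    ord <- order(names(agg), method = "radix")
    data.frame(group_id = names(agg)[ord], count = as.numeric(agg)[ord],
               row.names = NULL)
}

#' Upper-quartile normalization
#'
#' Scales each sample so that its 75th percentile of counts, taken over the
#' genes nonzero in that sample, equals the across-sample mean of those
#' percentiles. Type-7 (linear interpolation) quantiles, as everywhere in
#' the package.
#'
#' @param x an [ExpressionMatrix-class] of raw counts, every sample with at
#'   least one nonzero gene.
#' @return an [ExpressionMatrix-class] with scale \code{"normalized"}.
#' @examples
#' m <- ExpressionMatrix(matrix(c(1, 4, 10, 2, 8, 20), 3, 2,
#'     dimnames = list(paste0("g", 1:3), c("s1", "s2"))), "raw_counts")
#' upperQuartileNormalize(m)
#' @export
upperQuartileNormalize <- function(x) {
    stopifnot(is(x, "ExpressionMatrix"))
    if (exprScale(x) != "raw_counts")
        stop("upper-quartile normalization expects raw counts")
    v <- x@.Data
    uq <- vapply(seq_len(ncol(v)), function(j) {
        col <- v[, j]
        nz <- col[col > 0]
        if (length(nz) == 0L)
            stop("sample has no nonzero genes: ", colnames(v)[j])
        stats::quantile(nz, 0.75, type = 7, names = FALSE)
    }, numeric(1))
    target <- mean(uq)
    out <- sweep(v, 2L, uq / target, "/")
    ExpressionMatrix(out, "normalized")
}
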