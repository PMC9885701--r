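#' @include AllClasses.R
NULL

#' Extract a promoter window around a TSS
#'
#' All coordinates are 0-based half-open on the chromosome's forward
#' strand. For a + strand gene the window is [tss - upstream,
#' tss + downstream); for a - strand gene it is the reverse complement of
#' [tss - downstream, tss + upstream), so the returned sequence always
#' reads 5' to 3' on the gene's strand with the upstream flank first. At
#' the defaults (1500 nt upstream, 500 nt downstream of the TSS) the window
#' is 2000 nt. Windows extending beyond the chromosome are an error; no
#' clipping is done.
#'
#' @param genome a [Biostrings::DNAStringSet-class] keyed by sequence name
#'   (e.g. read with [Biostrings::readDNAStringSet()]).
#' @param gene gene id recorded on the window.
#' @param tss 0-based TSS position on the forward strand.
#' @param strand `"+"` or `"-"`.
#' @param upstream,downstream window extents in nt (defaults 1500 / 500).
#' @param seqname chromosome name in `genome` (default: its first
#'   sequence).
#' @return A [PromoterWindow-class]; the TSS sits at offset `upstream`.
#' @examples
#' genome <- Biostrings::DNAStringSet(c(chr1 = "AAAACGTAAAA"))
#' extractPromoter(genome, "toy", tss = 7, strand = "-",
#'     upstream = 3, downstream = 2)
#' @export
extractPromoter <- function(genome, gene, tss, strand = c("+", "-"),
                            upstream = 1500, downstream = 500,
                            seqname = names(genome)[1L]) {
    strand <- match.arg(strand)
    stopifnot(upstream >= 0, downstream >= 0, upstream + downstream >= 1)
    chrom <- genome[[seqname]]
    chrLen <- length(chrom)
    if (strand == "+") {
        start0 <- tss - upstream; end0 <- tss + downstream
    } else {
        start0 <- tss - downstream; end0 <- tss + upstream
    }
    if (start0 < 0 || end0 > chrLen)
        stop(sprintf(
            "promoter window [%d, %d) out of bounds for %s (length %d)",
            start0, end0, seqname, chrLen))
    win <- Biostrings::subseq(chrom, start = start0 + 1L, end = end0)
    if (strand == "-") win <- Biostrings::reverseComplement(win)
    new("PromoterWindow", gene = gene, sequence = as.character(win),
        tssOffset = as.integer(upstream))
}

.BASE_IDX <- c(A = 1L, C = 2L, G = 3L, T = 4L)

# Score a character sequence against a PWM at every offset; N scores as the
# column minimum. Returns a numeric vector of length nchar(seq) - L + 1.
.slideScores <- function(seqchars, pwm) {
    L <- ncol(pwm)
    n <- length(seqchars)
    colMin <- apply(pwm, 2L, min)
    idx <- .BASE_IDX[seqchars]
    nWin <- n - L + 1L
    scores <- numeric(nWin)
    for (j in seq_len(L)) {
        b <- idx[j:(j + nWin - 1L)]
        s <- pwm[cbind(b, j)]
        s[is.na(b)] <- colMin[j]
        scores <- scores + s
    }
    scores
}

#' Scan a promoter window with a PWM on both strands
#'
#' Slides the PWM over the window's forward sequence and its reverse
#' complement, reporting every offset whose score reaches
#' `minScore + minScoreFraction * (maxScore - minScore)`, where min and max
#' are the PWM's attainable score range. Positions are 0-based starts on
#' the forward strand of the window for both strands; `N` bases score as
#' the column minimum.
#'
#' @param window a [PromoterWindow-class] (or a plain character sequence).
#' @param pwm 4 x L score matrix with rows A, C, G, T.
#' @param minScoreFraction threshold fraction of the attainable score
#'   range, in (0, 1]; 0.8 is the common default of the matchPWM tool
#'   family, 1.0 keeps only perfect-score matches.
#' @return data.frame with `position`, `strand`, `score`, ordered by
#'   position then strand.
#' @examples
#' scanPwm("TTACGTT", consensusPwm("ACGT"), 1.0)  # forward hit at 2
#' @export
scanPwm <- function(window, pwm, minScoreFraction = 0.8) {
    if (!(minScoreFraction > 0 && minScoreFraction <= 1))
        stop("minScoreFraction must be in (0, 1]")
    stopifnot(nrow(pwm) == 4L)
    if (is.null(rownames(pwm))) rownames(pwm) <- c("A", "C", "G", "T")
    seq <- if (is(window, "PromoterWindow")) window@sequence
           else as.character(window)
    L <- ncol(pwm)
    n <- nchar(seq)
    if (L > n) stop("PWM is longer than the window")
    maxScore <- sum(apply(pwm, 2L, max))
    minScore <- sum(apply(pwm, 2L, min))
    thr <- minScore + minScoreFraction * (maxScore - minScore)
    fwd <- strsplit(toupper(seq), "")[[1L]]
    rev <- strsplit(as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(paste(fwd, collapse = "")))), "")[[1L]]
    fwdScores <- .slideScores(fwd, pwm)
    revScores <- .slideScores(rev, pwm)
    hitF <- which(fwdScores >= thr)
    hitR <- which(revScores >= thr)
    out <- data.frame(
        position = c(hitF - 1L, n - L - (hitR - 1L)),
        strand = rep(c("+", "-"), c(length(hitF), length(hitR))),
        score = c(fwdScores[hitF], revScores[hitR]))
    out <- out[order(out$position, out$strand), , drop = FALSE]
    rownames(out) <- NULL
    out
}
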