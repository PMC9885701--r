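test_that("promoter windows follow 0-based half-open strand arithmetic", {
    chrom <- paste(rep("ACGT", 3000), collapse = "")
    genome <- Biostrings::DNAStringSet(setNames(chrom, "chr1"))
    win <- extractPromoter(genome, "geneX", tss = 5000, strand = "+")
    expect_identical(nchar(win@sequence), 2000L)
    expect_identical(win@sequence, substr(chrom, 3501, 5500))
    expect_identical(win@tssOffset, 1500L)

    toy <- Biostrings::DNAStringSet(setNames("AAAACGTAAAA", "chrT"))
    w <- extractPromoter(toy, "toy", tss = 7, strand = "-",
                         upstream = 3, downstream = 2)
    # reverse complement of forward positions [5, 10)
    expect_identical(w@sequence, "TTTAC")

    expect_error(extractPromoter(genome, "g", tss = 100, strand = "+"),
                 "out of bounds")
})

test_that("PWM scan finds exact consensus matches on both strands", {
    # ACGT is its own reverse complement, so the both-strand scan reports
    # the exact match at position 2 on each strand
    hitsF <- scanPwm("TTACGTT", consensusPwm("ACGT"), 1.0)
    expect_identical(hitsF$position, c(2L, 2L))
    expect_setequal(hitsF$strand, c("+", "-"))

    hitsR <- scanPwm("TGGTTA", consensusPwm("AACC"), 1.0)
    expect_identical(nrow(hitsR), 1L)
    expect_identical(hitsR$position, 1L)
    expect_identical(hitsR$strand, "-")

    none <- scanPwm("TTTTTTTTTT", consensusPwm("ACGA"), 1.0)
    expect_identical(nrow(none), 0L)

    expect_error(scanPwm("ACG", consensusPwm("ACGT"), 1.0), "longer")
    expect_error(scanPwm("ACGTA", consensusPwm("ACGT"), 0), "minScoreFraction")
})

test_that("scanning a sequence and its reverse complement mirrors hits", {
    set.seed(12)
    seq <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                 collapse = "")
    pwm <- pfmToPwm(consensusPwm("ACGTAC") * 10 + 1)
    hits <- scanPwm(seq, pwm, 0.8)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    hitsRc <- scanPwm(rc, pwm, 0.8)
    L <- 6
    mirrored <- data.frame(
        position = nchar(seq) - L - hitsRc$position,
        strand = ifelse(hitsRc$strand == "+", "-", "+"),
        score = hitsRc$score)
    mirrored <- mirrored[order(mirrored$position, mirrored$strand), ]
    rownames(mirrored) <- NULL
    expect_equal(hits, mirrored)
})

test_that("N bases score as the column minimum", {
    pwm <- pfmToPwm(consensusPwm("ACGT") * 10 + 1)
    full <- scanPwm("ACGT", pwm, 0.01)
    withN <- scanPwm("ACNT", pwm, 0.01)
    fwdFull <- full$score[full$strand == "+"]
    fwdN <- withN$score[withN$strand == "+"]
    expect_equal(fwdN, fwdFull - max(pwm[, 3]) + min(pwm[, 3]))
})

test_that("consensus scan agrees with Biostrings string matching", {
    set.seed(77)
    seqs <- simulatePromoters(5, 400, consensusPwm("ACGTTGCA"),
        list(`2` = data.frame(position = 100, strand = "+")), seed = 77)
    for (i in seq_along(seqs)) {
        s <- as.character(seqs[[i]])
        ours <- scanPwm(s, consensusPwm("ACGTTGCA"), 1.0)
        fwd <- Biostrings::start(Biostrings::matchPattern("ACGTTGCA",
            Biostrings::DNAString(s))) - 1L
        rev <- Biostrings::start(Biostrings::matchPattern(
            as.character(Biostrings::reverseComplement(
                Biostrings::DNAString("ACGTTGCA"))),
            Biostrings::DNAString(s))) - 1L
        expect_setequal(ours$position[ours$strand == "+"], fwd)
        expect_setequal(ours$position[ours$strand == "-"], rev)
    }
})
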