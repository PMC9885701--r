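#' @include AllClasses.R
NULL

# Run expr under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards: generators are pure functions of (scenario, seed).
.withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

#' Simulation scenario components
#'
#' `driverSpec` describes one planted driver gene: the fraction of tumors
#' mutated, the indices of its target genes, and the log2 fold-change its
#' mutation imposes on their means. `subtypeSpec` describes a planted sample
#' subtype: its cohort proportion, the drivers forced to mutated state in its
#' samples, and a multiplicative hazard for survival. `survivalSpec` holds
#' the exponential event and censoring rates (per day) and the
#' administrative follow-up limit.
#'
#' @param name driver or subtype name.
#' @param mutationRate fraction of tumors mutated, in (0, 1).
#' @param targetGenes integer indices of the driver's target genes.
#' @param effectLog2FC signed log2 fold-change applied to target means in
#'   mutated samples.
#' @return An S4 spec object for use in [simulationScenario()].
#' @name scenario-specs
NULL

#' @exportClass DriverSpec
setClass("DriverSpec",
    representation(name = "character", mutationRate = "numeric",
                   targetGenes = "integer", effectLog2FC = "numeric"))

setValidity("DriverSpec", function(object) {
    msg <- character()
    if (!(object@mutationRate > 0 && object@mutationRate < 1))
        msg <- c(msg, "mutationRate must be in (0, 1)")
    if (length(object@targetGenes) < 1L)
        msg <- c(msg, "target gene set must be non-empty")
    if (length(msg)) msg else TRUE
})

#' @rdname scenario-specs
#' @export
driverSpec <- function(name, mutationRate, targetGenes, effectLog2FC) {
    new("DriverSpec", name = name, mutationRate = mutationRate,
        targetGenes = as.integer(targetGenes), effectLog2FC = effectLog2FC)
}

#' @exportClass SubtypeSpec
setClass("SubtypeSpec",
    representation(name = "character", proportion = "numeric",
                   activeDrivers = "character", hazardMultiplier = "numeric"))

setValidity("SubtypeSpec", function(object) {
    msg <- character()
    if (!(object@proportion > 0 && object@proportion < 1))
        msg <- c(msg, "proportion must be in (0, 1)")
    if (!(object@hazardMultiplier > 0))
        msg <- c(msg, "hazardMultiplier must be positive")
    if (length(msg)) msg else TRUE
})

#' @rdname scenario-specs
#' @param proportion subtype proportion in (0, 1); proportions across
#'   subtypes must sum to 1.
#' @param activeDrivers names of drivers forced to mutated state in this
#'   subtype's samples.
#' @param hazardMultiplier multiplies the baseline event hazard.
#' @export
subtypeSpec <- function(name, proportion, activeDrivers = character(),
                        hazardMultiplier = 1) {
    new("SubtypeSpec", name = name, proportion = proportion,
        activeDrivers = activeDrivers, hazardMultiplier = hazardMultiplier)
}

#' @exportClass SurvivalSpec
setClass("SurvivalSpec",
    representation(baselineHazard = "numeric", censoringRate = "numeric",
                   maxFollowup = "numeric"))

setValidity("SurvivalSpec", function(object) {
    msg <- character()
    if (!(object@baselineHazard > 0))
        msg <- c(msg, "baselineHazard must be positive")
    if (object@censoringRate < 0)
        msg <- c(msg, "censoringRate must be >= 0")
    if (!(object@maxFollowup > 0))
        msg <- c(msg, "maxFollowup must be positive")
    if (length(msg)) msg else TRUE
})

#' @rdname scenario-specs
#' @param baselineHazard exponential event rate per day.
#' @param censoringRate exponential censoring rate per day (0 = none).
#' @param maxFollowup administrative censoring horizon, days (may be `Inf`).
#' @export
survivalSpec <- function(baselineHazard = 2e-4, censoringRate = 1.5e-4,
                         maxFollowup = 3650) {
    new("SurvivalSpec", baselineHazard = baselineHazard,
        censoringRate = censoringRate, maxFollowup = maxFollowup)
}

#' Simulation scenario for a synthetic tumor cohort
#'
#' Defines the generative model every simulator draws from: per-gene NB
#' counts with log-uniform means and a shared size (dispersion) parameter,
#' planted drivers whose mutation shifts target-gene means, planted sample
#' subtypes (with deterministic driver coupling, so clusters have a ground
#' truth), and exponential survival whose hazard depends on the subtype.
#'
#' @param nGenes,nNormals,nTumors cohort dimensions.
#' @param nbMeanRange (low, high) range of per-gene NB means; means are
#'   drawn log-uniformly within it.
#' @param nbDispersion shared NB size parameter (variance = mean +
#'   mean^2/size).
#' @param drivers list of [driverSpec()] objects.
#' @param subtypes list of [subtypeSpec()] objects; proportions must sum
#'   to 1 (empty list = one homogeneous population).
#' @param survival a [survivalSpec()].
#' @param seed integer seed; all simulators are pure functions of
#'   (scenario, seed).
#' @return A validated `SimulationScenario`.
#' @seealso [defaultScenario()], [simulateCohort()]
#' @exportClass SimulationScenario
#' @export simulationScenario
setClass("SimulationScenario",
    representation(nGenes = "integer", nNormals = "integer",
                   nTumors = "integer", nbMeanRange = "numeric",
                   nbDispersion = "numeric", drivers = "list",
                   subtypes = "list", survival = "SurvivalSpec",
                   seed = "integer"))

setValidity("SimulationScenario", function(object) {
    msg <- character()
    if (object@nGenes < 1L || object@nNormals < 1L || object@nTumors < 1L)
        msg <- c(msg, "nGenes, nNormals, nTumors must be >= 1")
    if (length(object@nbMeanRange) != 2L ||
        !all(object@nbMeanRange > 0) ||
        object@nbMeanRange[1L] > object@nbMeanRange[2L])
        msg <- c(msg, "nbMeanRange must be a valid positive (low, high) pair")
    if (!(object@nbDispersion > 0))
        msg <- c(msg, "nbDispersion must be positive")
    if (!all(vapply(object@drivers, is, logical(1), "DriverSpec")))
        msg <- c(msg, "drivers must be DriverSpec objects")
    if (!all(vapply(object@subtypes, is, logical(1), "SubtypeSpec")))
        msg <- c(msg, "subtypes must be SubtypeSpec objects")
    if (length(object@subtypes)) {
        props <- vapply(object@subtypes, function(s) s@proportion, numeric(1))
        if (abs(sum(props) - 1) > 1e-8)
            msg <- c(msg, "subtype proportions must sum to 1")
        drv <- vapply(object@drivers, function(d) d@name, character(1))
        act <- unique(unlist(lapply(object@subtypes,
                                    function(s) s@activeDrivers)))
        if (length(setdiff(act, drv)))
            msg <- c(msg, "subtype activeDrivers reference unknown drivers")
    }
    bad <- vapply(object@drivers, function(d)
        any(d@targetGenes < 1L | d@targetGenes > object@nGenes), logical(1))
    if (any(bad))
        msg <- c(msg, "driver target indices out of gene range")
    if (length(msg)) msg else TRUE
})

simulationScenario <- function(nGenes = 2000, nNormals = 200, nTumors = 400,
                               nbMeanRange = c(10, 1000), nbDispersion = 10,
                               drivers = list(), subtypes = list(),
                               survival = survivalSpec(), seed = 1) {
    new("SimulationScenario", nGenes = as.integer(nGenes),
        nNormals = as.integer(nNormals), nTumors = as.integer(nTumors),
        nbMeanRange = as.numeric(nbMeanRange), nbDispersion = nbDispersion,
        drivers = drivers, subtypes = subtypes, survival = survival,
        seed = as.integer(seed))
}

#' Default synthetic-cohort scenario
#'
#' The reference study conditions for end-to-end validation: 2000 genes,
#' 200 normals, 400 tumors; three drivers, each mutated in 30% of tumors,
#' with disjoint 40-gene target sets shifted by |log2FC| = 1.5 (up, down,
#' up); four equal-sized subtypes (no driver / one active driver each) with
#' hazard multipliers 1, 1.8, 3 and 6 on an exponential baseline of 2e-4
#' events per day, censoring rate 1.5e-4 per day and 10-year follow-up.
#'
#' @param seed integer seed.
#' @param effectLog2FC absolute planted effect size (default 1.5); set to 0
#'   for a null cohort with no mutation-linked expression structure.
#' @return A [SimulationScenario-class].
#' @examples
#' sc <- defaultScenario(seed = 7)
#' @export
defaultScenario <- function(seed = 1, effectLog2FC = 1.5) {
    drivers <- list(
        driverSpec("DRV1", 0.3, 1:40, effectLog2FC),
        driverSpec("DRV2", 0.3, 41:80, -effectLog2FC),
        driverSpec("DRV3", 0.3, 81:120, effectLog2FC))
    subtypes <- list(
        subtypeSpec("S1", 0.25, character(), 1),
        subtypeSpec("S2", 0.25, "DRV1", 1.8),
        subtypeSpec("S3", 0.25, "DRV2", 3),
        subtypeSpec("S4", 0.25, "DRV3", 6))
    simulationScenario(drivers = drivers, subtypes = subtypes, seed = seed)
}

.geneIds <- function(sc) sprintf("gene_%04d", seq_len(sc@nGenes))

# Per-gene baseline NB means, a deterministic function of the scenario seed
# shared by the reference and tumor simulators.
.geneMeans <- function(sc) {
    .withSeed(sc@seed, {
        lo <- log(sc@nbMeanRange[1L]); hi <- log(sc@nbMeanRange[2L])
        stats::setNames(exp(stats::runif(sc@nGenes, lo, hi)), .geneIds(sc))
    })
}

#' Simulate a normal reference cohort
#'
#' Draws an nGenes x nNormals count matrix; gene g is i.i.d.
#' NB(mean_g, size) with mean_g log-uniform in the scenario's mean range.
#'
#' @param sc a [SimulationScenario-class].
#' @return An [ExpressionMatrix-class] of raw counts.
#' @examples
#' normals <- simulateReferenceCohort(defaultScenario(seed = 7))
#' @export
simulateReferenceCohort <- function(sc) {
    stopifnot(is(sc, "SimulationScenario"))
    validObject(sc)
    mu <- .geneMeans(sc)
    v <- .withSeed(sc@seed + 1L,
        matrix(stats::rnbinom(sc@nGenes * sc@nNormals, mu = rep(mu, sc@nNormals),
                              size = sc@nbDispersion),
               nrow = sc@nGenes, ncol = sc@nNormals))
    dimnames(v) <- list(.geneIds(sc), sprintf("normal_%04d", seq_len(sc@nNormals)))
    ExpressionMatrix(v, "raw_counts")
}

#' Simulate a tumor cohort with planted drivers and subtypes
#'
#' Tumors are drawn from the reference NB model. Each tumor gets a subtype
#' by the scenario proportions; each driver's mutation status is
#' Bernoulli(mutationRate), forced to 1 for subtypes listing the driver as
#' active. In mutated samples the driver's target-gene means are multiplied
#' by 2^effectLog2FC; overlapping effects add in log2 space.
#'
#' @param sc a [SimulationScenario-class].
#' @return list with `expression` ([ExpressionMatrix-class]), `mutations`
#'   (samples x drivers 0/1 matrix) and `subtypes` (named character vector).
#' @examples
#' tum <- simulateTumorCohort(defaultScenario(seed = 7))
#' @export
simulateTumorCohort <- function(sc) {
    stopifnot(is(sc, "SimulationScenario"))
    validObject(sc)
    mu <- .geneMeans(sc)
    sampleIds <- sprintf("tumor_%04d", seq_len(sc@nTumors))
    drvNames <- vapply(sc@drivers, function(d) d@name, character(1))
    .withSeed(sc@seed + 2L, {
        if (length(sc@subtypes)) {
            stNames <- vapply(sc@subtypes, function(s) s@name, character(1))
            props <- vapply(sc@subtypes, function(s) s@proportion, numeric(1))
            labels <- sample(stNames, sc@nTumors, replace = TRUE, prob = props)
        } else {
            labels <- rep("base", sc@nTumors)
        }
        mut <- matrix(0, nrow = sc@nTumors, ncol = length(sc@drivers),
                      dimnames = list(sampleIds, drvNames))
        for (i in seq_along(sc@drivers))
            mut[, i] <- stats::rbinom(sc@nTumors, 1L, sc@drivers[[i]]@mutationRate)
        if (length(sc@subtypes)) {
            for (s in sc@subtypes)
                if (length(s@activeDrivers))
                    mut[labels == s@name, s@activeDrivers] <- 1
        }
        logMu <- matrix(log2(mu), nrow = sc@nGenes, ncol = sc@nTumors)
        for (i in seq_along(sc@drivers)) {
            d <- sc@drivers[[i]]
            mutated <- mut[, i] == 1
            if (any(mutated))
                logMu[d@targetGenes, mutated] <-
                    logMu[d@targetGenes, mutated] + d@effectLog2FC
        }
        v <- matrix(stats::rnbinom(length(logMu), mu = 2^as.vector(logMu),
                                   size = sc@nbDispersion),
                    nrow = sc@nGenes, ncol = sc@nTumors,
                    dimnames = list(.geneIds(sc), sampleIds))
        list(expression = ExpressionMatrix(v, "raw_counts"),
             mutations = mut,
             subtypes = stats::setNames(labels, sampleIds))
    })
}

#' Simulate survival outcomes for labelled samples
#'
#' Event times are exponential with rate baselineHazard x the subtype's
#' hazard multiplier; censoring times are exponential with the censoring
#' rate, truncated at the follow-up horizon. Observed time is the minimum;
#' the event flag is 1 iff the event time came first.
#'
#' @param labels named character vector, sample -> subtype name.
#' @param sc a [SimulationScenario-class] whose subtypes cover all labels.
#' @param seedOffset added to the scenario seed for this draw (default 3).
#' @return A clinical data.frame (`sample_id`, `time`, `event`, `subtype`).
#' @examples
#' sc <- defaultScenario(seed = 7)
#' tum <- simulateTumorCohort(sc)
#' clin <- simulateSurvival(tum$subtypes, sc)
#' @export
simulateSurvival <- function(labels, sc, seedOffset = 3L) {
    stopifnot(is(sc, "SimulationScenario"))
    stNames <- vapply(sc@subtypes, function(s) s@name, character(1))
    unknown <- setdiff(unique(labels), stNames)
    if (length(unknown))
        stop("labels without a SubtypeSpec: ", paste(unknown, collapse = ", "))
    hm <- stats::setNames(
        vapply(sc@subtypes, function(s) s@hazardMultiplier, numeric(1)),
        stNames)
    sv <- sc@survival
    n <- length(labels)
    .withSeed(sc@seed + as.integer(seedOffset), {
        evt <- stats::rexp(n, rate = sv@baselineHazard * hm[labels])
        cens <- if (sv@censoringRate > 0) stats::rexp(n, rate = sv@censoringRate)
                else rep(Inf, n)
        cens <- pmin(cens, sv@maxFollowup)
        data.frame(sample_id = if (is.null(names(labels)))
                       sprintf("sample_%04d", seq_len(n)) else names(labels),
                   time = pmin(evt, cens),
                   event = as.integer(evt <= cens),
                   subtype = as.character(labels),
                   row.names = NULL, stringsAsFactors = FALSE)
    })
}

#' Simulate a full cohort
#'
#' Convenience wrapper running the reference, tumor and survival simulators
#' on one scenario.
#'
#' @param sc a [SimulationScenario-class].
#' @return list with `normals`, `tumors`, `mutations`, `subtypes`,
#'   `clinical` and `truth` (the planted target sets and hazards).
#' @export
simulateCohort <- function(sc) {
    normals <- simulateReferenceCohort(sc)
    tum <- simulateTumorCohort(sc)
    clinical <- if (length(sc@subtypes))
        simulateSurvival(tum$subtypes, sc) else NULL
    truth <- list(
        targets = stats::setNames(
            lapply(sc@drivers, function(d) .geneIds(sc)[d@targetGenes]),
            vapply(sc@drivers, function(d) d@name, character(1))),
        effects = stats::setNames(
            vapply(sc@drivers, function(d) d@effectLog2FC, numeric(1)),
            vapply(sc@drivers, function(d) d@name, character(1))),
        hazards = stats::setNames(
            vapply(sc@subtypes, function(s) s@hazardMultiplier, numeric(1)),
            vapply(sc@subtypes, function(s) s@name, character(1))))
    list(normals = normals, tumors = tum$expression,
         mutations = tum$mutations, subtypes = tum$subtypes,
         clinical = clinical, truth = truth)
}

#' Simulate promoter windows with planted motif occurrences
#'
#' Sequences are i.i.d. uniform A/C/G/T backgrounds; at each planted
#' position the PWM's consensus (or its reverse complement, for minus-strand
#' plants) overwrites the background. Overlapping plants are an error.
#'
#' @param n number of sequences.
#' @param length sequence length (nt).
#' @param pwm 4 x L matrix, rows A, C, G, T; its column-wise argmax defines
#'   the consensus.
#' @param plantedPositions list indexed by sequence number; each element a
#'   data.frame with 0-based `position` and `strand` ("+" or "-") columns.
#'   Sequences without an entry get no plant.
#' @param seed integer seed.
#' @return A [Biostrings::DNAStringSet-class] named `promoter_<i>`.
#' @examples
#' pwm <- consensusPwm("ACGTACGT")
#' simulatePromoters(2, 100, pwm,
#'     list(`1` = data.frame(position = 10, strand = "+")), seed = 1)
#' @export
simulatePromoters <- function(n, length, pwm, plantedPositions = list(),
                              seed = 1) {
    stopifnot(nrow(pwm) == 4L, length >= ncol(pwm))
    L <- ncol(pwm)
    consensus <- paste(rownames(pwm)[apply(pwm, 2L, which.max)], collapse = "")
    rcConsensus <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(consensus)))
    seqs <- .withSeed(seed, vapply(seq_len(n), function(i)
        paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
              collapse = ""), character(1)))
    for (key in names(plantedPositions)) {
        i <- as.integer(key)
        plants <- plantedPositions[[key]]
        if (nrow(plants) == 0L) next
        if (any(plants$position < 0L | plants$position + L > length))
            stop("planted position out of bounds in sequence ", i)
        ord <- order(plants$position)
        starts <- plants$position[ord]
        if (any(diff(starts) < L))
            stop("overlapping plants in sequence ", i)
        for (r in seq_len(nrow(plants))) {
            p <- plants$position[r]
            motif <- if (plants$strand[r] == "-") rcConsensus else consensus
            substring(seqs[i], p + 1L, p + L) <- motif
        }
    }
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- sprintf("promoter_%d", seq_len(n))
    out
}

#' Simulate subtype-structured NES profiles
#'
#' Generates a signatures x samples NES matrix where each planted subtype
#' has a distinct activity profile: subtype centers sit at the corners
#' 0.5 +/- amplitude of a binary code over the signatures, and samples add
#' Gaussian noise, truncated to [0, 1]. With the defaults the closest two
#' centers are 2 x amplitude = 8 noise standard deviations apart.
#'
#' @param sc a [SimulationScenario-class] supplying the subtypes, tumor
#'   count and seed.
#' @param nSignatures number of signature rows.
#' @param amplitude half-distance of the subtype code (default 0.2).
#' @param noiseSd within-subtype noise sd (default 0.05).
#' @return list with `nes` ([NESMatrix-class]) and `labels` (named subtype
#'   vector).
#' @export
simulateSubtypeNes <- function(sc, nSignatures = 8, amplitude = 0.2,
                               noiseSd = 0.05) {
    stopifnot(is(sc, "SimulationScenario"), length(sc@subtypes) >= 1L)
    stNames <- vapply(sc@subtypes, function(s) s@name, character(1))
    props <- vapply(sc@subtypes, function(s) s@proportion, numeric(1))
    nSub <- length(stNames)
    nBits <- max(1L, ceiling(log2(nSub)))
    code <- sapply(seq_len(nSignatures), function(i) {
        bit <- (i - 1L) %% nBits
        ifelse(bitwAnd(seq_len(nSub) - 1L, bitwShiftL(1L, bit)) > 0L, 1, -1)
    })
    code <- matrix(code, nrow = nSub)
    centers <- 0.5 + amplitude * code   # nSub x nSignatures
    .withSeed(sc@seed + 4L, {
        labels <- sample(stNames, sc@nTumors, replace = TRUE, prob = props)
        idx <- match(labels, stNames)
        v <- t(centers[idx, , drop = FALSE]) +
            matrix(stats::rnorm(nSignatures * sc@nTumors, sd = noiseSd),
                   nrow = nSignatures)
        v <- pmin(pmax(v, 0), 1)
        dimnames(v) <- list(sprintf("sig_%02d", seq_len(nSignatures)),
                            sprintf("tumor_%04d", seq_len(sc@nTumors)))
        list(nes = NESMatrix(v),
             labels = stats::setNames(labels, colnames(v)))
    })
}

#' Write a scenario's cohort to plain-text fixtures
#'
#' Writes normal and tumor expression TSVs, the mutation and clinical
#' tables, and a `truth.json` with the planted targets, effects and
#' hazards.
#'
#' @param sc a [SimulationScenario-class].
#' @param dir output directory (created if needed).
#' @return named character vector of the files written, invisibly.
#' @export
writeScenarioFixtures <- function(sc, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    cohort <- simulateCohort(sc)
    paths <- c(normals = file.path(dir, "normals.tsv"),
               tumors = file.path(dir, "tumors.tsv"),
               mutations = file.path(dir, "mutations.tsv"),
               clinical = file.path(dir, "clinical.tsv"),
               truth = file.path(dir, "truth.json"))
    writeExpressionMatrix(cohort$normals, paths[["normals"]])
    writeExpressionMatrix(cohort$tumors, paths[["tumors"]])
    writeMutationTable(cohort$mutations, paths[["mutations"]])
    if (!is.null(cohort$clinical))
        writeClinicalTable(cohort$clinical, paths[["clinical"]])
    jsonlite::write_json(cohort$truth, paths[["truth"]], auto_unbox = TRUE,
                         digits = NA)
    invisible(paths)
}

#' Build a 0/1 consensus PWM from a DNA string
#'
#' Utility for tests and examples: each column scores 1 for the consensus
#' base and 0 otherwise, so a threshold fraction of 1.0 matches exact
#' occurrences only.
#'
#' @param consensus DNA string over A/C/G/T.
#' @return 4 x nchar(consensus) matrix with rows A, C, G, T.
#' @export
consensusPwm <- function(consensus) {
    bases <- strsplit(toupper(consensus), "")[[1L]]
    stopifnot(all(bases %in% c("A", "C", "G", "T")))
    pwm <- matrix(0, nrow = 4L, ncol = length(bases),
                  dimnames = list(c("A", "C", "G", "T"), NULL))
    pwm[cbind(match(bases, rownames(pwm)), seq_along(bases))] <- 1
    pwm
}
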