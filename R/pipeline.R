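#' @include AllClasses.R
NULL

.writeTsvDf <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Run the full onco-signature pipeline
#'
#' Orchestrates every stage on one cohort: fit the normal reference, and
#' binarize the tumors (once; per-driver matrices are column subsets),
#' derive signatures, score them per sample (NES), screen with univariate
#' Cox models, cluster samples on the NES of the selected signatures
#' (Ward.D2, k clusters), compare cluster survival (KM + log-rank), and
#' run differential expression between the best- and worst-surviving
#' clusters at the configured thresholds. All declared outputs are written
#' to `outdir`; reruns with the same config, seed and inputs are
#' byte-identical (the run log records config and seed, never wall-clock
#' time).
#'
#' Inputs may be file paths (`paths`: `normals`, `tumors`, `mutations`,
#' `clinical` TSVs) or in-memory objects (`data`: the same elements as
#' returned by [simulateCohort()]); with neither, the cohort is simulated
#' from [defaultScenario()] at the config seed.
#'
#' @param config a [PipelineConfig-class].
#' @param outdir output directory, created if needed.
#' @param paths optional named list of input TSV paths.
#' @param data optional named list of in-memory inputs.
#' @return named list of results (`model`, `deg`, `signatures`, `nes`,
#'   `coxScreen`, `clusters`, `kmCurves`, `logrank`, `de`, `files`),
#'   invisibly.
#' @examples
#' \donttest{
#' res <- runPipeline(oncoConfig(seed = 7), tempfile("run"))
#' }
#' @export
runPipeline <- function(config = oncoConfig(), outdir, paths = NULL,
                        data = NULL) {
    stopifnot(is(config, "PipelineConfig"))
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    stage <- function(name, expr)
        tryCatch(expr, error = function(e)
            stop(sprintf("pipeline stage '%s' failed: %s", name,
                         conditionMessage(e)), call. = FALSE))

    if (is.null(data)) {
        if (is.null(paths)) {
            data <- stage("simulate",
                simulateCohort(defaultScenario(seed = config@seed)))
        } else {
            data <- stage("read", list(
                normals = readExpressionMatrix(paths$normals, "raw_counts"),
                tumors = readExpressionMatrix(paths$tumors, "raw_counts"),
                mutations = readMutationTable(paths$mutations),
                clinical = readClinicalTable(paths$clinical)))
        }
    }

    model <- stage("fit_reference", fitReferenceModel(data$normals))
    deg <- stage("binarize",
        binarizeMatrix(data$tumors, model, config@binarizationAlpha))
    sigs <- stage("derive_signatures",
        deriveSignatures(deg, data$mutations, config))

    files <- c(model = file.path(outdir, "reference_model.tsv"),
               signatures = file.path(outdir, "signatures.gmt"),
               nes = file.path(outdir, "nes_matrix.tsv"),
               cox = file.path(outdir, "cox_screen.tsv"),
               clusters = file.path(outdir, "clusters.tsv"),
               km = file.path(outdir, "km_curves.tsv"),
               logrank = file.path(outdir, "logrank.tsv"),
               de = file.path(outdir, "de_table.tsv"),
               log = file.path(outdir, "run_log.json"))
    .writeTsvDf(modelParameters(model), files[["model"]])
    writeSignatureGmt(sigs, files[["signatures"]])

    emptyDownstream <- function(reason) {
        .writeTsvDf(data.frame(signature = character(), sample = character(),
                               nes = numeric()), files[["nes"]])
        .writeTsvDf(data.frame(signature = character(),
                               log_hazard_ratio = numeric(),
                               p_value = numeric(), q_value = numeric(),
                               estimable = logical(), selected = logical()),
                    files[["cox"]])
        .writeTsvDf(data.frame(sample_id = character(), cluster = integer()),
                    files[["clusters"]])
        .writeTsvDf(data.frame(cluster = integer(), time = numeric(),
                               n_risk = integer(), n_event = integer(),
                               survival = numeric()), files[["km"]])
        .writeTsvDf(data.frame(comparison = character(), statistic = numeric(),
                               df = integer(), p_value = numeric()),
                    files[["logrank"]])
        .writeTsvDf(data.frame(gene = character(), log2fc = numeric(),
                               p_value = numeric(), fdr = numeric(),
                               status = character()), files[["de"]])
        jsonlite::write_json(
            list(config = .configAsList(config), seed = config@seed,
                 n_signatures = length(sigs), note = reason),
            files[["log"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
        invisible(list(model = model, deg = deg, signatures = sigs,
                       nes = NULL, coxScreen = NULL, clusters = NULL,
                       kmCurves = NULL, logrank = NULL, de = NULL,
                       files = files))
    }
    if (length(sigs) == 0L)
        return(emptyDownstream("no signatures retained"))

    nes <- stage("nes", nesMatrix(data$tumors, sigs))
    nesDf <- data.frame(signature = rownames(nes),
                        as.data.frame(nes@.Data, check.names = FALSE),
                        check.names = FALSE)
    .writeTsvDf(nesDf, files[["nes"]])

    cox <- stage("cox_screen", coxScreen(nes, data$clinical, config@coxAlpha))
    .writeTsvDf(cox, files[["cox"]])

    selected <- cox$signature[cox$selected]
    # cluster on the prognostic signatures; fall back to all if none pass
    clusterRows <- if (length(selected)) selected else rownames(nes)
    nClust <- min(config@nClusters, ncol(nes))
    clusters <- stage("cluster",
        wardCluster(NESMatrix(nes@.Data[clusterRows, , drop = FALSE]),
                    nClust))
    labels <- clusterLabels(clusters)
    .writeTsvDf(data.frame(sample_id = names(labels),
                           cluster = unname(labels)), files[["clusters"]])

    clin <- .alignClinical(data$clinical, names(labels))
    kmAll <- do.call(rbind, lapply(sort(unique(labels)), function(cl) {
        sub <- clin[labels[clin$sample_id] == cl, , drop = FALSE]
        if (nrow(sub) == 0L) return(NULL)
        cbind(cluster = cl, kmEstimate(sub))
    }))
    .writeTsvDf(kmAll, files[["km"]])

    lr <- stage("logrank", logrankTest(clin, labels))
    .writeTsvDf(data.frame(comparison = "all_clusters",
                           statistic = lr$statistic, df = lr$df,
                           p_value = lr$p_value), files[["logrank"]])

    # extreme clusters for characterization: rank by observed event fraction
    evFrac <- tapply(clin$event, labels[clin$sample_id], mean)
    worst <- as.integer(names(which.max(evFrac)))
    best <- as.integer(names(which.min(evFrac)))
    de <- NULL
    if (best != worst) {
        gA <- names(labels)[labels == best]
        gB <- names(labels)[labels == worst]
        if (length(gA) >= 3L && length(gB) >= 3L) {
            normTum <- if (exprScale(data$tumors) == "raw_counts")
                upperQuartileNormalize(data$tumors) else data$tumors
            de <- stage("differential_expression",
                differentialExpression(normTum, gA, gB,
                                       config@degLfc, config@degFdr))
        }
    }
    if (is.null(de))
        de <- data.frame(gene = character(), log2fc = numeric(),
                         p_value = numeric(), fdr = numeric(),
                         status = character())
    .writeTsvDf(de, files[["de"]])

    jsonlite::write_json(
        list(config = .configAsList(config), seed = config@seed,
             n_signatures = length(sigs),
             n_selected = sum(cox$selected),
             clusters = as.list(table(labels)),
             de_up = sum(de$status == "up"),
             de_down = sum(de$status == "down")),
        files[["log"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)

    invisible(list(model = model, deg = deg, signatures = sigs, nes = nes,
                   coxScreen = cox, clusters = clusters, kmCurves = kmAll,
                   logrank = lr, de = de, files = files))
}

.configAsList <- function(config) {
    list(binarization_alpha = config@binarizationAlpha,
         support_quantile = config@supportQuantile,
         min_markers = config@minMarkers,
         cox_alpha = config@coxAlpha,
         n_clusters = config@nClusters,
         deg_lfc = config@degLfc,
         deg_fdr = config@degFdr,
         mirna_lfc = config@mirnaLfc,
         seed = config@seed)
}
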