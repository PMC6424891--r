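#' @include AllClasses.R AllGenerics.R
NULL

#' Read and validate a run configuration
#'
#' A run configuration is a single JSON document describing either a
#' simulated run (`scenario`) or a file-based run (`annotation` plus a
#' `samples` manifest), the `comparisons` to perform, the threshold
#' scheme and the analysis policies. It is fully round-trippable into
#' the run log.
#'
#' Fields:
#' * `scenario`: `"default"` or an object with overrides for
#'   [defaultStudyScenario()] (currently `depth`, `n_orfs`,
#'   `rrna_fraction`, `non_unique_fraction`); mutually exclusive with
#'   `annotation`/`samples`.
#' * `annotation`: path to a GFF3 file.
#' * `samples`: array of objects `sample_id`, `condition_id`, `path`,
#'   optional `format` (`"sam"`/`"tsv"`).
#' * `comparisons`: array of objects `baseline`, `other` (condition
#'   ids). For simulated runs it defaults to every other condition
#'   against the first condition.
#' * `thresholds`: object `up`, `down` (see [thresholdScheme()]).
#' * `policies`: object `stranded`, `multi_orf`, `pseudocount`,
#'   `unique_policy`.
#' * `seed`: integer, required for simulated runs.
#'
#' @param config Path to a JSON file, a JSON string, or an equivalent
#'   list.
#' @return A validated named list.
#' @export
readRunConfig <- function(config) {
    if (is.character(config) && length(config) == 1L)
        config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
    if (!is.list(config)) stop("run config must be a JSON object")
    defaults <- list(
        thresholds = list(up = c(2, 10), down = c(0.5, 0.1)),
        policies = list(stranded = FALSE, multi_orf = "count-each",
                        pseudocount = "none",
                        unique_policy = "nh-mapq"))
    for (k in names(defaults))
        config[[k]] <- utils::modifyList(
            defaults[[k]],
            if (is.list(config[[k]])) config[[k]] else list())
    if (is.null(config$seed)) config$seed <- 1L
    config$seed <- as.integer(config$seed[[1]])
    simulated <- !is.null(config$scenario)
    if (!simulated) {
        if (is.null(config$annotation) || is.null(config$samples))
            stop("run config needs either 'scenario' or both 'annotation' and 'samples'")
        smp <- as.data.frame(config$samples)
        need <- c("sample_id", "condition_id", "path")
        if (!all(need %in% colnames(smp)))
            stop("sample manifest needs fields: ",
                 paste(need, collapse = ", "))
        if (anyDuplicated(smp$sample_id))
            stop("duplicate sample_id in manifest")
        config$samples <- smp
        if (is.null(config$comparisons))
            stop("run config needs 'comparisons' for file-based runs")
    }
    if (!is.null(config$comparisons)) {
        cmp <- as.data.frame(config$comparisons)
        if (!all(c("baseline", "other") %in% colnames(cmp)))
            stop("each comparison needs fields 'baseline' and 'other'")
        config$comparisons <- cmp
    }
    config
}

.schemeFromConfig <- function(config) {
    thresholdScheme(up = unlist(config$thresholds$up),
                    down = unlist(config$thresholds$down))
}

.scenarioFromConfig <- function(config) {
    cfg <- defaultStudyScenario(seed = config$seed)
    ov <- config$scenario
    if (is.list(ov)) {
        if (!is.null(ov$depth)) cfg@depth <- as.numeric(ov$depth)
        if (!is.null(ov$rrna_fraction))
            cfg@rrnaFraction <- as.numeric(ov$rrna_fraction)
        if (!is.null(ov$non_unique_fraction))
            cfg@nonUniqueFraction <- as.numeric(ov$non_unique_fraction)
    }
    cfg
}

#' Run the pipeline end to end
#'
#' Orchestrates simulate (or read) -> filter -> count -> normalize ->
#' compare -> report. Produces, under `outDir`: per-sample count tables
#' (`counts_<sample>.tsv`, with abundances and filter statistics), a
#' `filter_stats.json` report, per-comparison result tables
#' (`comparison_<other>_vs_<baseline>.tsv`) and scatter exports
#' (`scatter_<other>_vs_<baseline>.tsv`), a regulon summary for
#' simulated runs (`regulon_summary.tsv`), the annotation and truth of
#' simulated runs, and a machine-readable `run_log.json` recording the
#' package version, the full configuration and every policy. Outputs
#' are byte-identical across reruns with the same configuration and
#' seed.
#'
#' @param config A run configuration (path, JSON string or list); see
#'   [readRunConfig()].
#' @param outDir Output directory (created if needed).
#' @return `outDir`, invisibly.
#' @export
runPipeline <- function(config, outDir) {
    config <- readRunConfig(config)
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    scheme <- .schemeFromConfig(config)
    pol <- config$policies
    simulated <- !is.null(config$scenario)

    written <- character()
    emit <- function(f) written <<- c(written, basename(f))

    if (simulated) {
        simCfg <- .scenarioFromConfig(config)
        g <- tryCatch(buildGenome(simCfg), error = function(e)
            stop("stage simulate (genome): ", conditionMessage(e),
                 call. = FALSE))
        annotation <- g$annotation
        truth <- g$truth
        emit(writeAnnotation(annotation,
                             file.path(outDir, "annotation.gff3")))
        emit(writeTruthTable(truth, file.path(outDir, "truth.tsv")))
        manifest <- do.call(rbind, lapply(
            seq_len(nrow(simCfg@conditions)), function(i)
                data.frame(
                    condition_id =
                        simCfg@conditions$condition_id[i],
                    replicate =
                        seq_len(simCfg@conditions$replicates[i]))))
        manifest$sample_id <- sprintf("%s_rep%d",
                                      manifest$condition_id,
                                      manifest$replicate)
        getAlignments <- function(i)
            simulateAlignments(truth, manifest$condition_id[i],
                               simCfg, annotation,
                               replicate = manifest$replicate[i])
        if (is.null(config$comparisons)) {
            conds <- simCfg@conditions$condition_id
            config$comparisons <- data.frame(baseline = conds[1],
                                             other = conds[-1])
        }
    } else {
        annotation <- tryCatch(readAnnotation(config$annotation),
            error = function(e) stop("stage annotation: ",
                conditionMessage(e), call. = FALSE))
        truth <- NULL
        manifest <- config$samples
        getAlignments <- function(i) {
            if (!file.exists(manifest$path[i]))
                stop("stage read (sample ", manifest$sample_id[i],
                     "): alignment file not found: ", manifest$path[i],
                     call. = FALSE)
            readAlignments(manifest$path[i],
                format = if (is.null(manifest$format))
                    "auto" else manifest$format[i],
                uniquePolicy = pol$unique_policy)
        }
    }

    countTables <- list()
    statsReport <- list()
    for (i in seq_len(nrow(manifest))) {
        sid <- manifest$sample_id[i]
        res <- tryCatch({
            aln <- getAlignments(i)
            flt <- filterAlignments(aln, annotation,
                                    stranded = isTRUE(pol$stranded))
            countReads(flt$alignments, annotation, sampleId = sid,
                       multiOrf = pol$multi_orf,
                       stranded = isTRUE(pol$stranded),
                       filterStats = flt$stats)
        }, error = function(e)
            stop("stage count (sample ", sid, "): ",
                 conditionMessage(e), call. = FALSE))
        countTables[[sid]] <- res
        statsReport[[sid]] <- as.list(filterStats(res))
        emit(writeCountTable(res, annotation,
            file.path(outDir, sprintf("counts_%s.tsv", sid))))
    }
    jsonlite::write_json(statsReport,
                         file.path(outDir, "filter_stats.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    emit(file.path(outDir, "filter_stats.json"))

    groups <- lapply(unique(manifest$condition_id), function(cond)
        SampleGroup(cond,
                    countTables[manifest$sample_id[
                        manifest$condition_id == cond]]))
    names(groups) <- unique(manifest$condition_id)

    cmp <- config$comparisons
    bad <- setdiff(c(cmp$baseline, cmp$other), names(groups))
    if (length(bad))
        stop("stage compare: comparison references unknown condition(s): ",
             paste(unique(bad), collapse = ", "))
    regsum <- list()
    for (i in seq_len(nrow(cmp))) {
        b <- cmp$baseline[i]; o <- cmp$other[i]
        res <- tryCatch(
            compareConditions(groups[[b]], groups[[o]],
                              scheme = scheme,
                              pseudocount = pol$pseudocount),
            error = function(e)
                stop("stage compare (", o, " vs ", b, "): ",
                     conditionMessage(e), call. = FALSE))
        tag <- sprintf("%s_vs_%s", o, b)
        emit(writeComparison(res,
            file.path(outDir, sprintf("comparison_%s.tsv", tag)),
            baselineId = b, otherId = o))
        emit(exportScatter(res, scheme,
            file.path(outDir, sprintf("scatter_%s.tsv", tag))))
        if (!is.null(truth) && length(regulons(truth))) {
            rs <- regulonSummary(res, regulons(truth), scheme = scheme)
            rs <- cbind(comparison = tag, rs)
            regsum[[tag]] <- rs
        }
    }
    if (length(regsum)) {
        allsum <- do.call(rbind, regsum)
        f <- file.path(outDir, "regulon_summary.tsv")
        utils::write.table(allsum, f, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        emit(f)
    }

    log <- list(
        tool = "orfprop",
        version = as.character(utils::packageVersion("orfprop")),
        mode = if (simulated) "simulate" else "files",
        seed = config$seed,
        policies = pol,
        thresholds = list(up = scheme@upLevels,
                          down = scheme@downLevels,
                          boundary_inclusive =
                              scheme@boundaryInclusive),
        comparisons = config$comparisons,
        samples = manifest,
        outputs = sort(unique(written)))
    if (simulated)
        log$scenario <- list(
            n_orfs = simCfg@nOrfs,
            depth = simCfg@depth,
            rrna_fraction = simCfg@rrnaFraction,
            non_unique_fraction = simCfg@nonUniqueFraction)
    jsonlite::write_json(log, file.path(outDir, "run_log.json"),
                         auto_unbox = TRUE, pretty = TRUE,
                         dataframe = "rows", digits = NA)
    invisible(outDir)
}

#' Export a scatter-style table of a comparison
#'
#' Per-gene export of the scatter representation of a comparison:
#' baseline relative abundance (x), comparison relative abundance (y)
#' and change class, with the scheme's threshold lines encoded as
#' `#key=value` metadata comments. Genes with undefined ratios are
#' exported with the `undefined` sentinel class, never dropped.
#'
#' @param results Data frame from [compareConditions()].
#' @param scheme The [ThresholdScheme-class] used.
#' @param path Optional output TSV path.
#' @return The scatter data frame (invisibly `path` when writing).
#' @export
exportScatter <- function(results, scheme = thresholdScheme(),
                          path = NULL) {
    if (nrow(results) == 0L) stop("empty comparison result")
    df <- data.frame(feature_id = results$feature_id,
                     r_baseline = results$r_baseline,
                     r_other = results$r_other,
                     change_class = results$change_class)
    if (is.null(path)) return(df)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(sprintf("#up_thresholds=%s",
                         paste(scheme@upLevels, collapse = ",")),
                 sprintf("#down_thresholds=%s",
                         paste(scheme@downLevels, collapse = ",")),
                 sprintf("#boundary_inclusive=%s",
                         tolower(scheme@boundaryInclusive))), con)
    out <- df
    out$r_baseline <- .fmtNum(df$r_baseline)
    out$r_other <- .fmtNum(df$r_other)
    utils::write.table(out, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Summarize a comparison per regulon
#'
#' For each gene set: member count, median condition ratio (undefined
#' ratios excluded and counted), per-class counts, and a direction
#' verdict: `up` when the median ratio is >= 2, `down` when <= 0.5,
#' `mixed` when at least 25% of members fall in increase classes and at
#' least 25% in decrease classes, otherwise `unchanged`.
#'
#' @param results Data frame from [compareConditions()].
#' @param memberships Named list, regulon name -> member feature_ids.
#' @param scheme The [ThresholdScheme-class] used (for the class
#'   columns).
#' @return A data frame, one row per regulon: `regulon`, `n_members`,
#'   `n_undefined`, `median_ratio`, one `n_<class>` column per change
#'   class, `verdict`.
#' @export
regulonSummary <- function(results, memberships,
                           scheme = thresholdScheme()) {
    unknown <- setdiff(unlist(memberships), results$feature_id)
    if (length(unknown))
        stop("membership names unknown feature(s): ",
             paste(unknown, collapse = ", "))
    classes <- changeClasses(scheme)
    upClasses <- grep("^up_", classes, value = TRUE)
    downClasses <- grep("^down_", classes, value = TRUE)
    rows <- lapply(names(memberships), function(nm) {
        sub <- results[results$feature_id %in% memberships[[nm]], ]
        ratios <- sub$ratio
        med <- stats::median(ratios[!is.na(ratios)])
        classCounts <- vapply(classes, function(cl)
            sum(sub$change_class == cl), integer(1))
        fracUp <- sum(classCounts[upClasses]) / nrow(sub)
        fracDown <- sum(classCounts[downClasses]) / nrow(sub)
        verdict <- if (fracUp >= 0.25 && fracDown >= 0.25) "mixed"
            else if (!is.na(med) && med >= 2) "up"
            else if (!is.na(med) && med <= 0.5) "down"
            else "unchanged"
        out <- data.frame(regulon = nm, n_members = nrow(sub),
                          n_undefined = sum(is.na(ratios)),
                          median_ratio = med,
                          stringsAsFactors = FALSE)
        for (cl in classes)
            out[[paste0("n_", cl)]] <- classCounts[[cl]]
        out$verdict <- verdict
        out
    })
    do.call(rbind, rows)
}
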