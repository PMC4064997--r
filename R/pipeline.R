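.default_config <- function() {
    list(outcomes = NULL, labels = NULL, matrix = NULL, out_dir = ".",
         min_actives = 6, ccr_cutoff = 0.6, top_fraction = 0.5,
         compound_min_actives = 3, coverage_fraction = 0.5,
         s_threshold = 0, seed = 1, drop_marginal = TRUE,
         stats_scope = "panel", min_l = NULL)
}

#' Read a pipeline run configuration
#'
#' Loads a flat YAML file of [runPipeline()] parameters and merges it over
#' the defaults (which reproduce the standard settings: min_actives 6,
#' ccr_cutoff 0.6, top_fraction 0.5, compound_min_actives 3,
#' coverage_fraction 0.5, s_threshold 0, seed 1).
#'
#' @param path YAML file; keys as in [runPipeline()]'s `config`.
#' @return a complete config list.
#' @export
readRunConfig <- function(path) {
    if (!file.exists(path))
        stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    cfg <- .default_config()
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
        stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    cfg[names(user)] <- user
    cfg
}

.write_tsv <- function(df, path, params) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# ToxProfiler %s", .pkg_version()), con)
    writeLines(sprintf("# %s: %s", names(params),
                       vapply(params, function(p) paste(format(p), collapse = ","),
                              character(1))), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

.pkg_version <- function() {
    as.character(utils::packageVersion("ToxProfiler"))
}

.stage <- function(name) message("[toxprofiler] stage: ", name)

#' Run the profiling pipeline end to end
#'
#' Chains the stages: read outcomes and labels (or a prebuilt matrix),
#' drop marginal compounds, remove low-information assays, score assay
#' relevance and select the panel, then score and rank compounds. Writes
#' `matrix.tsv`, `relevance.tsv`, `scores.tsv`, `profiles.tsv` and a
#' `manifest.json` recording parameters, package version, seed and input
#' checksums. Reruns with identical inputs and config produce
#' byte-identical outputs.
#'
#' @param config list (or path handled by [readRunConfig()]) with entries:
#'   `outcomes` and `labels` file paths (or `matrix` for a prebuilt wide
#'   TSV plus `labels`), `out_dir`, and the stage parameters
#'   `min_actives`, `ccr_cutoff`, `top_fraction`, `compound_min_actives`,
#'   `coverage_fraction`, `s_threshold`, `seed`, `drop_marginal`,
#'   `stats_scope`, `min_l`.
#' @return invisibly, a list with the in-memory stage results (`matrix`,
#'   `selection`, `scores`, `manifest`).
#' @export
runPipeline <- function(config) {
    if (is.character(config))
        config <- readRunConfig(config)
    cfg <- .default_config()
    cfg[names(config)] <- config
    if (is.null(cfg$labels))
        stop("config must name a labels file")
    inputs <- c(outcomes = cfg$outcomes, labels = cfg$labels,
                matrix = cfg$matrix)
    for (f in inputs)
        if (!file.exists(f))
            stop("input file not found: ", f)

    .stage("load")
    labels <- readLabels(cfg$labels)
    m <- if (!is.null(cfg$matrix)) {
        readMatrix(cfg$matrix)
    } else {
        if (is.null(cfg$outcomes))
            stop("config must name an outcomes file or a matrix file")
        buildMatrix(readOutcomes(cfg$outcomes))
    }
    if (isTRUE(cfg$drop_marginal))
        labels <- dropMarginal(labels)

    .stage("filter-assays")
    flt <- filterLowInfoAssays(m, cfg$min_actives)
    m <- flt$matrix

    .stage("rank-assays")
    rel <- assayRelevance(m, labels)
    selec <- rankAndSelect(rel, cfg$ccr_cutoff, cfg$top_fraction, cfg$min_l)
    panel <- panelAssays(selec)

    .stage("score-compounds")
    scores <- if (length(panel)) {
        prioritizeCompounds(m, panel, labels,
                            min_actives = cfg$compound_min_actives,
                            coverage_fraction = cfg$coverage_fraction,
                            threshold = cfg$s_threshold,
                            scope = cfg$stats_scope)
    } else {
        warning("empty panel; no compounds scored")
        data.frame()
    }

    .stage("write")
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    params <- cfg[c("min_actives", "ccr_cutoff", "top_fraction",
                    "compound_min_actives", "coverage_fraction",
                    "s_threshold", "seed")]
    writeMatrix(m, file.path(cfg$out_dir, "matrix.tsv"))
    .write_tsv(relevanceTable(selec), file.path(cfg$out_dir, "relevance.tsv"),
               params)
    .write_tsv(scores, file.path(cfg$out_dir, "scores.tsv"), params)
    if (nrow(scores)) {
        prof <- attr(scores, "profiles")
        .write_tsv(data.frame(compound_id = rownames(prof), prof,
                              check.names = FALSE),
                   file.path(cfg$out_dir, "profiles.tsv"), params)
    }
    manifest <- list(package = "ToxProfiler", version = .pkg_version(),
                     parameters = params,
                     removed_assays = length(flt$removed),
                     panel = panel,
                     inputs = as.list(tools::md5sum(inputs)))
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(list(matrix = m, selection = selec, scores = scores,
                   manifest = manifest))
}
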