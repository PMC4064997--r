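#' Parameters for the planted-signal screening simulator
#'
#' Describes a synthetic sparse screening campaign: a compound set with a
#' binary acute-toxicity endpoint, a bioassay set of which a known subset
#' is genuinely correlated with the endpoint, per-cell missingness and an
#' inconclusive share. The defaults describe the standard validation
#' condition used throughout the package: 1,000 compounds x 100 assays,
#' 10 planted relevant assays with sensitivity 0.9 and false-positive rate
#' 0.02, background active rate 0.05, half of the cells tested, 40% toxic
#' compounds.
#'
#' @param n_compounds,n_assays matrix dimensions.
#' @param toxic_fraction probability a compound is toxic, in (0, 1).
#' @param n_relevant_assays number of planted toxicity-correlated assays.
#' @param relevant_sensitivity P(active | toxic, conclusive) in a relevant
#'   assay.
#' @param relevant_fp_rate P(active | nontoxic, conclusive) in a relevant
#'   assay.
#' @param irrelevant_active_rate P(active | conclusive) in a background
#'   assay, independent of the label.
#' @param tested_fraction per-cell probability of being tested, in (0, 1].
#' @param inconclusive_fraction probability a tested cell is inconclusive,
#'   in \[0, 1).
#' @param seed integer seed making the draw reproducible.
#' @return validated list of class `SyntheticSpec`.
#' @examples
#' spec <- syntheticSpec(n_compounds = 50, n_assays = 10, seed = 7)
#' @export
syntheticSpec <- function(n_compounds = 1000, n_assays = 100,
                          toxic_fraction = 0.4, n_relevant_assays = 10,
                          relevant_sensitivity = 0.9,
                          relevant_fp_rate = 0.02,
                          irrelevant_active_rate = 0.05,
                          tested_fraction = 0.5,
                          inconclusive_fraction = 0.05,
                          seed = 1) {
    stopifnot(n_compounds >= 1, n_assays >= 1,
              n_relevant_assays >= 0, n_relevant_assays <= n_assays,
              toxic_fraction > 0, toxic_fraction < 1,
              relevant_sensitivity >= 0, relevant_sensitivity <= 1,
              relevant_fp_rate >= 0, relevant_fp_rate <= 1,
              irrelevant_active_rate >= 0, irrelevant_active_rate <= 1,
              tested_fraction > 0, tested_fraction <= 1,
              inconclusive_fraction >= 0, inconclusive_fraction < 1)
    if (n_relevant_assays > 0 && relevant_sensitivity <= relevant_fp_rate)
        warning("relevant_sensitivity <= relevant_fp_rate: ",
                "no planted signal to recover")
    structure(list(n_compounds = n_compounds, n_assays = n_assays,
                   toxic_fraction = toxic_fraction,
                   n_relevant_assays = n_relevant_assays,
                   relevant_sensitivity = relevant_sensitivity,
                   relevant_fp_rate = relevant_fp_rate,
                   irrelevant_active_rate = irrelevant_active_rate,
                   tested_fraction = tested_fraction,
                   inconclusive_fraction = inconclusive_fraction,
                   seed = as.integer(seed)),
              class = "SyntheticSpec")
}

# run expr with a private, seeded RNG stream, restoring the caller's state
.with_seed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has)
        old <- get(".Random.seed", envir = globalenv())
    on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(seed)
    expr
}

#' Simulate a sparse screening matrix with planted toxicity signal
#'
#' Draws labels and a \{1, -1, 0\} response matrix under the cell-level
#' independence model of [syntheticSpec()]: each cell is untested with
#' probability `1 - tested_fraction`, inconclusive (given tested) with
#' probability `inconclusive_fraction` (both encoded 0), and otherwise
#' active with the rate of its assay class — `relevant_sensitivity` /
#' `relevant_fp_rate` for planted assays depending on the compound's
#' label, `irrelevant_active_rate` for background assays. Toxic compounds
#' additionally receive a -log10 LD50 drawn above 3, nontoxic below 2, so
#' the labels exercise the potency-based classification path.
#'
#' @param spec a [syntheticSpec()] object.
#' @return list with elements `matrix` (a [ResponseMatrix-class]) and
#'   `truth` (list: `labels` a [ToxicityLabels-class],
#'   `relevant_assays` the planted assay ids, `n_inconclusive` the number
#'   of tested-but-inconclusive cells).
#' @examples
#' sim <- simulateScreen(syntheticSpec(n_compounds = 20, n_assays = 5,
#'                                     seed = 42))
#' dim(sim$matrix)
#' @export
simulateScreen <- function(spec) {
    stopifnot(inherits(spec, "SyntheticSpec"))
    .with_seed(spec$seed, {
        n <- spec$n_compounds
        p <- spec$n_assays
        cid <- sprintf("C%05d", seq_len(n))
        aid <- sprintf("A%04d", seq_len(p))
        relevant <- sort(sample(aid, spec$n_relevant_assays))
        toxic <- stats::runif(n) < spec$toxic_fraction
        ld50 <- ifelse(toxic, stats::runif(n, 3.05, 6.00),
                       stats::runif(n, 0.10, 1.95))
        labels <- ToxicityLabels(cid, neg_log_ld50 = ld50)
        rate <- matrix(spec$irrelevant_active_rate, n, p)
        rel_col <- aid %in% relevant
        rate[toxic, rel_col] <- spec$relevant_sensitivity
        rate[!toxic, rel_col] <- spec$relevant_fp_rate
        tested <- matrix(stats::runif(n * p) < spec$tested_fraction, n, p)
        conclusive <- tested &
            (matrix(stats::runif(n * p), n, p) >= spec$inconclusive_fraction)
        active <- matrix(stats::runif(n * p), n, p) < rate
        vals <- matrix(0, n, p, dimnames = list(cid, aid))
        vals[conclusive & active] <- 1
        vals[conclusive & !active] <- -1
        list(matrix = ResponseMatrix(vals),
             truth = list(labels = labels,
                          relevant_assays = relevant,
                          n_inconclusive = sum(tested & !conclusive)))
    })
}

#' Planted-signal recovery experiment
#'
#' Runs the full selection-and-scoring workflow on `n_reps` independent
#' draws from `spec` (replicate r uses seed `spec$seed + r - 1`):
#' simulate, drop low-information assays, score assay relevance, select
#' the panel, and compute compound S scores. Per replicate it reports the
#' share of panel slots occupied by planted relevant assays
#' (`panel_precision`; its chance level under no signal is
#' `n_relevant_assays / n_assays`), the share of planted assays recovered
#' (`panel_recall`), the panel size, and the mean S score of toxic and of
#' nontoxic compounds.
#'
#' When panel selection and S scoring use the same draw, chance candidates
#' are selected precisely because their actives lined up with the toxic
#' labels, which inflates the apparent class separation (a selection
#' bias). `holdout = TRUE` therefore scores S on an independent draw from
#' the same spec, giving an unbiased view of the separation — under a
#' no-signal spec its expectation is exactly zero.
#'
#' @param spec a [syntheticSpec()] object.
#' @param n_reps number of replicates (>= 1).
#' @param ccr_cutoff,top_fraction passed to [rankAndSelect()].
#' @param min_actives passed to [filterLowInfoAssays()].
#' @param holdout score S on an independent validation draw instead of the
#'   draw the panel was selected on.
#' @return list with `per_rep` (one data.frame row per replicate,
#'   including the standardized class separation `cohens_d`) and
#'   `summary` (mean and sd of each metric, empty panels excluded from
#'   the precision average).
#' @export
recoveryExperiment <- function(spec, n_reps = 20, ccr_cutoff = 0.6,
                               top_fraction = 0.5, min_actives = 6,
                               holdout = FALSE) {
    stopifnot(inherits(spec, "SyntheticSpec"), n_reps >= 1)
    rows <- lapply(seq_len(n_reps), function(r) {
        rspec <- spec
        rspec$seed <- spec$seed + r - 1L
        sim <- simulateScreen(rspec)
        flt <- filterLowInfoAssays(sim$matrix, min_actives)
        rel <- assayRelevance(flt$matrix, sim$truth$labels)
        selec <- withCallingHandlers(
            rankAndSelect(rel, ccr_cutoff, top_fraction),
            warning = function(w) invokeRestart("muffleWarning"))
        panel <- panelAssays(selec)
        hit <- sum(panel %in% sim$truth$relevant_assays)
        if (holdout) {
            vspec <- spec
            vspec$seed <- spec$seed + 100000L + r - 1L
            eval_sim <- simulateScreen(vspec)
        } else {
            eval_sim <- sim
        }
        eval_m <- if (holdout) eval_sim$matrix else flt$matrix
        s <- if (length(panel)) sScore(eval_m, panel) else
            stats::setNames(numeric(length(compoundIds(eval_m))),
                            compoundIds(eval_m))
        cls <- toxClass(eval_sim$truth$labels)[names(s)]
        st <- s[cls == "toxic"]
        sn <- s[cls == "nontoxic"]
        pooled <- sqrt((stats::var(st) * (length(st) - 1) +
                        stats::var(sn) * (length(sn) - 1)) /
                       max(1, length(st) + length(sn) - 2))
        data.frame(rep = r, seed = rspec$seed,
                   panel_size = length(panel),
                   panel_precision = if (length(panel)) hit / length(panel)
                                     else NA_real_,
                   panel_recall = if (spec$n_relevant_assays > 0)
                       hit / spec$n_relevant_assays else NA_real_,
                   mean_s_toxic = mean(st),
                   mean_s_nontoxic = mean(sn),
                   cohens_d = if (pooled > 0)
                       (mean(st) - mean(sn)) / pooled else 0)
    })
    per_rep <- do.call(rbind, rows)
    per_rep$s_separation <- per_rep$mean_s_toxic - per_rep$mean_s_nontoxic
    metrics <- c("panel_size", "panel_precision", "panel_recall",
                 "mean_s_toxic", "mean_s_nontoxic", "s_separation",
                 "cohens_d")
    summary <- data.frame(
        metric = metrics,
        mean = vapply(metrics, function(k) mean(per_rep[[k]], na.rm = TRUE),
                      numeric(1)),
        sd = vapply(metrics, function(k) stats::sd(per_rep[[k]], na.rm = TRUE),
                    numeric(1)),
        row.names = NULL)
    list(per_rep = per_rep, summary = summary, spec = spec,
         params = list(n_reps = n_reps, ccr_cutoff = ccr_cutoff,
                       top_fraction = top_fraction,
                       min_actives = min_actives))
}
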