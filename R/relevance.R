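.as_counts <- function(counts) {
    stopifnot(all(c("tp", "fp", "tn", "fn") %in% names(counts)))
    counts
}

#' Confusion counts between an assay column and the toxicity endpoint
#'
#' Cross-tabulates one assay's responses against the binary animal-toxicity
#' endpoint. A compound contributes only when it has a conclusive response
#' in the assay (entry 1 or -1) and a non-marginal label: TP = active and
#' toxic, FP = active and nontoxic, TN = inactive and nontoxic, FN =
#' inactive and toxic. Compounds with entry 0, a marginal label or no label
#' at all are excluded.
#'
#' @param assay_column named numeric vector over compounds with values in
#'   \{1, -1, 0\} (one column of a [ResponseMatrix-class]).
#' @param labels a [ToxicityLabels-class].
#' @return named numeric vector with elements `tp`, `fp`, `tn`, `fn`.
#' @examples
#' lab <- ToxicityLabels(c("c1", "c2"), tox_class = c("toxic", "nontoxic"))
#' confusionCounts(c(c1 = 1, c2 = -1), lab)
#' @export
confusionCounts <- function(assay_column, labels) {
    stopifnot(!is.null(names(assay_column)), is(labels, "ToxicityLabels"))
    cls <- toxClass(labels)[names(assay_column)]
    keep <- assay_column != 0 & !is.na(cls) & cls != "marginal"
    a <- assay_column[keep]
    toxic <- cls[keep] == "toxic"
    c(tp = sum(a == 1 & toxic), fp = sum(a == 1 & !toxic),
      tn = sum(a == -1 & !toxic), fn = sum(a == -1 & toxic))
}

#' Correct classification rate (balanced accuracy) of an assay
#'
#' Treats the assay as a binary predictor of the animal endpoint:
#' sensitivity = TP / (TP + FN), specificity = TN / (TN + FP), and
#' CCR = (sensitivity + specificity) / 2. If the assay saw no conclusive
#' toxic compounds or no conclusive nontoxic compounds the rate is
#' undefined and `NA` is returned (the assay is unscorable).
#'
#' @param counts named vector or one-row data.frame with `tp`, `fp`, `tn`,
#'   `fn`.
#' @return CCR in \[0, 1\], or `NA`.
#' @examples
#' ccr(c(tp = 8, fp = 4, tn = 6, fn = 2))
#' @export
ccr <- function(counts) {
    counts <- .as_counts(counts)
    tp <- counts[["tp"]]; fp <- counts[["fp"]]
    tn <- counts[["tn"]]; fn <- counts[["fn"]]
    if (tp + fn == 0 || tn + fp == 0)
        return(NA_real_)
    (tp / (tp + fn) + tn / (tn + fp)) / 2
}

#' L relevance score of an assay
#'
#' A likelihood-of-correlation score designed around the systemic-toxicity
#' view of screening data: an active response in a relevant assay is strong
#' evidence of toxicity, while an inactive response says little. The score
#' therefore up-weights the true positive rate and penalizes false
#' positives sharply:
#' \deqn{L = \mathrm{TPR} \times \frac{TP}{FP + 1},\qquad
#'       \mathrm{TPR} = \frac{TP}{TP + FN}.}
#' With other counts fixed, L strictly decreases as FP grows; assays with
#' many confirmed actives among toxic compounds and few false alarms score
#' highest. Undefined (`NA`) when the assay saw no conclusive toxic
#' compounds (TP + FN = 0).
#'
#' @inheritParams ccr
#' @return non-negative real, or `NA`.
#' @examples
#' lScore(c(tp = 30, fp = 2, tn = 200, fn = 4))
#' @export
lScore <- function(counts) {
    counts <- .as_counts(counts)
    tp <- counts[["tp"]]; fp <- counts[["fp"]]; fn <- counts[["fn"]]
    if (tp + fn == 0)
        return(NA_real_)
    (tp / (tp + fn)) * tp / (fp + 1)
}

#' Pearson chi-square association between assay and endpoint
#'
#' Pearson's chi-square statistic on the 2x2 table (TP, FN / FP, TN),
#' without continuity correction by default (the correction can be turned
#' on with `correct = TRUE`). Undefined (`NA`) when any row or column
#' margin is zero.
#'
#' @inheritParams ccr
#' @param correct apply the Yates continuity correction.
#' @return non-negative statistic, or `NA`.
#' @examples
#' chi2Association(c(tp = 10, fn = 5, fp = 20, tn = 40))
#' @export
chi2Association <- function(counts, correct = FALSE) {
    counts <- .as_counts(counts)
    tab <- matrix(c(counts[["tp"]], counts[["fn"]],
                    counts[["fp"]], counts[["tn"]]), 2, 2, byrow = TRUE)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
        return(NA_real_)
    unname(suppressWarnings(
        stats::chisq.test(tab, correct = correct)$statistic))
}

#' Score every assay's relevance to the animal endpoint
#'
#' Computes, for each assay column of the response matrix, the confusion
#' counts against the toxicity labels plus sensitivity, specificity, CCR,
#' the L score and the chi-square association.
#'
#' @param m a [ResponseMatrix-class].
#' @param labels a [ToxicityLabels-class]; marginal compounds are ignored.
#' @param correct passed to [chi2Association()].
#' @return data.frame with one row per assay: `assay_id`, `tp`, `fp`, `tn`,
#'   `fn`, `sensitivity`, `specificity`, `ccr`, `l_score`, `chi2`.
#' @export
assayRelevance <- function(m, labels, correct = FALSE) {
    stopifnot(is(m, "ResponseMatrix"), is(labels, "ToxicityLabels"))
    cls <- toxClass(labels)
    ids <- intersect(compoundIds(m), names(cls)[cls != "marginal"])
    sub <- m@responses[match(ids, compoundIds(m)), , drop = FALSE]
    toxic <- cls[ids] == "toxic"
    act <- sub == 1
    ina <- sub == -1
    tp <- Matrix::colSums(act[toxic, , drop = FALSE])
    fp <- Matrix::colSums(act[!toxic, , drop = FALSE])
    fn <- Matrix::colSums(ina[toxic, , drop = FALSE])
    tn <- Matrix::colSums(ina[!toxic, , drop = FALSE])
    sens <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
    spec <- ifelse(tn + fp > 0, tn / (tn + fp), NA_real_)
    res <- data.frame(assay_id = assayIds(m),
                      tp = as.integer(tp), fp = as.integer(fp),
                      tn = as.integer(tn), fn = as.integer(fn),
                      sensitivity = sens, specificity = spec,
                      ccr = (sens + spec) / 2,
                      l_score = ifelse(tp + fn > 0, sens * tp / (fp + 1),
                                       NA_real_),
                      stringsAsFactors = FALSE)
    res$chi2 <- vapply(seq_len(nrow(res)), function(k)
        chi2Association(res[k, ], correct = correct), numeric(1))
    rownames(res) <- NULL
    res
}

#' Two-stage assay panel selection
#'
#' Stage one pre-selects candidate assays whose CCR strictly exceeds
#' `ccr_cutoff` (unscorable assays are excluded). Stage two ranks the
#' candidates by L score (descending, ties broken by assay id ascending)
#' and keeps the top `floor(top_fraction * n_candidates)` as the panel.
#' An optional `min_l` additionally requires panel assays to reach that L
#' score.
#'
#' @param relevance per-assay table from [assayRelevance()].
#' @param ccr_cutoff CCR pre-selection cutoff (strict inequality).
#' @param top_fraction fraction of ranked candidates kept, in (0, 1\].
#' @param min_l optional lower bound on the panel's L scores.
#' @return an [AssaySelection-class] object.
#' @examples
#' rel <- data.frame(assay_id = c("a1", "a2"), tp = c(9, 2), fp = c(1, 8),
#'                   tn = c(9, 2), fn = c(1, 8))
#' rel$sensitivity <- rel$tp / (rel$tp + rel$fn)
#' rel$specificity <- rel$tn / (rel$tn + rel$fp)
#' rel$ccr <- (rel$sensitivity + rel$specificity) / 2
#' rel$l_score <- rel$sensitivity * rel$tp / (rel$fp + 1)
#' rel$chi2 <- NA_real_
#' panelAssays(rankAndSelect(rel, top_fraction = 1))
#' @export
rankAndSelect <- function(relevance, ccr_cutoff = 0.6, top_fraction = 0.5,
                          min_l = NULL) {
    stopifnot(is.data.frame(relevance), top_fraction > 0, top_fraction <= 1)
    cand <- !is.na(relevance$ccr) & !is.na(relevance$l_score) &
        relevance$ccr > ccr_cutoff
    relevance$candidate_flag <- cand
    relevance$rank <- NA_integer_
    relevance$panel_flag <- FALSE
    idx <- which(cand)
    ord <- idx[order(-relevance$l_score[idx], relevance$assay_id[idx])]
    relevance$rank[ord] <- seq_along(ord)
    n_panel <- floor(top_fraction * length(ord))
    panel <- ord[seq_len(n_panel)]
    if (!is.null(min_l))
        panel <- panel[relevance$l_score[panel] >= min_l]
    relevance$panel_flag[panel] <- TRUE
    fixed <- c("candidate_flag", "panel_flag", "rank")
    relevance <- relevance[c(setdiff(names(relevance), fixed), fixed)]
    if (!length(idx))
        warning("no assay passed the CCR cutoff; panel is empty")
    methods::new("AssaySelection",
        relevance = relevance,
        candidateAssays = relevance$assay_id[ord],
        panelAssays = relevance$assay_id[panel],
        ccrCutoff = ccr_cutoff,
        topFraction = top_fraction,
        minL = if (is.null(min_l)) NA_real_ else min_l,
        minLInPanel = if (length(panel))
            min(relevance$l_score[panel]) else NA_real_)
}

#' @rdname AssaySelection-class
#' @param x,object an `AssaySelection`
#' @export
setMethod("candidateAssays", "AssaySelection", function(x) x@candidateAssays)

#' @rdname AssaySelection-class
#' @export
setMethod("panelAssays", "AssaySelection", function(x) x@panelAssays)

#' @rdname AssaySelection-class
#' @export
setMethod("relevanceTable", "AssaySelection", function(x) x@relevance)

setMethod("show", "AssaySelection", function(object) {
    cat(sprintf("AssaySelection: %d/%d assays pass CCR > %g; panel of %d (top %g%% by L)\n",
                length(object@candidateAssays), nrow(object@relevance),
                object@ccrCutoff, length(object@panelAssays),
                100 * object@topFraction))
    if (length(object@panelAssays))
        cat(sprintf("  smallest L in panel: %.3f\n", object@minLInPanel))
    invisible(object)
})
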