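#' Active/inactive bookkeeping for a selected assay panel
#'
#' Counts, on the submatrix restricted to the panel columns (or, with
#' `scope = "full"`, with totals and per-compound counts taken over the
#' whole matrix), the quantities that normalize the per-cell response
#' contribution R: total actives A_t and inactives I_t, per-assay counts
#' A_i / I_i, and per-compound counts A_j / I_j.
#'
#' @param m a [ResponseMatrix-class].
#' @param panel character vector of assay ids; must all be present in `m`.
#' @param scope `"panel"` (default) computes every count on the panel
#'   submatrix, keeping the S score self-contained; `"full"` takes A_t/I_t
#'   and A_j/I_j over all assays of `m`.
#' @return list with elements `a_t`, `i_t`, `a_i`, `i_i`, `a_j`, `i_j`
#'   (the last four named by assay / compound id) and `panel`.
#' @examples
#' m <- ResponseMatrix(matrix(c(1, 0, -1, 1), 2, 2,
#'     dimnames = list(c("c1", "c2"), c("a1", "a2"))))
#' panelStats(m, c("a1", "a2"))$a_t
#' @export
panelStats <- function(m, panel, scope = c("panel", "full")) {
    stopifnot(is(m, "ResponseMatrix"))
    scope <- match.arg(scope)
    miss <- setdiff(panel, assayIds(m))
    if (length(miss))
        stop("panel assay(s) absent from matrix: ",
             paste(miss, collapse = ", "))
    sub <- m@responses[, match(panel, assayIds(m)), drop = FALSE]
    ref <- if (scope == "panel") sub else m@responses
    act <- sub == 1
    ina <- sub == -1
    list(a_t = sum(ref == 1), i_t = sum(ref == -1),
         a_i = Matrix::colSums(act), i_i = Matrix::colSums(ina),
         a_j = Matrix::rowSums(ref == 1), i_j = Matrix::rowSums(ref == -1),
         panel = panel, scope = scope)
}

#' Normalized response contribution R for one cell
#'
#' The contribution of compound j's response in panel assay i to the
#' compound's consensus S score. An active response contributes the
#' observed-over-expected co-occurrence weight
#' \deqn{R = \frac{A_i A_j}{A_t}}
#' (the product of the assay's and the compound's active counts, normalized
#' by the total number of actives), an inactive response contributes
#' \deqn{R = -\frac{I_i I_j}{I_t}}
#' with the corresponding inactive counts, and an untested or inconclusive
#' cell contributes exactly 0. Broadly active compounds in broadly active
#' assays therefore accumulate per-assay contributions near 1 and an S
#' score approaching the panel size.
#'
#' @param entry cell value in \{1, -1, 0\}.
#' @param stats a [panelStats()] result.
#' @param assay,compound ids locating the cell.
#' @return the scalar R value.
#' @export
responseValue <- function(entry, stats, assay, compound) {
    stopifnot(entry %in% c(1, -1, 0))
    if (entry == 0)
        return(0)
    if (entry == 1) {
        stopifnot(stats$a_t > 0)
        stats$a_i[[assay]] * stats$a_j[[compound]] / stats$a_t
    } else {
        stopifnot(stats$i_t > 0)
        -stats$i_i[[assay]] * stats$i_j[[compound]] / stats$i_t
    }
}

#' Matrix of R contributions over a panel
#'
#' Vectorized form of [responseValue()]: returns the dense
#' compounds-by-panel matrix of normalized response contributions.
#'
#' @inheritParams panelStats
#' @param stats optional precomputed [panelStats()]; defaults to
#'   panel-scope stats of `m`.
#' @return numeric matrix, rows = compounds of `m`, columns = `panel`.
#' @export
responseValues <- function(m, panel, stats = NULL) {
    if (is.null(stats))
        stats <- panelStats(m, panel)
    sub <- as.matrix(m@responses[, match(panel, assayIds(m)), drop = FALSE])
    pos <- if (stats$a_t > 0)
        (sub == 1) * outer(stats$a_j[compoundIds(m)], stats$a_i[panel]) / stats$a_t
    else 0
    neg <- if (stats$i_t > 0)
        (sub == -1) * outer(stats$i_j[compoundIds(m)], stats$i_i[panel]) / stats$i_t
    else 0
    r <- pos - neg
    if (!is.matrix(r))
        r <- matrix(0, nrow(sub), ncol(sub))
    dimnames(r) <- list(compoundIds(m), panel)
    r
}

#' Consensus S score of compounds over an assay panel
#'
#' The S score of compound j is the sum over the panel assays of its
#' normalized response contributions R ([responseValue()]). Compounds that
#' are broadly active across the panel accumulate large positive scores;
#' broadly inactive compounds go negative; compounds untested in every
#' panel assay score exactly 0.
#'
#' @inheritParams responseValues
#' @return named numeric vector of S scores over the compounds of `m`.
#' @examples
#' m <- ResponseMatrix(matrix(c(1, 0, -1, 1), 2, 2,
#'     dimnames = list(c("c1", "c2"), c("a1", "a2"))))
#' sScore(m, c("a1", "a2"))
#' @export
sScore <- function(m, panel, stats = NULL) {
    rowSums(responseValues(m, panel, stats))
}

#' Minimum reported responses satisfying the coverage clause
#'
#' The eligibility coverage clause requires a reported (active or inactive)
#' response in more than `coverage_fraction` of the panel assays; the
#' threshold is the smallest integer strictly greater than the half-up
#' rounding of `coverage_fraction * panel_size`, which reproduces 25 for a
#' 47-assay panel.
#'
#' @param panel_size number of assays in the panel.
#' @param coverage_fraction required fraction of the panel, default 0.5.
#' @return integer threshold.
#' @examples
#' coverageThreshold(47)
#' @export
coverageThreshold <- function(panel_size, coverage_fraction = 0.5) {
    as.integer(floor(coverage_fraction * panel_size + 0.5)) + 1L
}

#' Eligibility of a compound for S-score classification
#'
#' A compound is classified only when its panel profile carries enough
#' signal: either at least `min_actives` active responses in the panel, or
#' a reported response (active or inactive) in more than
#' `coverage_fraction` of the panel assays ([coverageThreshold()]).
#'
#' @param n_active,n_reported number of active and of reported (active +
#'   inactive) panel responses for the compound.
#' @param panel_size number of assays in the panel.
#' @param min_actives active-response clause threshold, default 3.
#' @param coverage_fraction coverage clause fraction, default 0.5.
#' @param use_coverage whether the coverage clause applies (it is dropped
#'   for unlabeled new-compound screening).
#' @return logical.
#' @examples
#' eligibility(n_active = 0, n_reported = 25, panel_size = 47)
#' @export
eligibility <- function(n_active, n_reported, panel_size, min_actives = 3,
                        coverage_fraction = 0.5, use_coverage = TRUE) {
    stopifnot(panel_size >= 1)
    n_active >= min_actives |
        (use_coverage & n_reported >= coverageThreshold(panel_size,
                                                        coverage_fraction))
}

#' Classify a compound from its S score
#'
#' Compounds with an S score strictly above the threshold (default 0) are
#' flagged as potential toxicants; a score exactly at the threshold is not.
#'
#' @param s numeric S score(s).
#' @param threshold classification boundary, default 0.
#' @return logical vector.
#' @export
classifyCompound <- function(s, threshold = 0) {
    s > threshold
}

#' Rank compounds by toxicity potential over an assay panel
#'
#' Computes S scores over the panel, applies the eligibility criteria, and
#' returns the eligible compounds ranked by decreasing S (ties broken by
#' compound id). When labels are supplied the known class is carried along
#' and the coverage eligibility clause is applied to labeled compounds;
#' unlabeled compounds are screened with the active-response clause only.
#'
#' @inheritParams panelStats
#' @param labels optional [ToxicityLabels-class].
#' @param min_actives,coverage_fraction eligibility parameters
#'   ([eligibility()]).
#' @param threshold S classification boundary ([classifyCompound()]).
#' @return data.frame of eligible compounds, columns `compound_id`,
#'   `s_score`, `n_active`, `n_inactive`, `n_reported`, `eligible`,
#'   `predicted_toxic`, `label`; the \{1, -1, 0\} panel profiles of the
#'   returned compounds are attached as `attr(, "profiles")`.
#' @export
prioritizeCompounds <- function(m, panel, labels = NULL, min_actives = 3,
                                coverage_fraction = 0.5, threshold = 0,
                                scope = c("panel", "full")) {
    stopifnot(length(panel) >= 1)
    scope <- match.arg(scope)
    stats <- panelStats(m, panel, scope = scope)
    sub <- m@responses[, match(panel, assayIds(m)), drop = FALSE]
    n_active <- as.integer(Matrix::rowSums(sub == 1))
    n_inactive <- as.integer(Matrix::rowSums(sub == -1))
    s <- sScore(m, panel, stats)
    lab <- rep(NA_character_, nrow(sub))
    if (!is.null(labels)) {
        cls <- toxClass(labels)
        lab <- as.character(cls[compoundIds(m)])
    }
    elig <- eligibility(n_active, n_active + n_inactive, length(panel),
                        min_actives, coverage_fraction,
                        use_coverage = !is.na(lab))
    res <- data.frame(compound_id = compoundIds(m),
                      s_score = unname(s),
                      n_active = n_active,
                      n_inactive = n_inactive,
                      n_reported = n_active + n_inactive,
                      eligible = elig,
                      predicted_toxic = classifyCompound(unname(s), threshold),
                      label = lab,
                      stringsAsFactors = FALSE)
    res <- res[res$eligible, , drop = FALSE]
    if (!nrow(res))
        warning("no compound satisfies the eligibility criteria")
    res <- res[order(-res$s_score, res$compound_id), , drop = FALSE]
    rownames(res) <- NULL
    profiles <- as.matrix(sub[match(res$compound_id, compoundIds(m)), ,
                              drop = FALSE])
    attr(res, "profiles") <- profiles
    res
}
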