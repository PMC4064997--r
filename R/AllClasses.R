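#' @import methods
#' @importClassesFrom Matrix dgCMatrix
NULL

.TOX_LEVELS <- c("nontoxic", "marginal", "toxic")
.OUTCOME_LEVELS <- c("ACTIVE", "INACTIVE", "INCONCLUSIVE", "UNTESTED")

#' ResponseMatrix: sparse compound-by-bioassay response profiles
#'
#' Stores screening outcomes for a set of compounds (rows) against a set of
#' bioassays (columns) as a sparse matrix with entries in \{1, -1, 0\}:
#' 1 = active, -1 = inactive, 0 = untested or inconclusive (the implicit
#' sparse default). Row and column names are the opaque compound and assay
#' identifiers (e.g. PubChem CIDs and AIDs rendered as text).
#'
#' @slot responses a \linkS4class{dgCMatrix} with values in \{1, -1\}
#'   (zeros are not stored) and unique, non-empty dimnames.
#'
#' @seealso [buildMatrix()], [filterLowInfoAssays()], [readMatrix()]
#' @exportClass ResponseMatrix
setClass("ResponseMatrix", representation(responses = "dgCMatrix"))

setValidity("ResponseMatrix", function(object) {
    m <- object@responses
    msg <- character()
    if (is.null(rownames(m)) || is.null(colnames(m)))
        msg <- c(msg, "compound and assay identifiers (dimnames) are required")
    else {
        if (anyDuplicated(rownames(m)))
            msg <- c(msg, "duplicated compound identifiers")
        if (anyDuplicated(colnames(m)))
            msg <- c(msg, "duplicated assay identifiers")
        if (any(!nzchar(rownames(m))) || any(!nzchar(colnames(m))))
            msg <- c(msg, "empty identifier strings are not allowed")
    }
    if (length(m@x) && !all(m@x %in% c(1, -1)))
        msg <- c(msg, "matrix entries must be in {1, -1, 0}")
    if (length(msg)) msg else TRUE
})

#' ToxicityLabels: per-compound acute-toxicity endpoint
#'
#' Holds, for each compound, an optional rat oral LD50 potency expressed as
#' -log10(LD50) in mol/kg and the derived (or directly supplied) toxicity
#' class. When a potency value is present the class is always derived from
#' it with [classifyLD50()]: strictly above 3.00 is toxic, strictly below
#' 2.00 is nontoxic, the closed band in between is marginal.
#'
#' @slot compound_id character vector of unique compound identifiers.
#' @slot neg_log_ld50 numeric vector (NA where no potency is available).
#' @slot tox_class factor with levels nontoxic, marginal, toxic.
#'
#' @seealso [ToxicityLabels()], [classifyLD50()], [dropMarginal()]
#' @exportClass ToxicityLabels
setClass("ToxicityLabels",
    representation(compound_id = "character",
                   neg_log_ld50 = "numeric",
                   tox_class = "factor"))

setValidity("ToxicityLabels", function(object) {
    msg <- character()
    n <- length(object@compound_id)
    if (length(object@neg_log_ld50) != n || length(object@tox_class) != n)
        msg <- c(msg, "slots must have equal length")
    if (anyDuplicated(object@compound_id))
        msg <- c(msg, "duplicated compound identifiers")
    if (n && (any(is.na(object@compound_id)) || any(!nzchar(object@compound_id))))
        msg <- c(msg, "compound identifiers must be non-empty")
    if (!identical(levels(object@tox_class), .TOX_LEVELS))
        msg <- c(msg, sprintf("tox_class levels must be {%s}",
                              paste(.TOX_LEVELS, collapse = ", ")))
    if (any(is.na(object@tox_class)))
        msg <- c(msg, "every compound needs a toxicity class")
    ld <- object@neg_log_ld50
    has <- !is.na(ld)
    if (any(has) &&
        !identical(as.character(object@tox_class[has]), .classifyLD50(ld[has])))
        msg <- c(msg, "tox_class inconsistent with neg_log_ld50")
    if (length(msg)) msg else TRUE
})

#' AssaySelection: result of the two-stage assay panel selection
#'
#' Produced by [rankAndSelect()]. Candidate assays are those whose balanced
#' classification rate (CCR) strictly exceeds the cutoff; the panel is the
#' top fraction of candidates after ranking by the L relevance score
#' (descending, ties broken by assay identifier).
#'
#' @slot relevance the per-assay relevance table with candidate/panel flags
#'   and ranks added.
#' @slot candidateAssays assay identifiers passing the CCR cutoff.
#' @slot panelAssays the selected panel, ordered by decreasing L score.
#' @slot ccrCutoff,topFraction,minL selection parameters.
#' @slot minLInPanel smallest L score among panel assays (NA if empty).
#'
#' @seealso [rankAndSelect()], [assayRelevance()]
#' @exportClass AssaySelection
setClass("AssaySelection",
    representation(relevance = "data.frame",
                   candidateAssays = "character",
                   panelAssays = "character",
                   ccrCutoff = "numeric",
                   topFraction = "numeric",
                   minL = "numeric",
                   minLInPanel = "numeric"))

setValidity("AssaySelection", function(object) {
    msg <- character()
    if (!all(object@panelAssays %in% object@candidateAssays))
        msg <- c(msg, "panel assays must be a subset of candidate assays")
    l <- object@relevance$l_score[match(object@panelAssays,
                                        object@relevance$assay_id)]
    if (length(l) > 1 && any(diff(l) > 0))
        msg <- c(msg, "panel must be ordered by non-increasing l_score")
    if (length(msg)) msg else TRUE
})
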