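.classifyLD50 <- function(x) {
    ifelse(x > 3, "toxic", ifelse(x < 2, "nontoxic", "marginal"))
}

#' Classify acute toxicity from -log10 LD50
#'
#' Rat oral LD50 potencies expressed as -log10(mol/kg) are discretized with
#' the standard acute-toxicity guideline cutoffs: strictly above 3.00 is
#' toxic, strictly below 2.00 is nontoxic. Values in the closed band
#' \[2.00, 3.00\] (including the boundaries, since both rules are strict
#' inequalities) are marginal.
#'
#' @param neg_log_ld50 numeric vector of -log10 LD50 values in mol/kg;
#'   all values must be finite.
#' @return factor with levels nontoxic, marginal, toxic.
#' @examples
#' classifyLD50(c(3.5, 3.0, 2.5, 2.0, 1.5))
#' @export
classifyLD50 <- function(neg_log_ld50) {
    if (!is.numeric(neg_log_ld50) || any(!is.finite(neg_log_ld50)))
        stop("neg_log_ld50 must be finite numeric")
    factor(.classifyLD50(neg_log_ld50), levels = .TOX_LEVELS)
}

#' Construct a ToxicityLabels object
#'
#' Either `neg_log_ld50` or `tox_class` must be supplied. When the potency
#' is given the class is derived from it ([classifyLD50()]); a class
#' supplied alongside a potency must agree with the derived one.
#'
#' @param compound_id character vector of unique compound identifiers.
#' @param neg_log_ld50 optional numeric vector, -log10 LD50 in mol/kg
#'   (NA allowed for compounds with a direct class).
#' @param tox_class optional vector with values among toxic, marginal,
#'   nontoxic (case-insensitive).
#' @return a [ToxicityLabels-class] object.
#' @examples
#' ToxicityLabels(c("c1", "c2"), neg_log_ld50 = c(4.2, 1.1))
#' @export
ToxicityLabels <- function(compound_id, neg_log_ld50 = NULL, tox_class = NULL) {
    compound_id <- as.character(compound_id)
    n <- length(compound_id)
    if (is.null(neg_log_ld50) && is.null(tox_class))
        stop("either neg_log_ld50 or tox_class is required")
    if (is.null(neg_log_ld50))
        neg_log_ld50 <- rep(NA_real_, n)
    if (!is.numeric(neg_log_ld50) || length(neg_log_ld50) != n)
        stop("neg_log_ld50 must be numeric of length ", n)
    if (any(is.infinite(neg_log_ld50)))
        stop("neg_log_ld50 must be finite (or NA)")
    has <- !is.na(neg_log_ld50)
    cls <- rep(NA_character_, n)
    cls[has] <- .classifyLD50(neg_log_ld50[has])
    if (!is.null(tox_class)) {
        given <- tolower(as.character(tox_class))
        bad <- !(given %in% .TOX_LEVELS) & !is.na(given)
        if (any(bad))
            stop("unknown tox_class value(s): ",
                 paste(unique(tox_class[bad]), collapse = ", "))
        conflict <- has & !is.na(given) & given != cls
        if (any(conflict))
            stop("tox_class disagrees with neg_log_ld50 for: ",
                 paste(utils::head(compound_id[conflict], 5), collapse = ", "))
        cls[!has] <- given[!has]
    }
    if (any(is.na(cls)))
        stop("compounds without neg_log_ld50 need an explicit tox_class")
    methods::new("ToxicityLabels",
                 compound_id = compound_id,
                 neg_log_ld50 = as.numeric(neg_log_ld50),
                 tox_class = factor(cls, levels = .TOX_LEVELS))
}

#' @rdname ToxicityLabels-class
#' @param x,object a `ToxicityLabels`
#' @export
setMethod("toxClass", "ToxicityLabels", function(x)
    stats::setNames(x@tox_class, x@compound_id))

#' @rdname ToxicityLabels-class
#' @export
setMethod("negLogLD50", "ToxicityLabels", function(x)
    stats::setNames(x@neg_log_ld50, x@compound_id))

#' @rdname ToxicityLabels-class
#' @export
setMethod("compoundIds", "ToxicityLabels", function(x) x@compound_id)

#' @rdname ToxicityLabels-class
#' @export
setMethod("length", "ToxicityLabels", function(x) length(x@compound_id))

#' @rdname ToxicityLabels-class
#' @param i index or compound ids
#' @export
setMethod("[", "ToxicityLabels", function(x, i, j, ..., drop = FALSE) {
    if (is.character(i)) i <- match(i, x@compound_id)
    methods::initialize(x,
        compound_id = x@compound_id[i],
        neg_log_ld50 = x@neg_log_ld50[i],
        tox_class = x@tox_class[i])
})

setMethod("show", "ToxicityLabels", function(object) {
    tab <- table(object@tox_class)
    cat(sprintf("ToxicityLabels: %d compounds (%s)\n", length(object),
                paste(sprintf("%d %s", tab, names(tab)), collapse = ", ")))
    invisible(object)
})

#' @rdname dropMarginal
#' @export
setMethod("dropMarginal", "ToxicityLabels", function(x)
    x[which(x@tox_class != "marginal")])
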