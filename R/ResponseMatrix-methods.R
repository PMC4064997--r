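#' Construct a ResponseMatrix from an ordinary matrix
#'
#' @param responses a base or sparse numeric matrix with values in
#'   \{1, -1, 0\}, rownames = compound ids, colnames = assay ids.
#' @return a [ResponseMatrix-class] object.
#' @examples
#' m <- ResponseMatrix(matrix(c(1, 0, -1, 1), 2, 2,
#'     dimnames = list(c("c1", "c2"), c("a1", "a2"))))
#' activesPerAssay(m)
#' @export
ResponseMatrix <- function(responses) {
    sp <- Matrix::drop0(methods::as(as(responses, "CsparseMatrix"), "generalMatrix"))
    sp <- methods::as(sp, "dgCMatrix")
    methods::new("ResponseMatrix", responses = sp)
}

#' @rdname ResponseMatrix-class
#' @export
setMethod("compoundIds", "ResponseMatrix", function(x) rownames(x@responses))

#' @rdname ResponseMatrix-class
#' @export
setMethod("assayIds", "ResponseMatrix", function(x) colnames(x@responses))

#' @rdname ResponseMatrix-class
#' @export
setMethod("responses", "ResponseMatrix", function(x) x@responses)

#' @rdname ResponseMatrix-class
#' @export
setMethod("dim", "ResponseMatrix", function(x) dim(x@responses))

#' @rdname ResponseMatrix-class
#' @export
setMethod("activesPerAssay", "ResponseMatrix", function(x)
    Matrix::colSums(x@responses == 1))

#' @rdname ResponseMatrix-class
#' @export
setMethod("inactivesPerAssay", "ResponseMatrix", function(x)
    Matrix::colSums(x@responses == -1))

#' @rdname ResponseMatrix-class
#' @param i,j,drop row (compound) and column (assay) indices or names;
#'   subsetting always returns a `ResponseMatrix`.
#' @export
setMethod("[", "ResponseMatrix", function(x, i, j, ..., drop = FALSE) {
    if (missing(i)) i <- seq_len(nrow(x@responses))
    if (missing(j)) j <- seq_len(ncol(x@responses))
    ResponseMatrix(x@responses[i, j, drop = FALSE])
})

setMethod("show", "ResponseMatrix", function(object) {
    m <- object@responses
    cat(sprintf("ResponseMatrix: %d compounds x %d assays\n", nrow(m), ncol(m)))
    n <- length(m@x)
    act <- sum(m@x == 1)
    cat(sprintf("  entries: %d active, %d inactive, %.1f%% untested/inconclusive\n",
                act, n - act,
                100 * (1 - n / max(1, prod(dim(m))))))
    invisible(object)
})

.outcome_to_code <- c(ACTIVE = 2L, INACTIVE = 1L, INCONCLUSIVE = 0L,
                      UNTESTED = 0L)

#' Build a response matrix from long-format outcome records
#'
#' Encodes one record per (compound, assay) pair as a sparse matrix entry:
#' active is 1, inactive is -1, inconclusive/untested is 0 (not stored).
#' Duplicate records for the same cell (e.g. several PubChem substances
#' mapping to one compound) are resolved conservatively toward activity:
#' any active wins, else any inactive, else 0.
#'
#' @param records data.frame with columns `compound_id`, `assay_id`,
#'   `outcome` (values among ACTIVE, INACTIVE, INCONCLUSIVE, UNTESTED,
#'   case-insensitive), as returned by [readOutcomes()].
#' @param compounds_of_interest optional character vector fixing the row
#'   universe and order; compounds with no records get all-zero rows.
#' @return a [ResponseMatrix-class]; rows/columns ordered by first
#'   appearance (or by `compounds_of_interest`).
#' @examples
#' rec <- data.frame(compound_id = c("c1", "c2"), assay_id = "a1",
#'                   outcome = c("ACTIVE", "INACTIVE"))
#' buildMatrix(rec)
#' @export
buildMatrix <- function(records, compounds_of_interest = NULL) {
    stopifnot(all(c("compound_id", "assay_id", "outcome") %in% names(records)))
    out <- toupper(as.character(records$outcome))
    bad <- !(out %in% .OUTCOME_LEVELS)
    if (any(bad))
        stop("unknown outcome value(s): ",
             paste(unique(records$outcome[bad]), collapse = ", "))
    cid <- as.character(records$compound_id)
    aid <- as.character(records$assay_id)
    if (is.null(compounds_of_interest)) {
        rows <- unique(cid)
    } else {
        rows <- unique(as.character(compounds_of_interest))
        keep <- cid %in% rows
        cid <- cid[keep]; aid <- aid[keep]; out <- out[keep]
    }
    cols <- unique(aid)
    code <- .outcome_to_code[out]
    # any-active-wins, then any-inactive: keep the highest code per cell
    o <- order(cid, aid, -code)
    dup <- duplicated(paste0(cid[o], "\r", aid[o]))
    sel <- o[!dup]
    nz <- sel[code[sel] > 0L]
    val <- ifelse(code[nz] == 2L, 1, -1)
    sp <- Matrix::sparseMatrix(i = match(cid[nz], rows),
                               j = match(aid[nz], cols),
                               x = val,
                               dims = c(length(rows), max(length(cols), 1L)),
                               dimnames = list(rows,
                                   if (length(cols)) cols else "a0"))
    if (!length(cols))
        sp <- sp[, 0, drop = FALSE]
    ResponseMatrix(sp)
}

#' Drop bioassays with too few active responses
#'
#' HTS assays with very few actives among the profiled compounds carry
#' little response information; they are removed before relevance scoring.
#' The default keeps assays with at least 6 actives.
#'
#' @param m a [ResponseMatrix-class].
#' @param min_actives minimum number of active (1) entries an assay column
#'   must have to be retained; must be >= 1.
#' @return list with elements `matrix` (the filtered `ResponseMatrix`,
#'   compound rows unchanged) and `removed` (ids of dropped assays).
#' @examples
#' m <- ResponseMatrix(matrix(c(1, 1, 0, 1), 2, 2,
#'     dimnames = list(c("c1", "c2"), c("a1", "a2"))))
#' filterLowInfoAssays(m, min_actives = 2)$removed
#' @export
filterLowInfoAssays <- function(m, min_actives = 6) {
    stopifnot(is(m, "ResponseMatrix"), min_actives >= 1)
    keep <- activesPerAssay(m) >= min_actives
    list(matrix = m[, which(keep)],
         removed = assayIds(m)[!keep])
}
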