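.read_delim <- function(path, sep = NULL) {
    if (!file.exists(path))
        stop("file not found: ", path)
    if (is.null(sep))
        sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                      colClasses = "character", comment.char = "#",
                      check.names = FALSE, stringsAsFactors = FALSE)
}

.require_columns <- function(df, cols, path) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
        stop(sprintf("%s: missing required column(s): %s",
                     path, paste(miss, collapse = ", ")))
}

#' Read long-format bioassay outcome records
#'
#' Expects delimited text (TSV by default, CSV by extension) with header
#' columns `compound_id`, `assay_id`, `outcome`. The outcome vocabulary is
#' \{Active, Inactive, Inconclusive, Untested\}, case-insensitive; anything
#' else is a parse error reporting the offending line.
#'
#' @param path path to the outcome table.
#' @param sep field separator; default inferred from the file extension.
#' @return data.frame with character columns `compound_id`, `assay_id` and
#'   `outcome` (upper-cased), one row per input data row.
#' @seealso [buildMatrix()]
#' @export
readOutcomes <- function(path, sep = NULL) {
    df <- .read_delim(path, sep)
    .require_columns(df, c("compound_id", "assay_id", "outcome"), path)
    out <- toupper(df$outcome)
    bad <- which(!(out %in% .OUTCOME_LEVELS))
    if (length(bad))
        stop(sprintf("%s: unknown outcome '%s' at line %d",
                     path, df$outcome[bad[1]], bad[1] + 1L))
    if (any(!nzchar(df$compound_id)) || any(!nzchar(df$assay_id)))
        stop(path, ": empty compound_id or assay_id")
    data.frame(compound_id = df$compound_id,
               assay_id = df$assay_id,
               outcome = out,
               stringsAsFactors = FALSE)
}

#' Read a compound toxicity label table
#'
#' Expects a delimited file with a `compound_id` column plus either a
#' `neg_log_ld50` column (-log10 LD50, mol/kg) or a `tox_class` column
#' (toxic / marginal / nontoxic), or both.
#'
#' @inheritParams readOutcomes
#' @return a [ToxicityLabels-class] object.
#' @export
readLabels <- function(path, sep = NULL) {
    df <- .read_delim(path, sep)
    .require_columns(df, "compound_id", path)
    has_ld <- "neg_log_ld50" %in% names(df)
    has_cl <- "tox_class" %in% names(df)
    if (!has_ld && !has_cl)
        stop(path, ": need a neg_log_ld50 or tox_class column")
    ld <- if (has_ld) suppressWarnings(as.numeric(df$neg_log_ld50)) else NULL
    if (has_ld && any(is.na(ld) & nzchar(df$neg_log_ld50)))
        stop(path, ": non-numeric neg_log_ld50 value")
    ToxicityLabels(df$compound_id,
                   neg_log_ld50 = ld,
                   tox_class = if (has_cl) df$tox_class else NULL)
}

#' Write / read a response matrix
#'
#' Two on-disk layouts are supported. `wide` (default): a TSV with first
#' column `compound_id` and one column per assay, cells in \{1, -1, 0\}.
#' `long`: a sparse TSV with columns `compound_id`, `assay_id`, `value`
#' where 0 cells are omitted; the full compound and assay universes are
#' kept in `#compounds:` / `#assays:` header comments so the round trip is
#' exact even with all-zero rows or columns.
#'
#' @param m a [ResponseMatrix-class].
#' @param path output (input) file path.
#' @param format `"wide"` or `"long"`.
#' @return `writeMatrix` returns `path` invisibly; `readMatrix` returns the
#'   reconstructed `ResponseMatrix`. Cells outside \{1, -1, 0\} are a parse
#'   error reporting the coordinates.
#' @export
writeMatrix <- function(m, path, format = c("wide", "long")) {
    stopifnot(is(m, "ResponseMatrix"))
    format <- match.arg(format)
    if (format == "wide") {
        dense <- as.matrix(m@responses)
        df <- data.frame(compound_id = rownames(dense), dense,
                         check.names = FALSE, stringsAsFactors = FALSE)
        utils::write.table(df, path, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = TRUE)
    } else {
        sp <- m@responses
        tri <- Matrix::summary(sp)
        con <- file(path, "w")
        on.exit(close(con))
        writeLines(c(paste0("#compounds:", paste(rownames(sp), collapse = "\t")),
                     paste0("#assays:", paste(colnames(sp), collapse = "\t")),
                     "compound_id\tassay_id\tvalue"), con)
        if (nrow(tri))
            writeLines(sprintf("%s\t%s\t%d", rownames(sp)[tri$i],
                               colnames(sp)[tri$j], as.integer(tri$x)), con)
    }
    invisible(path)
}

#' @rdname writeMatrix
#' @export
readMatrix <- function(path, format = c("wide", "long")) {
    if (!file.exists(path))
        stop("file not found: ", path)
    format <- match.arg(format)
    if (format == "wide") {
        df <- utils::read.table(path, header = TRUE, sep = "\t",
                                check.names = FALSE, colClasses = "character",
                                comment.char = "#")
        .require_columns(df, "compound_id", path)
        ids <- df$compound_id
        vals <- as.matrix(df[, setdiff(names(df), "compound_id"), drop = FALSE])
        num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                       dimnames = list(ids, colnames(vals))))
        bad <- which(is.na(num) | !(num %in% c(-1, 0, 1)), arr.ind = TRUE)
        if (nrow(bad))
            stop(sprintf("%s: invalid cell '%s' at compound %s, assay %s",
                         path, vals[bad[1, 1], bad[1, 2]],
                         ids[bad[1, 1]], colnames(vals)[bad[1, 2]]))
        ResponseMatrix(num)
    } else {
        hdr <- readLines(path, n = 2L)
        if (!startsWith(hdr[1], "#compounds:") || !startsWith(hdr[2], "#assays:"))
            stop(path, ": missing #compounds/#assays header lines")
        rows <- strsplit(sub("^#compounds:", "", hdr[1]), "\t", fixed = TRUE)[[1]]
        cols <- strsplit(sub("^#assays:", "", hdr[2]), "\t", fixed = TRUE)[[1]]
        df <- utils::read.table(path, header = TRUE, sep = "\t",
                                colClasses = "character", comment.char = "#")
        .require_columns(df, c("compound_id", "assay_id", "value"), path)
        v <- suppressWarnings(as.numeric(df$value))
        bad <- which(is.na(v) | !(v %in% c(-1, 0, 1)))
        if (length(bad))
            stop(sprintf("%s: invalid cell '%s' at compound %s, assay %s",
                         path, df$value[bad[1]], df$compound_id[bad[1]],
                         df$assay_id[bad[1]]))
        i <- match(df$compound_id, rows)
        j <- match(df$assay_id, cols)
        if (anyNA(i) || anyNA(j))
            stop(path, ": record references an id absent from the header")
        keep <- v != 0
        sp <- Matrix::sparseMatrix(i = i[keep], j = j[keep], x = v[keep],
                                   dims = c(length(rows), length(cols)),
                                   dimnames = list(rows, cols))
        ResponseMatrix(sp)
    }
}
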