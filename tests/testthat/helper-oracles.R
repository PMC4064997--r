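# Independent brute-force oracles and tiny fixture builders used across the
# suite. The oracles deliberately loop over cells one at a time so they share
# no code path with the package's vectorized implementations.

# random sparse {1,-1,0} matrix with named dims
random_matrix <- function(n, p, p_active = 0.15, p_inactive = 0.35) {
    vals <- sample(c(1, -1, 0), n * p, replace = TRUE,
                   prob = c(p_active, p_inactive, 1 - p_active - p_inactive))
    m <- matrix(vals, n, p,
                dimnames = list(sprintf("c%03d", seq_len(n)),
                                sprintf("a%03d", seq_len(p))))
    ResponseMatrix(m)
}

random_labels <- function(compound_ids, p_toxic = 0.5, p_marginal = 0.1) {
    cls <- sample(c("toxic", "nontoxic", "marginal"), length(compound_ids),
                  replace = TRUE,
                  prob = c(p_toxic, 1 - p_toxic - p_marginal, p_marginal))
    ToxicityLabels(compound_ids, tox_class = cls)
}

# cell-by-cell confusion recount for one assay column
brute_confusion <- function(column, labels) {
    cls <- toxClass(labels)
    tp <- fp <- tn <- fn <- 0
    for (cid in names(column)) {
        v <- column[[cid]]
        lab <- if (cid %in% names(cls)) as.character(cls[[cid]]) else NA
        if (v == 0 || is.na(lab) || lab == "marginal") next
        if (v == 1 && lab == "toxic") tp <- tp + 1
        if (v == 1 && lab == "nontoxic") fp <- fp + 1
        if (v == -1 && lab == "nontoxic") tn <- tn + 1
        if (v == -1 && lab == "toxic") fn <- fn + 1
    }
    c(tp = tp, fp = fp, tn = tn, fn = fn)
}

# from-scratch Pearson statistic sum((O-E)^2/E) on the 2x2 table
brute_chi2 <- function(counts) {
    O <- matrix(c(counts[["tp"]], counts[["fn"]],
                  counts[["fp"]], counts[["tn"]]), 2, 2, byrow = TRUE)
    if (any(rowSums(O) == 0) || any(colSums(O) == 0)) return(NA_real_)
    E <- outer(rowSums(O), colSums(O)) / sum(O)
    sum((O - E)^2 / E)
}

# cell-by-cell recount of panel bookkeeping
brute_panel_stats <- function(m, panel) {
    dense <- as.matrix(responses(m))[, panel, drop = FALSE]
    a_i <- apply(dense, 2, function(x) sum(x == 1))
    i_i <- apply(dense, 2, function(x) sum(x == -1))
    a_j <- apply(dense, 1, function(x) sum(x == 1))
    i_j <- apply(dense, 1, function(x) sum(x == -1))
    list(a_t = sum(a_i), i_t = sum(i_i), a_i = a_i, i_i = i_i,
         a_j = a_j, i_j = i_j)
}

# the 3x3 worked example used for frozen Eq-style golden values
toy_matrix <- function() {
    ResponseMatrix(matrix(c(1, -1, 0,
                            1,  1, -1,
                            0, -1, 1), 3, 3, byrow = TRUE,
                          dimnames = list(c("c1", "c2", "c3"),
                                          c("a1", "a2", "a3"))))
}

write_tsv_fixture <- function(lines, path = tempfile(fileext = ".tsv")) {
    writeLines(lines, path)
    path
}
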