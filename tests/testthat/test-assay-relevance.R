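test_that("confusion counts match the worked four-case example", {
    lab <- ToxicityLabels(c("c1", "c2", "c3", "c4"),
                          tox_class = c("toxic", "toxic",
                                        "nontoxic", "nontoxic"))
    a <- c(c1 = 1, c2 = 0, c3 = -1, c4 = 1)
    expect_equal(confusionCounts(a, lab),
                 c(tp = 1, fp = 1, tn = 1, fn = 0))
    expect_equal(confusionCounts(c(c1 = 0, c2 = 0, c3 = 0, c4 = 0), lab),
                 c(tp = 0, fp = 0, tn = 0, fn = 0))
    perfect <- c(c1 = 1, c2 = 1, c3 = -1, c4 = -1)
    cc <- confusionCounts(perfect, lab)
    expect_equal(cc[["fp"]] + cc[["fn"]], 0)
})

test_that("confusion counts equal a brute-force recount on random matrices", {
    set.seed(101)
    for (rep in 1:60) {
        m <- random_matrix(sample(2:20, 1), sample(1:10, 1))
        lab <- random_labels(compoundIds(m))
        dense <- as.matrix(responses(m))
        rel <- assayRelevance(m, lab)
        for (j in seq_len(ncol(dense))) {
            expected <- brute_confusion(dense[, j], lab)
            got <- unlist(rel[j, c("tp", "fp", "tn", "fn")])
            expect_equal(unname(got), unname(expected))
            expect_equal(confusionCounts(dense[, j], lab), expected)
            # marginal/unlabeled/zero exclusions: counts total the recount
            expect_equal(sum(got), sum(expected))
        }
    }
})

test_that("ccr reproduces golden values and degenerate rules", {
    expect_equal(ccr(c(tp = 8, fp = 4, tn = 6, fn = 2)), 0.7)
    expect_equal(ccr(c(tp = 5, fp = 0, tn = 9, fn = 0)), 1.0)
    expect_equal(ccr(c(tp = 3, fp = 7, tn = 7, fn = 3)), 0.5)
    expect_true(is.na(ccr(c(tp = 0, fp = 3, tn = 2, fn = 0))))  # no toxic side
    expect_true(is.na(ccr(c(tp = 2, fp = 0, tn = 0, fn = 1))))  # no nontoxic side
    expect_true(is.na(ccr(c(tp = 0, fp = 0, tn = 0, fn = 0))))
    # in [0,1] and 1 only for the perfect case
    set.seed(5)
    for (rep in 1:100) {
        cc <- c(tp = rpois(1, 4), fp = rpois(1, 4),
                tn = rpois(1, 4), fn = rpois(1, 4))
        v <- ccr(cc)
        if (!is.na(v)) {
            expect_gte(v, 0); expect_lte(v, 1)
            if (v == 1)
                expect_true(cc[["fp"]] == 0 && cc[["fn"]] == 0 &&
                            cc[["tp"]] > 0 && cc[["tn"]] > 0)
        }
    }
})

test_that("ccr is invariant under permutation of compound order", {
    set.seed(11)
    m <- random_matrix(15, 4)
    lab <- random_labels(compoundIds(m))
    dense <- as.matrix(responses(m))
    for (j in 1:4) {
        perm <- sample(nrow(dense))
        expect_equal(ccr(confusionCounts(dense[perm, j], lab)),
                     ccr(confusionCounts(dense[, j], lab)))
    }
})

test_that("L score is deterministic, strictly penalizes FP, and has a frozen golden value", {
    # golden value: TPR * TP / (FP + 1) = 0.8 * 8 / 5
    expect_equal(lScore(c(tp = 8, fp = 4, tn = 6, fn = 2)), 1.28)
    expect_equal(lScore(c(tp = 8, fp = 4, tn = 6, fn = 2)),
                 lScore(c(tp = 8, fp = 4, tn = 6, fn = 2)))
    expect_true(is.na(lScore(c(tp = 0, fp = 2, tn = 3, fn = 0))))

    # property sweep: increasing fp with tp/tn/fn fixed strictly lowers L
    grid <- expand.grid(tp = c(1, 3, 10, 40), fn = c(0, 2, 9),
                        tn = c(0, 5), fp = 0:20)
    for (k in seq_len(nrow(grid))) {
        g <- grid[k, ]
        l0 <- lScore(c(tp = g$tp, fp = g$fp, tn = g$tn, fn = g$fn))
        l1 <- lScore(c(tp = g$tp, fp = g$fp + 1, tn = g$tn, fn = g$fn))
        expect_lt(l1, l0)
    }
})

test_that("L score weights the true-positive side, not the true-negative side", {
    # with false positives fixed, the more sensitive assay outranks
    sensitive <- c(tp = 18, fn = 2, fp = 5, tn = 15)
    specific <- c(tp = 12, fn = 8, fp = 5, tn = 15)
    expect_gt(lScore(sensitive), lScore(specific))
    # the true-negative count itself carries no weight
    expect_equal(lScore(c(tp = 10, fn = 5, fp = 3, tn = 2)),
                 lScore(c(tp = 10, fn = 5, fp = 3, tn = 50)))
})

test_that("chi-square matches the hand Pearson computation", {
    expect_equal(chi2Association(c(tp = 10, fn = 5, fp = 20, tn = 40)),
                 50 / 9, tolerance = 1e-12)
    # identical row proportions -> independence -> 0
    expect_equal(chi2Association(c(tp = 6, fn = 4, fp = 12, tn = 8)), 0,
                 tolerance = 1e-12)
    # doubling all cells doubles the statistic
    cc <- c(tp = 7, fn = 3, fp = 5, tn = 15)
    expect_equal(chi2Association(cc * 2), 2 * chi2Association(cc),
                 tolerance = 1e-9)
    # zero margin -> undefined
    expect_true(is.na(chi2Association(c(tp = 0, fn = 0, fp = 3, tn = 9))))
    expect_true(is.na(chi2Association(c(tp = 0, fn = 4, fp = 0, tn = 9))))

    set.seed(21)
    for (rep in 1:200) {
        cc <- c(tp = rpois(1, 6), fn = rpois(1, 6),
                fp = rpois(1, 6), tn = rpois(1, 6))
        expect_equal(chi2Association(cc), brute_chi2(cc), tolerance = 1e-9)
    }
    # swapping both rows and both columns leaves the statistic unchanged
    expect_equal(chi2Association(c(tp = 9, fn = 2, fp = 4, tn = 11)),
                 chi2Association(c(tp = 11, fn = 4, fp = 2, tn = 9)))
})

test_that("panel selection reproduces the two-stage arithmetic", {
    # 95 candidates at top_fraction 0.5 give a 47-assay panel
    set.seed(3)
    n <- 120
    rel <- data.frame(assay_id = sprintf("a%03d", 1:n),
                      tp = 10, fp = 1, tn = 10, fn = 1,
                      sensitivity = 10 / 11, specificity = 10 / 11,
                      ccr = c(runif(95, 0.62, 0.95), runif(n - 95, 0.3, 0.6)),
                      l_score = runif(n, 1, 30), chi2 = NA_real_)
    sel <- rankAndSelect(rel, ccr_cutoff = 0.6, top_fraction = 0.5)
    expect_equal(length(candidateAssays(sel)), 95)
    expect_equal(length(panelAssays(sel)), 47)
    # panel = top candidates by L, in descending order
    l <- rel$l_score[match(panelAssays(sel), rel$assay_id)]
    expect_true(all(diff(l) <= 0))
    expect_equal(sel@minLInPanel, min(l))
    expect_gte(min(l),
               max(rel$l_score[match(setdiff(candidateAssays(sel),
                                             panelAssays(sel)),
                                     rel$assay_id)]))
})

test_that("panel selection breaks ties deterministically and handles edge cases", {
    rel <- data.frame(assay_id = c("b", "a", "d", "c"),
                      tp = 5, fp = 1, tn = 5, fn = 1,
                      sensitivity = 5 / 6, specificity = 5 / 6,
                      ccr = 0.8, l_score = c(2, 2, 9, 2), chi2 = NA_real_)
    sel <- rankAndSelect(rel, top_fraction = 0.5)
    expect_equal(panelAssays(sel), c("d", "a"))  # tie a/b/c -> id ascending
    expect_equal(length(panelAssays(rankAndSelect(rel, top_fraction = 1))), 4)

    # floor() panel sizing: 4 candidates at 0.5 -> 2
    expect_equal(length(panelAssays(rankAndSelect(rel, top_fraction = 0.5))), 2)

    # strict CCR cutoff: ccr == cutoff is not a candidate
    at_cut <- rel; at_cut$ccr <- 0.6
    expect_warning(s0 <- rankAndSelect(at_cut, ccr_cutoff = 0.6), "empty")
    expect_equal(length(panelAssays(s0)), 0)

    # unscorable assays (NA ccr) never enter the candidate set
    with_na <- rel; with_na$ccr[1] <- NA_real_
    expect_false("b" %in% candidateAssays(rankAndSelect(with_na)))

    # optional L floor trims the panel
    sel_l <- rankAndSelect(rel, top_fraction = 1, min_l = 5)
    expect_equal(panelAssays(sel_l), "d")
})

test_that("relevance table carries flags and ranks consistent with selection", {
    set.seed(9)
    sim <- simulateScreen(syntheticSpec(n_compounds = 150, n_assays = 20,
                                        n_relevant_assays = 4,
                                        tested_fraction = 0.9, seed = 5))
    rel <- assayRelevance(sim$matrix, sim$truth$labels)
    sel <- suppressWarnings(rankAndSelect(rel))
    tab <- relevanceTable(sel)
    expect_equal(tab$assay_id[which(tab$panel_flag)],
                 sort(panelAssays(sel)))
    ranked <- tab[!is.na(tab$rank), ]
    ranked <- ranked[order(ranked$rank), ]
    expect_equal(ranked$assay_id, candidateAssays(sel))
})
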