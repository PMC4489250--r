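test_that("metrics follow the textbook confusion-matrix formulas", {
    r <- metricsFromCounts(tp = 11, fp = 2, tn = 37, fn = 1)
    m <- classifierMetrics(r)
    expect_equal(unname(m["sensitivity"]), 11 / 12)
    expect_equal(unname(m["specificity"]), 37 / 39)
    expect_equal(unname(m["precision"]), 11 / 13)
    expect_equal(unname(m["fdr"]), 2 / 13)
    expect_equal(unname(m["accuracy"]), 48 / 51)
    expect_equal(unname(m["mcc"]),
                 (11 * 37 - 2 * 1) / sqrt(13 * 12 * 39 * 38))
    expect_error(metricsFromCounts(-1, 0, 1, 0), "non-negative")
})

test_that("degenerate marginals give flagged NaN ratios and MCC 0", {
    r <- metricsFromCounts(tp = 0, fp = 0, tn = 10, fn = 0)
    m <- classifierMetrics(r)
    expect_equal(unname(m["specificity"]), 1)
    expect_true(is.nan(m[["precision"]]))
    expect_true(is.nan(m[["sensitivity"]]))
    expect_equal(unname(m["mcc"]), 0)
    expect_true(all(c("precision", "mcc") %in% r@undefined))
})

test_that("fdr complements precision and mcc is swap-invariant", {
    set.seed(31)
    for (rep in 1:20) {
        cts <- sample(0:30, 4, replace = TRUE)
        if (sum(cts) == 0) cts[1] <- 1
        m <- classifierMetrics(do.call(metricsFromCounts, as.list(cts)))
        if (!is.nan(m[["precision"]]))
            expect_equal(unname(m["precision"] + m["fdr"]), 1)
        swapped <- classifierMetrics(metricsFromCounts(
            tp = cts[3], fp = cts[4], tn = cts[1], fn = cts[2]))
        expect_equal(unname(m["mcc"]), unname(swapped["mcc"]))
    }
})

test_that("labels are matched by id, ignoring unlabeled predictions", {
    calls <- c(p1 = TRUE, p2 = TRUE, n1 = FALSE, n2 = TRUE, extra = TRUE)
    labels <- c(p1 = 1, p2 = 1, n1 = 0, n2 = 0)
    r <- evaluateAgainstLabels(calls, labels)
    expect_identical(confusionCounts(r), c(tp = 2L, fp = 1L, tn = 1L, fn = 0L))
    expect_error(evaluateAgainstLabels(calls, c(ghost = 1)), "missing")
    # perfect and inverted predictors on a 5+/5- synthetic set
    ds <- makeLabeledDataset(5, 5, seed = 12)
    perfect <- setNames(ds$labels == 1, names(ds$labels))
    expect_identical(confusionCounts(evaluateAgainstLabels(perfect, ds$labels)),
                     c(tp = 5L, fp = 0L, tn = 5L, fn = 0L))
    expect_identical(confusionCounts(evaluateAgainstLabels(!perfect, ds$labels)),
                     c(tp = 0L, fp = 5L, tn = 0L, fn = 5L))
})

test_that("the default sweep grid spans 35-90 in 551 steps", {
    sw <- sweepCutoff(c(a = 60), c(a = 1))
    tab <- sweepTable(sw)
    expect_identical(nrow(tab), 551L)
    expect_equal(tab$cutoff[1], 35)
    expect_equal(tab$cutoff[551], 90)
    expect_true(all(diff(tab$cutoff) > 0))
    # single sequence scoring 60: positive iff cutoff <= 60
    expect_identical(tab$tp, as.integer(tab$cutoff <= 60))
    expect_error(sweepCutoff(c(a = 60), c(a = 1), cutoffs = numeric(0)),
                 "empty")
})

test_that("sweep thresholding equals a full re-scan at each cutoff", {
    ds <- makeLabeledDataset(3, 3, seed = 8)
    cfg <- scanConfig(toyQN)  # graded scores, not just 0/100
    res <- scanBatch(ds$sequences, cfg)
    sw <- sweepCutoff(res, ds$labels, cutoffs = c(50, 60, 73.55, 75))
    tab <- sweepTable(sw)
    for (k in seq_len(nrow(tab))) {
        cfgK <- scanConfig(toyQN, pwaltzCutoff = tab$cutoff[k])
        resK <- scanBatch(ds$sequences, cfgK)
        direct <- confusionCounts(evaluateAgainstLabels(resK, ds$labels))
        expect_identical(as.integer(tab[k, c("tp", "fp", "tn", "fn")]),
                         unname(direct))
    }
})

test_that("the best-cutoff range matches a planted score distribution", {
    # positives score 80/85, negatives 40/70: accuracy is maximal exactly for
    # cutoffs in (70, 80]; on the 0.1 grid that is 70.1 .. 80.0
    scores <- c(p1 = 80, p2 = 85, n1 = 40, n2 = 70)
    labels <- c(p1 = 1, p2 = 1, n1 = 0, n2 = 0)
    sw <- sweepCutoff(scores, labels)
    expect_equal(bestCutoffRange(sw, "accuracy"), c(70.1, 80.0))
    expect_equal(bestCutoffRange(sw, "mcc"), c(70.1, 80.0))
    # proteins without any core stay negative at every cutoff
    sw2 <- sweepCutoff(c(scores, n3 = NA), c(labels, n3 = 0))
    expect_identical(sweepTable(sw2)$fp, sweepTable(sw)$fp)
})
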