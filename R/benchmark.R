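#' Classifier metrics from confusion counts
#'
#' Computes sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, precision
#' `tp/(tp+fp)`, false discovery rate `fp/(tp+fp)`, accuracy `(tp+tn)/total`
#' and the Matthews correlation coefficient
#' `(tp*tn - fp*fn)/sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`. Ratios with a zero
#' denominator are reported as `NaN` and flagged; MCC with any zero marginal
#' is defined as 0 (flagged).
#'
#' @param tp,fp,tn,fn non-negative confusion counts (total >= 1).
#' @return A [BenchmarkResult-class].
#' @examples
#' metricsFromCounts(tp = 11, fp = 2, tn = 37, fn = 1)
#' @export
metricsFromCounts <- function(tp, fp, tn, fn) {
    counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
    if (any(counts < 0))
        stop("confusion counts must be non-negative")
    counts <- stats::setNames(as.integer(round(counts)), names(counts))

    safeDiv <- function(num, den) if (den > 0) num / den else NaN
    tp <- counts[["tp"]]; fp <- counts[["fp"]]
    tn <- counts[["tn"]]; fn <- counts[["fn"]]
    m <- c(
        sensitivity = safeDiv(tp, tp + fn),
        specificity = safeDiv(tn, tn + fp),
        precision = safeDiv(tp, tp + fp),
        fdr = safeDiv(fp, tp + fp),
        accuracy = (tp + tn) / sum(counts)
    )
    marginals <- c(tp + fp, tp + fn, tn + fp, tn + fn)
    mcc <- if (any(marginals == 0L)) 0 else
        (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(prod(marginals))
    m <- c(m, mcc = mcc)
    undefined <- names(m)[is.nan(m)]
    if (any(marginals == 0L))
        undefined <- c(undefined, "mcc")
    new("BenchmarkResult", tp = tp, fp = fp, tn = tn, fn = fn,
        metrics = m, undefined = undefined)
}

#' Confusion counts of predictions against reference labels
#'
#' @param predictions a [PrLDScanResult-class], or a named logical vector of
#'   positive calls.
#' @param labels named 0/1 (or logical) vector; every labeled id must appear
#'   among the predictions. Unlabeled predictions are ignored.
#' @return A [BenchmarkResult-class] for the labeled subset.
#' @export
evaluateAgainstLabels <- function(predictions, labels) {
    calls <- if (is(predictions, "PrLDScanResult")) isPositive(predictions)
             else predictions
    stopifnot(is.logical(calls), !is.null(names(calls)), !is.null(names(labels)))
    missing <- setdiff(names(labels), names(calls))
    if (length(missing))
        stop("labeled id(s) missing from predictions: ",
             paste(utils::head(missing, 5L), collapse = ", "))
    lab <- as.logical(labels)
    prd <- calls[names(labels)]
    metricsFromCounts(tp = sum(prd & lab), fp = sum(prd & !lab),
                      tn = sum(!prd & !lab), fn = sum(!prd & lab))
}

#' Sweep the core-score cut-off over a grid
#'
#' Re-derives positive calls at each grid cut-off by thresholding the stored
#' best-core scores (no re-scanning: a scan retains the best score even for
#' sub-cut-off proteins), computes the confusion metrics against the labels,
#' and reports the cut-off ranges maximizing accuracy and MCC. A protein with
#' no core at all (`NA` score) is negative at every cut-off. The default grid
#' runs from 35 to 90 in 0.1 steps (551 values), the grid used to
#' parameterize the default 73.55 cut-off.
#'
#' @param predictions a [PrLDScanResult-class], or a named numeric vector of
#'   best-core scores (`NA` for proteins without a core).
#' @param labels named 0/1 labels, as in [evaluateAgainstLabels()].
#' @param cutoffs increasing numeric grid of cut-offs.
#' @return A [CutoffSweep-class].
#' @export
sweepCutoff <- function(predictions, labels,
                        cutoffs = seq(350L, 900L) / 10) {
    scores <- if (is(predictions, "PrLDScanResult")) bestScores(predictions)
              else predictions
    stopifnot(is.numeric(scores), !is.null(names(scores)))
    if (!length(cutoffs))
        stop("empty cut-off grid")
    if (is.unsorted(cutoffs, strictly = TRUE))
        stop("'cutoffs' must be strictly increasing")
    missing <- setdiff(names(labels), names(scores))
    if (length(missing))
        stop("labeled id(s) missing from predictions: ",
             paste(utils::head(missing, 5L), collapse = ", "))

    lab <- as.logical(labels)
    sc <- scores[names(labels)]
    rows <- lapply(cutoffs, function(co) {
        prd <- !is.na(sc) & sc >= co
        res <- metricsFromCounts(tp = sum(prd & lab), fp = sum(prd & !lab),
                                 tn = sum(!prd & !lab), fn = sum(!prd & lab))
        c(cutoff = co, tp = res@tp, fp = res@fp, tn = res@tn, fn = res@fn,
          res@metrics)
    })
    tab <- as.data.frame(do.call(rbind, rows))
    for (col in c("tp", "fp", "tn", "fn"))
        tab[[col]] <- as.integer(tab[[col]])
    bestRange <- function(v) {
        at <- which(v >= max(v, na.rm = TRUE) - 1e-12)
        range(tab$cutoff[at])
    }
    new("CutoffSweep", table = tab,
        bestAccuracyRange = bestRange(tab$accuracy),
        bestMCCRange = bestRange(tab$mcc))
}

## ---- methods ---------------------------------------------------------------

#' @rdname BenchmarkResult-class
#' @export
setMethod("confusionCounts", "BenchmarkResult", function(object)
    c(tp = object@tp, fp = object@fp, tn = object@tn, fn = object@fn))

#' @rdname BenchmarkResult-class
#' @export
setMethod("classifierMetrics", "BenchmarkResult", function(object) object@metrics)

setMethod("show", "BenchmarkResult", function(object) {
    cat("BenchmarkResult (tp =", object@tp, ", fp =", object@fp,
        ", tn =", object@tn, ", fn =", object@fn, ")\n")
    m <- round(object@metrics, 3L)
    for (nm in names(m))
        cat(sprintf("  %-12s %.3f%s\n", nm, m[[nm]],
                    if (nm %in% object@undefined) " (undefined)" else ""))
})

#' @rdname CutoffSweep-class
#' @export
setMethod("sweepTable", "CutoffSweep", function(object) object@table)

#' @rdname CutoffSweep-class
#' @export
setMethod("bestCutoffRange", "CutoffSweep", function(object,
        which = c("accuracy", "mcc")) {
    which <- match.arg(which)
    if (which == "accuracy") object@bestAccuracyRange else object@bestMCCRange
})

setMethod("show", "CutoffSweep", function(object) {
    cat("CutoffSweep over", nrow(object@table), "cut-offs [",
        min(object@table$cutoff), "-", max(object@table$cutoff), "]\n")
    cat(sprintf("  best accuracy %.3f at cut-offs %.2f-%.2f\n",
                max(object@table$accuracy), object@bestAccuracyRange[1L],
                object@bestAccuracyRange[2L]))
    cat(sprintf("  best MCC %.3f at cut-offs %.2f-%.2f\n",
                max(object@table$mcc), object@bestMCCRange[1L],
                object@bestMCCRange[2L]))
})
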