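#' @rdname ScoringMatrix-class
#' @param object,x an object.
#' @export
setGeneric("scoringWeights", function(object) standardGeneric("scoringWeights"))

#' @rdname ScoringMatrix-class
#' @export
setGeneric("rawScoreRange", function(object) standardGeneric("rawScoreRange"))

#' @rdname DisorderProfile-class
#' @export
setGeneric("foldIndexValues", function(object) standardGeneric("foldIndexValues"))

#' @rdname DisorderProfile-class
#' @export
setGeneric("disorderCalls", function(object) standardGeneric("disorderCalls"))

#' @rdname PrLDPrediction-class
#' @export
setGeneric("isPositive", function(object) standardGeneric("isPositive"))

#' @rdname PrLDPrediction-class
#' @export
setGeneric("reasonCode", function(object) standardGeneric("reasonCode"))

#' @rdname PrLDPrediction-class
#' @export
setGeneric("coreScore", function(object) standardGeneric("coreScore"))

#' @rdname PrLDPrediction-class
#' @export
setGeneric("coreSequence", function(object) standardGeneric("coreSequence"))

#' @rdname PrLDPrediction-class
#' @export
setGeneric("prldRange", function(object) standardGeneric("prldRange"))

#' @rdname PrLDPrediction-class
#' @export
setGeneric("candidateTable", function(object) standardGeneric("candidateTable"))

#' @rdname PrLDScanResult-class
#' @export
setGeneric("predictionTable", function(object) standardGeneric("predictionTable"))

#' @rdname PrLDScanResult-class
#' @export
setGeneric("bestScores", function(object) standardGeneric("bestScores"))

#' @rdname PrLDScanResult-class
#' @export
setGeneric("scanConfigOf", function(object) standardGeneric("scanConfigOf"))

#' @rdname BenchmarkResult-class
#' @export
setGeneric("confusionCounts", function(object) standardGeneric("confusionCounts"))

#' @rdname BenchmarkResult-class
#' @export
setGeneric("classifierMetrics", function(object) standardGeneric("classifierMetrics"))

#' @rdname CutoffSweep-class
#' @export
setGeneric("sweepTable", function(object) standardGeneric("sweepTable"))

#' @rdname CutoffSweep-class
#' @param which `"accuracy"` or `"mcc"`.
#' @export
setGeneric("bestCutoffRange", function(object, which = c("accuracy", "mcc"))
    standardGeneric("bestCutoffRange"))
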