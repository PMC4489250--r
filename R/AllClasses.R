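#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
NULL

.STD_RESIDUES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.AMBIGUOUS_RESIDUES <- c("B", "Z", "X", "U", "O", "J")

#' ScoringMatrix: position-specific weights for amyloid-core scoring
#'
#' Holds a position-specific scoring matrix used to rate 21-residue candidate
#' amyloid cores. A core's raw score is the sum of the matrix score over every
#' consecutive `motifLength`-mer placement inside the 21-mer; `minRaw` and
#' `maxRaw` are the analytically smallest and largest raw scores any 21-mer can
#' achieve under the matrix and anchor the 0-100 normalization.
#'
#' @slot weights numeric matrix, one row per motif position, one column per
#'   standard residue (all 20 must be present).
#' @slot minRaw,maxRaw smallest/largest achievable raw 21-mer score;
#'   `minRaw < maxRaw` is required, otherwise normalization is undefined.
#' @slot provenance free-text origin note (e.g. "synthetic toy matrix").
#'
#' @exportClass ScoringMatrix
setClass("ScoringMatrix",
    representation(
        weights = "matrix",
        minRaw = "numeric",
        maxRaw = "numeric",
        provenance = "character"
    )
)

setValidity("ScoringMatrix", function(object) {
    w <- object@weights
    if (!is.numeric(w) || nrow(w) < 1L)
        return("'weights' must be a numeric matrix with at least one row")
    missing <- setdiff(.STD_RESIDUES, colnames(w))
    if (length(missing))
        return(paste0("weights missing residue column(s): ",
                      paste(missing, collapse = ", ")))
    if (anyNA(w))
        return("weights contain missing values")
    if (length(object@minRaw) != 1L || length(object@maxRaw) != 1L)
        return("'minRaw' and 'maxRaw' must be scalars")
    if (!(object@minRaw < object@maxRaw))
        return("degenerate matrix: minRaw must be strictly less than maxRaw")
    TRUE
})

#' ScanConfig: parameters of a prion-like domain scan
#'
#' @slot window odd fold-index window length in residues (default 51).
#' @slot minDRLength minimum disordered-region length (default 60).
#' @slot qnThreshold minimum Q/N fraction of the candidate stretch, in \[0, 1\]
#'   (default 0.25); 0 reports whole disordered regions.
#' @slot coreLength amyloid-core window length (fixed at 21).
#' @slot pwaltzCutoff score cut-off above which the best core makes the
#'   protein positive; allowed range \[50, 75\], default 73.55.
#' @slot maxSequences maximum batch size (default 10000).
#' @slot matrix the [ScoringMatrix-class] used to score candidate cores.
#'
#' @exportClass ScanConfig
setClass("ScanConfig",
    representation(
        window = "integer",
        minDRLength = "integer",
        qnThreshold = "numeric",
        coreLength = "integer",
        pwaltzCutoff = "numeric",
        maxSequences = "integer",
        matrix = "ScoringMatrix"
    )
)

setValidity("ScanConfig", function(object) {
    if (object@window < 3L || object@window %% 2L == 0L)
        return("'window' must be an odd integer >= 3")
    if (object@minDRLength < 1L)
        return("'minDRLength' must be >= 1")
    if (object@qnThreshold < 0 || object@qnThreshold > 1)
        return("'qnThreshold' must lie in [0, 1]")
    if (object@coreLength != 21L)
        return("'coreLength' must be 21")
    if (object@pwaltzCutoff < 50 || object@pwaltzCutoff > 75)
        return("input parameter out of range: 'pwaltzCutoff' must lie in [50, 75]")
    if (object@maxSequences < 1L)
        return("'maxSequences' must be >= 1")
    TRUE
})

#' DisorderProfile: per-residue fold-index values
#'
#' @slot values one fold-index value per residue; negative values indicate
#'   predicted disorder. Values are bounded in \[-2.151, 1.634\].
#' @slot window the sliding-window length used.
#' @slot calls per-residue disorder call (`values < 0`).
#'
#' @exportClass DisorderProfile
setClass("DisorderProfile",
    representation(
        values = "numeric",
        window = "integer",
        calls = "logical"
    )
)

setValidity("DisorderProfile", function(object) {
    if (length(object@values) != length(object@calls))
        return("'values' and 'calls' must have equal length")
    if (length(object@values) &&
        (min(object@values) < -2.151 - 1e-9 || max(object@values) > 1.634 + 1e-9))
        return("fold-index values outside the attainable range [-2.151, 1.634]")
    if (!identical(object@calls, object@values < 0))
        return("'calls' must equal 'values < 0'")
    TRUE
})

#' PrLDPrediction: per-protein scan verdict
#'
#' All coordinates are 1-based inclusive within the protein sequence. Negative
#' predictions carry a reason code in `reason` ("no disordered region",
#' "no QN stretch", "stretch too short", "core below cutoff", "scan error");
#' the best core score is retained even for negatives so that cut-off sweeps
#' need no re-scan.
#'
#' @slot id protein identifier.
#' @slot positive whether the best core score reached the cut-off.
#' @slot reason reason code for negatives; `NA` when positive.
#' @slot prldStart,prldEnd bounds of the winning Q/N stretch (NA when none).
#' @slot prldSequence sequence of the winning stretch.
#' @slot coreStart start of the best 21-residue amyloid core.
#' @slot coreSequence the 21-residue core sequence.
#' @slot coreScore normalized core score in \[0, 100\]; NA when no core exists.
#' @slot candidates data.frame of all per-disordered-region (stretch, core)
#'   candidates considered.
#'
#' @exportClass PrLDPrediction
setClass("PrLDPrediction",
    representation(
        id = "character",
        positive = "logical",
        reason = "character",
        prldStart = "integer",
        prldEnd = "integer",
        prldSequence = "character",
        coreStart = "integer",
        coreSequence = "character",
        coreScore = "numeric",
        candidates = "data.frame"
    )
)

#' PrLDScanResult: ordered collection of per-protein predictions
#'
#' @slot predictions list of [PrLDPrediction-class], in input order.
#' @slot config the [ScanConfig-class] used for the scan.
#'
#' @exportClass PrLDScanResult
setClass("PrLDScanResult",
    representation(
        predictions = "list",
        config = "ScanConfig"
    )
)

setValidity("PrLDScanResult", function(object) {
    if (!all(vapply(object@predictions, is, logical(1), class2 = "PrLDPrediction")))
        return("'predictions' must contain PrLDPrediction objects only")
    TRUE
})

#' BenchmarkResult: confusion counts and derived classifier metrics
#'
#' @slot tp,fp,tn,fn confusion counts.
#' @slot metrics named numeric vector: sensitivity, specificity, precision,
#'   fdr, accuracy, mcc. Ratios with zero denominator are `NaN`; MCC with any
#'   zero marginal is defined as 0. Both cases are listed in `undefined`.
#' @slot undefined names of metrics whose textbook ratio was undefined.
#'
#' @exportClass BenchmarkResult
setClass("BenchmarkResult",
    representation(
        tp = "integer", fp = "integer", tn = "integer", fn = "integer",
        metrics = "numeric",
        undefined = "character"
    )
)

setValidity("BenchmarkResult", function(object) {
    counts <- c(object@tp, object@fp, object@tn, object@fn)
    if (any(counts < 0L))
        return("confusion counts must be non-negative")
    if (sum(counts) < 1L)
        return("at least one observation is required")
    TRUE
})

#' CutoffSweep: classifier metrics along a score cut-off grid
#'
#' @slot table data.frame with one row per cut-off: cutoff, tp, fp, tn, fn and
#'   the six derived metrics.
#' @slot bestAccuracyRange,bestMCCRange smallest and largest grid cut-off
#'   achieving the maximal accuracy / MCC.
#'
#' @exportClass CutoffSweep
setClass("CutoffSweep",
    representation(
        table = "data.frame",
        bestAccuracyRange = "numeric",
        bestMCCRange = "numeric"
    )
)
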