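#' Build a scan configuration
#'
#' Assembles and validates the parameters of a prion-like domain scan. Two
#' named presets are provided: `"yeast-default"` (Q/N threshold 0.25, score
#' cut-off 73.55), the parameterization on experimentally characterized yeast
#' prion domains, and `"human-prionlike"` (0.15, 64.00), a permissive setting
#' that retrieves known human prion-like proteins whose amyloid cores are
#' weaker than those of bona fide yeast prions.
#'
#' @param matrix a [ScoringMatrix-class] used to score candidate cores.
#' @param qnThreshold minimum Q/N fraction of the stretch, in \[0, 1\].
#' @param pwaltzCutoff core-score cut-off; values outside \[50, 75\] are
#'   rejected.
#' @param window fold-index window length (odd, default 51).
#' @param minDRLength minimum disordered-region length (default 60).
#' @param maxSequences maximum batch size (default 10000).
#' @param preset optional preset name overriding `qnThreshold` and
#'   `pwaltzCutoff`.
#' @return A [ScanConfig-class].
#' @examples
#' cfg <- scanConfig(toyScoringMatrix("q"))
#' cfg
#' @export
scanConfig <- function(matrix, qnThreshold = 0.25, pwaltzCutoff = 73.55,
                       window = 51L, minDRLength = 60L,
                       maxSequences = 10000L, preset = NULL) {
    stopifnot(is(matrix, "ScoringMatrix"))
    if (!is.null(preset)) {
        preset <- match.arg(preset, c("yeast-default", "human-prionlike"))
        if (preset == "yeast-default") {
            qnThreshold <- 0.25
            pwaltzCutoff <- 73.55
        } else {
            qnThreshold <- 0.15
            pwaltzCutoff <- 64.00
        }
    }
    new("ScanConfig", window = as.integer(window),
        minDRLength = as.integer(minDRLength),
        qnThreshold = qnThreshold, coreLength = 21L,
        pwaltzCutoff = pwaltzCutoff,
        maxSequences = as.integer(maxSequences), matrix = matrix)
}

.negativePrediction <- function(id, reason, candidates) {
    new("PrLDPrediction", id = id, positive = FALSE, reason = reason,
        prldStart = NA_integer_, prldEnd = NA_integer_,
        prldSequence = NA_character_, coreStart = NA_integer_,
        coreSequence = NA_character_, coreScore = NA_real_,
        candidates = candidates)
}

.emptyCandidates <- function() {
    data.frame(dr_start = integer(), dr_end = integer(),
               stretch_start = integer(), stretch_end = integer(),
               qn_fraction = numeric(), core_start = integer(),
               core_sequence = character(), core_score = numeric(),
               stringsAsFactors = FALSE)
}

#' Scan one protein for a prion-like domain
#'
#' Runs the three sequential stages on a single sequence: (i) fold-index
#' disorder prediction and extraction of disordered regions of at least
#' `minDRLength` residues; (ii) within each region, search for the longest
#' contiguous stretch with Q/N fraction at or above `qnThreshold`; (iii)
#' scoring of every 21-residue window of each stretch, keeping the best core.
#' When several regions yield a core, the stretch containing the
#' highest-scoring core is reported (leftmost on ties). The protein is called
#' positive when that score reaches `pwaltzCutoff`. Degenerate inputs yield
#' negative predictions with a reason code, never errors.
#'
#' @param sequence amino-acid string, `AAString`, or length-1 `AAStringSet`.
#' @param config a [ScanConfig-class].
#' @param id protein identifier (defaults to the sequence name, else
#'   `"query"`).
#' @return A [PrLDPrediction-class]; all per-region candidates are retained
#'   in `candidateTable()`, and the best core score is recorded even for
#'   negative calls.
#' @export
scanProtein <- function(sequence, config, id = NULL) {
    stopifnot(is(config, "ScanConfig"))
    if (is.null(id))
        id <- if (!is.null(names(sequence)) && nzchar(names(sequence)[1L]))
            names(sequence)[1L] else "query"
    seqStr <- .asSequenceString(sequence)

    profile <- foldIndexProfile(seqStr, window = config@window)
    regions <- disorderedRegions(profile, minLength = config@minDRLength)
    if (!length(regions))
        return(.negativePrediction(id, "no disordered region", .emptyCandidates()))

    cand <- .emptyCandidates()
    for (k in seq_along(regions)) {
        drStart <- IRanges::start(regions)[k]
        drEnd <- IRanges::end(regions)[k]
        regionSeq <- substr(seqStr, drStart, drEnd)
        stretch <- longestQNStretch(regionSeq, threshold = config@qnThreshold)
        if (!length(stretch)) {
            cand <- rbind(cand, data.frame(
                dr_start = drStart, dr_end = drEnd,
                stretch_start = NA_integer_, stretch_end = NA_integer_,
                qn_fraction = NA_real_, core_start = NA_integer_,
                core_sequence = NA_character_, core_score = NA_real_,
                stringsAsFactors = FALSE))
            next
        }
        sStart <- drStart + IRanges::start(stretch)[1L] - 1L
        sEnd <- drStart + IRanges::end(stretch)[1L] - 1L
        stretchSeq <- substr(seqStr, sStart, sEnd)
        core <- findBestCore(stretchSeq, config@matrix)
        cand <- rbind(cand, data.frame(
            dr_start = drStart, dr_end = drEnd,
            stretch_start = sStart, stretch_end = sEnd,
            qn_fraction = S4Vectors::mcols(stretch)$qnFraction[1L],
            core_start = if (is.null(core)) NA_integer_ else
                sStart + core$start - 1L,
            core_sequence = if (is.null(core)) NA_character_ else core$sequence,
            core_score = if (is.null(core)) NA_real_ else core$score,
            stringsAsFactors = FALSE))
    }

    if (all(is.na(cand$stretch_start)))
        return(.negativePrediction(id, "no QN stretch", cand))
    if (all(is.na(cand$core_score)))
        return(.negativePrediction(id, "stretch too short", cand))

    best <- which.max(cand$core_score)  # leftmost region on score ties
    score <- cand$core_score[best]
    positive <- score >= config@pwaltzCutoff
    new("PrLDPrediction", id = id, positive = positive,
        reason = if (positive) NA_character_ else "core below cutoff",
        prldStart = cand$stretch_start[best], prldEnd = cand$stretch_end[best],
        prldSequence = substr(seqStr, cand$stretch_start[best],
                              cand$stretch_end[best]),
        coreStart = cand$core_start[best],
        coreSequence = cand$core_sequence[best],
        coreScore = score, candidates = cand)
}

#' Scan a batch of proteins
#'
#' Applies [scanProtein()] to every record, preserving input order. A record
#' that fails to scan is reported as a negative with reason `"scan error"`
#' (with a warning) and the batch continues. Batches larger than
#' `maxSequences` are rejected before any scanning.
#'
#' @param records a named `AAStringSet` (as returned by [readFasta()]) or a
#'   named character vector of sequences.
#' @param config a [ScanConfig-class].
#' @return A [PrLDScanResult-class].
#' @examples
#' cfg <- scanConfig(toyScoringMatrix("q"))
#' res <- scanBatch(c(polyQ = strrep("Q", 100), polyI = strrep("I", 120)), cfg)
#' res
#' @export
scanBatch <- function(records, config) {
    stopifnot(is(config, "ScanConfig"))
    ids <- names(records)
    seqs <- unname(as.character(records))
    n <- length(seqs)
    if (n > config@maxSequences)
        stop("batch-size error: ", n,
             " sequences exceed the maximum allowed (", config@maxSequences, ")")
    if (is.null(ids))
        ids <- paste0("seq", seq_len(n))
    preds <- vector("list", n)
    for (i in seq_len(n)) {
        preds[[i]] <- tryCatch(
            scanProtein(seqs[[i]], config, id = ids[[i]]),
            error = function(e) {
                warning("record '", ids[[i]], "' skipped: ",
                        conditionMessage(e))
                .negativePrediction(ids[[i]], "scan error", .emptyCandidates())
            })
    }
    new("PrLDScanResult", predictions = preds, config = config)
}

## ---- accessors and methods -------------------------------------------------

#' @rdname PrLDPrediction-class
#' @export
setMethod("isPositive", "PrLDPrediction", function(object) object@positive)

#' @rdname PrLDPrediction-class
#' @export
setMethod("reasonCode", "PrLDPrediction", function(object) object@reason)

#' @rdname PrLDPrediction-class
#' @export
setMethod("coreScore", "PrLDPrediction", function(object) object@coreScore)

#' @rdname PrLDPrediction-class
#' @export
setMethod("coreSequence", "PrLDPrediction", function(object) object@coreSequence)

#' @rdname PrLDPrediction-class
#' @export
setMethod("prldRange", "PrLDPrediction", function(object) {
    if (is.na(object@prldStart))
        return(IRanges::IRanges())
    IRanges::IRanges(start = object@prldStart, end = object@prldEnd)
})

#' @rdname PrLDPrediction-class
#' @export
setMethod("candidateTable", "PrLDPrediction", function(object) object@candidates)

setMethod("show", "PrLDPrediction", function(object) {
    cat("PrLDPrediction for '", object@id, "': ",
        if (object@positive) "POSITIVE" else
            paste0("negative (", object@reason, ")"), "\n", sep = "")
    if (!is.na(object@coreScore)) {
        cat(sprintf("  PrLD %d-%d, core %d-%d, score %.2f\n",
                    object@prldStart, object@prldEnd, object@coreStart,
                    object@coreStart + 20L, object@coreScore))
    }
})

#' @rdname PrLDScanResult-class
#' @export
setMethod("length", "PrLDScanResult", function(x) length(x@predictions))

#' @rdname PrLDScanResult-class
#' @export
setMethod("names", "PrLDScanResult", function(x)
    vapply(x@predictions, function(p) p@id, character(1L)))

#' @rdname PrLDScanResult-class
#' @param i index or id.
#' @export
setMethod("[[", "PrLDScanResult", function(x, i) {
    if (is.character(i))
        i <- match(i, names(x))
    x@predictions[[i]]
})

#' @rdname PrLDScanResult-class
#' @export
setMethod("isPositive", "PrLDScanResult", function(object)
    stats::setNames(vapply(object@predictions, isPositive, logical(1L)),
                    names(object)))

#' @rdname PrLDScanResult-class
#' @export
setMethod("bestScores", "PrLDScanResult", function(object)
    stats::setNames(vapply(object@predictions, coreScore, numeric(1L)),
                    names(object)))

#' @rdname PrLDScanResult-class
#' @export
setMethod("scanConfigOf", "PrLDScanResult", function(object) object@config)

#' @rdname PrLDScanResult-class
#' @export
setMethod("predictionTable", "PrLDScanResult", function(object) {
    do.call(rbind, lapply(object@predictions, function(p) data.frame(
        id = p@id, positive = p@positive, reason = p@reason,
        prld_start = p@prldStart, prld_end = p@prldEnd,
        core_start = p@coreStart, core_sequence = p@coreSequence,
        core_score = p@coreScore, stringsAsFactors = FALSE)))
})

setMethod("show", "PrLDScanResult", function(object) {
    pos <- sum(isPositive(object))
    cat("PrLDScanResult:", length(object), "sequences scanned,", pos,
        "positive\n")
    cat(sprintf("  qnThreshold %.2f, cutoff %.2f\n",
                object@config@qnThreshold, object@config@pwaltzCutoff))
    if (pos == 0L)
        cat("None of your sequences contains a predicted Prion-like Domain.\n")
})

setMethod("show", "ScanConfig", function(object) {
    cat("ScanConfig:\n")
    cat(sprintf("  window %d, minDRLength %d, qnThreshold %.2f, cutoff %.2f\n",
                object@window, object@minDRLength, object@qnThreshold,
                object@pwaltzCutoff))
    cat("  matrix:", object@matrix@provenance, "\n")
})
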