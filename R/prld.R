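#' Longest contiguous Q/N-enriched stretch
#'
#' Scans a (disordered-region) sequence for the longest contiguous substring
#' whose glutamine + asparagine fraction is at least `threshold`. Among
#' equal-length qualifying substrings the leftmost wins. With `threshold = 0`
#' every substring qualifies, so the whole region is returned. Returns an
#' empty `IRanges` when no substring of length >= 1 qualifies, which can only
#' happen when the region contains no Q/N and `threshold > 0`.
#'
#' When `threshold` corresponds to a whole percent (e.g. the 0.25 default),
#' the fraction comparison is done in exact integer arithmetic
#' (`100 * count >= percent * length`) to avoid floating-point
#' misclassification at the boundary; otherwise a 1e-9 tolerance is used.
#'
#' @param sequence amino-acid string (a region, not a whole proteome record).
#' @param threshold minimum Q/N fraction in \[0, 1\] (default 0.25).
#' @return An `IRanges` of length 0 or 1 with metadata column `qnFraction`.
#' @examples
#' longestQNStretch("AAQNQNQNAA", threshold = 0.5)
#' @export
longestQNStretch <- function(sequence, threshold = 0.25) {
    sequence <- .asSequenceString(sequence)
    n <- nchar(sequence)
    stopifnot(n >= 1L)
    if (threshold < 0 || threshold > 1)
        stop("'threshold' must lie in [0, 1]")

    qn <- strsplit(sequence, "", fixed = TRUE)[[1L]] %in% c("Q", "N")
    cs <- c(0L, cumsum(qn))

    pct <- threshold * 100
    exactPct <- abs(pct - round(pct)) < 1e-9
    pct <- round(pct)

    for (L in seq.int(n, 1L)) {
        starts <- seq_len(n - L + 1L)
        counts <- cs[starts + L] - cs[starts]
        ok <- if (exactPct) 100L * counts >= pct * L else
            counts >= threshold * L - 1e-9
        if (any(ok)) {
            s <- starts[which(ok)[1L]]
            out <- IRanges::IRanges(start = s, width = L)
            S4Vectors::mcols(out) <- S4Vectors::DataFrame(
                qnFraction = counts[which(ok)[1L]] / L)
            return(out)
        }
    }
    out <- IRanges::IRanges()
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(qnFraction = numeric())
    out
}

# Per-hexamer placement scores along a sequence; positions with ambiguity
# codes contribute the per-position minimum weight (with a warning upstream).
.placementScores <- function(residues, weights) {
    L <- nrow(weights)
    n <- length(residues)
    posMin <- apply(weights, 1L, min)
    colIdx <- match(residues, colnames(weights))
    vapply(seq_len(n - L + 1L), function(k) {
        idx <- colIdx[k:(k + L - 1L)]
        w <- weights[cbind(seq_len(L), idx)]
        w[is.na(idx)] <- posMin[is.na(idx)]
        sum(w)
    }, numeric(1L))
}

#' Score a 21-residue candidate amyloid core
#'
#' The raw score is the sum over all consecutive motif-length placements
#' (16 hexamer placements for a 6-position matrix) of the per-position
#' weights; it is min-max normalized to \[0, 100\] using the matrix's
#' analytical raw-score range. Ambiguity-coded residues score the
#' per-position minimum and trigger a warning.
#'
#' @param window a string of exactly 21 residues.
#' @param matrix a [ScoringMatrix-class].
#' @return Normalized score in \[0, 100\].
#' @export
scoreCore <- function(window, matrix) {
    window <- .asSequenceString(window)
    stopifnot(is(matrix, "ScoringMatrix"))
    if (nchar(window) != 21L)
        stop("core window must be exactly 21 residues, got ", nchar(window))
    residues <- strsplit(window, "", fixed = TRUE)[[1L]]
    if (any(!residues %in% colnames(matrix@weights)))
        warning("non-standard residues in core window score the per-position minimum")
    raw <- sum(.placementScores(residues, matrix@weights))
    100 * (raw - matrix@minRaw) / (matrix@maxRaw - matrix@minRaw)
}

#' Best-scoring 21-residue core within a stretch
#'
#' Slides a 21-residue window in single-residue steps over the stretch and
#' returns the maximally scoring window; ties are broken by the leftmost
#' start. Returns `NULL` when the stretch is shorter than 21 residues.
#'
#' @param sequence the stretch sequence.
#' @param matrix a [ScoringMatrix-class].
#' @return A list with `start` (1-based within the stretch), `sequence`
#'   (21 residues) and `score`, or `NULL`.
#' @export
findBestCore <- function(sequence, matrix) {
    sequence <- .asSequenceString(sequence)
    stopifnot(is(matrix, "ScoringMatrix"))
    n <- nchar(sequence)
    coreLen <- 21L
    if (n < coreLen)
        return(NULL)
    residues <- strsplit(sequence, "", fixed = TRUE)[[1L]]
    if (any(!residues %in% colnames(matrix@weights)))
        warning("non-standard residues score the per-position minimum")
    hex <- .placementScores(residues, matrix@weights)
    nPlace <- nrow(matrix@weights)
    perWindow <- coreLen - nPlace + 1L
    csHex <- c(0, cumsum(hex))
    starts <- seq_len(n - coreLen + 1L)
    raw <- csHex[starts + perWindow] - csHex[starts]
    score <- 100 * (raw - matrix@minRaw) / (matrix@maxRaw - matrix@minRaw)
    best <- which.max(score)  # which.max returns the first (leftmost) maximum
    list(start = starts[best],
         sequence = substr(sequence, starts[best], starts[best] + coreLen - 1L),
         score = score[best])
}
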