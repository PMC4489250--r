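#' Construct a position-specific scoring matrix for core scoring
#'
#' Builds a [ScoringMatrix-class] from a numeric weight matrix. The raw score
#' of a 21-residue window is the sum over all consecutive motif placements
#' (`21 - nrow(weights) + 1` of them) of the per-position weights; `minRaw`
#' and `maxRaw` are computed analytically: residue slot `i` of the 21-mer is
#' covered by a fixed set of matrix positions, so the extreme raw scores are
#' the sums over slots of the per-slot extreme residue contributions.
#'
#' @param weights numeric matrix: one row per motif position, one column per
#'   standard amino acid (one-letter codes; all 20 required).
#' @param provenance free-text note on the matrix origin.
#' @return A [ScoringMatrix-class].
#' @examples
#' m <- toyScoringMatrix("q")
#' rawScoreRange(m)
#' @export
ScoringMatrix <- function(weights, provenance = "user-supplied") {
    if (is.data.frame(weights))
        weights <- as.matrix(weights)
    if (!is.numeric(weights))
        stop("scoring-matrix weights must be numeric")
    missing <- setdiff(.STD_RESIDUES, colnames(weights))
    if (length(missing))
        stop("weights missing residue column(s): ", paste(missing, collapse = ", "))
    weights <- weights[, .STD_RESIDUES, drop = FALSE]
    rng <- .rawScoreRange(weights)
    new("ScoringMatrix", weights = weights, minRaw = rng[[1L]],
        maxRaw = rng[[2L]], provenance = provenance)
}

# Per-slot coverage: slot i of the 21-mer is read by matrix position p for
# every placement j with j + p - 1 == i, j in 1..(21 - L + 1).
.slotPositions <- function(i, motifLength, coreLength = 21L) {
    nPlace <- coreLength - motifLength + 1L
    pLo <- max(1L, i - nPlace + 1L)
    pHi <- min(motifLength, i)
    seq.int(pLo, pHi)
}

.rawScoreRange <- function(weights, coreLength = 21L) {
    L <- nrow(weights)
    if (L > coreLength)
        stop("motif length (", L, ") exceeds the core length (", coreLength, ")")
    lo <- hi <- 0
    for (i in seq_len(coreLength)) {
        contrib <- colSums(weights[.slotPositions(i, L, coreLength), , drop = FALSE])
        lo <- lo + min(contrib)
        hi <- hi + max(contrib)
    }
    list(lo, hi)
}

#' Read a scoring matrix from a TSV file
#'
#' Expects a tab-separated file with a header row naming the 20 standard
#' residues and one data row per matrix position.
#'
#' @param path path to the TSV file.
#' @param provenance origin note stored in the asset; defaults to the path.
#' @return A [ScoringMatrix-class].
#' @export
readScoringMatrix <- function(path, provenance = path) {
    tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                             colClasses = "numeric")
    if (nrow(tab) < 1L)
        stop("scoring-matrix file has no position rows: ", path)
    ScoringMatrix(as.matrix(tab), provenance = provenance)
}

#' Synthetic toy scoring matrices
#'
#' Deterministic toy matrices with analytically known score ranges, used to
#' validate the scanning pipeline independently of any externally derived
#' amyloid matrix:
#' \describe{
#'   \item{"q"}{weight 1 for Q at every position, 0 otherwise; a poly-Q
#'     21-mer scores 100, any Q-free window scores 0.}
#'   \item{"a"}{weight 1 for A at every position, 0 otherwise.}
#'   \item{"qn"}{weight 1 for Q and 0.5 for N at every position; grades cores
#'     by Q over N content.}
#' }
#'
#' @param type which toy matrix to build.
#' @param motifLength number of motif positions (default 6).
#' @return A [ScoringMatrix-class].
#' @export
toyScoringMatrix <- function(type = c("q", "a", "qn"), motifLength = 6L) {
    type <- match.arg(type)
    w <- matrix(0, nrow = motifLength, ncol = length(.STD_RESIDUES),
                dimnames = list(NULL, .STD_RESIDUES))
    if (type == "q") {
        w[, "Q"] <- 1
    } else if (type == "a") {
        w[, "A"] <- 1
    } else {
        w[, "Q"] <- 1
        w[, "N"] <- 0.5
    }
    ScoringMatrix(w, provenance = paste0("synthetic toy matrix '", type, "'"))
}

#' @rdname ScoringMatrix-class
#' @export
setMethod("scoringWeights", "ScoringMatrix", function(object) object@weights)

#' @rdname ScoringMatrix-class
#' @export
setMethod("rawScoreRange", "ScoringMatrix", function(object)
    c(min = object@minRaw, max = object@maxRaw))

setMethod("show", "ScoringMatrix", function(object) {
    cat("ScoringMatrix with", nrow(object@weights), "motif positions\n")
    cat("  raw 21-mer score range: [", format(object@minRaw), ", ",
        format(object@maxRaw), "]\n", sep = "")
    cat("  provenance:", object@provenance, "\n")
})
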