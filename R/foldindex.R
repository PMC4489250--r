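# Kyte-Doolittle hydropathy values for the 20 standard residues.
.KD <- c(A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
         Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
         L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
         S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)

# Scaled hydrophobicity in [0, 1]; ambiguity codes are imputed neutrally (0.5).
.scaledHydrophobicity <- function(residues) {
    h <- (.KD[residues] + 4.5) / 9
    h[is.na(h)] <- 0.5
    unname(h)
}

# Net charge at neutral pH: K/R +1, D/E -1, H and everything else 0.
.netCharge <- function(residues) {
    ch <- numeric(length(residues))
    ch[residues %in% c("K", "R")] <- 1
    ch[residues %in% c("D", "E")] <- -1
    ch
}

#' Per-residue fold-index disorder profile
#'
#' Computes a sliding-window fold index
#' \deqn{FI = 2.785 \langle H \rangle - |\langle R \rangle| - 1.151}
#' where \eqn{\langle H \rangle} is the mean Kyte-Doolittle hydrophobicity
#' rescaled to \[0, 1\] via `(KD + 4.5)/9` and \eqn{\langle R \rangle} is the
#' mean net charge over the window. Each full window assigns its value to the
#' central residue; terminal residues with no full window inherit the nearest
#' full-window value, keeping the averaging scale uniform. Sequences shorter
#' than the window receive a single whole-sequence value. Negative fold index
#' marks predicted disorder; 0 is classified ordered.
#'
#' @param sequence an amino-acid string, `AAString`, or length-1 `AAStringSet`.
#' @param window odd window length in residues, `>= 3` (default 51).
#' @return A [DisorderProfile-class].
#' @examples
#' prof <- foldIndexProfile(strrep("Q", 100))
#' head(foldIndexValues(prof))
#' @export
foldIndexProfile <- function(sequence, window = 51L) {
    sequence <- .asSequenceString(sequence)
    n <- nchar(sequence)
    if (n < 1L)
        stop("empty sequence")
    window <- as.integer(window)
    if (is.na(window) || window < 3L || window %% 2L == 0L)
        stop("'window' must be an odd integer >= 3")

    residues <- strsplit(sequence, "", fixed = TRUE)[[1L]]
    h <- .scaledHydrophobicity(residues)
    r <- .netCharge(residues)

    if (n < window) {
        fi <- 2.785 * mean(h) - abs(mean(r)) - 1.151
        values <- rep(fi, n)
    } else {
        csH <- c(0, cumsum(h))
        csR <- c(0, cumsum(r))
        starts <- seq_len(n - window + 1L)
        meanH <- (csH[starts + window] - csH[starts]) / window
        meanR <- (csR[starts + window] - csR[starts]) / window
        centerVals <- 2.785 * meanH - abs(meanR) - 1.151
        half <- (window - 1L) %/% 2L
        values <- c(rep(centerVals[1L], half),
                    centerVals,
                    rep(centerVals[length(centerVals)], half))
    }
    new("DisorderProfile", values = values, window = window,
        calls = values < 0)
}

#' Extract disordered regions from a fold-index profile
#'
#' Finds maximal runs of residues with negative fold index and keeps those of
#' at least `minLength` residues. Regions are returned left to right as an
#' `IRanges` (1-based inclusive) and are non-overlapping by construction.
#'
#' @param profile a [DisorderProfile-class].
#' @param minLength minimum region length in residues (default 60).
#' @return An [IRanges::IRanges] of disordered regions.
#' @export
disorderedRegions <- function(profile, minLength = 60L) {
    stopifnot(is(profile, "DisorderProfile"))
    calls <- profile@calls
    if (!length(calls) || !any(calls))
        return(IRanges::IRanges())
    rl <- rle(calls)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    keep <- rl$values & rl$lengths >= as.integer(minLength)
    IRanges::IRanges(start = starts[keep], end = ends[keep])
}

.asSequenceString <- function(x) {
    if (is(x, "AAStringSet")) {
        stopifnot(length(x) == 1L)
        x <- x[[1L]]
    }
    if (is(x, "XString"))
        x <- as.character(x)
    stopifnot(is.character(x), length(x) == 1L)
    toupper(x)
}

#' @rdname DisorderProfile-class
#' @export
setMethod("foldIndexValues", "DisorderProfile", function(object) object@values)

#' @rdname DisorderProfile-class
#' @export
setMethod("disorderCalls", "DisorderProfile", function(object) object@calls)

setMethod("show", "DisorderProfile", function(object) {
    n <- length(object@values)
    cat("DisorderProfile of", n, "residues (window ", object@window, ")\n",
        sep = "")
    cat(sprintf("  %d residues (%.1f%%) predicted disordered\n",
                sum(object@calls), 100 * mean(object@calls)))
})

setMethod("length", "DisorderProfile", function(x) length(x@values))
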