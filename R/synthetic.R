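# Run `expr` under a seeded RNG without disturbing the caller's RNG state.
.withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
    expr
}

#' Generate a disordered Q/N-enriched segment
#'
#' Builds a segment with an exact Q/N count of `round(qnFraction * length)`;
#' Q/N positions are drawn uniformly and the remaining positions are filled
#' from the disorder-promoting residues G, S and P (sampled with weights
#' 0.1/0.3/0.6, keeping the mean hydrophobicity low enough that every full
#' fold-index window over such a segment is called disordered with a wide
#' margin). Deterministic per seed.
#'
#' @param length segment length (>= 1).
#' @param qnFraction target Q/N fraction in \[0, 1\].
#' @param seed integer RNG seed.
#' @param qnResidues residues used for the enriched positions; defaults to
#'   both Q and N.
#' @return An amino-acid string.
#' @export
makeDisorderedQNSegment <- function(length, qnFraction, seed,
                                    qnResidues = c("Q", "N")) {
    stopifnot(length >= 1L, qnFraction >= 0, qnFraction <= 1,
              all(qnResidues %in% c("Q", "N")))
    nQN <- round(qnFraction * length)
    .withSeed(seed, {
        res <- sample(c("G", "S", "P"), length, replace = TRUE,
                      prob = c(0.1, 0.3, 0.6))
        if (nQN > 0L) {
            at <- sample.int(length, nQN)
            res[at] <- sample(qnResidues, nQN, replace = TRUE)
        }
        paste0(res, collapse = "")
    })
}

#' Generate an ordered flank segment
#'
#' Draws residues uniformly from the strongly hydrophobic, uncharged set
#' I, V, L, F, guaranteeing a positive fold index for every full window the
#' flank dominates.
#'
#' @param length flank length (>= 1).
#' @param seed integer RNG seed.
#' @return An amino-acid string.
#' @export
makeOrderedFlank <- function(length, seed) {
    stopifnot(length >= 1L)
    .withSeed(seed, paste0(sample(c("I", "V", "L", "F"), length,
                                  replace = TRUE), collapse = ""))
}

#' Generate a labeled synthetic dataset with known ground truth
#'
#' Builds a FASTA batch of positives and negatives whose classification under
#' the paired toy matrix is known by construction, for end-to-end validation
#' of the scanning pipeline:
#' \itemize{
#'   \item positives: ordered flank + disordered Q/N-rich segment with a
#'     planted 21-residue poly-Q core at its center + ordered flank. Under the
#'     Q-rewarding toy matrix the planted core scores 100.
#'   \item negatives, each violating exactly one requirement:
#'     `"ordered"` (hydrophobic sequence, no disordered region),
#'     `"lowqn"` (disordered region devoid of Q/N, no qualifying stretch),
#'     `"weakcore"` (disordered N-only enriched region whose best core scores
#'     0 under the Q-rewarding matrix).
#' }
#' Record ids encode the ground truth (`pos_*` / `neg_<kind>_*`). Output is
#' reproducible bit-for-bit per seed.
#'
#' @param nPositive,nNegative number of positive / negative records.
#' @param seed integer RNG seed.
#' @param drLength length of the planted disordered segment (default 120;
#'   with a 51-residue fold-index window, edge smoothing against the flanks
#'   erodes roughly 19 residues per side, so 120 keeps the detected region
#'   comfortably above the 60-residue minimum).
#' @param flankLength ordered flank length on each side (default 60).
#' @param qnFraction Q/N fraction of the enriched background (default 0.3).
#' @param negativeKinds kinds cycled over for the negatives.
#' @return A list with `sequences` (named character vector), `fasta` (FASTA
#'   text) and `labels` (named 0/1 vector).
#' @examples
#' ds <- makeLabeledDataset(nPositive = 2, nNegative = 2, seed = 42)
#' ds$labels
#' @export
makeLabeledDataset <- function(nPositive, nNegative, seed,
                               drLength = 120L, flankLength = 60L,
                               qnFraction = 0.3,
                               negativeKinds = c("ordered", "lowqn",
                                                 "weakcore")) {
    stopifnot(drLength >= 98L, flankLength >= 1L)
    negativeKinds <- match.arg(negativeKinds, several.ok = TRUE)
    coreLen <- 21L
    bgLeft <- (drLength - coreLen) %/% 2L
    bgRight <- drLength - coreLen - bgLeft

    seqs <- character(0L)
    labels <- integer(0L)
    subSeed <- seed
    nextSeed <- function() {
        subSeed <<- as.integer((as.numeric(subSeed) * 7 + 13) %% 2147483647)
        subSeed
    }

    for (i in seq_len(nPositive)) {
        dr <- paste0(
            makeDisorderedQNSegment(bgLeft, qnFraction, nextSeed(),
                                    qnResidues = "N"),
            strrep("Q", coreLen),
            makeDisorderedQNSegment(bgRight, qnFraction, nextSeed(),
                                    qnResidues = "N"))
        s <- paste0(makeOrderedFlank(flankLength, nextSeed()), dr,
                    makeOrderedFlank(flankLength, nextSeed()))
        id <- paste0("pos_core_", i)
        seqs[id] <- s
        labels[id] <- 1L
    }
    for (i in seq_len(nNegative)) {
        kind <- negativeKinds[(i - 1L) %% length(negativeKinds) + 1L]
        s <- switch(kind,
            ordered = makeOrderedFlank(2L * flankLength + drLength, nextSeed()),
            lowqn = paste0(makeOrderedFlank(flankLength, nextSeed()),
                           makeDisorderedQNSegment(drLength, 0, nextSeed()),
                           makeOrderedFlank(flankLength, nextSeed())),
            weakcore = paste0(makeOrderedFlank(flankLength, nextSeed()),
                              makeDisorderedQNSegment(drLength, qnFraction,
                                                      nextSeed(),
                                                      qnResidues = "N"),
                              makeOrderedFlank(flankLength, nextSeed())))
        id <- paste0("neg_", kind, "_", i)
        seqs[id] <- s
        labels[id] <- 0L
    }
    list(sequences = seqs, fasta = asFastaText(seqs), labels = labels)
}
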