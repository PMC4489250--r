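# Independent brute-force oracles, deliberately written as explicit loops so
# they share no code path with the package implementation.

# Fold index via an explicit per-window loop.
bruteForceFoldIndex <- function(sequence, window = 51L) {
    kd <- c(A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
            Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
            L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
            S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)
    res <- strsplit(sequence, "")[[1L]]
    n <- length(res)
    fiAt <- function(lo, hi) {
        hs <- numeric(0); ch <- numeric(0)
        for (k in lo:hi) {
            h <- if (res[k] %in% names(kd)) (kd[[res[k]]] + 4.5) / 9 else 0.5
            c1 <- if (res[k] %in% c("K", "R")) 1 else
                if (res[k] %in% c("D", "E")) -1 else 0
            hs <- c(hs, h); ch <- c(ch, c1)
        }
        2.785 * mean(hs) - abs(mean(ch)) - 1.151
    }
    if (n < window)
        return(rep(fiAt(1L, n), n))
    half <- (window - 1L) %/% 2L
    vals <- numeric(n)
    for (c0 in (half + 1L):(n - half)) vals[c0] <- fiAt(c0 - half, c0 + half)
    for (c0 in seq_len(half)) vals[c0] <- vals[half + 1L]
    for (c0 in (n - half + 1L):n) vals[c0] <- vals[n - half]
    vals
}

# Longest Q/N-qualifying substring by exhaustive enumeration of all (i, j).
bruteForceQNStretch <- function(sequence, threshold) {
    res <- strsplit(sequence, "")[[1L]]
    n <- length(res)
    best <- NULL
    for (i in seq_len(n)) {
        for (j in i:n) {
            cnt <- sum(res[i:j] %in% c("Q", "N"))
            len <- j - i + 1L
            if (cnt >= threshold * len - 1e-9) {
                if (is.null(best) || len > best$len)
                    best <- list(start = i, end = j, len = len,
                                 frac = cnt / len)
            }
        }
    }
    best
}

# Best 21-mer by an explicit loop of scoreCore calls.
bruteForceBestCore <- function(sequence, matrix) {
    n <- nchar(sequence)
    if (n < 21L) return(NULL)
    best <- NULL
    for (s in seq_len(n - 20L)) {
        sc <- scoreCore(substr(sequence, s, s + 20L), matrix)
        if (is.null(best) || sc > best$score)
            best <- list(start = s, score = sc)
    }
    best
}

# Random amino-acid sequence over the 20 standard residues.
randomProtein <- function(n, qnBias = 0.3) {
    std <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
             "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
    probs <- rep((1 - qnBias) / 18, 20)
    probs[std %in% c("Q", "N")] <- qnBias / 2
    paste0(sample(std, n, replace = TRUE, prob = probs), collapse = "")
}

toyQ <- toyScoringMatrix("q")
toyA <- toyScoringMatrix("a")
toyQN <- toyScoringMatrix("qn")
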