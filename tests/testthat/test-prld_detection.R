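test_that("longest Q/N stretch handles the documented boundary cases", {
    # homopolymer of Q: whole string, fraction 1
    s <- longestQNStretch("QQQQQQ", threshold = 0.25)
    expect_identical(IRanges::width(s), 6L)
    expect_equal(S4Vectors::mcols(s)$qnFraction, 1)
    # threshold 0: whole region regardless of content
    s <- longestQNStretch("AAAAILVF", threshold = 0)
    expect_identical(IRanges::width(s), 8L)
    # full string qualifies when its overall fraction does (55-substring check)
    s <- longestQNStretch("AAQNQNQNAA", threshold = 0.5)
    expect_identical(IRanges::start(s), 1L)
    expect_identical(IRanges::width(s), 10L)
    expect_equal(S4Vectors::mcols(s)$qnFraction, 0.6)
    # no Q/N present and positive threshold: no stretch
    expect_length(longestQNStretch("AAAA", threshold = 0.25), 0L)
    expect_error(longestQNStretch("AAQQ", threshold = 1.5), "0, 1")
})

test_that("exact percent arithmetic is used at the 25% boundary", {
    # 1 Q in 4 residues is exactly 25%: must qualify, not fall to float error
    s <- longestQNStretch("QAAA", threshold = 0.25)
    expect_identical(IRanges::width(s), 4L)
    # 1 Q in 5 residues (20%) must not stretch to length 5 at 25%
    s <- longestQNStretch("QAAAA", threshold = 0.25)
    expect_identical(IRanges::width(s), 4L)
})

test_that("stretch search agrees with exhaustive substring enumeration", {
    set.seed(5)
    for (rep in 1:8) {
        n <- sample(20:60, 1)
        s <- randomProtein(n, qnBias = runif(1, 0.1, 0.5))
        for (thr in c(0.25, 0.4)) {
            got <- longestQNStretch(s, threshold = thr)
            want <- bruteForceQNStretch(s, thr)
            if (is.null(want)) {
                expect_length(got, 0L)
            } else {
                expect_identical(IRanges::width(got), want$len)
                expect_identical(IRanges::start(got), want$start)
            }
        }
    }
})

test_that("raising the threshold never lengthens the stretch", {
    set.seed(9)
    for (rep in 1:5) {
        s <- randomProtein(80, qnBias = 0.35)
        widths <- vapply(c(0, 0.2, 0.4, 0.6, 0.8), function(thr) {
            st <- longestQNStretch(s, threshold = thr)
            if (length(st)) IRanges::width(st) else 0L
        }, integer(1))
        expect_true(all(diff(widths) <= 0L))
    }
})

test_that("core scoring matches brute-force hexamer placement sums", {
    # Q-rewarding toy matrix: poly-Q 21-mer raw = 16 placements x 6 = 96 = max
    expect_equal(scoreCore(strrep("Q", 21), toyQ), 100)
    expect_equal(scoreCore(strrep("A", 21), toyQ), 0)
    # graded matrix: all-N 21-mer sits midway between all-A and all-Q
    expect_equal(scoreCore(strrep("N", 21), toyQN), 50)
    expect_error(scoreCore("QQQ", toyQ), "21 residues")
    expect_warning(sc <- scoreCore(paste0(strrep("Q", 20), "X"), toyQ),
                   "non-standard")
    expect_true(sc >= 0 && sc <= 100)
    # any window under any valid matrix scores within [0, 100]
    set.seed(2)
    w <- matrix(rnorm(120), 6, dimnames = list(NULL, colnames(scoringWeights(toyQ))))
    m <- ScoringMatrix(w)
    scores <- vapply(1:50, function(i) scoreCore(randomProtein(21), m), 0)
    expect_true(all(scores >= -1e-9 & scores <= 100 + 1e-9))
})

test_that("best-core search slides a 21-mer and is leftmost on ties", {
    # stretch of exactly 21 residues: that window is the core
    core <- findBestCore(strrep("N", 21), toyQ)
    expect_identical(core$start, 1L)
    # shorter than 21: none
    expect_null(findBestCore(strrep("N", 20), toyQ))
    # planted poly-Q 21-mer at offset 31 (1-based) of an 80-residue poly-N
    s <- paste0(strrep("N", 30), strrep("Q", 21), strrep("N", 29))
    core <- findBestCore(s, toyQ)
    expect_identical(core$start, 31L)
    expect_identical(core$sequence, strrep("Q", 21))
    expect_equal(core$score, 100)
    # tie everywhere (homopolymer): leftmost window wins
    expect_identical(findBestCore(strrep("Q", 40), toyQ)$start, 1L)
})

test_that("best-core selection equals an explicit scoreCore loop", {
    set.seed(13)
    for (rep in 1:6) {
        s <- randomProtein(sample(21:120, 1), qnBias = 0.4)
        got <- findBestCore(s, toyQN)
        want <- bruteForceBestCore(s, toyQN)
        expect_identical(got$start, want$start)
        expect_equal(got$score, want$score, tolerance = 1e-9)
    }
})
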