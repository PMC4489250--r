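test_that("FASTA text parses into named records in input order", {
    aa <- readFasta(">s1 first record\nPQR\n>s2\nNN\nQQ")
    expect_s4_class(aa, "AAStringSet")
    expect_identical(names(aa), c("s1", "s2"))
    expect_identical(as.character(aa[[1]]), "PQR")
    expect_identical(as.character(aa[[2]]), "NNQQ")
    expect_identical(S4Vectors::mcols(aa)$description, c("first record", ""))
})

test_that("sequences are normalized: case, whitespace, digits, stop codons", {
    aa <- readFasta(">s1\n  pq r1\n2nn*\n")
    expect_identical(as.character(aa[[1]]), "PQRNN")
})

test_that("malformed input is rejected with informative errors", {
    expect_error(readFasta("PQR"), "before any '>' header")
    expect_error(readFasta("PQR\n>s1\nQQ"), "line 1")
    expect_error(readFasta(">s1\nPQ-R"), "gap")
    expect_error(readFasta(">s1\n\n>s2\nQQ"), "empty sequence")
    expect_error(readFasta(">s1\nPQ1R%"), "invalid residue")
})

test_that("ambiguity codes pass with a warning; duplicates get suffixes", {
    expect_warning(aa <- readFasta(">s1\nPQXR"), "non-standard")
    expect_identical(as.character(aa[[1]]), "PQXR")
    aa <- readFasta(">a\nQQ\n>a\nNN\n>a\nPP\n>b\nRR")
    expect_identical(names(aa), c("a", "a_2", "a_3", "b"))
})

test_that("batch size cap is enforced at parse time", {
    txt <- paste0(">s", 1:5, "\nQQ", collapse = "\n")
    expect_error(readFasta(txt, maxSequences = 4), "batch-size")
    expect_length(readFasta(txt, maxSequences = 5), 5)
})

test_that("parse/serialize round-trips id and sequence pairs", {
    set.seed(11)
    seqs <- setNames(vapply(1:8, function(i) randomProtein(30), ""),
                     paste0("rec", 1:8))
    aa <- readFasta(asFastaText(seqs))
    expect_identical(names(aa), names(seqs))
    expect_identical(unname(as.character(aa)), unname(seqs))
    # record count equals number of headers
    expect_identical(length(aa), lengths(regmatches(
        asFastaText(seqs), gregexpr(">", asFastaText(seqs))))[[1]])
})

test_that("prediction CSV has a header, positives only, ordered, 21-mer cores", {
    cfg <- scanConfig(toyQ)
    res <- scanBatch(c(a = strrep("Q", 100), b = strrep("I", 120),
                       c = strrep("Q", 90)), cfg)
    path <- withr::local_tempfile(fileext = ".csv")
    writePredictionsCSV(res, path)
    tab <- read.csv(path, colClasses = "character")
    expect_identical(nrow(tab), 2L)
    expect_identical(tab$id, c("a", "c"))
    expect_true(all(nchar(tab$core_sequence) == 21L))
    expect_true(all(grepl("^\\d+\\.\\d{2}$", tab$core_score)))
    # empty prediction list -> header-only file
    writePredictionsCSV(list(), path)
    empty <- read.csv(path)
    expect_identical(nrow(empty), 0L)
    expect_identical(ncol(empty), 7L)
})

test_that("label tables read as named 0/1 vectors", {
    path <- withr::local_tempfile(lines = c("p1\t1", "n1\t0"))
    lab <- readLabels(path)
    expect_identical(lab, c(p1 = 1L, n1 = 0L))
    bad <- withr::local_tempfile(lines = c("p1\t2"))
    expect_error(readLabels(bad), "0 or 1")
})

test_that("scoring-matrix loader computes the analytic score range", {
    path <- system.file("extdata", "toy_q_matrix.tsv", package = "prionScan")
    m <- readScoringMatrix(path)
    rng <- rawScoreRange(m)
    # brute-force evaluation of the 16 hexamer placements of a poly-Q 21-mer
    polyQraw <- sum(vapply(1:16, function(k) sum(rep(1, 6)), 0))
    expect_equal(unname(rng), c(0, polyQraw))
    expect_equal(scoreCore(strrep("Q", 21), m), 100)

    # extreme raws are achieved by per-slot argmin/argmax construction
    set.seed(3)
    w <- matrix(rnorm(120), nrow = 6,
                dimnames = list(NULL, colnames(scoringWeights(m))))
    rpath <- withr::local_tempfile()
    write.table(w, rpath, sep = "\t", quote = FALSE, row.names = FALSE)
    mr <- readScoringMatrix(rpath)
    scores <- vapply(1:200, function(i)
        scoreCore(randomProtein(21), mr), 0)
    expect_true(all(scores >= -1e-9 & scores <= 100 + 1e-9))
})

test_that("degenerate and malformed matrices are rejected", {
    zeros <- matrix(0, 6, 20,
                    dimnames = list(NULL, colnames(scoringWeights(toyQ))))
    zpath <- withr::local_tempfile()
    write.table(zeros, zpath, sep = "\t", quote = FALSE, row.names = FALSE)
    expect_error(readScoringMatrix(zpath), "degenerate")
    noW <- zeros[, colnames(zeros) != "W"]
    wpath <- withr::local_tempfile()
    write.table(noW, wpath, sep = "\t", quote = FALSE, row.names = FALSE)
    expect_error(readScoringMatrix(wpath), "W")
})
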