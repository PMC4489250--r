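#' Read protein sequences from FASTA text or file
#'
#' Parses FASTA input into an [Biostrings::AAStringSet] with record ids as
#' names and the remainder of each header in `mcols(x)$description`.
#' Sequences are upper-cased, whitespace and digits are removed, terminal stop
#' characters (`*`) are stripped, and alignment gaps (`-`) are rejected.
#' Ambiguity codes (B, Z, X, U, O, J) are accepted with a warning. Duplicate
#' ids are suffixed deterministically (`_2`, `_3`, ...) in input order.
#'
#' @param input either a path to a FASTA file or raw FASTA text (recognized by
#'   a leading `>` or an embedded newline).
#' @param maxSequences maximum number of records accepted in one batch
#'   (default 10000).
#' @return An `AAStringSet`, one element per record, in input order.
#' @examples
#' aa <- readFasta(">s1 demo\nPQR\n>s2\nNNQQ")
#' names(aa)
#' @export
readFasta <- function(input, maxSequences = 10000L) {
    stopifnot(is.character(input), length(input) >= 1L)
    if (length(input) == 1L && !grepl("[\n>]", input) && file.exists(input)) {
        lines <- readLines(input, warn = FALSE)
    } else {
        lines <- unlist(strsplit(input, "\n", fixed = TRUE), use.names = FALSE)
    }
    lines <- sub("\r$", "", lines)
    nonEmpty <- which(nzchar(trimws(lines)))
    if (!length(nonEmpty))
        stop("empty FASTA input")

    headerAt <- startsWith(trimws(lines), ">")
    firstHeader <- which(headerAt)[1L]
    if (is.na(firstHeader) || nonEmpty[1L] < firstHeader)
        stop("malformed FASTA: sequence data before any '>' header at line ",
             nonEmpty[1L], ": '", trimws(lines[nonEmpty[1L]]), "'")

    idx <- cumsum(headerAt)
    headers <- trimws(lines[headerAt])
    nRec <- length(headers)
    if (nRec > maxSequences)
        stop("batch-size error: ", nRec,
             " sequences exceed the maximum allowed (", maxSequences, ")")

    bare <- sub("^>", "", headers)
    ids <- sub("\\s.*$", "", bare)
    desc <- ifelse(grepl("\\s", bare), sub("^\\S+\\s+", "", bare), "")
    if (any(!nzchar(ids)))
        stop("malformed FASTA: empty record id in header '",
             headers[which(!nzchar(ids))[1L]], "'")

    seqLines <- !headerAt & nzchar(trimws(lines))
    seqs <- vapply(seq_len(nRec), function(k) {
        paste0(lines[seqLines & idx == k], collapse = "")
    }, character(1L))
    seqs <- toupper(gsub("[[:space:][:digit:]]", "", seqs))
    seqs <- sub("\\*+$", "", seqs)

    if (any(!nzchar(seqs)))
        stop("malformed FASTA: record '", ids[which(!nzchar(seqs))[1L]],
             "' has an empty sequence")
    if (any(grepl("-", seqs, fixed = TRUE)))
        stop("gap characters '-' are not allowed (record '",
             ids[grep("-", seqs, fixed = TRUE)[1L]], "')")
    allowed <- paste0(c(.STD_RESIDUES, .AMBIGUOUS_RESIDUES), collapse = "")
    bad <- grepl(paste0("[^", allowed, "]"), seqs)
    if (any(bad)) {
        chars <- gsub(paste0("[", allowed, "]"), "", seqs[bad][1L])
        stop("invalid residue character(s) '", chars, "' in record '",
             ids[bad][1L], "'")
    }
    hasAmbig <- grepl(paste0("[", paste0(.AMBIGUOUS_RESIDUES, collapse = ""), "]"),
                      seqs)
    if (any(hasAmbig))
        warning("non-standard residue codes (B/Z/X/U/O/J) in record(s): ",
                paste(utils::head(ids[hasAmbig], 5L), collapse = ", "),
                if (sum(hasAmbig) > 5L) ", ..." else "")

    if (anyDuplicated(ids)) {
        for (dup in unique(ids[duplicated(ids)])) {
            at <- which(ids == dup)
            ids[at[-1L]] <- paste0(dup, "_", seq_along(at)[-1L] )
        }
    }

    out <- Biostrings::AAStringSet(seqs)
    names(out) <- ids
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(description = desc)
    out
}

#' Write positive predictions to CSV
#'
#' Writes one row per positive prediction with 1-based inclusive coordinates:
#' sequence id, PrLD start/end and sequence, core start, the 21-residue core
#' sequence and its score rounded to 2 decimals. A header row is always
#' written; negative predictions are omitted.
#'
#' @param predictions a [PrLDScanResult-class] or a list of
#'   [PrLDPrediction-class] objects.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
writePredictionsCSV <- function(predictions, path) {
    if (is(predictions, "PrLDScanResult"))
        predictions <- predictions@predictions
    pos <- Filter(isPositive, predictions)
    rows <- lapply(pos, function(p) {
        data.frame(id = p@id,
                   prld_start = p@prldStart, prld_end = p@prldEnd,
                   prld_sequence = p@prldSequence,
                   core_start = p@coreStart,
                   core_sequence = p@coreSequence,
                   core_score = sprintf("%.2f", p@coreScore),
                   stringsAsFactors = FALSE)
    })
    tab <- if (length(rows)) do.call(rbind, rows) else
        data.frame(id = character(), prld_start = integer(),
                   prld_end = integer(), prld_sequence = character(),
                   core_start = integer(), core_sequence = character(),
                   core_score = character(), stringsAsFactors = FALSE)
    utils::write.csv(tab, path, row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}

#' Read a label table for benchmarking
#'
#' Expects a two-column tab-separated file, `id<TAB>label`, labels 0
#' (negative) or 1 (positive), without a header.
#'
#' @param path path to the TSV file.
#' @return Named integer vector of 0/1 labels.
#' @export
readLabels <- function(path) {
    tab <- utils::read.delim(path, header = FALSE, col.names = c("id", "label"),
                             colClasses = c("character", "integer"))
    if (!all(tab$label %in% c(0L, 1L)))
        stop("labels must be 0 or 1")
    if (anyDuplicated(tab$id))
        stop("duplicate ids in label file")
    stats::setNames(tab$label, tab$id)
}

#' Serialize records back to FASTA text
#'
#' @param x a named `AAStringSet` or named character vector.
#' @return A single FASTA-formatted string.
#' @export
asFastaText <- function(x) {
    ids <- names(x)
    seqs <- unname(as.character(x))
    stopifnot(!is.null(ids))
    paste0(paste0(">", ids, "\n", seqs, collapse = "\n"), "\n")
}
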