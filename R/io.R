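#' Read RNA sequences from a FASTA file
#'
#' Multi-record, wrapped-line FASTA via \pkg{Biostrings}, followed by this
#' package's normalization (case raised, \code{T} read as \code{U}) and
#' fail-fast validation: any residue outside \code{AUGCT} (for example an
#' IUPAC ambiguity code) is a parse error reporting the offending line
#' number rather than a silently unpairable base.
#'
#' @param path FASTA file path
#' @return a list of [RNASequence-class], in file order
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">toy", "gcgc"), fa)
#' readRnaFasta(fa)
#' @export
readRnaFasta <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
    set <- tryCatch(Biostrings::readBStringSet(path),
                    error = function(e)
                        stop("malformed FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE))
    if (length(set) == 0L)
        stop("empty FASTA file: ", path, call. = FALSE)
    lapply(seq_along(set), function(i) {
        txt <- as.character(set[[i]])
        name <- names(set)[i]
        tryCatch(rnaSequence(txt, name = name), error = function(e) {
            lines <- readLines(path, warn = FALSE)
            badpat <- "[^ACGUTacgut[:space:]>]"
            hit <- grep(badpat, lines)
            hit <- hit[!startsWith(trimws(lines[hit]), ">")]
            where <- if (length(hit)) sprintf(" (line %d)", hit[1]) else ""
            stop("record '", name, "'", where, ": ",
                 conditionMessage(e), call. = FALSE)
        })
    })
}

#' Fold every record of a FASTA file
#'
#' @param path FASTA file path
#' @param engine folding engine (see [foldEngine()])
#' @param traceback also compute dot-bracket structures (default TRUE)
#' @param ... passed to the tiled engine
#' @return a list of records, each a list with \code{sequence}
#'   ([RNASequence-class]), \code{matrix} ([NussinovMatrix-class]), and
#'   (if requested) \code{structure} ([SecondaryStructure-class])
#' @export
foldFasta <- function(path, engine = "reference", traceback = TRUE, ...) {
    lapply(readRnaFasta(path), function(s) {
        m <- foldEngine(s, engine, ...)
        rec <- list(sequence = s, matrix = m)
        if (traceback) rec$structure <- tracebackStructure(m)
        rec
    })
}

#' Write folding results
#'
#' Vienna layout per record: a \code{>name} header, the sequence line, then
#' the dot-bracket line.
#'
#' @param records output of [foldFasta()] (with traceback)
#' @param file connection or path; \code{""} prints to stdout
#' @return invisibly, the character vector written
#' @export
writeFoldResults <- function(records, file = "") {
    out <- unlist(lapply(records, function(r) {
        c(paste0(">", seqName(r$sequence)),
          residues(r$sequence),
          dotBracket(r$structure))
    }))
    if (is.character(file) && !nzchar(file)) file <- stdout()
    writeLines(out, con = file)
    invisible(out)
}

#' Summary table of folding results
#'
#' @param records output of [foldFasta()]
#' @return data.frame with columns name, length, score
#' @export
foldResultsTable <- function(records) {
    data.frame(
        name = vapply(records, function(r) seqName(r$sequence), ""),
        length = vapply(records, function(r) length(r$sequence), 1L),
        score = vapply(records, function(r) maxPairs(r$matrix), 1L))
}
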