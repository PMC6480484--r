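#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib SpaceTimeFold, .registration = TRUE
NULL

RNA_ALPHABET <- c("A", "C", "G", "U")

#' Validated RNA sequence
#'
#' A plain nucleotide string over \code{A}, \code{C}, \code{G}, \code{U}
#' together with a free-text identifier.  Construct with
#' \code{\link{rnaSequence}}, which normalizes case and DNA-style \code{T}
#' to \code{U} and rejects anything else (including IUPAC ambiguity codes:
#' scoring them silently as unpairable would hide input errors).
#'
#' @slot residues single character string over \code{AUGC}
#' @slot name identifier (may be empty)
#' @seealso [rnaSequence()], [readRnaFasta()], [randomRna()]
#' @exportClass RNASequence
setClass("RNASequence",
    representation(residues = "character", name = "character"))

setValidity("RNASequence", function(object) {
    if (length(object@residues) != 1L || is.na(object@residues))
        return("'residues' must be a single string")
    if (nchar(object@residues) < 1L)
        return("sequence must contain at least one residue")
    bad <- setdiff(unique(strsplit(object@residues, "")[[1]]), RNA_ALPHABET)
    if (length(bad))
        return(sprintf("invalid residue(s): %s (alphabet is A, C, G, U)",
                       paste(bad, collapse = ", ")))
    if (length(object@name) != 1L)
        return("'name' must be a single string")
    TRUE
})

#' Construct an RNASequence
#'
#' @param residues character string of nucleotides; lower case is raised and
#'   \code{T}/\code{t} is read as \code{U}.  Any other character is an error.
#' @param name sequence identifier.
#' @return an [RNASequence-class] object.
#' @examples
#' rnaSequence("acgu")
#' rnaSequence("GCGCTT", name = "dna-style input")
#' @export
rnaSequence <- function(residues, name = "") {
    if (is(residues, "RNASequence")) return(residues)
    stopifnot(is.character(residues), length(residues) == 1L)
    res <- chartr("acgut", "ACGUU", residues)
    res <- chartr("T", "U", res)
    new("RNASequence", residues = res, name = as.character(name))
}

#' @describeIn RNASequence-class number of residues
#' @param x an \code{RNASequence}
#' @export
setMethod("length", "RNASequence", function(x) nchar(x@residues))

#' Residues of an RNA sequence
#' @param x an [RNASequence-class]
#' @param as.vector return a character vector of single bases instead of one
#'   string
#' @return character
#' @export
residues <- function(x, as.vector = FALSE) {
    stopifnot(is(x, "RNASequence"))
    if (as.vector) strsplit(x@residues, "")[[1]] else x@residues
}

#' Name of a sequence
#' @param x an [RNASequence-class]
#' @export
seqName <- function(x) x@name

setMethod("show", "RNASequence", function(object) {
    n <- length(object)
    head <- if (n > 60) paste0(substr(object@residues, 1, 57), "...")
            else object@residues
    cat(sprintf("RNASequence %s(%d nt): %s\n",
        if (nzchar(object@name)) paste0("'", object@name, "' ") else "",
        n, head))
})

#' Nussinov score matrix
#'
#' The completed N x N dynamic-programming matrix \eqn{S}: the upper
#' triangle \eqn{j > i} holds the maximum number of non-crossing
#' complementary pairs within the subsequence \eqn{x_i..x_j} (0-based);
#' \code{S[1, N]} (R indexing) is the optimum for the whole strand.  The
#' transpose engine additionally fills the lower triangle with the mirror
#' \eqn{S[j, i] = S[i, j]}; the other engines leave it zero.
#'
#' @slot score integer matrix
#' @slot sequence the folded [RNASequence-class]
#' @slot engine which engine produced it ("reference", "transpose", "tiled")
#' @seealso [foldReference()], [foldTranspose()], [foldTiled()],
#'   [tracebackStructure()]
#' @exportClass NussinovMatrix
setClass("NussinovMatrix",
    representation(score = "matrix", sequence = "RNASequence",
                   engine = "character"))

setValidity("NussinovMatrix", function(object) {
    n <- length(object@sequence)
    if (!is.integer(object@score)) return("score matrix must be integer")
    if (!all(dim(object@score) == c(n, n)))
        return("score matrix dimensions must equal the sequence length")
    TRUE
})

#' Score matrix accessor
#' @param x a [NussinovMatrix-class]
#' @return the integer matrix S
#' @export
scoreMatrix <- function(x) {
    stopifnot(is(x, "NussinovMatrix"))
    x@score
}

#' Optimal pair count
#'
#' \code{S[0, N-1]} in 0-based terms: the maximum number of non-crossing
#' AU/GC/GU pairs over the full sequence.
#' @param x a [NussinovMatrix-class]
#' @return integer
#' @export
maxPairs <- function(x) {
    stopifnot(is(x, "NussinovMatrix"))
    n <- ncol(x@score)
    if (n < 2L) 0L else x@score[1L, n]
}

#' @describeIn NussinovMatrix-class the sequence that was folded
#' @param x a \code{NussinovMatrix}
#' @export
foldedSequence <- function(x) x@sequence

setMethod("show", "NussinovMatrix", function(object) {
    cat(sprintf("NussinovMatrix (%s engine): %d x %d, max pairs %d\n",
        object@engine, ncol(object@score), ncol(object@score),
        maxPairs(object)))
})

#' RNA secondary structure (non-crossing pairing)
#'
#' A set of base pairs produced by [tracebackStructure()], stored both as a
#' two-column matrix of 1-based paired positions (i < j) and as a Vienna
#' dot-bracket string.
#'
#' @slot pairs integer matrix, columns \code{i}, \code{j}, 1-based, i < j
#' @slot dotbracket string over \code{(}, \code{)}, \code{.}
#' @slot sequence the underlying [RNASequence-class]
#' @exportClass SecondaryStructure
setClass("SecondaryStructure",
    representation(pairs = "matrix", dotbracket = "character",
                   sequence = "RNASequence"))

setValidity("SecondaryStructure", function(object) {
    n <- length(object@sequence)
    if (nchar(object@dotbracket) != n)
        return("dot-bracket length must equal sequence length")
    p <- object@pairs
    if (nrow(p)) {
        if (any(p[, 1] >= p[, 2])) return("pairs must satisfy i < j")
        if (any(p < 1L) || any(p > n)) return("pair index out of range")
        idx <- as.vector(p)
        if (anyDuplicated(idx)) return("a position occurs in two pairs")
    }
    if (sum(strsplit(object@dotbracket, "")[[1]] == "(") != nrow(p))
        return("dot-bracket '(' count must equal the number of pairs")
    TRUE
})

#' Base pairs of a structure
#' @param x a [SecondaryStructure-class]
#' @return two-column integer matrix of 1-based positions
#' @export
basePairs <- function(x) {
    stopifnot(is(x, "SecondaryStructure"))
    x@pairs
}

#' Dot-bracket string of a structure
#' @param x a [SecondaryStructure-class]
#' @export
dotBracket <- function(x) {
    stopifnot(is(x, "SecondaryStructure"))
    x@dotbracket
}

setMethod("show", "SecondaryStructure", function(object) {
    cat(sprintf("SecondaryStructure: %d pairs\n", nrow(object@pairs)))
    cat(residues(object@sequence), "\n")
    cat(object@dotbracket, "\n")
})

#' Space-time tiling parameters
#'
#' Widths of the two space bands and of the time slice for a problem size
#' \code{n}.  \code{ws} bounds a tile along the row index i and along the
#' anti-diagonal d = j - i; \code{wt} bounds it along the split index k (and
#' along j for the pairing statement), so every tile is finite in all three
#' loop dimensions regardless of \code{n}.  The defaults (16, 16) are the
#' widths used throughout the tiled executor's documentation and benchmarks;
#' any positive widths are legal.
#'
#' @slot ws space band width (>= 1)
#' @slot wt time slice width (>= 1)
#' @slot n sequence length the tiling is laid over (>= 2)
#' @seealso [tilingParams()], [enumerateTiles()], [validateSchedule()]
#' @exportClass TilingParams
setClass("TilingParams",
    representation(ws = "integer", wt = "integer", n = "integer"))

setValidity("TilingParams", function(object) {
    if (object@ws < 1L) return("ws must be >= 1")
    if (object@wt < 1L) return("wt must be >= 1")
    if (object@n < 2L) return("n must be >= 2 (no pairable cell otherwise)")
    TRUE
})

#' Construct tiling parameters
#' @param n sequence length (>= 2)
#' @param ws space band width, default 16
#' @param wt time slice width, default 16
#' @return a [TilingParams-class]
#' @examples
#' tilingParams(40, ws = 16, wt = 16)
#' @export
tilingParams <- function(n, ws = 16, wt = 16) {
    new("TilingParams", ws = as.integer(ws), wt = as.integer(wt),
        n = as.integer(n))
}

setMethod("show", "TilingParams", function(object) {
    cat(sprintf("TilingParams: N = %d, Ws = %d, Wt = %d\n",
        object@n, object@ws, object@wt))
})

#' Box iteration space with constant dependence distance vectors
#'
#' The schedule laboratory's input: a d-dimensional box
#' \eqn{[0,n_1) x ... x [0,n_d)} plus a list of integer distance vectors,
#' each lexicographically positive (destination after source under the box's
#' ascending lexicographic iteration order).
#'
#' @slot dims integer extents
#' @slot dvs matrix with one distance vector per row
#' @seealso [depBox()], [freeSchedule()]
#' @exportClass DepBox
setClass("DepBox", representation(dims = "integer", dvs = "matrix"))

setValidity("DepBox", function(object) {
    if (any(object@dims < 1L)) return("all box extents must be >= 1")
    if (ncol(object@dvs) != length(object@dims))
        return("distance vectors must match the box dimensionality")
    lexpos <- apply(object@dvs, 1L, function(v) {
        nz <- which(v != 0)
        length(nz) > 0 && v[nz[1]] > 0
    })
    if (!all(lexpos))
        return("every distance vector must be lexicographically positive")
    TRUE
})

#' Construct a dependence box
#' @param dims integer vector of extents, box is `[0, dims[1]) x ...`
#' @param dvs list of integer vectors (or a matrix with one vector per row)
#' @return a [DepBox-class]
#' @examples
#' depBox(c(3, 3, 3), list(c(0, 0, 1), c(0, 1, 0), c(1, 0, -1)))
#' @export
depBox <- function(dims, dvs) {
    if (is.list(dvs)) dvs <- do.call(rbind, dvs)
    storage.mode(dvs) <- "integer"
    new("DepBox", dims = as.integer(dims), dvs = dvs)
}

setMethod("show", "DepBox", function(object) {
    cat(sprintf("DepBox: [%s] with %d distance vector(s)\n",
        paste0("0,", object@dims, collapse = ") x ["), nrow(object@dvs)))
})

#' Earliest-start time partitioning of a box
#'
#' Result of [freeSchedule()]: each point of the box is assigned the length
#' of the longest dependence chain reaching it; points with equal time form
#' a partition whose members are mutually independent.
#'
#' @slot box the [DepBox-class] it was computed on
#' @slot points integer matrix of all box points in lexicographic order
#' @slot t integer vector, \code{t[p]} for each row of \code{points}
#' @seealso [partitionSets()], [timeSlices()], [checkSliceLegality()]
#' @exportClass TimePartitioning
setClass("TimePartitioning",
    representation(box = "DepBox", points = "matrix", t = "integer"))

setMethod("show", "TimePartitioning", function(object) {
    cat(sprintf("TimePartitioning: %d points, partitions t0..t%d\n",
        nrow(object@points), max(object@t)))
})

#' Benchmark configuration
#'
#' The harness protocol: random strands at each length (one per repeat,
#' derived deterministically from \code{seed}) folded by each engine at each
#' width/thread setting.  Default lengths 2500..15000 follow the standard
#' large-strand protocol for cache studies of this kernel; tests and examples
#' pass smaller ones.
#'
#' @slot lengths integer strand lengths
#' @slot widths list of c(ws, wt) pairs for the tiled engine
#' @slot threads integer thread counts
#' @slot seed master seed
#' @slot repeats repeats per cell (median is reported)
#' @slot verifyCap lengths up to this are re-folded with the reference
#'   engine and checked elementwise
#' @seealso [benchConfig()], [runBench()]
#' @exportClass BenchConfig
setClass("BenchConfig",
    representation(lengths = "integer", widths = "list", threads = "integer",
                   seed = "integer", repeats = "integer",
                   verifyCap = "integer"))

setValidity("BenchConfig", function(object) {
    if (any(object@lengths < 1L)) return("lengths must be positive")
    if (any(object@threads < 1L)) return("threads must be positive")
    if (object@repeats < 1L) return("repeats must be positive")
    if (!all(vapply(object@widths, length, 1L) == 2L))
        return("each widths entry must be c(ws, wt)")
    TRUE
})

#' Construct a benchmark configuration
#' @param lengths strand lengths
#' @param widths list of \code{c(ws, wt)} tile widths
#' @param threads thread counts to sweep
#' @param seed master seed; the same seed always yields the same strands
#' @param repeats timed repeats per cell
#' @param verifyCap verification length cap (reference re-fold), default 1000
#' @return a [BenchConfig-class]
#' @export
benchConfig <- function(lengths = c(2500, 5000, 7500, 10000, 12500, 15000),
                        widths = list(c(16, 16)), threads = 1L, seed = 1L,
                        repeats = 1L, verifyCap = 1000L) {
    new("BenchConfig", lengths = as.integer(lengths), widths = widths,
        threads = as.integer(threads), seed = as.integer(seed),
        repeats = as.integer(repeats), verifyCap = as.integer(verifyCap))
}
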