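#' Pairing indicator sigma
#'
#' Returns 1 if the two nucleotides form an AU, GC or GU (wobble) pair,
#' in either order, and 0 otherwise.  Vectorized over both arguments.
#'
#' @param a,b nucleotides (single characters; lower case and \code{T} are
#'   normalized first).  Non-nucleotide input is an error.
#' @return integer vector of 0/1
#' @examples
#' sigmaPair("A", "U")  # 1
#' sigmaPair("U", "G")  # 1, wobble is unordered
#' sigmaPair("A", "G")  # 0
#' @export
sigmaPair <- function(a, b) {
    a <- normalizeBases(a)
    b <- normalizeBases(b)
    key <- paste0(pmin(a, b), pmax(a, b))
    as.integer(key %in% c("AU", "CG", "GU"))
}

normalizeBases <- function(x) {
    x <- chartr("acgut", "ACGUU", as.character(x))
    x <- chartr("T", "U", x)
    bad <- setdiff(unique(x), RNA_ALPHABET)
    if (length(bad))
        stop("invalid nucleotide(s): ", paste(bad, collapse = ", "),
             call. = FALSE)
    x
}

# 0-based integer codes for the C++ kernels: A=0, C=1, G=2, U=3
encodeSeq <- function(x) {
    x <- rnaSequence(x)
    match(residues(x, as.vector = TRUE), RNA_ALPHABET) - 1L
}

asRnaInput <- function(x) if (is(x, "RNASequence")) x else rnaSequence(x)

#' Fold with the reference engine
#'
#' Fills the Nussinov matrix in the original loop order: the row index i
#' descends, j ascends, and for each cell all split candidates
#' \eqn{S[i][i+k] + S[i+k+1][j]} (k ascending) are applied before the
#' pairing candidate \eqn{S[i+1][j-1] + \sigma(x_i, x_j)}.  There is no
#' minimum hairpin-loop length: adjacent bases may pair, exactly as the
#' recurrence allows (many thermodynamic folders forbid such sharp turns;
#' this maximum-matching model does not).
#'
#' @param x an [RNASequence-class] or a character string
#' @return a [NussinovMatrix-class]
#' @examples
#' m <- foldReference("GCGC")
#' maxPairs(m)  # 2
#' @seealso [foldTranspose()], [foldTiled()], [tracebackStructure()]
#' @export
foldReference <- function(x) {
    x <- asRnaInput(x)
    new("NussinovMatrix", score = nussinov_ref_cpp(encodeSeq(x)),
        sequence = x, engine = "reference")
}

#' Fold with the transpose (cache-friendly) engine
#'
#' Same recurrence and result as [foldReference()], but the lower triangle
#' stores the transpose of finished cells so the split sum reads two
#' row-contiguous operands (\eqn{S[i][i+k] + S[j][i+k+1]}), which is far
#' kinder to the cache than walking a column.  The returned matrix has the
#' mirror in its lower triangle.
#'
#' @inheritParams foldReference
#' @return a [NussinovMatrix-class]
#' @export
foldTranspose <- function(x) {
    x <- asRnaInput(x)
    new("NussinovMatrix", score = nussinov_transpose_cpp(encodeSeq(x)),
        sequence = x, engine = "transpose")
}

#' Fold with the space-time tiled engine
#'
#' Executes the same statement bodies as [foldReference()] under the tiled
#' wavefront schedule: wavefronts \eqn{w = ii + jj} run serially; the space
#' tiles within a wavefront are mutually independent and may run in any
#' order or concurrently; inside a tile the anti-diagonal, the time slice,
#' and then the instances run in schedule-tuple order.  The result is
#' elementwise equal to the reference engine for every sequence and any
#' positive widths.
#'
#' @inheritParams foldReference
#' @param ws,wt space and time widths (see [TilingParams-class])
#' @param threads number of OpenMP threads for same-wavefront tiles
#' @param shuffle randomly permute same-wavefront tile order (used to
#'   demonstrate order-independence; the result must not change)
#' @param seed seed for the shuffle permutations only
#' @return a [NussinovMatrix-class]
#' @examples
#' m <- foldTiled("GCGC", ws = 2, wt = 2)
#' identical(scoreMatrix(m), scoreMatrix(foldReference("GCGC")))
#' @export
foldTiled <- function(x, ws = 16, wt = 16, threads = 1, shuffle = FALSE,
                      seed = 1) {
    x <- asRnaInput(x)
    stopifnot(ws >= 1, wt >= 1, threads >= 1)
    new("NussinovMatrix",
        score = nussinov_tiled_cpp(encodeSeq(x), as.integer(ws),
                                   as.integer(wt), as.integer(threads),
                                   isTRUE(shuffle), as.integer(seed)),
        sequence = x, engine = "tiled")
}

#' Fold with a named engine
#' @param x sequence input
#' @param engine one of "reference", "transpose", "tiled"
#' @param ... passed to [foldTiled()] when engine = "tiled"
#' @return a [NussinovMatrix-class]
#' @export
foldEngine <- function(x, engine = c("reference", "transpose", "tiled"),
                       ...) {
    switch(match.arg(engine),
        reference = foldReference(x),
        transpose = foldTranspose(x),
        tiled = foldTiled(x, ...))
}

#' Traceback to a secondary structure
#'
#' Recovers one optimal non-crossing pairing from a completed score matrix.
#' Deterministic tie-break: at each cell the pairing case
#' \eqn{S[i+1][j-1] + \sigma} is preferred whenever it attains the maximum,
#' otherwise the smallest split k attaining it is taken.  The pair count
#' always equals [maxPairs()].
#'
#' @param x a [NussinovMatrix-class] (from any engine)
#' @return a [SecondaryStructure-class]
#' @examples
#' dotBracket(tracebackStructure(foldReference("GC")))  # "()"
#' @export
tracebackStructure <- function(x) {
    stopifnot(is(x, "NussinovMatrix"))
    S <- x@score
    n <- ncol(S)
    bases <- residues(x@sequence, as.vector = TRUE)
    pairs <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("i", "j")))
    if (n >= 2) {
        stack <- list(c(0L, n - 1L))            # 0-based [i, j]
        while (length(stack)) {
            ij <- stack[[length(stack)]]
            stack[[length(stack)]] <- NULL
            i <- ij[1]; j <- ij[2]
            if (i >= j) next
            target <- S[i + 1L, j + 1L]
            if (target == 0L) next
            inner <- if (i + 1L <= j - 1L) S[i + 2L, j] else 0L
            sig <- sigmaPair(bases[i + 1L], bases[j + 1L])
            if (inner + sig == target) {         # pairing case preferred
                if (sig == 1L)
                    pairs <- rbind(pairs, c(i + 1L, j + 1L))
                stack[[length(stack) + 1L]] <- c(i + 1L, j - 1L)
                next
            }
            done <- FALSE
            for (k in 0:(j - i - 1L)) {          # smallest split k
                if (S[i + 1L, i + k + 1L] + S[i + k + 2L, j + 1L] == target) {
                    stack[[length(stack) + 1L]] <- c(i, i + k)
                    stack[[length(stack) + 1L]] <- c(i + k + 1L, j)
                    done <- TRUE
                    break
                }
            }
            if (!done)
                stop("inconsistent score matrix: no case attains S[",
                     i, "][", j, "]", call. = FALSE)
        }
    }
    db <- rep(".", n)
    if (nrow(pairs)) {
        db[pairs[, 1]] <- "("
        db[pairs[, 2]] <- ")"
        pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
    }
    new("SecondaryStructure", pairs = pairs,
        dotbracket = paste(db, collapse = ""), sequence = x@sequence)
}
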