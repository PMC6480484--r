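#' Random RNA strand
#'
#' Uniform i.i.d. bases over \code{A, U, G, C}, reproducible per
#' \code{(length, seed)} and independent of (and not disturbing) the
#' global RNG state.  Cache behaviour of the folding engines depends only
#' on the strand length, not its content, so uniformly random strands are
#' the standard benchmark input for this kernel.
#'
#' @param length strand length (>= 1)
#' @param seed integer seed
#' @param name identifier for the generated sequence
#' @return an [RNASequence-class]
#' @examples
#' identical(residues(randomRna(8, 42)), residues(randomRna(8, 42)))
#' @export
randomRna <- function(length, seed = 1L,
                      name = sprintf("random_L%d_s%d", length, seed)) {
    stopifnot(length >= 1)
    bases <- withLocalSeed(seed, sample(RNA_ALPHABET, length, replace = TRUE))
    rnaSequence(paste(bases, collapse = ""), name = name)
}

# run expr under a private RNG stream, restoring .Random.seed afterwards
withLocalSeed <- function(seed, expr) {
    env <- globalenv()
    old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
        get(".Random.seed", envir = env) else NULL
    on.exit({
        if (is.null(old)) rm(".Random.seed", envir = env)
        else assign(".Random.seed", old, envir = env)
    })
    set.seed(seed)
    expr
}

#' Run the engine benchmark
#'
#' For each length a strand is drawn per repeat (deterministically from the
#' config seed), then every engine x width x thread cell is timed; the
#' median wall time over repeats is reported.  For lengths up to
#' \code{verifyCap} each engine's matrix is checked elementwise against the
#' reference engine; a mismatch aborts naming the offending cell.  Timings
#' are machine-dependent and are reported, never asserted.
#'
#' @param cfg a [BenchConfig-class]
#' @param engines subset of c("reference", "transpose", "tiled")
#' @param quiet suppress progress messages
#' @return data.frame: engine, length, ws, wt, threads, median_s, verified
#' @examples
#' cfg <- benchConfig(lengths = c(60, 120), widths = list(c(8, 8)), seed = 7)
#' runBench(cfg, quiet = TRUE)
#' @export
runBench <- function(cfg, engines = c("reference", "transpose", "tiled"),
                     quiet = FALSE) {
    stopifnot(is(cfg, "BenchConfig"))
    engines <- match.arg(engines, several.ok = TRUE)
    rows <- list()
    for (len in cfg@lengths) {
        seqs <- lapply(seq_len(cfg@repeats), function(r)
            randomRna(len, seed = cfg@seed + 1000L * r))
        refs <- if (len <= cfg@verifyCap)
            lapply(seqs, function(s) scoreMatrix(foldReference(s))) else NULL
        for (eng in engines) {
            grid <- if (eng == "tiled")
                expand.grid(w = seq_along(cfg@widths),
                            th = cfg@threads)
            else data.frame(w = NA_integer_, th = cfg@threads[1])
            for (g in seq_len(nrow(grid))) {
                wpair <- if (eng == "tiled") cfg@widths[[grid$w[g]]]
                         else c(NA_integer_, NA_integer_)
                times <- numeric(cfg@repeats)
                verified <- NA
                for (r in seq_len(cfg@repeats)) {
                    t0 <- proc.time()[["elapsed"]]
                    m <- switch(eng,
                        reference = foldReference(seqs[[r]]),
                        transpose = foldTranspose(seqs[[r]]),
                        tiled = foldTiled(seqs[[r]], ws = wpair[1],
                                          wt = wpair[2],
                                          threads = grid$th[g]))
                    times[r] <- proc.time()[["elapsed"]] - t0
                    if (!is.null(refs)) {
                        up <- upper.tri(refs[[r]])
                        same <- all(scoreMatrix(m)[up] == refs[[r]][up])
                        if (!same)
                            stop(sprintf(
                                "verification failed: engine %s, length %d, ws %s wt %s",
                                eng, len, wpair[1], wpair[2]), call. = FALSE)
                        verified <- TRUE
                    }
                }
                rows[[length(rows) + 1L]] <- data.frame(
                    engine = eng, length = len,
                    ws = wpair[1], wt = wpair[2], threads = grid$th[g],
                    median_s = stats::median(times), verified = verified)
                if (!quiet)
                    message(sprintf("bench: %s N=%d ws=%s wt=%s th=%d: %.3fs",
                        eng, len, wpair[1], wpair[2], grid$th[g],
                        stats::median(times)))
            }
        }
    }
    do.call(rbind, rows)
}

#' Write a benchmark table as TSV
#' @param bench data.frame from [runBench()]
#' @param file path or connection
#' @export
writeBenchTsv <- function(bench, file = "") {
    utils::write.table(bench, file = file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(bench)
}

#' Is the tiled engine running with OpenMP?
#' @return logical
#' @export
hasOpenMP <- function() has_openmp_cpp()
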