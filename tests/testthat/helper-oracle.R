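# Independent maximum-matching oracle: recursive decomposition on whether
# position i is unpaired or paired with some compatible j' (1-based,
# memoized per interval).  Never uses the package's split recurrence.
oracleMaxMatching <- function(bases) {
    n <- length(bases)
    memo <- matrix(NA_integer_, n, n)
    f <- function(i, j) {
        if (i >= j) return(0L)
        if (!is.na(memo[i, j])) return(memo[i, j])
        best <- f(i + 1L, j)                       # i unpaired
        for (jp in (i + 1L):j)                     # i paired with jp
            if (sigmaPair(bases[i], bases[jp]) == 1L)
                best <- max(best, 1L + f(i + 1L, jp - 1L) + f(jp + 1L, j))
        memo[i, j] <<- best
        best
    }
    f(1L, n)
}

# Literal exhaustive enumeration of every non-crossing sigma-compatible
# matching (as lists of pairs); exponential, for tiny n only.  Used to
# certify oracleMaxMatching on small cases.
enumerateMatchings <- function(bases, i = 1L, j = length(bases)) {
    if (i >= j) return(list(list()))
    out <- lapply(enumerateMatchings(bases, i + 1L, j), identity)
    for (jp in (i + 1L):j) {
        if (sigmaPair(bases[i], bases[jp]) != 1L) next
        inner <- enumerateMatchings(bases, i + 1L, jp - 1L)
        outer <- enumerateMatchings(bases, jp + 1L, j)
        for (a in inner) for (b in outer)
            out[[length(out) + 1L]] <- c(list(c(i, jp)), a, b)
    }
    out
}

randomBases <- function(n, seed) {
    residues(randomRna(n, seed = seed), as.vector = TRUE)
}

# canonical row order for comparing point sets as matrices
sortRows <- function(m) {
    m <- unname(as.matrix(m))
    m[do.call(order, as.data.frame(m)), , drop = FALSE]
}

expectSameRows <- function(a, b) {
    expect_equal(sortRows(a), sortRows(b))
}

upperEqual <- function(a, b) {
    up <- upper.tri(a)
    all(a[up] == b[up])
}

# hand-derived earliest-start partitions of the 3x3x3 worked example
expectedPartitions <- list(
    t0 = rbind(c(0, 0, 0)),
    t1 = rbind(c(0, 0, 1), c(0, 1, 0)),
    t2 = rbind(c(0, 0, 2), c(0, 1, 1), c(0, 2, 0), c(1, 0, 0)),
    t3 = rbind(c(0, 1, 2), c(0, 2, 1), c(1, 0, 1), c(1, 1, 0)),
    t4 = rbind(c(0, 2, 2), c(1, 0, 2), c(1, 1, 1), c(1, 2, 0), c(2, 0, 0)),
    t5 = rbind(c(1, 1, 2), c(1, 2, 1), c(2, 0, 1), c(2, 1, 0)),
    t6 = rbind(c(1, 2, 2), c(2, 0, 2), c(2, 1, 1), c(2, 2, 0)),
    t7 = rbind(c(2, 1, 2), c(2, 2, 1)),
    t8 = rbind(c(2, 2, 2)))

expectedTime2 <- rbind(
    c(0, 2, 2), c(1, 1, 2), c(0, 1, 2), c(1, 0, 2), c(1, 2, 1), c(0, 2, 1),
    c(1, 1, 1), c(2, 0, 1), c(1, 0, 1), c(1, 2, 0), c(2, 1, 0), c(1, 1, 0),
    c(2, 0, 0))

expectedTime3 <- rbind(
    c(2, 2, 2), c(1, 2, 2), c(2, 1, 2), c(2, 0, 2), c(2, 2, 1), c(2, 1, 1),
    c(2, 2, 0))
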