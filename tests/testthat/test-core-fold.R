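test_that("sigma scores exactly the AU, GC, GU pairs, unordered", {
    expect_equal(sigmaPair("A", "U"), 1L)
    expect_equal(sigmaPair("U", "A"), 1L)
    expect_equal(sigmaPair("G", "C"), 1L)
    expect_equal(sigmaPair("U", "G"), 1L)
    expect_equal(sigmaPair("A", "G"), 0L)
    expect_equal(sigmaPair("A", "A"), 0L)
    expect_equal(sigmaPair("C", "U"), 0L)
    expect_equal(sigmaPair("t", "a"), 1L)   # normalized before scoring
    expect_error(sigmaPair("A", "N"), "invalid nucleotide")
})

test_that("sequence construction normalizes and validates", {
    s <- rnaSequence("acgt", name = "x")
    expect_equal(residues(s), "ACGU")
    expect_equal(length(s), 4L)
    expect_equal(seqName(s), "x")
    expect_error(rnaSequence(""), "at least one residue")
    expect_error(rnaSequence("ACGN"), "invalid residue")
    expect_error(rnaSequence("ACG-U"), "invalid residue")
})

test_that("reference engine reproduces small closed cases", {
    expect_equal(maxPairs(foldReference("AAAA")), 0L)
    expect_equal(maxPairs(foldReference("GC")), 1L)
    expect_equal(maxPairs(foldReference("GCGC")), 2L)
    expect_equal(maxPairs(foldReference("A")), 0L)
})

test_that("score matrices satisfy the bound and monotonicity invariants", {
    for (seed in 1:10) {
        n <- sample(2:40, 1)
        S <- scoreMatrix(foldReference(randomRna(n, seed = seed)))
        expect_true(all(S[lower.tri(S, diag = TRUE)] == 0L))
        for (i in 1:(n - 1)) for (j in (i + 1):n) {
            expect_lte(S[i, j], (j - i + 1) %/% 2)
            expect_gte(S[i, j], 0L)
            expect_gte(S[i, j], S[i + 1, j])
            expect_gte(S[i, j], S[i, j - 1])
        }
    }
})

test_that("transpose engine equals reference and mirrors the triangle", {
    t0 <- scoreMatrix(foldTranspose("AAAA"))
    expect_equal(t0[1, 4], 0L)
    expect_equal(t0[4, 1], 0L)
    for (n in c(2, 3, 5, 17, 64, 301)) {
        for (seed in 1:50) {
            s <- randomRna(n, seed = seed)
            ref <- scoreMatrix(foldReference(s))
            tr <- scoreMatrix(foldTranspose(s))
            expect_true(upperEqual(ref, tr))
            expect_true(all(tr == t(tr)))          # mirror maintained
        }
    }
})

test_that("both engines match the independent maximum-matching oracle", {
    for (seed in 1:30) {
        n <- 2L + (seed %% 11L)
        b <- randomBases(n, seed)
        s <- paste(b, collapse = "")
        expect_equal(maxPairs(foldReference(s)), oracleMaxMatching(b))
        expect_equal(maxPairs(foldTranspose(s)), oracleMaxMatching(b))
    }
})

test_that("the interval oracle agrees with literal matching enumeration", {
    for (seed in 1:12) {
        b <- randomBases(2L + (seed %% 6L), seed + 100L)
        best <- max(vapply(enumerateMatchings(b), length, 1L))
        expect_equal(oracleMaxMatching(b), best)
    }
})

test_that("traceback returns a valid optimal non-crossing structure", {
    expect_equal(dotBracket(tracebackStructure(foldReference("AAAA"))),
                 "....")
    expect_equal(dotBracket(tracebackStructure(foldReference("GC"))), "()")
    st <- tracebackStructure(foldReference("GCGC"))
    expect_equal(nrow(basePairs(st)), 2L)

    for (seed in 1:20) {
        s <- randomRna(sample(2:60, 1), seed = seed + 500L)
        m <- foldReference(s)
        st <- tracebackStructure(m)
        p <- basePairs(st)
        expect_equal(nrow(p), maxPairs(m))
        b <- residues(s, as.vector = TRUE)
        if (nrow(p)) {
            expect_true(all(sigmaPair(b[p[, 1]], b[p[, 2]]) == 1L))
            # non-crossing: no i < i2 < j < j2
            for (a in seq_len(nrow(p))) {
                crossing <- p[, 1] > p[a, 1] & p[, 1] < p[a, 2] &
                            p[, 2] > p[a, 2]
                expect_false(any(crossing))
            }
        }
        # deterministic, and engine-independent input is accepted
        st2 <- tracebackStructure(foldTranspose(s))
        expect_identical(dotBracket(st), dotBracket(st2))
    }
})

test_that("FASTA reading normalizes, keeps order, and fails loudly", {
    fa <- tempfile(fileext = ".fa")
    writeLines(c(">a", "acgt", ">b desc", "GGG", "CCC"), fa)
    seqs <- readRnaFasta(fa)
    expect_length(seqs, 2L)
    expect_equal(residues(seqs[[1]]), "ACGU")
    expect_equal(residues(seqs[[2]]), "GGGCCC")    # wrapped lines joined
    expect_match(seqName(seqs[[1]]), "^a")

    empty <- tempfile(fileext = ".fa")
    file.create(empty)
    expect_error(readRnaFasta(empty), "empty|malformed")

    bad <- tempfile(fileext = ".fa")
    writeLines(c(">a", "ACGU", ">b", "ACGN"), bad)
    expect_error(readRnaFasta(bad), "line 4")
    expect_error(readRnaFasta(tempfile()), "no such file")
})

test_that("fold results are written in Vienna layout with a TSV summary", {
    fa <- tempfile(fileext = ".fa")
    writeLines(c(">x", "GCGC", ">y", "AAAA"), fa)
    recs <- foldFasta(fa)
    out <- writeFoldResults(recs, file = tempfile())
    expect_equal(out[1:3], c(">x", "GCGC", "(())"))
    expect_equal(out[4:6], c(">y", "AAAA", "...."))
    tab <- foldResultsTable(recs)
    expect_equal(tab$name, c("x", "y"))
    expect_equal(tab$length, c(4L, 4L))
    expect_equal(tab$score, c(2L, 0L))
})
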