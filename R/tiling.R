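#' Tile coordinates of instances
#'
#' Maps instances to their space-time tile (ii, jj, i0, tt):
#' \itemize{
#'   \item \code{ii = floor((n-1-i)/ws)}: row band, anchored at the top
#'     (ii = 0 covers i in [n-ws, n-1]) because the i loop descends;
#'   \item \code{i0 = j - i}: the anti-diagonal;
#'   \item \code{jj = floor((i0-1)/ws)}: anti-diagonal band,
#'     i0 in (ws*jj, ws*jj + ws] (half-open below);
#'   \item \code{tt = floor(k/wt)} for S1 and \code{floor(j/wt)} for S2:
#'     the time slice.
#' }
#'
#' @param inst data.frame with columns stmt, i, j, k (rows must lie in the
#'   domain of \code{params@n})
#' @param params a [TilingParams-class]
#' @return data.frame with columns ii, jj, i0, tt, w (= ii + jj)
#' @examples
#' p <- tilingParams(40)
#' tileOfInstance(data.frame(stmt = 1, i = 30, j = 35, k = 2), p)
#' @export
tileOfInstance <- function(inst, params) {
    stopifnot(is(params, "TilingParams"))
    n <- params@n; ws <- params@ws; wt <- params@wt
    ok <- inst$i >= 0L & inst$i <= n - 2L & inst$j > inst$i &
        inst$j <= n - 1L &
        (inst$stmt == 2L | (inst$k >= 0L & inst$k <= inst$j - inst$i - 1L))
    if (!all(ok))
        stop("instance outside the iteration domain of n = ", n,
             call. = FALSE)
    i0 <- inst$j - inst$i
    data.frame(
        ii = (n - 1L - inst$i) %/% ws,
        jj = (i0 - 1L) %/% ws,
        i0 = i0,
        tt = ifelse(inst$stmt == 1L, inst$k %/% wt, inst$j %/% wt),
        w = (n - 1L - inst$i) %/% ws + (i0 - 1L) %/% ws)
}

#' Tile membership by the defining inequalities
#'
#' Independent of the closed-form coordinates of [tileOfInstance()]: checks
#' the band and slice inequalities that define a tile's instance set
#' directly.  Used to verify that the tiles partition the domain (each
#' instance satisfies its own tile's constraints and no neighbouring
#' tile's).
#'
#' @param inst data.frame with stmt, i, j, k
#' @param ii,jj,i0,tt tile coordinates (scalars or vectors aligned with
#'   \code{inst})
#' @param params a [TilingParams-class]
#' @return logical vector
#' @export
tileMembership <- function(inst, ii, jj, i0, tt, params) {
    n <- params@n; ws <- params@ws; wt <- params@wt
    i <- inst$i; j <- inst$j; k <- inst$k
    space <- ii >= 0L & jj >= 0L & tt >= 0L &
        i >= n - ws * (ii + 1L) & i < n - ws * ii &            # row band
        (j - i) > ws * jj & (j - i) <= ws * jj + ws &          # diag band
        (j - i) == i0 &
        i >= 0L & i <= n - 2L & j > i & j < n
    time1 <- inst$stmt == 1L & !is.na(k) &
        k >= wt * tt & k <= wt * tt + wt - 1L & k < i0 & k >= 0L
    time2 <- inst$stmt == 2L & j >= wt * tt & j <= wt * tt + wt - 1L
    out <- space & (time1 | time2)
    out & !is.na(out)
}

#' Enumerate the non-empty tiles in execution order
#'
#' Groups the full iteration domain by tile and returns one row per
#' non-empty tile, sorted by the execution order (w = ii + jj, then jj,
#' i0, tt).  Tiles with equal w form a wavefront and are mutually
#' independent.
#'
#' @param params a [TilingParams-class]
#' @return data.frame: ii, jj, i0, tt, w, nS1, nS2, n (instance counts)
#' @examples
#' enumerateTiles(tilingParams(6, ws = 2, wt = 2))
#' @export
enumerateTiles <- function(params) {
    dom <- enumerateDomain(params@n)
    tc <- tileOfInstance(dom, params)
    key <- (((tc$w * 1e4 + tc$jj) * 1e4) + tc$i0) * 1e4 + tc$tt
    ord <- order(key)
    key <- key[ord]
    isS1 <- dom$stmt[ord] == 1L
    grp <- cumsum(!duplicated(key))
    first <- !duplicated(key)
    data.frame(
        ii = tc$ii[ord][first], jj = tc$jj[ord][first],
        i0 = tc$i0[ord][first], tt = tc$tt[ord][first],
        w = tc$w[ord][first],
        nS1 = as.integer(rowsum(as.integer(isS1), grp)),
        nS2 = as.integer(rowsum(as.integer(!isS1), grp)),
        n = as.integer(tabulate(grp)))
}

#' Instances of one tile, from its defining constraints
#'
#' Built directly from the tile inequalities (not by filtering a
#' precomputed assignment), so it can serve as a cross-check of
#' [tileOfInstance()].
#'
#' @param params a [TilingParams-class]
#' @param ii,jj,i0,tt tile coordinates
#' @return data.frame of instances (stmt, i, j, k), in intra-tile
#'   schedule order (i, j, s, k ascending)
#' @export
tileInstances <- function(params, ii, jj, i0, tt) {
    n <- params@n; ws <- params@ws; wt <- params@wt
    if (i0 <= ws * jj || i0 > ws * jj + ws || i0 > n - 1L)
        return(data.frame(stmt = integer(0), i = integer(0),
                          j = integer(0), k = integer(0)))
    iLo <- max(0L, n - ws * (ii + 1L))
    iHi <- min(n - ws * ii - 1L, n - 2L, n - 1L - i0)
    if (iLo > iHi) return(data.frame(stmt = integer(0), i = integer(0),
                                     j = integer(0), k = integer(0)))
    kLo <- wt * tt
    kHi <- min(wt * tt + wt - 1L, i0 - 1L)
    rows <- lapply(iLo:iHi, function(i) {
        j <- i0 + i
        out <- NULL
        if (kLo <= kHi)
            out <- data.frame(stmt = 1L, i = i, j = j, k = kLo:kHi)
        if (j %/% wt == tt)
            out <- rbind(out, data.frame(stmt = 2L, i = i, j = j,
                                         k = NA_integer_))
        out
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) data.frame(stmt = integer(0), i = integer(0),
                                 j = integer(0), k = integer(0))
    else out
}

#' Schedule tuples of instances
#'
#' The parallel space-time schedule: each instance maps to the 8-tuple
#' (w, jj, i0, tt, i, j, s, k), compared lexicographically ascending.
#' The skewing w = ii + jj makes the first coordinate a serial wavefront;
#' within it, tiles differing in jj are independent.  The statement
#' ordinal s (S1 = 0 before S2 = 1) breaks the tie between S1(i, j, .)
#' and S2(i, j) at an identical prefix: S2 reads what every S1 of its
#' cell wrote, so it must come last — [validateSchedule()] proves this
#' safe exhaustively.
#'
#' @param inst data.frame with stmt, i, j, k
#' @param params a [TilingParams-class]
#' @return integer matrix with columns w, jj, i0, tt, i, j, s, k
#' @export
scheduleTuple <- function(inst, params) {
    tc <- tileOfInstance(inst, params)
    cbind(w = tc$w, jj = tc$jj, i0 = tc$i0, tt = tc$tt,
          i = inst$i, j = inst$j, s = inst$stmt - 1L,
          k = ifelse(inst$stmt == 1L, inst$k, 0L))
}

# row-wise lexicographic comparison: -1 if a < b, 0 if equal, 1 if a > b
lexCompare <- function(a, b) {
    res <- integer(nrow(a))
    done <- logical(nrow(a))
    for (c in seq_len(ncol(a))) {
        lt <- !done & a[, c] < b[, c]
        gt <- !done & a[, c] > b[, c]
        res[lt] <- -1L
        res[gt] <- 1L
        done <- done | lt | gt
    }
    res
}

#' Validate the space-time schedule exhaustively
#'
#' Checks, for every brute-force dependence of the loop nest at size
#' \code{params@n}, that the source's schedule tuple precedes the
#' destination's.  All of flow, anti and output dependences are treated as
#' ordering constraints — a deliberate over-approximation of a value-based
#' legality test: any schedule passing this passes the weaker one.
#' Additionally asserts wavefront safety: no dependence may link two tiles
#' with equal w = ii + jj and different jj, since such tiles are declared
#' executable in parallel.
#'
#' @param params a [TilingParams-class]
#' @param deps optionally a precomputed [extractDeps()] table for
#'   \code{params@n}
#' @param maxN brute-force cap passed to [extractDeps()]
#' @param negate_w self-test knob: negates the wavefront coordinate, which
#'   must break the schedule (reversing a total order violates some
#'   dependence)
#' @return object of class \code{scheduleValidation}: list with
#'   \code{valid}, \code{nDeps}, \code{violations} and
#'   \code{wavefrontViolations} (data.frames of offending dependences)
#' @examples
#' validateSchedule(tilingParams(12, 4, 4))
#' @export
validateSchedule <- function(params, deps = NULL, maxN = 80L,
                             negate_w = FALSE) {
    stopifnot(is(params, "TilingParams"))
    if (is.null(deps)) deps <- extractDeps(params@n, maxN = maxN)
    dom <- attr(deps, "domain")
    tup <- scheduleTuple(dom, params)
    if (negate_w) tup[, "w"] <- -tup[, "w"]
    a <- tup[deps$srcId, , drop = FALSE]
    b <- tup[deps$dstId, , drop = FALSE]
    badOrder <- lexCompare(a, b) != -1L
    badWave <- a[, "w"] == b[, "w"] & a[, "jj"] != b[, "jj"]
    structure(list(
        params = params,
        nDeps = nrow(deps),
        valid = !any(badOrder) && !any(badWave),
        violations = expandDeps(deps)[badOrder, , drop = FALSE],
        wavefrontViolations = expandDeps(deps)[badWave, , drop = FALSE]),
        class = "scheduleValidation")
}

#' @export
print.scheduleValidation <- function(x, ...) {
    p <- x$params
    cat(sprintf("Schedule validation: N = %d, Ws = %d, Wt = %d\n",
        p@n, p@ws, p@wt))
    cat(sprintf("  dependences checked : %d\n", x$nDeps))
    cat(sprintf("  ordering violations : %d\n", nrow(x$violations)))
    cat(sprintf("  wavefront violations: %d\n",
        nrow(x$wavefrontViolations)))
    cat(if (x$valid) "  schedule is VALID\n" else "  schedule is INVALID\n")
    invisible(x)
}

#' Tile statistics
#'
#' Per-tile instance counts and their maxima.  For fixed widths the
#' maximum tile cardinality saturates as n grows — tile size does not
#' depend on the problem-size parameter — and the S1 count per tile is
#' bounded by ws * wt (i spans at most ws values and k at most wt within
#' a tile).
#'
#' @param params a [TilingParams-class]
#' @return object of class \code{tileStats}: list with the \code{tiles}
#'   table ([enumerateTiles()]), \code{nTiles}, \code{nWavefronts},
#'   \code{maxInstances}, \code{maxS1}
#' @export
tileStats <- function(params) {
    tiles <- enumerateTiles(params)
    structure(list(
        params = params, tiles = tiles, nTiles = nrow(tiles),
        nWavefronts = length(unique(tiles$w)),
        maxInstances = max(tiles$n), maxS1 = max(tiles$nS1)),
        class = "tileStats")
}

#' @export
print.tileStats <- function(x, ...) {
    p <- x$params
    cat(sprintf("Tile statistics: N = %d, Ws = %d, Wt = %d\n",
        p@n, p@ws, p@wt))
    cat(sprintf("  tiles: %d across %d wavefronts\n", x$nTiles,
        x$nWavefronts))
    cat(sprintf("  max instances per tile: %d (S1 only: %d, bound ws*wt = %d)\n",
        x$maxInstances, x$maxS1, p@ws * p@wt))
    invisible(x)
}
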