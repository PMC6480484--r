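#' Enumerate the loop-nest iteration domain
#'
#' All dynamic instances of the two statements of the folding loop nest,
#' in original execution order.  The split statement S1(i, j, k) applies
#' \code{S[i][j] <- max(S[i][j], S[i][i+k] + S[i+k+1][j])} and the pairing
#' statement S2(i, j) applies
#' \code{S[i][j] <- max(S[i][j], S[i+1][j-1] + sigma(x_i, x_j))}.
#' The original order is the global stamp (i, j, s, k) compared
#' lexicographically with i DESCENDING (the i loop decrements) and the
#' statement ordinal s = 0 for S1, 1 for S2: for each cell, all splits
#' (k ascending) run before the pairing statement.
#'
#' @param n sequence length, >= 2 (the domain is empty below that)
#' @return data.frame with columns \code{id} (execution rank), \code{stmt}
#'   (1 = S1, 2 = S2), \code{i}, \code{j}, \code{k} (\code{NA} for S2),
#'   rows in execution order.  The instance count is
#'   \eqn{\sum_{d=1}^{n-1} (n-d)(d+1)}.
#' @examples
#' enumerateDomain(3)
#' @export
enumerateDomain <- function(n) {
    n <- as.integer(n)
    if (n < 2L)
        stop("empty iteration domain: n must be >= 2", call. = FALSE)
    ci <- rep((n - 2L):0L, times = 1L:(n - 1L))          # i descending
    cj <- unlist(lapply((n - 2L):0L, function(i) (i + 1L):(n - 1L)))
    d <- cj - ci                                          # anti-diagonal
    cell <- rep(seq_along(ci), times = d + 1L)            # d S1's + one S2
    pos <- sequence(d + 1L)
    stmt <- ifelse(pos == d[cell] + 1L, 2L, 1L)
    data.frame(id = seq_along(cell), stmt = stmt,
               i = ci[cell], j = cj[cell],
               k = ifelse(stmt == 1L, pos - 1L, NA_integer_))
}

#' Global timestamps of instances
#'
#' Maps instances to the 4-tuple (i, j, s, k) of the common iteration
#' space; s is the statement ordinal (S1 -> 0, S2 -> 1, with k = 0).
#' The single place the sign convention lives: ordering compares i
#' descending, the rest ascending.
#'
#' @param inst data.frame with columns stmt, i, j, k
#' @return integer matrix with columns i, j, s, k
#' @export
globalStamp <- function(inst) {
    cbind(i = inst$i, j = inst$j, s = inst$stmt - 1L,
          k = ifelse(inst$stmt == 1L, inst$k, 0L))
}

#' @rdname globalStamp
#' @return \code{stampOrder}: the permutation sorting instances into
#'   original execution order
#' @export
stampOrder <- function(inst) {
    st <- globalStamp(inst)
    order(-st[, "i"], st[, "j"], st[, "s"], st[, "k"])
}

#' Memory accesses of an instance
#'
#' S1(i, j, k) writes cell (i, j) and reads (i, j), (i, i+k) and
#' (i+k+1, j); S2(i, j) writes (i, j) and reads (i, j) and (i+1, j-1).
#'
#' @param inst a single-row data.frame (or list) with stmt, i, j, k
#' @return list with \code{write} = c(r, c) and \code{reads} = list of
#'   c(r, c)
#' @examples
#' accessesOf(list(stmt = 1, i = 0, j = 2, k = 0))
#' @export
accessesOf <- function(inst) {
    i <- as.integer(inst$i); j <- as.integer(inst$j)
    if (inst$stmt == 1L) {
        k <- as.integer(inst$k)
        list(write = c(i, j),
             reads = list(c(i, j), c(i, i + k), c(i + k + 1L, j)))
    } else {
        list(write = c(i, j),
             reads = list(c(i, j), c(i + 1L, j - 1L)))
    }
}

# every access of every instance, as one flat table
accessTable <- function(dom) {
    s1 <- dom[dom$stmt == 1L, ]
    s2 <- dom[dom$stmt == 2L, ]
    data.frame(
        id = c(dom$id, dom$id, s1$id, s1$id, s2$id),
        r = c(dom$i, dom$i, s1$i, s1$i + s1$k + 1L, s2$i + 1L),
        c = c(dom$j, dom$j, s1$i + s1$k, s1$j, s2$j - 1L),
        write = c(rep(TRUE, nrow(dom)),
                  rep(FALSE, nrow(dom) + 2L * nrow(s1) + nrow(s2))))
}

#' Brute-force dependence extraction
#'
#' Enumerates every ordered pair of instances that touch the same matrix
#' cell with at least one write, the earlier one (in global-stamp order)
#' as source.  Pairs are found per cell: accesses are grouped by the cell
#' they touch and all ordered pairs within a group are formed, which is
#' equivalent to (but vastly cheaper than) scanning all instance pairs.
#' Categories: write-write = output, write-then-read = flow,
#' read-then-write = anti.  Rows are sorted by (source rank, destination
#' rank, category), so the output is deterministic and order-stable.
#'
#' @param n sequence length (>= 2)
#' @param maxN refuse beyond this size (the table grows like n^4); default 80
#' @return data.frame with columns \code{srcId}, \code{dstId} (execution
#'   ranks into [enumerateDomain()]), \code{category}, \code{cellR},
#'   \code{cellC}; the domain is attached as \code{attr(, "domain")}.
#' @seealso [expandDeps()], [distanceVectors()], [validateSchedule()]
#' @export
extractDeps <- function(n, maxN = 80L) {
    n <- as.integer(n)
    if (n > maxN)
        stop("n = ", n, " exceeds the brute-force cap (", maxN,
             "); dependence enumeration is ~n^4 in time and memory. ",
             "Raise maxN explicitly if you really mean it.", call. = FALSE)
    dom <- enumerateDomain(n)
    acc <- accessTable(dom)
    key <- acc$r * n + acc$c
    ord <- order(key, acc$id)
    acc <- acc[ord, ]
    key <- key[ord]
    sizes <- rle(key)$lengths
    ends <- cumsum(sizes)
    starts <- ends - sizes + 1L

    pieces <- vector("list", length(sizes))
    for (g in seq_along(sizes)) {
        m <- sizes[g]
        if (m < 2L) next
        aLoc <- rep.int(1L:(m - 1L), (m - 1L):1L)
        bLoc <- aLoc + sequence((m - 1L):1L)
        pieces[[g]] <- cbind(starts[g] - 1L + aLoc, starts[g] - 1L + bLoc)
    }
    ab <- do.call(rbind, pieces)
    if (is.null(ab)) ab <- matrix(integer(0), 0, 2)
    aId <- acc$id[ab[, 1]]; bId <- acc$id[ab[, 2]]
    aW <- acc$write[ab[, 1]]; bW <- acc$write[ab[, 2]]
    keep <- (aId != bId) & (aW | bW)
    deps <- data.frame(
        srcId = aId[keep], dstId = bId[keep],
        category = ifelse(aW[keep],
                          ifelse(bW[keep], "output", "flow"), "anti"),
        cellR = acc$r[ab[keep, 1]], cellC = acc$c[ab[keep, 1]])
    # dedupe per (src, dst, category, cell); construction cannot actually
    # produce duplicates (an instance touches a given cell with at most one
    # read and one write), but the contract promises it
    catCode <- match(deps$category, c("flow", "anti", "output"))
    dkey <- ((deps$srcId * (nrow(dom) + 1) + deps$dstId) * 3 + catCode)
    deps <- deps[!duplicated(dkey), ]
    deps <- deps[order(deps$srcId, deps$dstId, deps$category), ]
    rownames(deps) <- NULL
    attr(deps, "domain") <- dom
    deps
}

#' Add instance columns to a dependence table
#' @param deps output of [extractDeps()]
#' @return the same rows with src/dst stmt, i, j, k columns joined in
#' @export
expandDeps <- function(deps) {
    dom <- attr(deps, "domain")
    out <- cbind(deps,
        srcStmt = dom$stmt[deps$srcId], srcI = dom$i[deps$srcId],
        srcJ = dom$j[deps$srcId], srcK = dom$k[deps$srcId],
        dstStmt = dom$stmt[deps$dstId], dstI = dom$i[deps$dstId],
        dstJ = dom$j[deps$dstId], dstK = dom$k[deps$dstId])
    attr(out, "domain") <- dom
    out
}

#' Dump dependences as TSV
#' @param deps output of [extractDeps()]
#' @param file path or connection
#' @export
writeDepsTsv <- function(deps, file = "") {
    x <- expandDeps(deps)
    lab <- function(s, i, j, k)
        ifelse(s == 1L, sprintf("S1(%d,%d,%d)", i, j, k),
               sprintf("S2(%d,%d)", i, j))
    out <- data.frame(
        src = lab(x$srcStmt, x$srcI, x$srcJ, x$srcK),
        dst = lab(x$dstStmt, x$dstI, x$dstJ, x$dstK),
        category = x$category,
        cell = sprintf("(%d,%d)", x$cellR, x$cellC))
    utils::write.table(out, file = file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(out)
}

#' Membership in the closed-form dependence relation
#'
#' The loop nest's dependence relation can be written in closed form as a
#' union of seven affine clauses.  This predicate tests whether (src, dst)
#' satisfies at least one clause, vectorized over aligned rows of the two
#' data.frames.  It is the analytic counterpart against which the
#' brute-force [extractDeps()] output is cross-checked.
#'
#' @param src,dst data.frames (or single-row lists) with stmt, i, j, k
#' @param n the size parameter
#' @return logical vector
#' @examples
#' closedFormRMember(list(stmt = 2, i = 1, j = 2, k = NA),
#'                list(stmt = 1, i = 0, j = 2, k = 0), n = 3)
#' @export
closedFormRMember <- function(src, dst, n) {
    src <- as.data.frame(src); dst <- as.data.frame(dst)
    i <- src$i; j <- src$j; k <- src$k
    ip <- dst$i; jp <- dst$j; kp <- dst$k
    s1 <- src$stmt == 1L; d1 <- dst$stmt == 1L

    cl <- logical(nrow(src))
    # S1(i,j,k) -> S2(i', i+j-i')
    cl <- cl | (s1 & !d1 & (ip + jp == i + j) &
        k >= 0L & k < j - i & ip >= i - 1L & ip >= 0L &
        ip > i + j - n & ip <= i)
    # S1(i,j,k) -> S1(i,j,k'), k < k' < j-i
    cl <- cl | (s1 & d1 & ip == i & jp == j &
        i >= 0L & j < n & k >= 0L & kp > k & kp < j - i)
    # S1(i,j,k) -> S1(i,j',j-i), j < j' < n
    cl <- cl | (s1 & d1 & ip == i & kp == j - i &
        i >= 0L & k >= 0L & k < j - i & jp > j & jp < n)
    # S1(i,j,k) -> S1(i',j,i-i'-1), 0 <= i' < i
    cl <- cl | (s1 & d1 & jp == j & kp == i - ip - 1L &
        j < n & k >= 0L & k < j - i & ip >= 0L & ip < i)
    # S2(i,j) -> S1(i,j',j-i), j < j' < n
    cl <- cl | (!s1 & d1 & ip == i & kp == j - i &
        i >= 0L & j > i & jp > j & jp < n)
    # S2(i,j) -> S1(i',j,i-i'-1), 0 <= i' < i
    cl <- cl | (!s1 & d1 & jp == j & kp == i - ip - 1L &
        i < j & j < n & ip >= 0L & ip < i)
    # S2(i,j) -> S2(i-1,j+1)
    cl <- cl | (!s1 & !d1 & ip == i - 1L & jp == j + 1L &
        i > 0L & i < j & j <= n - 2L)
    cl & !is.na(cl)
}

#' Distance vectors in the global iteration space
#'
#' Componentwise destination-minus-source differences of all dependences,
#' mapped through the global stamp (i, j, s, k).  With i decremented by
#' the loop, a negative first component is "forward" in time.
#'
#' @param n size parameter
#' @param deps optionally a precomputed [extractDeps()] table for this n
#' @return integer matrix of unique (di, dj, ds, dk) rows
#' @export
distanceVectors <- function(n, deps = NULL) {
    if (is.null(deps)) deps <- extractDeps(n)
    dom <- attr(deps, "domain")
    st <- globalStamp(dom)
    dv <- st[deps$dstId, , drop = FALSE] - st[deps$srcId, , drop = FALSE]
    colnames(dv) <- c("di", "dj", "ds", "dk")
    unique(dv)
}
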