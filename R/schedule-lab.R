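#' Earliest-start (free) schedule of a dependence box
#'
#' Assigns every point p of the box the length t(p) of the longest
#' dependence chain reaching it: t(p) = 0 if no predecessor p - dv lies in
#' the box, otherwise 1 + max over in-box predecessors.  Points with equal
#' t form a time partition; all points of a partition are mutually
#' independent and may run in parallel, while partitions themselves run in
#' ascending order.  Computed by relaxation to a fixpoint: with
#' lexicographically positive distance vectors one sweep in lexicographic
#' point order suffices, but the iteration is repeated until nothing
#' changes so the routine stays correct for any acyclic vector set; a
#' fixpoint not reached within #points sweeps means a dependence cycle,
#' which is reported as an error naming a cyclic point.
#'
#' @param box a [DepBox-class]
#' @return a [TimePartitioning-class]
#' @examples
#' b <- depBox(c(3, 3, 3), list(c(0, 0, 1), c(0, 1, 0), c(1, 0, -1)))
#' fs <- freeSchedule(b)
#' partitionSets(fs)[[3]]  # partition t2
#' @export
freeSchedule <- function(box) {
    stopifnot(is(box, "DepBox"))
    dims <- box@dims
    d <- length(dims)
    pts <- as.matrix(rev(expand.grid(rev(lapply(dims, function(m)
        0L:(m - 1L))))))            # lexicographic order, first dim slowest
    colnames(pts) <- NULL
    storage.mode(pts) <- "integer"
    np <- nrow(pts)
    # integer encoding of a point for O(1) predecessor lookup
    mult <- rev(cumprod(rev(c(dims[-1L], 1L))))
    enc <- function(m) as.vector(m %*% mult) + 1L
    idxOf <- integer(np)
    idxOf[enc(pts)] <- seq_len(np)

    t <- integer(np)
    for (sweep in seq_len(np + 1L)) {
        tNew <- integer(np)
        for (v in seq_len(nrow(box@dvs))) {
            pred <- sweep(pts, 2L, box@dvs[v, ], "-")
            inbox <- rowSums(pred >= 0L) == d &
                rowSums(pred < rep(dims, each = np)) == d
            cand <- integer(np)
            cand[inbox] <- t[idxOf[enc(pred[inbox, , drop = FALSE])]] + 1L
            tNew <- pmax(tNew, cand)
        }
        if (identical(tNew, t)) break
        t <- tNew
        if (sweep == np + 1L)
            stop("dependence cycle detected through point (",
                 paste(pts[which.max(t), ], collapse = ","), ")",
                 call. = FALSE)
    }
    new("TimePartitioning", box = box, points = pts, t = t)
}

#' Time partitions as point sets
#'
#' @param tp a [TimePartitioning-class]
#' @return list of integer matrices; element s + 1 holds the points of
#'   partition t_s (one row per point)
#' @export
partitionSets <- function(tp) {
    stopifnot(is(tp, "TimePartitioning"))
    lapply(0L:max(tp@t), function(s)
        tp@points[tp@t == s, , drop = FALSE])
}

#' Partition index of every point
#' @param tp a [TimePartitioning-class]
#' @return integer vector aligned with \code{tp@points}
#' @export
partitionIndex <- function(tp) tp@t

#' Combine time partitions into slices
#'
#' Slice s is the union of partitions with index in [s*W, (s+1)*W): a unit
#' of W consecutive partitions executed together to bound the working set.
#'
#' @param tp a [TimePartitioning-class]
#' @param W slice width (number of partitions per slice, >= 1)
#' @return list of integer matrices, ordered, disjoint, covering the box
#' @export
timeSlices <- function(tp, W) {
    stopifnot(is(tp, "TimePartitioning"), W >= 1)
    s <- tp@t %/% as.integer(W)
    lapply(0L:max(s), function(x)
        tp@points[s == x, , drop = FALSE])
}

#' Are slices legal under lexicographic (serial) enumeration?
#'
#' TRUE iff no dependence p - dv -> p crosses slices backwards, i.e. every
#' dependence's source lies in the same or an earlier slice than its
#' destination, so by the time a slice starts all data it needs exist.
#'
#' @param box a [DepBox-class]
#' @param slices list of point matrices covering the box
#' @return logical
#' @export
checkSliceLegality <- function(box, slices) {
    stopifnot(is(box, "DepBox"))
    dims <- box@dims
    mult <- rev(cumprod(rev(c(dims[-1L], 1L))))
    sliceOf <- integer(prod(dims))
    for (s in seq_along(slices)) {
        m <- slices[[s]]
        if (nrow(m)) sliceOf[as.vector(m %*% mult) + 1L] <- s
    }
    for (s in seq_along(slices)) {
        m <- slices[[s]]
        if (!nrow(m)) next
        for (v in seq_len(nrow(box@dvs))) {
            pred <- sweep(m, 2L, box@dvs[v, ], "-")
            inbox <- rowSums(pred >= 0L) == length(dims) &
                rowSums(pred < rep(dims, each = nrow(m))) == length(dims)
            if (!any(inbox)) next
            srcSlice <- sliceOf[as.vector(
                pred[inbox, , drop = FALSE] %*% mult) + 1L]
            if (any(srcSlice > s)) return(FALSE)
        }
    }
    TRUE
}

#' The canonical 3 x 3 x 3 worked example
#'
#' A single tile of width 3 whose internal dependences are the constant
#' distance vectors (0,0,1), (0,1,0), (1,0,-1).  Returns the earliest-start
#' partitioning t0..t8 of its 27 points and the three slices of width 3.
#' On this box the earliest-start time coincides pointwise with the affine
#' form 2i + j + k.
#'
#' @param W slice width, default 3
#' @return list with \code{box}, \code{schedule} (a
#'   [TimePartitioning-class]), \code{partitions}, \code{slices}
#' @examples
#' ex <- workedExample()
#' length(ex$partitions)  # 9 partitions, t0..t8
#' @export
workedExample <- function(W = 3) {
    box <- depBox(c(3L, 3L, 3L),
                  list(c(0L, 0L, 1L), c(0L, 1L, 0L), c(1L, 0L, -1L)))
    fs <- freeSchedule(box)
    list(box = box, schedule = fs, partitions = partitionSets(fs),
         slices = timeSlices(fs, W))
}
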