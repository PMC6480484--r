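test_that("the iteration domain is enumerated in original order", {
    d2 <- enumerateDomain(2)
    expect_equal(d2$stmt, c(1L, 2L))
    expect_equal(d2$i, c(0L, 0L))
    expect_equal(d2$j, c(1L, 1L))
    expect_equal(d2$k, c(0L, NA_integer_))

    d3 <- enumerateDomain(3)
    expect_equal(nrow(d3), 7L)
    expect_equal(unlist(d3[1, c("stmt", "i", "j", "k")], use.names = FALSE),
                 c(1L, 1L, 2L, 0L))               # i descends: row 1 first
    expect_equal(unlist(d3[2, c("stmt", "i", "j")], use.names = FALSE),
                 c(2L, 1L, 2L))

    expect_equal(nrow(enumerateDomain(4)), 16L)   # 3*2 + 2*3 + 1*4
    for (n in 2:12) {
        d <- 1:(n - 1)
        expect_equal(nrow(enumerateDomain(n)), sum((n - d) * (d + 1)))
    }
    expect_error(enumerateDomain(1), "empty iteration domain")
})

test_that("stamp order reconstructs the enumeration order", {
    dom <- enumerateDomain(7)
    perm <- sample(nrow(dom))
    shuffled <- dom[perm, ]
    expect_equal(shuffled$id[stampOrder(shuffled)], dom$id)
})

test_that("statement accesses follow the statement bodies", {
    a <- accessesOf(list(stmt = 1L, i = 0L, j = 2L, k = 0L))
    expect_equal(a$write, c(0L, 2L))
    expectSameRows(do.call(rbind, a$reads),
                   rbind(c(0, 2), c(0, 0), c(1, 2)))
    b <- accessesOf(list(stmt = 2L, i = 1L, j = 2L, k = NA))
    expect_equal(b$write, c(1L, 2L))
    expectSameRows(do.call(rbind, b$reads), rbind(c(1, 2), c(2, 1)))
    c3 <- accessesOf(list(stmt = 1L, i = 0L, j = 3L, k = 2L))
    reads <- do.call(rbind, c3$reads)
    expect_true(any(reads[, 1] == 0 & reads[, 2] == 2))
    expect_true(any(reads[, 1] == 3 & reads[, 2] == 3))
})

test_that("brute-force dependences contain the expected witnesses", {
    d3 <- expandDeps(extractDeps(3))
    hit <- d3$category == "flow" &
        d3$srcStmt == 2L & d3$srcI == 1L & d3$srcJ == 2L &
        d3$dstStmt == 1L & d3$dstI == 0L & d3$dstJ == 2L & d3$dstK == 0L
    expect_equal(sum(hit), 1L)
    expect_equal(d3$cellR[hit], 1L)
    expect_equal(d3$cellC[hit], 2L)

    d4 <- expandDeps(extractDeps(4))
    hit <- d4$category == "flow" &
        d4$srcStmt == 2L & d4$srcI == 1L & d4$srcJ == 2L &
        d4$dstStmt == 2L & d4$dstI == 0L & d4$dstJ == 3L
    expect_equal(sum(hit), 1L)
    expect_equal(unique(d4$cellR[hit]), 1L)
    expect_equal(unique(d4$cellC[hit]), 2L)

    # n = 2: only the same-cell (0,1) chain between S1(0,1,0) and S2(0,1)
    d2 <- expandDeps(extractDeps(2))
    expect_true(all(d2$cellR == 0L & d2$cellC == 1L))
    expect_setequal(d2$category, c("flow", "anti", "output"))
})

test_that("every dependence respects original execution order", {
    for (n in c(3, 5, 9)) {
        deps <- extractDeps(n)
        expect_true(all(deps$srcId < deps$dstId))  # id equals stamp rank
    }
})

test_that("dependence extraction is deterministic and order-stable", {
    a <- extractDeps(8)
    b <- extractDeps(8)
    attr(a, "domain") <- attr(b, "domain") <- NULL
    expect_identical(a, b)
})

test_that("the cap on brute-force size is enforced with guidance", {
    expect_error(extractDeps(81), "cap")
    expect_silent(invisible(extractDeps(5, maxN = 5)))
})

test_that("the closed-form relation admits the known witnesses", {
    expect_true(closedFormRMember(
        list(stmt = 1L, i = 0L, j = 2L, k = 1L),
        list(stmt = 1L, i = 0L, j = 3L, k = 2L), n = 4))
    expect_true(closedFormRMember(
        list(stmt = 2L, i = 1L, j = 2L, k = NA),
        list(stmt = 2L, i = 0L, j = 3L, k = NA), n = 4))
    expect_false(closedFormRMember(
        list(stmt = 2L, i = 0L, j = 3L, k = NA),
        list(stmt = 2L, i = 1L, j = 2L, k = NA), n = 4))
})

test_that("closed-form membership implies a genuine ordered dependence,
           and brute-force flow is contained in its transitive closure", {
    for (n in 3:12) {
        deps <- extractDeps(n)
        dom <- attr(deps, "domain")
        ni <- nrow(dom)
        pr <- expand.grid(a = dom$id, b = dom$id)
        adm <- closedFormRMember(dom[pr$a, ], dom[pr$b, ], n)

        depKey <- unique(deps$srcId * (ni + 1) + deps$dstId)
        admA <- pr$a[adm]; admB <- pr$b[adm]
        expect_true(all((admA * (ni + 1) + admB) %in% depKey))
        expect_true(all(admA < admB))              # source precedes dest

        A <- matrix(FALSE, ni, ni)
        A[cbind(admA, admB)] <- TRUE
        R <- A
        repeat {
            R2 <- R | (R %*% A > 0)
            if (identical(R2, R)) break
            R <- R2
        }
        fl <- deps[deps$category == "flow", ]
        expect_true(all(R[cbind(fl$srcId, fl$dstId)]))
    }
})

test_that("global distance vectors have the expected members and signs", {
    dv4 <- distanceVectors(4)
    expect_true(any(dv4[, "di"] == -1 & dv4[, "dj"] == 1 &
                    dv4[, "ds"] == 0 & dv4[, "dk"] == 0))
    wob <- dv4[, "di"] == 0 & dv4[, "dj"] == 1 & dv4[, "ds"] == -1
    expect_true(any(wob & dv4[, "dk"] > 0 & dv4[, "dk"] < 3))

    for (n in c(3, 6, 10)) {
        dv <- distanceVectors(n)
        expect_true(all(dv[, "di"] <= 0))
        # forward in time: (-di, dj, ds, dk) lexicographically positive
        fwd <- cbind(-dv[, "di"], dv[, "dj"], dv[, "ds"], dv[, "dk"])
        lexpos <- apply(fwd, 1, function(v) {
            nz <- which(v != 0)
            length(nz) > 0 && v[nz[1]] > 0
        })
        expect_true(all(lexpos))
    }
})

test_that("dependence TSV dump is well formed", {
    out <- writeDepsTsv(extractDeps(3), file = tempfile())
    expect_named(out, c("src", "dst", "category", "cell"))
    expect_true(any(grepl("^S2\\(1,2\\)$", out$src)))
})
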