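test_that("anchors sit at equidistant angles starting at 12 o'clock", {
    a15 <- makeAnchors(sprintf("item_%02d", 1:15))
    expect_equal(nAnchors(a15), 15L)

    a4 <- makeAnchors(c("A", "B", "C", "D"), radius = 1)
    P <- anchorPositions(a4)
    expect_equal(unname(P),
                 rbind(c(0, 1), c(1, 0), c(0, -1), c(-1, 0)),
                 tolerance = 1e-12)

    a8 <- makeAnchors(letters[1:8])
    gaps <- diff(a8@angles)
    expect_equal(unname(gaps), rep(-2 * pi / 8, 7), tolerance = 1e-12)

    expect_error(makeAnchors(c("A", "B")), "at least 3")
})

test_that("the per-variable position rule interpolates between its bounds", {
    expect_identical(eq1Position(7, 7, 97, 0, 1), 0)
    expect_identical(eq1Position(97, 7, 97, 0, 1), 1)
    expect_equal(eq1Position(52, 7, 97, 0, 10), 5)
    # affine in the value; 1000 randomized cases against direct re-evaluation
    set.seed(7)
    for (i in 1:1000) {
        vMin <- runif(1, -50, 50); vMax <- vMin + runif(1, 0.1, 100)
        pMin <- runif(1, -5, 5); pMax <- pMin + runif(1, 0.1, 10)
        v <- runif(1, vMin, vMax)
        direct <- (v - vMin) / (vMax - vMin) * (pMax - pMin) + pMin
        expect_equal(eq1Position(v, vMin, vMax, pMin, pMax), direct,
                     tolerance = 1e-12)
    }
    # degenerate variable contributes the neutral midpoint
    expect_equal(eq1Position(3, 3, 3, 0, 10), 5)
})

test_that("2D projection realizes the anchor-pull principle", {
    a8 <- makeAnchors(LETTERS[1:8])
    vals <- c(20, 35, 50, 7, 60, 45, 97, 80)
    u <- eq1Position(vals, 7, 97)
    expect_equal(which.max(u), 7L)  # anchor G pulls hardest (value 97)
    expect_equal(which.min(u), 4L)  # anchor D pulls weakest (value 7)
    expect_equal(order(u), order(vals))  # pull order = value order

    # unit weight on one anchor puts the point exactly there
    e1 <- c(1, rep(0, 7))
    expect_equal(unname(projectRadVis2D(e1, a8)[c("x", "y")]),
                 unname(anchorPositions(a8)[1L, ]), tolerance = 1e-12)
    # equal nonzero weights cancel at the center
    expect_equal(unname(projectRadVis2D(rep(0.4, 8), a8)),
                 c(0, 0, 0), tolerance = 1e-12)
    expect_error(projectRadVis2D(c(1, 0), a8), "does not match")
})

test_that("2D points stay inside the anchor convex hull (disc)", {
    set.seed(21)
    a <- makeAnchors(letters[1:6])
    u <- matrix(runif(600), ncol = 6)
    lay <- layoutCohort(`colnames<-`(u, a@variableOrder), a, "radvis2d")
    expect_true(all(sqrt(lay$x^2 + lay$y^2) <= a@radius + 1e-12))
    expect_true(all(lay$z == 0))
})

test_that("3D projection sends minima to the bottom-center and maxima to the top", {
    a <- makeAnchors(sprintf("v%02d", 1:15), height = 1)
    expect_equal(unname(projectRadVis3D(rep(0, 15), a)), c(0, 0, 0))
    expect_equal(unname(projectRadVis3D(rep(1, 15), a)), c(0, 0, 1),
                 tolerance = 1e-12)
})

test_that("proportional rows overlap in (x, y) but separate in z", {
    set.seed(33)
    a <- makeAnchors(letters[1:10])
    for (i in 1:50) {
        u <- runif(10, 0.05, 1)
        cc <- runif(1, 0.05, 0.95)
        p1 <- projectRadVis3D(u, a)
        p2 <- projectRadVis3D(cc * u, a)
        expect_equal(p1[c("x", "y")], p2[c("x", "y")], tolerance = 1e-9)
        expect_equal(unname(p2["z"]), unname(cc * p1["z"]), tolerance = 1e-9)
    }
})

test_that("raising any single value strictly increases height", {
    set.seed(5)
    a <- makeAnchors(letters[1:7])
    u <- runif(7, 0, 0.9)
    z0 <- projectRadVis3D(u, a)["z"]
    for (j in 1:7) {
        u2 <- u; u2[j] <- u2[j] + 0.05
        expect_gt(projectRadVis3D(u2, a)["z"], z0)
    }
})

test_that("permuting variables and anchors together leaves points fixed", {
    set.seed(8)
    nms <- letters[1:9]
    u <- runif(9); names(u) <- nms
    a <- makeAnchors(nms)
    p0 <- projectRadVis3D(u, a)
    # rotating the variable order rotates anchor labels with their positions,
    # so the laid-out point only rotates by the same angle around the axis
    shift <- 2L
    perm <- c(nms[-seq_len(shift)], nms[seq_len(shift)])
    p1 <- projectRadVis3D(u[perm], makeAnchors(perm))
    th <- 2 * pi * shift / 9   # each anchor position rotates by +th
    rot <- c(cos(th) * p0["x"] - sin(th) * p0["y"],
             sin(th) * p0["x"] + cos(th) * p0["y"])
    expect_equal(unname(p1[c("x", "y")]), unname(rot), tolerance = 1e-12)
    expect_equal(p1["z"], p0["z"], tolerance = 1e-12)
})

test_that("vectorized layout equals per-row recomputation", {
    set.seed(13)
    total <- 0L
    for (n in c(3, 5, 8, 12, 20)) {
        rows <- 200L
        total <- total + rows
        a <- makeAnchors(sprintf("v%d", seq_len(n)))
        u <- matrix(runif(rows * n), ncol = n,
                    dimnames = list(NULL, a@variableOrder))
        for (mode in c("radvis2d", "radvis3d")) {
            lay <- layoutCohort(u, a, mode)
            expect_equal(unname(as.matrix(lay[, c("x", "y", "z")])),
                         unname(oracleProject(u, a, mode)), tolerance = 1e-12)
        }
    }
    expect_gte(total, 1000L)
})

test_that("layout is deterministic and duplicates rows to identical points", {
    co <- separatedCohort(100, seed = 2)
    u <- normalizeScores(co)
    a <- makeAnchors(selectVariables(co, rownames(co), "anchors"))
    lay1 <- layoutCohort(u, a, "radvis3d")
    lay2 <- layoutCohort(u, a, "radvis3d")
    expect_identical(lay1, lay2)
    expect_equal(nrow(lay1), 100L)
    expect_true(all(sqrt(lay1$x^2 + lay1$y^2) <= a@radius + 1e-12))
    expect_true(all(lay1$z >= 0 & lay1$z <= a@height))
    u2 <- rbind(u, u[1L, , drop = FALSE])
    rownames(u2)[101] <- "dup"
    lay3 <- layoutCohort(u2, a, "radvis3d")
    expect_equal(unlist(lay3[101, c("x", "y", "z")]),
                 unlist(lay3[1, c("x", "y", "z")]), ignore_attr = TRUE)
    expect_error(layoutCohort(u[, rev(colnames(u))], a, "radvis3d"),
                 "order")
})
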