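test_that("forgy initialization samples distinct data points, seeded", {
    set.seed(1)
    pts <- matrix(rnorm(30), ncol = 3,
                  dimnames = list(paste0("p", 1:10), c("x", "y", "z")))
    c1 <- initCenters(pts, 4, "forgy", seed = 7)
    expect_identical(c1, initCenters(pts, 4, "forgy", seed = 7))
    expect_true(all(apply(c1, 1, function(r)
        any(colSums(abs(t(pts) - r)) < 1e-12))))
    # k = n: a permutation of all the points
    cAll <- initCenters(pts, 10, "forgy", seed = 3)
    expect_equal(cAll[order(cAll[, 1]), ], pts[order(pts[, 1]), ],
                 ignore_attr = TRUE)
    expect_error(initCenters(pts, 11, "forgy"), "k <= 10")
    expect_error(initCenters(pts, 0, "forgy"), "k")
})

test_that("random pivots land inside the cylinder volume", {
    pts <- matrix(0, 2, 3)
    ctr <- initCenters(pts, 10000, "random", seed = 2, radius = 1, height = 1)
    expect_true(all(ctr[, 1]^2 + ctr[, 2]^2 <= 1))
    expect_true(all(ctr[, 3] >= 0 & ctr[, 3] <= 1))
    # without a cylinder: bounding box of the data
    pts2 <- rbind(c(-2, 5), c(4, 6))
    ctr2 <- initCenters(pts2, 1000, "random", seed = 2)
    expect_true(all(ctr2[, 1] >= -2 & ctr2[, 1] <= 4))
    expect_true(all(ctr2[, 2] >= 5 & ctr2[, 2] <= 6))
})

test_that("k = 1 collapses to the global mean in at most two iterations", {
    set.seed(6)
    pts <- matrix(rnorm(40), ncol = 2)
    m <- kmeansRadVis(pts, 1, "forgy", seed = 1, space = "feature")
    expect_equal(unname(m@centers[1, ]), unname(colMeans(pts)))
    expect_lte(m@nIterations, 2L)
    expect_true(m@converged)
})

test_that("separated point masses are recovered exactly", {
    pts <- rbind(matrix(rep(c(1, 0, 0), 5), ncol = 3, byrow = TRUE),
                 matrix(rep(c(-1, 0, 0), 5), ncol = 3, byrow = TRUE))
    rownames(pts) <- paste0("p", 1:10)
    m <- kmeansRadVis(pts, 2, "forgy", seed = 2)
    expect_equal(sort(m@centers[, 1]), c(-1, 1))
    expect_equal(totalWithinSS(m), 0)
})

test_that("the objective never increases and fixtures converge", {
    set.seed(31)
    for (rep in 1:10) {
        pts <- matrix(rnorm(60 * 3), ncol = 3)
        rownames(pts) <- paste0("p", 1:60)
        init <- if (rep %% 2) "forgy" else "random"
        m <- kmeansRadVis(pts, 4, init, seed = rep, radius = 3, height = 3)
        expect_true(all(diff(m@wssTrace) <= 1e-8))
        expect_true(m@converged)
        expect_lte(m@nIterations, 300L)
        # every point is assigned to its nearest center
        D <- outer(rowSums(pts^2), rowSums(m@centers^2), "+") -
            2 * pts %*% t(m@centers)
        expect_equal(unname(m@assignments), max.col(-D, ties.method = "first"))
        # non-empty cluster centers equal their member means
        for (j in unique(m@assignments))
            expect_equal(unname(m@centers[j, ]),
                         unname(colMeans(pts[m@assignments == j, , drop = FALSE])),
                         tolerance = 1e-8)
    }
})

test_that("forgy with a fixed seed is bit-identical across runs", {
    co <- separatedCohort(150, seed = 4)
    u <- normalizeScores(co)
    runs <- lapply(1:3, function(i)
        kmeansRadVis(u, 5, "forgy", seed = 42, space = "feature"))
    expect_identical(runs[[1]]@centers, runs[[2]]@centers)
    expect_identical(runs[[2]]@centers, runs[[3]]@centers)
    expect_identical(runs[[1]]@assignments, runs[[3]]@assignments)
    expect_identical(runs[[1]]@wssTrace, runs[[3]]@wssTrace)
})

test_that("restarts reach the exhaustive-enumeration optimum on small data", {
    set.seed(17)
    pts <- matrix(runif(10 * 2), ncol = 2)
    rownames(pts) <- paste0("p", 1:10)
    best <- oracleBestWSS(pts, 3)
    m <- kmeansRadVis(pts, 3, "random", seed = 1, space = "feature",
                      nRestarts = 10)
    expect_gte(totalWithinSS(m) + 1e-9, best)     # never below the optimum
    expect_equal(totalWithinSS(m), best, tolerance = 1e-6)
})

test_that("converged fits agree with an independent Lloyd implementation", {
    set.seed(23)
    pts <- rbind(matrix(rnorm(40, 0), ncol = 2),
                 matrix(rnorm(40, 6), ncol = 2))
    rownames(pts) <- paste0("p", 1:40)
    m <- kmeansRadVis(pts, 2, "forgy", seed = 5, space = "feature",
                      nRestarts = 5)
    ref <- stats::kmeans(pts, 2, nstart = 10)
    expect_equal(totalWithinSS(m), ref$tot.withinss, tolerance = 1e-8)
})

test_that("empty clusters are repaired so k clusters survive", {
    # three distinct points, k = 3, random init in a box far from the data
    pts <- rbind(c(0, 0), c(10, 0), c(5, 8), c(0.1, 0), c(10.1, 0), c(5, 8.1))
    rownames(pts) <- paste0("p", 1:6)
    m <- kmeansRadVis(pts, 3, "random", seed = 11, space = "feature")
    expect_equal(sort(unique(m@assignments)), 1:3)
    expect_true(m@converged)
})

test_that("cluster summaries report exact means, medians and shares", {
    co <- tinyCohort()
    # hand-made assignment: {p1,p2,p3} vs {p4,p5,p6}
    model <- methods::new("ClusterModel", k = 2L, space = "feature",
                          init = "forgy", seed = 1L,
                          centers = matrix(0, 2, 3),
                          assignments = stats::setNames(
                              c(1L, 1L, 1L, 2L, 2L, 2L), paste0("p", 1:6)),
                          nIterations = 1L, converged = TRUE, wssTrace = 1)
    s <- summarizeClusters(model, co)
    expect_equal(unname(s$sizes), c(3L, 3L))
    n1 <- s$numeric[s$numeric$cluster == 1 & s$numeric$variable == "item_01", ]
    expect_equal(n1$mean, mean(c(0, 3, 2)))
    expect_equal(n1$median, 2)
    shares <- s$categorical
    ad1 <- shares[shares$cluster == 1 & shares$variable == "diagnosis" &
                  shares$level == "AD", "share"]
    expect_equal(ad1, 1 / 3)
    expect_equal(sum(s$sizes), length(model@assignments))
    # single-member cluster: mean = median = the row's value
    model1 <- methods::new("ClusterModel", k = 6L, space = "feature",
                           init = "forgy", seed = 1L,
                           centers = matrix(0, 6, 3),
                           assignments = stats::setNames(1:6, paste0("p", 1:6)),
                           nIterations = 1L, converged = TRUE, wssTrace = 0)
    s1 <- summarizeClusters(model1, co)
    r <- s1$numeric[s1$numeric$cluster == 2 & s1$numeric$variable == "item_01", ]
    expect_equal(r$mean, 3); expect_equal(r$median, 3)
})

test_that("cluster CSV export round-trips, including labels with commas", {
    sc <- rbind(item_01 = c(1, 2, 3, 0), item_02 = c(0, 1, 2, 3),
                item_03 = c(2, 2, 1, 1))
    colnames(sc) <- paste0("p", 1:4)
    co <- CohortExperiment(sc, colData = data.frame(
        site = c("Seoul, KR", "Busan, KR", "Seoul, KR", "Daegu, KR")),
        vMin = 0, vMax = 3)
    u <- normalizeScores(co)
    a <- makeAnchors(rownames(co))
    lay <- layoutCohort(u, a, "radvis3d")
    m <- kmeansRadVis(u, 2, "forgy", seed = 1, space = "feature")
    p <- withr::local_tempfile(fileext = ".csv")
    exportClusters(m, co, p, layout = lay)
    back <- utils::read.csv(p)
    expect_equal(nrow(back), 4L)
    expect_equal(back$cluster, unname(m@assignments[back$id]))
    expect_equal(back$site, as.character(
        SummarizedExperiment::colData(co)$site[match(back$id, colnames(co))]))
    expect_equal(back$x, lay$x[match(back$id, lay$id)])
    # and the file re-loads as a cohort
    co2 <- readCohort(p)
    expect_equal(ncol(co2), 4L)
})
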