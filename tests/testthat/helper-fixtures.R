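# Fixtures built in code; no files.

# hand-built 6-patient cohort: 3 items on [0, 3], stage + gender covariates
tinyCohort <- function() {
    scores <- rbind(
        item_01 = c(0, 3, 2, 1, 3, 0),
        item_02 = c(1, 2, 2, 0, 3, 1),
        item_03 = c(0, 3, 1, 1, 2, 0)
    )
    colnames(scores) <- paste0("p", 1:6)
    CohortExperiment(scores,
                     colData = data.frame(
                         diagnosis = c("AD", "SMI", "MCI", "AD", "SMI", "SVD"),
                         gender = c("F", "M", "F", "M", "F", "M")),
                     vMin = 0, vMax = 3)
}

# independent per-row RadVis barycenter, deliberately loop-based
oracleProject <- function(u, anchors, mode = "radvis2d") {
    A <- anchorPositions(anchors)
    H <- anchors@height
    t(vapply(seq_len(nrow(u)), function(r) {
        w <- if (mode == "radvis3d")
            anchors@pMin + u[r, ] * (anchors@pMax - anchors@pMin)
        else u[r, ]
        s <- sum(w)
        xy <- if (s > 0) colSums(w * A) / s else c(0, 0)
        c(xy, if (mode == "radvis3d") H * mean(u[r, ]) else 0)
    }, numeric(3L)))
}

# brute-force multifilter oracle: naive per-row scan over a plain data.frame
oracleFilter <- function(df, filters) {
    pass <- vapply(seq_len(nrow(df)), function(i) {
        for (nm in names(filters)) {
            sel <- filters[[nm]]
            v <- df[[nm]][i]
            ok <- if (is.character(sel)) {
                as.character(v) %in% sel
            } else {
                any(vapply(seq_len(nrow(sel)),
                           function(r) v >= sel[r, 1] && v <= sel[r, 2],
                           logical(1)))
            }
            if (!ok) return(FALSE)
        }
        TRUE
    }, logical(1))
    df$id[pass]
}

# exhaustive k-means optimum: minimum within-cluster SS over all assignments
# of n points into at most k clusters (enumeration over k^n label vectors)
oracleBestWSS <- function(points, k) {
    n <- nrow(points)
    best <- Inf
    labels <- rep(1L, n)
    repeat {
        wss <- 0
        for (j in unique(labels)) {
            m <- points[labels == j, , drop = FALSE]
            ctr <- colMeans(m)
            wss <- wss + sum(sweep(m, 2L, ctr)^2)
        }
        if (wss < best) best <- wss
        # odometer increment in base k
        i <- 1L
        while (i <= n) {
            labels[i] <- labels[i] + 1L
            if (labels[i] <= k) break
            labels[i] <- 1L
            i <- i + 1L
        }
        if (i > n) break
    }
    best
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

separatedCohort <- local({
    cache <- new.env()
    function(n = 500L, seed = 1L) {
        key <- paste0("c", n, "_", seed)
        if (is.null(cache[[key]]))
            cache[[key]] <- generateCohort(defaultSeparatedConfig(n, seed))
        cache[[key]]
    }
})
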