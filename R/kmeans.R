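#' Initial cluster centers
#'
#' \code{forgy}: a seeded sample of k distinct data points (without
#' replacement) becomes the initial centers, so a fixed seed always yields the
#' same segmentation. \code{random}: k pivot points drawn uniformly inside the
#' data volume -- the cylinder of the 3D layout when \code{radius} and
#' \code{height} are supplied (area-uniform over the disc), otherwise the
#' per-dimension bounding box of the points.
#'
#' @param points n-by-d numeric matrix (rows = patients).
#' @param k number of centers.
#' @param init \code{"forgy"} or \code{"random"}.
#' @param seed integer RNG seed.
#' @param radius,height cylinder geometry for random pivots in 3D layout
#'   space; \code{NULL} falls back to the bounding box.
#' @return k-by-d matrix of centers.
#' @export
initCenters <- function(points, k, init = c("forgy", "random"), seed = 1L,
                        radius = NULL, height = NULL) {
    init <- match.arg(init)
    points <- as.matrix(points)
    if (k <= 0) stop("k must be >= 1")
    set.seed(seed)
    if (init == "forgy") {
        distinct <- unique(points)
        if (k > nrow(distinct))
            stop(sprintf("forgy needs k <= %d distinct points", nrow(distinct)))
        centers <- distinct[sample.int(nrow(distinct), k), , drop = FALSE]
    } else if (!is.null(radius) && !is.null(height) && ncol(points) == 3L) {
        r <- radius * sqrt(stats::runif(k))
        th <- stats::runif(k, 0, 2 * pi)
        centers <- cbind(r * cos(th), r * sin(th), stats::runif(k, 0, height))
    } else {
        lo <- apply(points, 2L, min)
        hi <- apply(points, 2L, max)
        centers <- sapply(seq_len(ncol(points)),
                          function(j) stats::runif(k, lo[j], hi[j]))
        centers <- matrix(centers, nrow = k)
    }
    dimnames(centers) <- list(NULL, colnames(points))
    centers
}

# squared Euclidean distances, n x k (internal)
sqDistToCenters <- function(points, centers) {
    pp <- rowSums(points^2)
    cc <- rowSums(centers^2)
    outer(pp, cc, "+") - 2 * points %*% t(centers)
}

#' Lloyd k-means segmentation
#'
#' Alternates nearest-center assignment (Euclidean distance, ties broken to
#' the lowest cluster index) and center mean updates until no center moves by
#' more than 1e-9 or \code{maxIter} is reached -- i.e., "until the central
#' point remains constant". An empty cluster is repaired by reseeding its
#' center at the point farthest from it, keeping k clusters. The total
#' within-cluster sum of squares is recorded after every iteration and is
#' non-increasing. With \code{nRestarts > 1} the run is repeated from seeds
#' \code{seed, seed + 1, ...} and the model with the lowest objective wins.
#'
#' @inheritParams initCenters
#' @param maxIter iteration cap (default 300).
#' @param space label stored on the model: \code{"layout3d"} when clustering
#'   cylinder coordinates from [layoutCohort()], \code{"feature"} when
#'   clustering the normalized item matrix directly.
#' @param nRestarts best-of-m restarts by objective (default 1).
#' @return A \linkS4class{ClusterModel}.
#' @examples
#' pts <- rbind(matrix(rnorm(60, 0), 30), matrix(rnorm(60, 5), 30))
#' rownames(pts) <- paste0("p", 1:60)
#' kmeansRadVis(pts, k = 2, init = "forgy", seed = 3, space = "feature")
#' @export
kmeansRadVis <- function(points, k, init = c("forgy", "random"), seed = 1L,
                         maxIter = 300L, space = c("layout3d", "feature"),
                         radius = NULL, height = NULL, nRestarts = 1L) {
    init <- match.arg(init)
    space <- match.arg(space)
    points <- as.matrix(points)
    storage.mode(points) <- "double"
    if (is.null(rownames(points)))
        rownames(points) <- as.character(seq_len(nrow(points)))
    if (k < 1L || k > nrow(points))
        stop("k must satisfy 1 <= k <= number of points")
    best <- NULL
    for (r in seq_len(nRestarts)) {
        s <- as.integer(seed) + r - 1L
        fit <- lloydOnce(points, k, init, s, maxIter, radius, height)
        if (is.null(best) || fit$wss < best$wss - 1e-12) {
            best <- fit
            best$seed <- s
        }
    }
    methods::new("ClusterModel", k = as.integer(k), space = space, init = init,
                 seed = best$seed, centers = best$centers,
                 assignments = best$assignments,
                 nIterations = best$iter, converged = best$converged,
                 wssTrace = best$trace)
}

lloydOnce <- function(points, k, init, seed, maxIter, radius, height) {
    centers <- initCenters(points, k, init, seed, radius, height)
    trace <- numeric(0)
    converged <- FALSE
    iter <- 0L
    assign <- integer(nrow(points))
    repeat {
        iter <- iter + 1L
        D <- sqDistToCenters(points, centers)
        assign <- max.col(-D, ties.method = "first")
        # empty-cluster repair: reseed at the farthest point, then reassign
        empty <- setdiff(seq_len(k), unique(assign))
        for (j in empty) {
            far <- which.max(D[, j])
            centers[j, ] <- points[far, ]
            D <- sqDistToCenters(points, centers)
            assign <- max.col(-D, ties.method = "first")
        }
        newCenters <- centers
        for (j in seq_len(k)) {
            members <- assign == j
            if (any(members))
                newCenters[j, ] <- colMeans(points[members, , drop = FALSE])
        }
        trace <- c(trace, sum(sqDistToCenters(points, newCenters)[
            cbind(seq_len(nrow(points)), assign)]))
        moved <- max(abs(newCenters - centers))
        centers <- newCenters
        if (moved <= 1e-9) { converged <- TRUE; break }
        if (iter >= maxIter) break
    }
    list(centers = centers,
         assignments = stats::setNames(assign, rownames(points)),
         iter = iter, converged = converged, trace = trace,
         wss = trace[length(trace)])
}

#' Total within-cluster sum of squares
#' @param model a \linkS4class{ClusterModel}.
#' @export
totalWithinSS <- function(model) model@wssTrace[length(model@wssTrace)]

#' Per-cluster descriptive statistics
#'
#' The cluster index panel: per cluster, its size, the mean and median of
#' every numeric variable (score items and numeric covariates), and the
#' composition share of every categorical covariate level (e.g., the
#' diagnosis-stage mix of each cluster).
#'
#' @param model a \linkS4class{ClusterModel}.
#' @param cohort the \linkS4class{CohortExperiment} the model was fit on;
#'   patients are matched by id (patients dropped before clustering, e.g. for
#'   missing values, are simply absent from the summary).
#' @return list of class \code{"ClusterSummary"}: \code{sizes} (named integer),
#'   \code{numeric} (data.frame cluster/variable/mean/median) and
#'   \code{categorical} (data.frame cluster/variable/level/share).
#' @export
summarizeClusters <- function(model, cohort) {
    ids <- names(model@assignments)
    if (!all(ids %in% colnames(cohort)))
        stop("model assignments name patients absent from the cohort")
    cl <- model@assignments
    sizes <- stats::setNames(tabulate(cl, nbins = model@k), seq_len(model@k))
    info <- variableInfo(cohort)
    numNames <- info$name[info$kind == "numeric"]
    catNames <- info$name[info$kind == "categorical"]
    raw <- rawValues(cohort, numNames)[, ids, drop = FALSE]
    num <- do.call(rbind, lapply(seq_len(model@k), function(j) {
        cols <- cl == j
        if (!any(cols))
            return(NULL)
        data.frame(cluster = j, variable = numNames,
                   mean = rowMeans(raw[, cols, drop = FALSE]),
                   median = apply(raw[, cols, drop = FALSE], 1L, stats::median),
                   row.names = NULL, stringsAsFactors = FALSE)
    }))
    cd <- SummarizedExperiment::colData(cohort)[ids, , drop = FALSE]
    cat <- do.call(rbind, lapply(catNames, function(nm) {
        do.call(rbind, lapply(seq_len(model@k), function(j) {
            v <- cd[[nm]][cl == j]
            if (!length(v)) return(NULL)
            tab <- table(v) / length(v)
            data.frame(cluster = j, variable = nm, level = names(tab),
                       share = as.numeric(tab),
                       row.names = NULL, stringsAsFactors = FALSE)
        }))
    }))
    structure(list(sizes = sizes, numeric = num, categorical = cat),
              class = "ClusterSummary")
}

#' @export
print.ClusterSummary <- function(x, ...) {
    cat("ClusterSummary:", length(x$sizes), "clusters; sizes:",
        paste(x$sizes, collapse = ", "), "\n")
    invisible(x)
}

#' Export a clustered cohort to CSV
#'
#' Writes the original patient rows (id, covariates, items), the layout
#' coordinates when given, and the cluster index, quoting labels so the file
#' re-parses with standard CSV tooling.
#'
#' @param model a \linkS4class{ClusterModel}.
#' @param cohort the source \linkS4class{CohortExperiment}.
#' @param path output CSV path.
#' @param layout optional layout data.frame from [layoutCohort()] supplying
#'   x, y, z columns (matched by id).
#' @return invisibly, \code{path}.
#' @export
exportClusters <- function(model, cohort, path, layout = NULL) {
    ids <- names(model@assignments)
    cd <- as.data.frame(SummarizedExperiment::colData(cohort)[ids, , drop = FALSE])
    scores <- t(SummarizedExperiment::assay(cohort, "scores")[, ids, drop = FALSE])
    df <- data.frame(id = ids, cd, scores, check.names = FALSE,
                     stringsAsFactors = FALSE)
    if (!is.null(layout)) {
        m <- match(ids, layout$id)
        if (anyNA(m)) stop("layout is missing some clustered patients")
        df$x <- layout$x[m]; df$y <- layout$y[m]; df$z <- layout$z[m]
    }
    df$cluster <- as.integer(model@assignments)
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
    invisible(path)
}

#' @describeIn kmeansRadVis compact display of a ClusterModel
#' @param object a \code{ClusterModel}
#' @export
setMethod("show", "ClusterModel", function(object) {
    cat(sprintf(
        "ClusterModel: k = %d (%s init, seed %d, %s space)\n  %d iterations, converged = %s, total within-SS = %.6g\n",
        object@k, object@init, object@seed, object@space, object@nIterations,
        object@converged, totalWithinSS(object)))
})
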