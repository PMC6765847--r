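#' Patient-patient similarity matrix
#'
#' Pairwise similarity of patients across their normalized item values.
#' \code{cosine}: dot(a, b) / (|a| |b|), with the convention that any pair
#' involving an all-zero vector scores 0. \code{pearson} / \code{spearman}:
#' the sample (rank) correlation of the two rows across variables; pairs whose
#' correlation is undefined (a constant row) score 0. Diagonal entries are 1
#' for rows where the metric is defined.
#'
#' @param u patients-by-variables normalized matrix (>= 2 rows, >= 2 columns).
#' @param metric \code{"cosine"}, \code{"pearson"} or \code{"spearman"}.
#' @return symmetric patients-by-patients matrix with dimnames from
#'   \code{rownames(u)}.
#' @export
similarityMatrix <- function(u, metric = c("cosine", "pearson", "spearman")) {
    metric <- match.arg(metric)
    u <- as.matrix(u)
    if (nrow(u) < 2L || ncol(u) < 2L)
        stop("need at least 2 patients and 2 variables")
    if (metric == "cosine") {
        nrm <- sqrt(rowSums(u^2))
        s <- u %*% t(u)
        denom <- outer(nrm, nrm)
        s <- ifelse(denom > 0, s / denom, 0)
        diag(s)[nrm > 0] <- 1
    } else {
        s <- suppressWarnings(stats::cor(t(u), method = metric))
        s[is.na(s)] <- 0
        diag(s)[apply(u, 1L, function(r) stats::var(r) > 0)] <- 1
    }
    dimnames(s) <- list(rownames(u), rownames(u))
    s
}

#' Build a thresholded similarity graph
#'
#' Links every unordered pair of distinct patients whose similarity is at
#' least the threshold. Raising the threshold can only remove edges (nested
#' graphs); since the threshold lives in [0, 1], negative correlations never
#' form edges.
#'
#' @param sim symmetric similarity matrix (e.g., from [similarityMatrix()]).
#' @param threshold number in [0, 1].
#' @param metric label stored on the graph (default \code{"cosine"}).
#' @return A \linkS4class{SimilarityGraph}.
#' @export
buildSimilarityGraph <- function(sim, threshold, metric = "cosine") {
    sim <- as.matrix(sim)
    if (nrow(sim) != ncol(sim) || max(abs(sim - t(sim))) > 1e-9)
        stop("similarity matrix must be symmetric")
    if (threshold < 0 || threshold > 1)
        stop("threshold must lie in [0, 1]")
    ids <- rownames(sim)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(sim)))
    pairs <- which(upper.tri(sim) & sim >= threshold, arr.ind = TRUE)
    edges <- data.frame(from = ids[pairs[, 1L]], to = ids[pairs[, 2L]],
                        weight = sim[pairs], stringsAsFactors = FALSE)
    methods::new("SimilarityGraph", nodeIds = ids, metric = metric,
                 threshold = threshold, edges = edges)
}

#' Seeded force-directed layout of a similarity graph
#'
#' Fruchterman-Reingold placement (via igraph) from seeded uniform initial
#' positions, so a fixed seed reproduces the layout exactly. A single-node
#' graph is placed at the origin.
#'
#' @param graph a \linkS4class{SimilarityGraph}.
#' @param iterations iteration count (default 250).
#' @param seed integer RNG seed.
#' @return numeric matrix (nodes x 2) of positions, rownames = node ids.
#' @export
forceLayout <- function(graph, iterations = 250L, seed = 1L) {
    stopifnot(methods::is(graph, "SimilarityGraph"))
    ids <- graph@nodeIds
    if (length(ids) == 0L) stop("graph has no nodes")
    if (length(ids) == 1L)
        return(matrix(0, 1L, 2L, dimnames = list(ids, c("x", "y"))))
    g <- igraph::graph_from_data_frame(graph@edges, directed = FALSE,
                                       vertices = data.frame(name = ids))
    set.seed(seed)
    coords0 <- matrix(stats::runif(2L * length(ids), -1, 1), ncol = 2L)
    xy <- igraph::layout_with_fr(g, coords = coords0, niter = iterations)
    dimnames(xy) <- list(ids, c("x", "y"))
    xy
}

#' @describeIn buildSimilarityGraph compact display
#' @param object a \code{SimilarityGraph}
#' @export
setMethod("show", "SimilarityGraph", function(object) {
    cat(sprintf("SimilarityGraph: %d nodes, %d edges (%s >= %.3g)\n",
                length(object@nodeIds), nrow(object@edges),
                object@metric, object@threshold))
})
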