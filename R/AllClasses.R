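#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' CohortExperiment: a patient cohort with questionnaire scores
#'
#' Container for a patient cohort measured on a battery of numeric test items
#' (e.g., the 15 S-IADL daily-living questions on a 0--3 Likert scale) together
#' with demographic and diagnostic covariates. Extends
#' \linkS4class{SummarizedExperiment}: the \code{"scores"} assay holds the
#' items-by-patients matrix, \code{rowData} carries the declared per-item value
#' bounds \code{vMin}/\code{vMax} that drive min--max normalization, and
#' \code{colData} carries the per-patient covariates (categorical factors such
#' as diagnosis stage and gender, or additional numerics such as age).
#'
#' @slot .. see \linkS4class{SummarizedExperiment}.
#' @seealso [CohortExperiment()] for construction, [readCohort()] for CSV
#'   ingestion, [normalizeScores()] for the normalized matrix.
#' @exportClass CohortExperiment
setClass("CohortExperiment", contains = "SummarizedExperiment")

setValidity("CohortExperiment", function(object) {
    msg <- character()
    if (!"scores" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'scores' is required")
    else if (!is.numeric(SummarizedExperiment::assay(object, "scores")))
        msg <- c(msg, "assay 'scores' must be numeric")
    rd <- SummarizedExperiment::rowData(object)
    if (!all(c("vMin", "vMax") %in% colnames(rd)))
        msg <- c(msg, "rowData must contain vMin and vMax")
    else if (any(rd$vMin > rd$vMax))
        msg <- c(msg, "vMin must not exceed vMax")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "patient ids (colnames) must be unique")
    if (length(msg)) msg else TRUE
})

#' AnchorLayout: dimensional anchors on a circle or cylinder
#'
#' Geometry of a RadVis layout: \code{n} dimensional anchors placed at
#' equidistant angles on a circle of given radius (2D) or as the vertical
#' edges of a cylinder of given height (3D). Each variable additionally has
#' position bounds \code{pMin}/\code{pMax} onto which its normalized value is
#' mapped; with the defaults 0 and 1 the placement rule reduces to plain
#' min--max normalization.
#'
#' @slot angles numeric, anchor angles in radians, strictly equally spaced.
#' @slot radius positive number, circle/cylinder radius.
#' @slot height positive number, cylinder height (ignored by 2D projections).
#' @slot pMin,pMax numeric per-variable position bounds, \code{pMin < pMax}.
#' @slot variableOrder character, variable names in anchor order.
#' @seealso [makeAnchors()], [layoutCohort()]
#' @exportClass AnchorLayout
setClass("AnchorLayout", representation(
    angles = "numeric",
    radius = "numeric",
    height = "numeric",
    pMin = "numeric",
    pMax = "numeric",
    variableOrder = "character"
))

setValidity("AnchorLayout", function(object) {
    n <- length(object@angles)
    msg <- character()
    if (n < 3L)
        msg <- c(msg, "at least 3 anchors are required")
    if (length(object@radius) != 1L || object@radius <= 0)
        msg <- c(msg, "radius must be a single positive number")
    if (length(object@height) != 1L || object@height <= 0)
        msg <- c(msg, "height must be a single positive number")
    if (n >= 2L) {
        gaps <- diff(object@angles)
        if (max(abs(abs(gaps) - 2 * pi / n)) > 1e-8)
            msg <- c(msg, "anchor angles must be equally spaced by 2*pi/n")
    }
    if (length(object@pMin) != n || length(object@pMax) != n)
        msg <- c(msg, "pMin and pMax must have one entry per anchor")
    else if (any(object@pMin >= object@pMax))
        msg <- c(msg, "pMin must be strictly less than pMax")
    if (length(object@variableOrder) != n)
        msg <- c(msg, "variableOrder must name every anchor")
    if (length(msg)) msg else TRUE
})

#' SimilarityGraph: thresholded patient-patient similarity graph
#'
#' Undirected graph over patients in which an edge joins two distinct patients
#' whenever their similarity (cosine, Pearson or Spearman over the normalized
#' item values) reaches a threshold in [0, 1].
#'
#' @slot nodeIds character, patient identifiers.
#' @slot metric one of \code{"cosine"}, \code{"pearson"}, \code{"spearman"}.
#' @slot threshold numeric in [0, 1].
#' @slot edges data.frame with columns \code{from}, \code{to}, \code{weight};
#'   each unordered pair appears once.
#' @seealso [similarityMatrix()], [buildSimilarityGraph()], [forceLayout()]
#' @exportClass SimilarityGraph
setClass("SimilarityGraph", representation(
    nodeIds = "character",
    metric = "character",
    threshold = "numeric",
    edges = "data.frame"
))

setValidity("SimilarityGraph", function(object) {
    msg <- character()
    if (!object@metric %in% c("cosine", "pearson", "spearman"))
        msg <- c(msg, "metric must be cosine, pearson or spearman")
    if (length(object@threshold) != 1L ||
        object@threshold < 0 || object@threshold > 1)
        msg <- c(msg, "threshold must lie in [0, 1]")
    e <- object@edges
    if (!all(c("from", "to", "weight") %in% colnames(e)))
        msg <- c(msg, "edges needs columns from, to, weight")
    else {
        if (nrow(e) && !all(c(e$from, e$to) %in% object@nodeIds))
            msg <- c(msg, "edge endpoints must be node ids")
        if (nrow(e) && any(e$from == e$to))
            msg <- c(msg, "self loops are not allowed")
    }
    if (length(msg)) msg else TRUE
})

#' ClusterModel: a converged k-means segmentation
#'
#' Result of Lloyd k-means over patient points, either in 3D layout space
#' (the cylinder coordinates) or in normalized feature space.
#'
#' @slot k integer number of clusters.
#' @slot space \code{"layout3d"} or \code{"feature"}.
#' @slot init \code{"forgy"} (seeded choice of k data points) or
#'   \code{"random"} (uniform draws inside the data volume).
#' @slot seed integer RNG seed used for initialization.
#' @slot centers k-by-d matrix of cluster centers.
#' @slot assignments named integer vector, cluster index per patient (1..k).
#' @slot nIterations integer Lloyd iterations executed.
#' @slot converged logical, TRUE when no center moved more than 1e-9.
#' @slot wssTrace numeric, total within-cluster sum of squares after each
#'   iteration (non-increasing).
#' @seealso [kmeansRadVis()], [summarizeClusters()], [exportClusters()]
#' @exportClass ClusterModel
setClass("ClusterModel", representation(
    k = "integer",
    space = "character",
    init = "character",
    seed = "integer",
    centers = "matrix",
    assignments = "integer",
    nIterations = "integer",
    converged = "logical",
    wssTrace = "numeric"
))

setValidity("ClusterModel", function(object) {
    msg <- character()
    if (object@k < 1L)
        msg <- c(msg, "k must be >= 1")
    if (nrow(object@centers) != object@k)
        msg <- c(msg, "centers must have k rows")
    if (length(object@assignments) &&
        (min(object@assignments) < 1L || max(object@assignments) > object@k))
        msg <- c(msg, "assignments must index 1..k")
    if (is.null(names(object@assignments)))
        msg <- c(msg, "assignments must be named by patient id")
    if (length(object@wssTrace) > 1L && any(diff(object@wssTrace) > 1e-8))
        msg <- c(msg, "within-cluster SS trace must be non-increasing")
    if (length(msg)) msg else TRUE
})

#' FilterSet: parallel-coordinates multifilter
#'
#' Per-axis selections combined conjunctively across axes. A numeric axis
#' carries a union of closed intervals (a two-column lo/hi matrix); a
#' categorical axis carries a set of selected category labels. Axes without a
#' selection are unconstrained.
#'
#' @slot filters named list; numeric matrix (m x 2) or character vector per axis.
#' @seealso [filterSet()], [applyFilter()]
#' @exportClass FilterSet
setClass("FilterSet", representation(filters = "list"))

setValidity("FilterSet", function(object) {
    f <- object@filters
    if (length(f) && is.null(names(f)))
        return("filters must be named by axis variable")
    for (nm in names(f)) {
        sel <- f[[nm]]
        if (is.matrix(sel)) {
            if (ncol(sel) != 2L || !is.numeric(sel))
                return(sprintf("axis '%s': intervals must be an m x 2 numeric matrix", nm))
            if (any(sel[, 1L] > sel[, 2L]))
                return(sprintf("axis '%s': interval lower bound exceeds upper bound", nm))
        } else if (!is.character(sel)) {
            return(sprintf("axis '%s': selection must be intervals or category labels", nm))
        }
    }
    TRUE
})
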