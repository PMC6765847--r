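#' Place dimensional anchors on a circle / cylinder
#'
#' Anchor i (counting from 0, in the given variable order) sits at angle
#' pi/2 - 2*pi*i/n: the first anchor at 12 o'clock, subsequent anchors
#' clockwise, all at equidistant angular intervals. In 3D the same angles give
#' the vertical edges of a cylinder of the given height.
#'
#' @param variables character vector of numeric variable names, or the result
#'   of [selectVariables()] with \code{purpose = "anchors"}.
#' @param radius circle/cylinder radius (default 1).
#' @param height cylinder height H (default 1).
#' @param pMin,pMax per-variable position bounds onto which normalized values
#'   are mapped (defaults 0 and 1, reducing the placement rule to min--max
#'   normalization).
#' @return An \linkS4class{AnchorLayout}.
#' @examples
#' a <- makeAnchors(sprintf("item_%02d", 1:15))
#' nAnchors(a)
#' @export
makeAnchors <- function(variables, radius = 1, height = 1, pMin = 0, pMax = 1) {
    if (is.data.frame(variables)) variables <- variables$name
    n <- length(variables)
    if (n < 3L) stop("at least 3 numeric variables are required for a radial layout")
    i <- seq_len(n) - 1L
    methods::new("AnchorLayout",
                 angles = pi / 2 - 2 * pi * i / n,
                 radius = radius, height = height,
                 pMin = rep_len(pMin, n), pMax = rep_len(pMax, n),
                 variableOrder = as.character(variables))
}

#' Number of anchors
#' @param anchors an \linkS4class{AnchorLayout}.
#' @export
nAnchors <- function(anchors) length(anchors@angles)

#' Cartesian anchor positions
#' @param anchors an \linkS4class{AnchorLayout}.
#' @return n x 2 matrix of (x, y) anchor coordinates on the circle.
#' @export
anchorPositions <- function(anchors) {
    cbind(x = anchors@radius * cos(anchors@angles),
          y = anchors@radius * sin(anchors@angles))
}

#' Per-variable position rule
#'
#' Linear interpolation of a raw value between its position bounds:
#' \deqn{Np(i) = (N(i) - Vmin(i)) / (Vmax(i) - Vmin(i)) \cdot (Pmax(i) - Pmin(i)) + Pmin(i)}
#' A value at the variable minimum maps to \code{pMin}, at the maximum to
#' \code{pMax}, affinely in between. A degenerate variable
#' (\code{vMin == vMax}) contributes the neutral midpoint weight 0.5.
#'
#' @param value raw value(s), within [vMin, vMax].
#' @param vMin,vMax variable value bounds.
#' @param pMin,pMax position bounds (default 0, 1).
#' @return numeric position(s) in [pMin, pMax].
#' @examples
#' eq1Position(52, 7, 97, 0, 10)  # 5
#' @export
eq1Position <- function(value, vMin, vMax, pMin = 0, pMax = 1) {
    stopifnot(all(pMin < pMax))
    n <- max(length(value), length(vMin), length(vMax))
    value <- rep_len(value, n)
    vMin <- rep_len(vMin, n)
    vMax <- rep_len(vMax, n)
    u <- rep(0.5, n)                      # degenerate bounds: neutral midpoint
    ok <- vMax > vMin
    u[ok] <- (value[ok] - vMin[ok]) / (vMax[ok] - vMin[ok])
    pMin + u * (pMax - pMin)
}

#' 2D RadVis projection of one normalized row
#'
#' Classic radial-coordinates placement: the record sits at the weighted
#' barycenter of the anchor points, each anchor pulling with strength equal to
#' the record's normalized value on that variable -- the higher the value, the
#' stronger the pull. An all-zero row sits at the circle center.
#'
#' @param uRow normalized values in [0, 1], one per anchor.
#' @param anchors an \linkS4class{AnchorLayout}.
#' @return named numeric c(x, y, z) with z = 0.
#' @export
projectRadVis2D <- function(uRow, anchors) {
    p <- projectRows(matrix(uRow, nrow = 1L), anchors, mode = "radvis2d")
    c(x = p[1L, "x"], y = p[1L, "y"], z = 0)
}

#' 3D cylindrical RadVis projection of one normalized row
#'
#' Horizontal position: the anchor-weighted barycenter with weights given by
#' [eq1Position()] on each variable's position bounds (with the default [0, 1]
#' bounds, the normalized values themselves). Height: z = H * mean(u). A
#' record at the minimum on every variable therefore sits at the bottom-center
#' of the cylinder (0, 0, 0); at the maximum on every variable it rises to
#' z = H. Records whose normalized vectors are proportional share (x, y) but
#' separate in z, which is what resolves the center overlap of 2D RadVis.
#'
#' @inheritParams projectRadVis2D
#' @return named numeric c(x, y, z).
#' @export
projectRadVis3D <- function(uRow, anchors) {
    p <- projectRows(matrix(uRow, nrow = 1L), anchors, mode = "radvis3d")
    c(x = p[1L, "x"], y = p[1L, "y"], z = p[1L, "z"])
}

# vectorized barycenter driver shared by both modes (internal)
projectRows <- function(u, anchors, mode) {
    n <- nAnchors(anchors)
    if (ncol(u) != n)
        stop(sprintf("row length %d does not match %d anchors", ncol(u), n))
    A <- anchorPositions(anchors)
    w <- if (mode == "radvis3d") {
        sweep(sweep(u, 2L, anchors@pMax - anchors@pMin, "*"), 2L, anchors@pMin, "+")
    } else {
        u
    }
    s <- rowSums(w)
    xy <- (w %*% A)
    nz <- s > 0
    xy[nz, ] <- xy[nz, , drop = FALSE] / s[nz]
    xy[!nz, ] <- 0
    z <- if (mode == "radvis3d") anchors@height * rowMeans(u) else rep(0, nrow(u))
    cbind(x = xy[, 1L], y = xy[, 2L], z = z)
}

#' Lay out every patient of a normalized matrix
#'
#' @param u patients-by-variables normalized matrix from [normalizeScores()];
#'   column order must match the anchors' variable order.
#' @param anchors an \linkS4class{AnchorLayout}.
#' @param mode \code{"radvis3d"} (cylinder) or \code{"radvis2d"} (disc, z = 0).
#' @return data.frame with columns \code{id}, \code{x}, \code{y}, \code{z},
#'   one row per patient, in input order.
#' @export
layoutCohort <- function(u, anchors, mode = c("radvis3d", "radvis2d")) {
    mode <- match.arg(mode)
    if (!identical(colnames(u), anchors@variableOrder))
        stop("column order of 'u' does not match the anchor variable order")
    p <- projectRows(u, anchors, mode)
    data.frame(id = if (is.null(rownames(u))) as.character(seq_len(nrow(u)))
                    else rownames(u),
               x = p[, "x"], y = p[, "y"], z = p[, "z"],
               stringsAsFactors = FALSE, row.names = NULL)
}

#' @describeIn makeAnchors compact display of an AnchorLayout
#' @param object an \code{AnchorLayout}
#' @export
setMethod("show", "AnchorLayout", function(object) {
    cat(sprintf("AnchorLayout: %d anchors, radius %.3g, height %.3g\n",
                nAnchors(object), object@radius, object@height))
    cat("  variables:", paste(utils::head(object@variableOrder, 6L), collapse = ", "),
        if (nAnchors(object) > 6L) "..." else "", "\n")
})
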