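# Static HTML/SVG exports. Self-contained text files: an SVG scatter of the
# cylinder layout (one <circle class="node"> per patient, one labelled anchor
# edge per variable) with a small inline script that re-projects the embedded
# coordinates when the rotation slider moves, and an SVG parallel-coordinates
# panel (one <polyline class="case"> per patient).

svgEsc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
}

# oblique projection used both here and by the inline JS
obliqueXY <- function(x, y, z, height) {
    list(sx = x - 0.35 * y, sy = -z - 0.35 * y)
}

PALETTE <- c("#1b9e77", "#d95f02", "#7570b3", "#e7298a", "#66a61e",
             "#e6ab02", "#a6761d", "#666666")

#' Render a 3D RadVis layout to a standalone HTML file
#'
#' Writes a self-contained HTML/SVG scatter of the cylindrical layout with the
#' labelled anchor edges and a rotation slider (inline JavaScript re-projects
#' the embedded coordinates about the z axis). Points are coloured by the
#' optional grouping (cluster index or a covariate such as diagnosis stage).
#'
#' @param layout data.frame from [layoutCohort()].
#' @param anchors the \linkS4class{AnchorLayout} used for the layout.
#' @param path output .html path.
#' @param groups optional factor-like vector, one entry per layout row.
#' @param title figure title.
#' @return invisibly, \code{path}.
#' @export
renderRadVisHTML <- function(layout, anchors, path, groups = NULL,
                             title = "3D RadVis layout") {
    n <- nrow(layout)
    if (is.null(groups)) groups <- rep("all", n)
    groups <- as.factor(groups)
    cols <- PALETTE[(as.integer(groups) - 1L) %% length(PALETTE) + 1L]
    A <- anchorPositions(anchors)
    H <- anchors@height
    sc <- 180
    cx <- 300; cy <- 330
    pr <- obliqueXY(layout$x, layout$y, layout$z, H)
    ar <- obliqueXY(A[, 1L], A[, 2L], 0, H)
    arTop <- obliqueXY(A[, 1L], A[, 2L], H, H)
    nodes <- sprintf(
        '<circle class="node" cx="%.2f" cy="%.2f" r="3" fill="%s" fill-opacity="0.75"><title>%s</title></circle>',
        cx + sc * pr$sx, cy + sc * pr$sy, cols, svgEsc(layout$id))
    edges <- sprintf(
        '<line class="anchor" x1="%.2f" y1="%.2f" x2="%.2f" y2="%.2f" stroke="#999"/>',
        cx + sc * ar$sx, cy + sc * ar$sy, cx + sc * arTop$sx, cy + sc * arTop$sy)
    labels <- sprintf(
        '<text class="anchor-label" x="%.2f" y="%.2f" font-size="10">%s</text>',
        cx + sc * 1.08 * ar$sx, cy + sc * 1.08 * arTop$sy - 6,
        svgEsc(anchors@variableOrder))
    data <- jsonlite::toJSON(list(
        x = layout$x, y = layout$y, z = layout$z,
        ax = A[, 1L], ay = A[, 2L], H = H, sc = sc, cx = cx, cy = cy))
    js <- paste0(
        "var D=", data, ";\n",
        "function prj(x,y,z,a){var c=Math.cos(a),s=Math.sin(a);",
        "var rx=x*c-y*s, ry=x*s+y*c;",
        "return [D.cx+D.sc*(rx-0.35*ry), D.cy+D.sc*(-z-0.35*ry)];}\n",
        "function redraw(a){var ns=document.querySelectorAll('.node');",
        "for(var i=0;i<ns.length;i++){var p=prj(D.x[i],D.y[i],D.z[i],a);",
        "ns[i].setAttribute('cx',p[0]);ns[i].setAttribute('cy',p[1]);}",
        "var es=document.querySelectorAll('.anchor');",
        "var ls=document.querySelectorAll('.anchor-label');",
        "for(var j=0;j<es.length;j++){var b=prj(D.ax[j],D.ay[j],0,a);",
        "var t=prj(D.ax[j],D.ay[j],D.H,a);",
        "es[j].setAttribute('x1',b[0]);es[j].setAttribute('y1',b[1]);",
        "es[j].setAttribute('x2',t[0]);es[j].setAttribute('y2',t[1]);",
        "ls[j].setAttribute('x',t[0]+3);",
        "ls[j].setAttribute('y',t[1]-6);}}\n")
    html <- c(
        "<!DOCTYPE html><html><head><meta charset='utf-8'>",
        sprintf("<title>%s</title></head><body>", svgEsc(title)),
        sprintf("<h3>%s</h3>", svgEsc(title)),
        "<p>Rotate: <input id='rot' type='range' min='0' max='628' value='0'/></p>",
        "<svg width='600' height='430' xmlns='http://www.w3.org/2000/svg'>",
        edges, labels, nodes,
        "</svg>",
        "<script>", js,
        "document.getElementById('rot').addEventListener('input',",
        "function(e){redraw(e.target.value/100);});",
        "</script></body></html>")
    writeLines(html, path)
    invisible(path)
}

#' Render parallel coordinates to a standalone HTML file
#'
#' One vertical axis per variable (numeric axes span their declared bounds,
#' categorical axes place level labels at equal spacing) and one polyline per
#' patient, coloured by the optional grouping.
#'
#' @param cohort a \linkS4class{CohortExperiment}.
#' @param axes an \code{"AxisSet"} from [buildAxes()].
#' @param path output .html path.
#' @param ids patients to draw (default all).
#' @param groups optional grouping vector aligned with \code{ids}.
#' @param title figure title.
#' @return invisibly, \code{path}.
#' @export
renderParallelCoordsHTML <- function(cohort, axes, path,
                                     ids = colnames(cohort), groups = NULL,
                                     title = "Parallel coordinates") {
    stopifnot(inherits(axes, "AxisSet"))
    m <- length(axes)
    if (is.null(groups)) groups <- rep("all", length(ids))
    groups <- as.factor(groups)
    cols <- PALETTE[(as.integer(groups) - 1L) %% length(PALETTE) + 1L]
    w <- max(760, 40 * m + 80); h <- 420
    xs <- seq(50, w - 30, length.out = m)
    cd <- SummarizedExperiment::colData(cohort)[ids, , drop = FALSE]
    # per-axis vertical position in [0,1] for every drawn patient
    pos <- sapply(seq_len(m), function(j) {
        ax <- axes[[j]]
        if (ax$kind == "numeric") {
            v <- as.numeric(rawValues(cohort, ax$name)[, ids])
            if (diff(ax$range) > 0) (v - ax$range[1L]) / diff(ax$range) else 0.5
        } else {
            idx <- match(as.character(cd[[ax$name]]), ax$categories)
            ax$positions[idx]
        }
    })
    pos <- matrix(pos, nrow = length(ids))
    toY <- function(p) (h - 60) - p * (h - 100)
    lines <- vapply(seq_along(ids), function(i) {
        pts <- paste(sprintf("%.1f,%.1f", xs, toY(pos[i, ])), collapse = " ")
        sprintf('<polyline class="case" points="%s" fill="none" stroke="%s" stroke-opacity="0.5"><title>%s</title></polyline>',
                pts, cols[i], svgEsc(ids[i]))
    }, character(1L))
    axisSvg <- unlist(lapply(seq_len(m), function(j) {
        ax <- axes[[j]]
        out <- c(sprintf('<line class="axis" x1="%.1f" y1="%.1f" x2="%.1f" y2="%.1f" stroke="#333"/>',
                         xs[j], toY(0), xs[j], toY(1)),
                 sprintf('<text class="axis-label" x="%.1f" y="%.1f" font-size="9" text-anchor="middle" transform="rotate(35 %.1f %.1f)">%s</text>',
                         xs[j], h - 30, xs[j], h - 30, svgEsc(ax$name)))
        if (ax$kind == "numeric")
            out <- c(out, sprintf('<text x="%.1f" y="%.1f" font-size="8">%g</text>',
                                  xs[j] + 2, c(toY(0), toY(1)) + 3, ax$range))
        out
    }))
    html <- c(
        "<!DOCTYPE html><html><head><meta charset='utf-8'>",
        sprintf("<title>%s</title></head><body><h3>%s</h3>",
                svgEsc(title), svgEsc(title)),
        sprintf("<svg width='%d' height='%d' xmlns='http://www.w3.org/2000/svg'>", w, h),
        axisSvg, lines, "</svg></body></html>")
    writeLines(html, path)
    invisible(path)
}
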