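#' Build a parallel-coordinates axis set
#'
#' One vertical axis per variable, order preserved. Numeric axes span the
#' declared value bounds; categorical axes place their categories at equally
#' spaced positions in declared level order.
#'
#' @param cohort a \linkS4class{CohortExperiment}.
#' @param names variables to include (mixed numeric / categorical allowed).
#' @return list of class \code{"AxisSet"}; each element has \code{name},
#'   \code{kind}, and either \code{range} (numeric) or \code{categories} plus
#'   \code{positions} (categorical, equally spaced on [0, 1]).
#' @examples
#' co <- generateCohort(defaultSeparatedConfig(50, seed = 2))
#' length(buildAxes(co, c("diagnosis", "gender", "age", "education_years",
#'                        sprintf("item_%02d", 1:15))))
#' @export
buildAxes <- function(cohort, names) {
    info <- selectVariables(cohort, names, "axes")
    axes <- lapply(seq_len(nrow(info)), function(i) {
        if (info$kind[i] == "numeric") {
            list(name = info$name[i], kind = "numeric",
                 range = c(info$vMin[i], info$vMax[i]))
        } else {
            cats <- info$categories[[i]]
            list(name = info$name[i], kind = "categorical", categories = cats,
                 positions = if (length(cats) > 1L)
                     seq(0, 1, length.out = length(cats)) else 0.5)
        }
    })
    structure(axes, names = info$name, class = "AxisSet")
}

#' Construct a multifilter
#'
#' Named per-axis selections: a numeric axis takes one or more closed
#' intervals (a length-2 vector, a list of length-2 vectors, or an m x 2
#' matrix) whose union is the pass set; a categorical axis takes a character
#' vector of selected levels. Axes are combined conjunctively by
#' [applyFilter()].
#'
#' @param ... named selections, e.g.
#'   \code{filterSet(item_01 = list(c(0, 0), c(3, 3)), diagnosis = "AD")}.
#' @return A \linkS4class{FilterSet}.
#' @export
filterSet <- function(...) {
    raw <- list(...)
    if (length(raw) == 1L && is.null(names(raw)) && is.list(raw[[1L]]) &&
        !is.null(names(raw[[1L]])))
        raw <- raw[[1L]]
    filters <- lapply(raw, function(sel) {
        if (is.character(sel) || is.factor(sel)) return(as.character(sel))
        if (is.numeric(sel) && is.null(dim(sel))) {
            if (length(sel) != 2L)
                stop("a numeric selection must be an interval c(lo, hi)")
            sel <- matrix(sel, 1L, 2L)
        }
        if (is.list(sel))
            sel <- do.call(rbind, lapply(sel, function(iv) {
                if (length(iv) != 2L) stop("each interval needs lo and hi")
                as.numeric(iv)
            }))
        matrix(as.numeric(sel), ncol = 2L)
    })
    methods::new("FilterSet", filters = filters)
}

#' Parse a command-line filter spec
#'
#' \code{"item_01:0-0,3-3"} selects the union of intervals [0,0] and [3,3] on
#' the numeric axis item_01; \code{"diagnosis:AD,SVD"} selects two categories.
#' Interval endpoints may be negative or fractional (\code{"-1.5--0.5"}).
#'
#' @param specs character vector of axis specs.
#' @return A \linkS4class{FilterSet}.
#' @export
parseFilterSpec <- function(specs) {
    parts <- lapply(specs, function(s) {
        kv <- regmatches(s, regexpr(":", s, fixed = TRUE), invert = TRUE)[[1L]]
        if (length(kv) != 2L) stop("filter spec must be 'variable:selection': ", s)
        tokens <- strsplit(kv[2L], ",", fixed = TRUE)[[1L]]
        ivs <- regmatches(tokens, regexpr("(?<=.)-", tokens, perl = TRUE),
                          invert = TRUE)
        numeric <- all(vapply(ivs, function(t)
            length(t) == 2L && !anyNA(suppressWarnings(as.numeric(t))), logical(1L)))
        sel <- if (numeric)
            t(vapply(ivs, as.numeric, numeric(2L)))
        else tokens
        stats::setNames(list(sel), kv[1L])
    })
    do.call(filterSet, do.call(c, parts))
}

#' Apply a multifilter to a cohort
#'
#' A patient passes a numeric axis iff the value lies in the union of that
#' axis's closed intervals, and a categorical axis iff the level is among the
#' selected ones; a patient is returned iff it passes every axis that carries
#' a selection. Axes without selections are unconstrained, so an empty filter
#' returns everyone.
#'
#' @param cohort a \linkS4class{CohortExperiment}.
#' @param filters a \linkS4class{FilterSet}.
#' @return character vector of passing patient ids, in cohort order.
#' @export
applyFilter <- function(cohort, filters) {
    stopifnot(methods::is(filters, "FilterSet"))
    info <- variableInfo(cohort)
    unknown <- setdiff(names(filters@filters), info$name)
    if (length(unknown))
        stop("filter names unknown variable(s): ", paste(unknown, collapse = ", "))
    pass <- rep(TRUE, ncol(cohort))
    cd <- SummarizedExperiment::colData(cohort)
    for (nm in names(filters@filters)) {
        sel <- filters@filters[[nm]]
        if (is.character(sel)) {
            if (info[nm, "kind"] != "categorical")
                stop(sprintf("axis '%s' is numeric; intervals expected", nm))
            pass <- pass & (as.character(cd[[nm]]) %in% sel)
        } else {
            v <- as.numeric(rawValues(cohort, nm))
            ok <- rep(FALSE, length(v))
            for (r in seq_len(nrow(sel)))
                ok <- ok | (!is.na(v) & v >= sel[r, 1L] & v <= sel[r, 2L])
            pass <- pass & ok
        }
    }
    colnames(cohort)[pass]
}

#' Extract the layout points of a selection
#'
#' The 3D-view side of linked brushing: returns exactly the layout rows whose
#' ids are in the subset, without reordering or mutation.
#'
#' @param layout data.frame from [layoutCohort()].
#' @param ids patient ids to highlight.
#' @return the matching rows of \code{layout}.
#' @export
linkedSelection <- function(layout, ids) {
    unknown <- setdiff(ids, layout$id)
    if (length(unknown))
        stop("unknown id(s): ", paste(unknown, collapse = ", "))
    layout[layout$id %in% ids, , drop = FALSE]
}
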