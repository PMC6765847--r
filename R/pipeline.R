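DEFAULT_ITEMS <- sprintf("item_%02d", 1:15)
DEFAULT_AXES <- c("diagnosis", "gender", "academic_background",
                  "education_years", "age", DEFAULT_ITEMS)

#' Run the full segmentation pipeline
#'
#' Non-interactive realization of the analysis workflow: obtain a cohort
#' (simulate one, or read a CSV), select anchor variables, compute the
#' normalized matrix and the radial layout, segment with k-means, apply an
#' optional multifilter, and write everything to an output directory:
#' \code{layout.csv} (coordinates plus pass-through covariates),
#' \code{clusters.csv}, \code{cluster_summary.csv}, \code{filtered.csv} (when
#' a filter is set), static HTML renders (when enabled), and
#' \code{manifest.json} recording parameters, seeds, versions and collected
#' warnings. Identical config (including seeds) reproduces byte-identical CSV
#' outputs. A failure in any stage removes the partial outputs and reports
#' the failing stage.
#'
#' @param config a named list, or the path to a YAML file, with fields:
#'   exactly one of \code{simulate} (\code{n}, \code{seed}) or \code{input}
#'   (\code{path}, optional \code{schema}); optional \code{anchors} (default
#'   the 15 items), \code{axes} (default the 5 covariates + 15 items),
#'   \code{mode} (\code{"radvis3d"}/\code{"radvis2d"}), \code{cluster}
#'   (\code{k}, \code{init}, \code{seed}, \code{space}, \code{restarts}),
#'   \code{filter} (character specs as in [parseFilterSpec()]), \code{render}
#'   (logical).
#' @param outDir output directory, created if needed.
#' @return invisibly, a list with the computed objects (\code{cohort},
#'   \code{layout}, \code{model}, \code{summary}, \code{filteredIds}) and the
#'   written \code{paths}.
#' @examples
#' \donttest{
#' out <- runPipeline(list(simulate = list(n = 120, seed = 7),
#'                         cluster = list(k = 5, init = "forgy", seed = 11)),
#'                    outDir = tempfile())
#' out$model
#' }
#' @export
runPipeline <- function(config, outDir) {
    if (is.character(config) && length(config) == 1L)
        config <- yaml::read_yaml(config)
    hasSim <- !is.null(config$simulate)
    hasInput <- !is.null(config$input)
    if (hasSim == hasInput)
        stop("config must contain exactly one of 'simulate' or 'input'")
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    written <- character(0)
    warnings <- character(0)
    stage <- "config"
    res <- tryCatch(
        withCallingHandlers({
            stage <- "cohort"
            cohort <- if (hasSim) {
                generateCohort(defaultSeparatedConfig(
                    nPatients = config$simulate$n,
                    seed = if (is.null(config$simulate$seed)) 1L
                           else config$simulate$seed))
            } else {
                readCohort(config$input$path,
                           schema = if (is.null(config$input$schema)) "infer"
                                    else config$input$schema)
            }
            if (hasSim) {
                p <- file.path(outDir, "cohort.csv")
                writeCohort(cohort, p)
                written <- c(written, p, paste0(p, ".schema.yaml"))
            }

            stage <- "layout"
            anchorNames <- if (is.null(config$anchors)) {
                intersect(DEFAULT_ITEMS, rownames(cohort))
            } else unlist(config$anchors)
            mode <- if (is.null(config$mode)) "radvis3d" else config$mode
            anchors <- makeAnchors(selectVariables(cohort, anchorNames, "anchors"))
            u <- normalizeScores(cohort, anchorNames)
            layout <- layoutCohort(u, anchors, mode)
            cd <- SummarizedExperiment::colData(cohort)[layout$id, , drop = FALSE]
            layoutOut <- data.frame(layout, as.data.frame(cd),
                                    check.names = FALSE)
            p <- file.path(outDir, "layout.csv")
            utils::write.csv(layoutOut, p, row.names = FALSE, quote = TRUE)
            written <- c(written, p)

            stage <- "cluster"
            cc <- config$cluster
            model <- NULL; summaryObj <- NULL
            if (!is.null(cc)) {
                space <- if (is.null(cc$space)) "layout3d" else cc$space
                pts <- if (space == "layout3d") {
                    m <- as.matrix(layout[, c("x", "y", "z")])
                    rownames(m) <- layout$id
                    m
                } else u
                model <- kmeansRadVis(
                    pts, k = cc$k,
                    init = if (is.null(cc$init)) "forgy" else cc$init,
                    seed = if (is.null(cc$seed)) 1L else cc$seed,
                    space = space,
                    radius = anchors@radius, height = anchors@height,
                    nRestarts = if (is.null(cc$restarts)) 1L else cc$restarts)
                summaryObj <- summarizeClusters(model, cohort)
                p <- file.path(outDir, "clusters.csv")
                exportClusters(model, cohort, p, layout = layout)
                written <- c(written, p)
                p <- file.path(outDir, "cluster_summary.csv")
                utils::write.csv(summaryObj$numeric, p, row.names = FALSE)
                written <- c(written, p)
            }

            stage <- "filter"
            filteredIds <- NULL
            if (!is.null(config$filter)) {
                fs <- if (methods::is(config$filter, "FilterSet")) config$filter
                      else parseFilterSpec(unlist(config$filter))
                filteredIds <- applyFilter(cohort, fs)
                sub <- linkedSelection(layout, filteredIds)
                p <- file.path(outDir, "filtered.csv")
                utils::write.csv(sub, p, row.names = FALSE, quote = TRUE)
                written <- c(written, p)
            }

            stage <- "render"
            doRender <- isTRUE(config$render)
            if (doRender) {
                groups <- if (!is.null(model)) {
                    factor(model@assignments[layout$id])
                } else if ("diagnosis" %in% colnames(cd)) {
                    cd$diagnosis
                } else NULL
                p <- file.path(outDir, "radvis3d.html")
                renderRadVisHTML(layout, anchors, p, groups = groups)
                written <- c(written, p)
                axisNames <- if (is.null(config$axes))
                    intersect(DEFAULT_AXES, variableInfo(cohort)$name)
                else unlist(config$axes)
                axes <- buildAxes(cohort, axisNames)
                p <- file.path(outDir, "parcoords.html")
                renderParallelCoordsHTML(cohort, axes, p, ids = layout$id,
                                         groups = groups)
                written <- c(written, p)
            }

            stage <- "manifest"
            manifest <- list(
                package = "RadVisSeg",
                version = as.character(utils::packageVersion("RadVisSeg")),
                r_version = paste(R.version$major, R.version$minor, sep = "."),
                config = config,
                n_patients = ncol(cohort),
                n_anchors = nAnchors(anchors),
                n_laid_out = nrow(layout),
                n_filtered = if (is.null(filteredIds)) NA_integer_
                             else length(filteredIds),
                cluster_sizes = if (is.null(summaryObj)) NULL
                                else as.list(summaryObj$sizes),
                converged = if (is.null(model)) NA else model@converged,
                warnings = warnings
            )
            p <- file.path(outDir, "manifest.json")
            jsonlite::write_json(manifest, p, auto_unbox = TRUE, pretty = TRUE,
                                 digits = NA, null = "null")
            written <- c(written, p)

            list(cohort = cohort, layout = layout, model = model,
                 summary = summaryObj, filteredIds = filteredIds,
                 paths = written)
        }, warning = function(w) {
            warnings <<- c(warnings, conditionMessage(w))
            invokeRestart("muffleWarning")
        }),
        error = function(e) {
            unlink(written)
            stop(sprintf("pipeline stage '%s' failed: %s", stage,
                         conditionMessage(e)), call. = FALSE)
        })
    invisible(res)
}
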