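#' Construct a CohortExperiment
#'
#' @param scores numeric matrix of test-item values, items in rows and
#'   patients in columns; dimnames required.
#' @param colData data.frame (or DataFrame) of per-patient covariates, one row
#'   per patient in column order of \code{scores}. Character columns are
#'   converted to factors whose level order follows first appearance unless
#'   already factors.
#' @param vMin,vMax per-item value bounds used by min--max normalization;
#'   either a single number recycled to all items or one value per item.
#'   Default: the observed per-item range.
#' @return A \linkS4class{CohortExperiment}.
#' @examples
#' m <- matrix(0:5, nrow = 3, dimnames = list(paste0("item_0", 1:3), c("p1", "p2")))
#' CohortExperiment(m, data.frame(stage = c("SMI", "AD")), vMin = 0, vMax = 5)
#' @export
CohortExperiment <- function(scores, colData = NULL, vMin = NULL, vMax = NULL) {
    scores <- as.matrix(scores)
    if (is.null(rownames(scores)) || is.null(colnames(scores)))
        stop("'scores' must have item rownames and patient colnames")
    storage.mode(scores) <- "double"
    if (is.null(vMin)) vMin <- apply(scores, 1L, min, na.rm = TRUE)
    if (is.null(vMax)) vMax <- apply(scores, 1L, max, na.rm = TRUE)
    vMin <- rep_len(as.numeric(vMin), nrow(scores))
    vMax <- rep_len(as.numeric(vMax), nrow(scores))
    if (is.null(colData)) {
        colData <- S4Vectors::DataFrame(row.names = colnames(scores))
    } else {
        colData <- as.data.frame(colData, stringsAsFactors = FALSE)
        stopifnot(nrow(colData) == ncol(scores))
        for (j in seq_along(colData))
            if (is.character(colData[[j]]))
                colData[[j]] <- factor(colData[[j]], levels = unique(colData[[j]]))
        colData <- S4Vectors::DataFrame(colData, row.names = colnames(scores))
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(scores = scores),
        rowData = S4Vectors::DataFrame(vMin = vMin, vMax = vMax,
                                       row.names = rownames(scores)),
        colData = colData
    )
    methods::new("CohortExperiment", se)
}

#' Variable metadata of a cohort
#'
#' One row per variable: every score item (numeric, with its declared bounds)
#' followed by every covariate column. Factor covariates are categorical with
#' their level set recorded; numeric covariates get their observed range as
#' bounds.
#'
#' @param cohort a \linkS4class{CohortExperiment}.
#' @return data.frame with columns \code{name}, \code{kind} ("numeric" or
#'   "categorical"), \code{vMin}, \code{vMax} (NA for categorical) and a list
#'   column \code{categories}.
#' @export
variableInfo <- function(cohort) {
    stopifnot(methods::is(cohort, "CohortExperiment"))
    rd <- SummarizedExperiment::rowData(cohort)
    items <- data.frame(name = rownames(cohort), kind = "numeric",
                        vMin = rd$vMin, vMax = rd$vMax,
                        stringsAsFactors = FALSE)
    items$categories <- vector("list", nrow(items))
    cd <- SummarizedExperiment::colData(cohort)
    covs <- lapply(colnames(cd), function(nm) {
        v <- cd[[nm]]
        if (is.numeric(v)) {
            data.frame(name = nm, kind = "numeric",
                       vMin = min(v, na.rm = TRUE), vMax = max(v, na.rm = TRUE),
                       categories = I(list(NULL)), stringsAsFactors = FALSE)
        } else {
            data.frame(name = nm, kind = "categorical", vMin = NA_real_,
                       vMax = NA_real_, categories = I(list(levels(factor(v)))),
                       stringsAsFactors = FALSE)
        }
    })
    out <- do.call(rbind, c(list(items), covs))
    rownames(out) <- out$name
    out
}

#' Select variables for use as layout anchors or parallel axes
#'
#' Dimensional anchors must be numeric test items; categorical covariates such
#' as gender or diagnosis stage cannot anchor a radial layout but are allowed
#' as parallel-coordinates axes.
#'
#' @param cohort a \linkS4class{CohortExperiment}.
#' @param names variable names, order preserved in the result.
#' @param purpose \code{"anchors"} (numeric only) or \code{"axes"} (any kind).
#' @return The [variableInfo()] rows for \code{names}, in the given order.
#' @export
selectVariables <- function(cohort, names, purpose = c("anchors", "axes")) {
    purpose <- match.arg(purpose)
    info <- variableInfo(cohort)
    unknown <- setdiff(names, info$name)
    if (length(unknown))
        stop("unknown variable(s): ", paste(unknown, collapse = ", "))
    sel <- info[match(names, info$name), , drop = FALSE]
    if (purpose == "anchors") {
        bad <- sel$name[sel$kind != "numeric"]
        if (length(bad))
            stop("categorical variable(s) cannot be dimensional anchors: ",
                 paste(bad, collapse = ", "))
    }
    sel
}

#' Min-max normalize selected numeric variables
#'
#' Maps each raw value N(i) to (N(i) - vMin(i)) / (vMax(i) - vMin(i)), the
#' unit-interval weight that drives all radial layouts. Values outside the
#' declared bounds are clamped with a warning; a constant variable
#' (vMin == vMax) contributes the neutral weight 0.5 everywhere, also with a
#' warning. Patients with a missing value in any selected variable are dropped
#' with a warning; their ids are recorded in \code{attr(, "droppedIds")}.
#'
#' @param cohort a \linkS4class{CohortExperiment}.
#' @param variables numeric variable names; default all score items.
#' @return patients-by-variables numeric matrix with entries in [0, 1].
#' @export
normalizeScores <- function(cohort, variables = rownames(cohort)) {
    if (length(variables) == 0L)
        stop("at least one variable is required")
    sel <- selectVariables(cohort, variables, "anchors")
    raw <- t(rawValues(cohort, variables))        # patients x variables
    keep <- rowSums(is.na(raw)) == 0L
    dropped <- rownames(raw)[!keep]
    if (length(dropped))
        warning(sprintf("dropping %d patient(s) with missing values", length(dropped)))
    raw <- raw[keep, , drop = FALSE]
    u <- raw
    nClamped <- 0L
    for (j in seq_len(ncol(raw))) {
        lo <- sel$vMin[j]; hi <- sel$vMax[j]
        x <- raw[, j]
        out <- x < lo | x > hi
        nClamped <- nClamped + sum(out)
        x <- pmin(pmax(x, lo), hi)
        if (hi > lo) {
            u[, j] <- (x - lo) / (hi - lo)
        } else {
            warning(sprintf("variable '%s' is constant (vMin == vMax); using 0.5", sel$name[j]))
            u[, j] <- 0.5
        }
    }
    if (nClamped > 0L)
        warning(sprintf("%d value(s) outside declared bounds were clamped", nClamped))
    colnames(u) <- sel$name
    attr(u, "droppedIds") <- dropped
    u
}

# raw values for a mixed variable set, variables x patients; factors as NA-free
# numeric only when requested numerically upstream (internal)
rawValues <- function(cohort, variables) {
    itemNames <- intersect(variables, rownames(cohort))
    cd <- SummarizedExperiment::colData(cohort)
    out <- matrix(NA_real_, length(variables), ncol(cohort),
                  dimnames = list(variables, colnames(cohort)))
    if (length(itemNames))
        out[itemNames, ] <- SummarizedExperiment::assay(cohort, "scores")[itemNames, , drop = FALSE]
    for (nm in setdiff(variables, itemNames)) {
        v <- cd[[nm]]
        if (!is.numeric(v))
            stop(sprintf("variable '%s' is not numeric", nm))
        out[nm, ] <- v
    }
    out
}

#' Read a cohort from CSV
#'
#' Expects a header row and an \code{id} column of unique patient identifiers.
#' With \code{schema = "infer"}, columns that parse entirely as numbers become
#' numeric score items with their observed range as bounds, and the remaining
#' columns become categorical covariates. An explicit schema (as written by
#' [writeCohort()], YAML with one entry per variable: name, kind, and either
#' v_min/v_max or categories) fixes kinds, bounds and category order instead.
#'
#' @param path CSV file path.
#' @param schema \code{"infer"} or path to a YAML schema file.
#' @return A \linkS4class{CohortExperiment}.
#' @export
readCohort <- function(path, schema = "infer") {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
    if (!"id" %in% colnames(df)) stop("CSV must contain an 'id' column")
    ids <- as.character(df$id)
    if (anyDuplicated(ids)) stop("duplicate row ids in ", path)
    vars <- setdiff(colnames(df), "id")

    if (identical(schema, "infer")) {
        numeric <- vapply(vars, function(nm) {
            v <- df[[nm]]
            is.numeric(v) || all(!is.na(suppressWarnings(as.numeric(v[!is.na(v)]))))
        }, logical(1L))
        spec <- data.frame(name = vars, kind = ifelse(numeric, "numeric", "categorical"),
                           role = ifelse(numeric, "item", "covariate"),
                           stringsAsFactors = FALSE)
        spec$vMin <- NA_real_; spec$vMax <- NA_real_
        spec$categories <- vector("list", nrow(spec))
    } else {
        sch <- yaml::read_yaml(schema)
        spec <- do.call(rbind, lapply(sch$variables, function(s) {
            data.frame(name = s$name, kind = s$kind,
                       role = if (is.null(s$role)) {
                           if (s$kind == "numeric") "item" else "covariate"
                       } else s$role,
                       vMin = if (is.null(s$v_min)) NA_real_ else as.numeric(s$v_min),
                       vMax = if (is.null(s$v_max)) NA_real_ else as.numeric(s$v_max),
                       categories = I(list(unlist(s$categories))),
                       stringsAsFactors = FALSE)
        }))
        missingCols <- setdiff(spec$name, vars)
        if (length(missingCols))
            stop("schema names absent from CSV header: ",
                 paste(missingCols, collapse = ", "))
        extra <- setdiff(vars, spec$name)
        if (length(extra)) {
            more <- data.frame(name = extra, kind = "categorical",
                               role = "covariate",
                               vMin = NA_real_, vMax = NA_real_,
                               stringsAsFactors = FALSE)
            more$categories <- vector("list", length(extra))
            spec <- rbind(spec, more)
        }
        spec <- spec[match(vars, spec$name), , drop = FALSE]
    }

    numNames <- spec$name[spec$kind == "numeric"]
    for (nm in numNames) {
        v <- suppressWarnings(as.numeric(df[[nm]]))
        if (any(is.na(v) & !is.na(df[[nm]]) & df[[nm]] != "NA" & df[[nm]] != ""))
            stop(sprintf("non-numeric token in numeric column '%s'", nm))
        df[[nm]] <- v
    }
    itemNames <- spec$name[spec$kind == "numeric" & spec$role == "item"]
    scores <- t(as.matrix(df[, itemNames, drop = FALSE]))
    dimnames(scores) <- list(itemNames, ids)
    covNames <- setdiff(spec$name, itemNames)
    cd <- df[, covNames, drop = FALSE]
    for (nm in covNames) {
        if (spec$kind[match(nm, spec$name)] == "numeric") next
        lev <- spec$categories[[match(nm, spec$name)]]
        cd[[nm]] <- if (length(lev)) factor(cd[[nm]], levels = lev)
                    else factor(cd[[nm]], levels = unique(cd[[nm]]))
    }
    idx <- match(itemNames, spec$name)
    vMin <- spec$vMin[idx]; vMax <- spec$vMax[idx]
    obsMin <- apply(scores, 1L, min, na.rm = TRUE)
    obsMax <- apply(scores, 1L, max, na.rm = TRUE)
    vMin[is.na(vMin)] <- obsMin[is.na(vMin)]
    vMax[is.na(vMax)] <- obsMax[is.na(vMax)]
    CohortExperiment(scores, cd, vMin = vMin, vMax = vMax)
}

#' Write a cohort to CSV (plus a YAML schema sidecar)
#'
#' Patients as rows: an \code{id} column, covariates, then score items.
#' The sidecar records each variable's kind, bounds and category order so that
#' [readCohort()] round-trips the cohort exactly.
#'
#' @param cohort a \linkS4class{CohortExperiment}.
#' @param path output CSV path.
#' @param schemaPath output YAML path; default \code{paste0(path, ".schema.yaml")};
#'   \code{NULL} skips the sidecar.
#' @return invisibly, \code{path}.
#' @export
writeCohort <- function(cohort, path, schemaPath = paste0(path, ".schema.yaml")) {
    cd <- as.data.frame(SummarizedExperiment::colData(cohort))
    scores <- t(SummarizedExperiment::assay(cohort, "scores"))
    df <- data.frame(id = colnames(cohort), cd, scores,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
    if (!is.null(schemaPath)) {
        info <- variableInfo(cohort)
        vars <- lapply(seq_len(nrow(info)), function(i) {
            role <- if (info$name[i] %in% rownames(cohort)) "item" else "covariate"
            if (info$kind[i] == "numeric")
                list(name = info$name[i], kind = "numeric", role = role,
                     v_min = info$vMin[i], v_max = info$vMax[i])
            else
                list(name = info$name[i], kind = "categorical", role = role,
                     categories = as.list(info$categories[[i]]))
        })
        yaml::write_yaml(list(variables = vars), schemaPath)
    }
    invisible(path)
}

#' @describeIn CohortExperiment compact display
#' @param object a \code{CohortExperiment}
#' @export
setMethod("show", "CohortExperiment", function(object) {
    cat(sprintf("CohortExperiment: %d patients, %d score items, %d covariate(s)\n",
                ncol(object), nrow(object),
                ncol(SummarizedExperiment::colData(object))))
    methods::callNextMethod()
})
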