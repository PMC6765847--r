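STAGES <- c("SMI", "MCI", "VCI", "SVD", "AD")

#' Configuration for a synthetic staged dementia cohort
#'
#' Describes a cohort on the schema of a staged dementia registry: a diagnosis
#' stage per patient drawn from five ordered categories (SMI, MCI, VCI, SVD,
#' AD), fifteen daily-living questionnaire items (item_01..item_15) on a
#' 0--3 Likert scale whose per-stage means encode disease progression
#' (higher = better daily function), and basic demographics.
#'
#' @param nPatients positive integer.
#' @param stageProportions five probabilities over the stages, summing to 1.
#' @param itemMeans 5 x 15 matrix of per-stage, per-item mean scores on the
#'   0--3 scale (rows in stage order SMI..AD).
#' @param itemSd positive common noise SD on the item scale.
#' @param seed integer RNG seed (Mersenne-Twister).
#' @param ageRange,educationRange integer ranges for the demographics.
#' @param genderProportions named probabilities for the gender levels.
#' @return list of class \code{"CohortConfig"}.
#' @export
cohortConfig <- function(nPatients,
                         stageProportions = rep(0.2, 5),
                         itemMeans,
                         itemSd = 0.25,
                         seed = 1L,
                         ageRange = c(55L, 90L),
                         educationRange = c(0L, 18L),
                         genderProportions = c(F = 0.55, M = 0.45)) {
    if (length(nPatients) != 1L || nPatients <= 0)
        stop("nPatients must be a positive integer")
    if (length(stageProportions) != 5L || any(stageProportions < 0) ||
        abs(sum(stageProportions) - 1) > 1e-9)
        stop("stageProportions must be 5 non-negative numbers summing to 1")
    itemMeans <- as.matrix(itemMeans)
    if (!all(dim(itemMeans) == c(5L, 15L)))
        stop("itemMeans must be a 5 x 15 matrix (stages x items)")
    if (any(itemMeans < 0) || any(itemMeans > 3))
        stop("itemMeans must lie on the 0-3 item scale")
    if (itemSd <= 0) stop("itemSd must be positive")
    structure(list(nPatients = as.integer(nPatients),
                   stageProportions = stats::setNames(stageProportions, STAGES),
                   itemMeans = itemMeans, itemSd = itemSd,
                   seed = as.integer(seed),
                   ageRange = as.integer(ageRange),
                   educationRange = as.integer(educationRange),
                   genderProportions = genderProportions),
              class = "CohortConfig")
}

#' Default well-separated cohort configuration
#'
#' Stage mean profiles step down the item scale from SMI (2.8, near the top:
#' largely intact daily function) to AD (0.4, near the bottom) in equal steps
#' of 0.6, with a common noise SD of 0.25 -- small against the 0.6 step, so
#' the five stages form well-separated clusters that a k = 5 segmentation
#' should recover almost perfectly. All 15 items share their stage mean.
#'
#' @param nPatients cohort size.
#' @param seed integer RNG seed.
#' @return A \code{"CohortConfig"}.
#' @export
defaultSeparatedConfig <- function(nPatients = 500L, seed = 1L) {
    stageMeans <- c(SMI = 2.8, MCI = 2.2, VCI = 1.6, SVD = 1.0, AD = 0.4)
    cohortConfig(nPatients,
                 itemMeans = matrix(stageMeans, nrow = 5L, ncol = 15L,
                                    dimnames = list(STAGES, NULL)),
                 itemSd = 0.25, seed = seed)
}

#' Generate a synthetic cohort
#'
#' Draws each patient's stage from the configured proportions, then each of
#' the 15 item scores as \code{round(clamp(Normal(mean[stage, item], sd), 0, 3))}
#' so every value lands on the 0--3 Likert grid. Demographics are drawn
#' independently (uniform integer age and education years, categorical
#' gender). Fully reproducible from the config seed.
#'
#' @param config a \code{"CohortConfig"} from [cohortConfig()] or
#'   [defaultSeparatedConfig()].
#' @return A \linkS4class{CohortExperiment} with covariates \code{diagnosis},
#'   \code{gender}, \code{academic_background} (banded from education years),
#'   \code{age}, \code{education_years} and items \code{item_01..item_15}
#'   with declared bounds [0, 3].
#' @examples
#' co <- generateCohort(defaultSeparatedConfig(100, seed = 7))
#' table(SummarizedExperiment::colData(co)$diagnosis)
#' @export
generateCohort <- function(config) {
    stopifnot(inherits(config, "CohortConfig"))
    n <- config$nPatients
    set.seed(config$seed)
    stage <- sample(STAGES, n, replace = TRUE, prob = config$stageProportions)
    stageIdx <- match(stage, STAGES)
    mu <- config$itemMeans[stageIdx, , drop = FALSE]     # n x 15
    raw <- mu + matrix(stats::rnorm(n * 15L, sd = config$itemSd), n, 15L)
    items <- round(pmin(pmax(raw, 0), 3))
    ids <- sprintf("P%05d", seq_len(n))
    dimnames(items) <- list(ids, sprintf("item_%02d", 1:15))
    gender <- sample(names(config$genderProportions), n, replace = TRUE,
                     prob = config$genderProportions)
    eduYears <- sample(config$educationRange[1L]:config$educationRange[2L],
                       n, replace = TRUE)
    eduBand <- cut(eduYears, breaks = c(-Inf, 0, 6, 9, 12, Inf),
                   labels = c("none", "elementary", "middle", "high", "college"))
    cd <- data.frame(
        diagnosis = factor(stage, levels = STAGES),
        gender = factor(gender, levels = names(config$genderProportions)),
        academic_background = eduBand,
        age = sample(config$ageRange[1L]:config$ageRange[2L], n, replace = TRUE),
        education_years = eduYears,
        stringsAsFactors = FALSE
    )
    CohortExperiment(t(items), cd, vMin = 0, vMax = 3)
}
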