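#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom S4Vectors metadata "metadata<-" DataFrame
#' @importFrom SummarizedExperiment assay "assay<-" assays "assays<-" rowData assayNames
#' @importFrom stats median sd cor quantile rnorm runif rbinom t.test complete.cases setNames
#' @importFrom utils head
NULL

.KEYWORD_CLASSES <- c("general", "volumemm3", "area", "thickavg", "grayvol",
                      "nvoxels", "numvert", "nvertices")
.ROLES    <- c("morphometric", "demographic", "clinical_score")
.MEASURES <- c("pcc", "mrc", "cos", "man", "euc")
.SCORES   <- c("MMSE", "GDS", "CDR", "NIQ", "FAQ")

#' Instrument and observed ranges of the five clinical test scores
#'
#' Returns the per-test score schema: the instrument range (the scale the test
#' is printed on, used for absolute error percentages) and the observed range
#' (the range seen in screening cohorts, used to min-max normalise scores).
#' The two differ only for MMSE, where screening cohorts rarely contain
#' scores below 8 although the instrument runs 0--30.
#'
#' @return A `data.frame` with one row per test (`MMSE`, `GDS`, `CDR`, `NIQ`,
#'   `FAQ`) and columns `name`, `instrument_min`, `instrument_max`,
#'   `observed_min`, `observed_max`.
#' @examples
#' defaultScoreSchemas()
#' @export
defaultScoreSchemas <- function() {
    data.frame(
        name           = .SCORES,
        instrument_min = c(0, 0, -1, 0, 0),
        instrument_max = c(30, 12, 3, 29, 30),
        observed_min   = c(8, 0, -1, 0, 0),
        observed_max   = c(30, 12, 3, 29, 30),
        stringsAsFactors = FALSE
    )
}

#' Cohort container for morphometric, demographic and clinical-score features
#'
#' `DementiaCohort` extends [SummarizedExperiment::SummarizedExperiment] with
#' features as rows and samples as columns.  Three assays are kept in step:
#' `values` (numeric; `NA` where unknown), `observed` (logical missingness
#' mask; `TRUE` means the cell entered the data observed) and `imputed`
#' (logical; `TRUE` where a value was filled in by an imputer).  `rowData`
#' carries the feature specification: `role` (one of `morphometric`,
#' `demographic`, `clinical_score`), `keyword_class` (one of the eight
#' FreeSurfer-stats keyword classes or `none`), `nominal` and `hemisphere`
#' (`left`, `right`, `bilateral` or `n/a`).  `metadata()` holds the score
#' schemas (`scoreSchemas`) and a `normalized` flag.
#'
#' Cells with `observed = FALSE` (and not imputed) are excluded from every
#' similarity, statistic and metric computed by the package.
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment]
#' @aliases DementiaCohort-class
#' @export
setClass("DementiaCohort", contains = "SummarizedExperiment")

.validDementiaCohort <- function(object) {
    msg <- character(0)
    an <- SummarizedExperiment::assayNames(object)
    need <- c("values", "observed", "imputed")
    if (!all(need %in% an))
        msg <- c(msg, sprintf("assays must include %s",
                              paste(setdiff(need, an), collapse = ", ")))
    else {
        v <- SummarizedExperiment::assay(object, "values")
        o <- SummarizedExperiment::assay(object, "observed")
        im <- SummarizedExperiment::assay(object, "imputed")
        if (!is.numeric(v)) msg <- c(msg, "'values' assay must be numeric")
        if (!is.logical(o)) msg <- c(msg, "'observed' assay must be logical")
        if (!is.logical(im)) msg <- c(msg, "'imputed' assay must be logical")
        if (is.logical(o) && is.numeric(v) &&
            any(!o & !is.na(v) & !im))
            msg <- c(msg, "cells with observed = FALSE must hold NA unless imputed")
    }
    rd <- SummarizedExperiment::rowData(object)
    for (col in c("role", "keyword_class", "nominal", "hemisphere"))
        if (!col %in% colnames(rd))
            msg <- c(msg, sprintf("rowData lacks '%s'", col))
    if ("role" %in% colnames(rd)) {
        if (!all(rd$role %in% .ROLES))
            msg <- c(msg, "unknown feature role")
        if ("keyword_class" %in% colnames(rd) &&
            any(rd$keyword_class != "none" & rd$role != "morphometric"))
            msg <- c(msg, "keyword_class != 'none' only allowed for morphometric features")
    }
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicate sample id")
    if (length(msg)) msg else TRUE
}
setValidity("DementiaCohort", .validDementiaCohort)

#' Construct a DementiaCohort
#'
#' @param values numeric matrix, samples in rows and features in columns (the
#'   orientation spreadsheets ship in); it is stored transposed,
#'   features-by-samples, following Bioconductor convention.  `NA` marks a
#'   missing cell.
#' @param featureSpecs `data.frame` with columns `name`, `role`,
#'   `keyword_class`, `nominal`, `hemisphere`, one row per feature.  When
#'   `NULL`, specs are inferred from column names via [inferFeatureSpecs()].
#' @param scoreSchemas score schema table as from [defaultScoreSchemas()].
#' @param sampleIds character sample identifiers; defaults to
#'   `rownames(values)` or the 0-based row index.
#' @param normalized logical flag recording whether features are already on
#'   the normalised \[0, 1\] scale.
#' @return A [DementiaCohort-class] object.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(NULL, c("Left-Hip_volumemm3",
#'                                     "Right-Hip_volumemm3", "AGE", "MMSE")))
#' DementiaCohort(m)
#' @export
DementiaCohort <- function(values, featureSpecs = NULL,
                           scoreSchemas = defaultScoreSchemas(),
                           sampleIds = NULL, normalized = FALSE) {
    values <- as.matrix(values)
    if (is.null(colnames(values)))
        stop("feature names (column names) are required")
    if (is.null(sampleIds))
        sampleIds <- if (!is.null(rownames(values))) rownames(values)
                     else as.character(seq_len(nrow(values)) - 1L)
    if (anyDuplicated(sampleIds))
        stop("duplicate sample id: ",
             paste(unique(sampleIds[duplicated(sampleIds)]), collapse = ", "))
    if (is.null(featureSpecs))
        featureSpecs <- inferFeatureSpecs(colnames(values), scoreSchemas)
    featureSpecs <- featureSpecs[match(colnames(values), featureSpecs$name), ,
                                 drop = FALSE]
    if (anyNA(featureSpecs$name))
        stop("featureSpecs must cover every feature name")
    v <- t(values)                       # features x samples
    storage.mode(v) <- "double"
    colnames(v) <- sampleIds
    obs <- !is.na(v)
    imp <- matrix(FALSE, nrow(v), ncol(v), dimnames = dimnames(v))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(values = v, observed = obs, imputed = imp),
        rowData = S4Vectors::DataFrame(featureSpecs, row.names = featureSpecs$name)
    )
    out <- methods::new("DementiaCohort", se)
    S4Vectors::metadata(out)$scoreSchemas <- scoreSchemas
    S4Vectors::metadata(out)$normalized <- isTRUE(normalized)
    validObject(out)
    out
}

#' Infer feature specifications from feature names
#'
#' Applies FreeSurfer naming conventions: a trailing keyword among
#' `general`, `volumemm3`, `area`, `thickavg`, `grayvol`, `nvoxels`,
#' `numvert`, `nvertices` classes a feature as morphometric; prefixes
#' `Left-`/`Right-`/`lh`/`rh` (case-insensitive) set the hemisphere,
#' anything else is `bilateral`.  Names matching a clinical test
#' (`MMSE`, `GDS`, `CDR`, `NIQ`, `FAQ`) become `clinical_score`; remaining
#' names become demographics, with `sex`/`apoE` marked nominal.
#'
#' @param names character feature names.
#' @param scoreSchemas schema table naming the clinical scores.
#' @return `data.frame` of feature specs (see [DementiaCohort()]).
#' @export
inferFeatureSpecs <- function(names, scoreSchemas = defaultScoreSchemas()) {
    kw <- vapply(names, function(nm) {
        hit <- .KEYWORD_CLASSES[vapply(.KEYWORD_CLASSES, function(k)
            grepl(paste0(k, "$"), nm, ignore.case = TRUE), logical(1))]
        if (length(hit)) hit[[1L]] else "none"
    }, character(1))
    score <- toupper(names) %in% toupper(scoreSchemas$name)
    role <- ifelse(score, "clinical_score",
                   ifelse(kw != "none", "morphometric", "demographic"))
    kw[role != "morphometric"] <- "none"
    hemi <- rep("n/a", length(names))
    hemi[role == "morphometric"] <- "bilateral"
    left  <- grepl("^(left[-_ ]|lh[-_.])", names, ignore.case = TRUE)
    right <- grepl("^(right[-_ ]|rh[-_.])", names, ignore.case = TRUE)
    hemi[role == "morphometric" & left]  <- "left"
    hemi[role == "morphometric" & right] <- "right"
    nominal <- grepl("^(sex|gender|apoe)", names, ignore.case = TRUE)
    data.frame(name = names, role = role, keyword_class = kw,
               nominal = nominal, hemisphere = hemi,
               stringsAsFactors = FALSE)
}

#' @describeIn DementiaCohort-class compact description of the cohort
#' @param object a `DementiaCohort`
#' @export
setMethod("show", "DementiaCohort", function(object) {
    rd <- SummarizedExperiment::rowData(object)
    obs <- observedMask(object)
    cat(sprintf("DementiaCohort: %d samples x %d features\n",
                ncol(object), nrow(object)))
    cat(sprintf("  morphometric: %d  demographic: %d  clinical_score: %d\n",
                sum(rd$role == "morphometric"), sum(rd$role == "demographic"),
                sum(rd$role == "clinical_score")))
    cat(sprintf("  missing cells: %d (%.1f%%)  imputed: %d  normalized: %s\n",
                sum(!obs), 100 * mean(!obs), sum(imputedMask(object)),
                isTRUE(S4Vectors::metadata(object)$normalized)))
})
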