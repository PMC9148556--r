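#' Accessors for DementiaCohort
#'
#' `featureValues()` returns the features-by-samples numeric matrix (`NA` at
#' unobserved cells), `observedMask()` the logical observation mask,
#' `imputedMask()` the imputation provenance mask, `featureSpecs()` the
#' feature specification table, `scoreSchemas()` the clinical score schema
#' table, `sampleIds()` the sample identifiers, `clinicalScores()` the names
#' of score features present, and `isNormalized()` the normalisation flag.
#'
#' @param x a [DementiaCohort-class]
#' @return matrix, data.frame or character vector as described.
#' @name cohort-accessors
NULL

#' @rdname cohort-accessors
#' @export
featureValues <- function(x) SummarizedExperiment::assay(x, "values", withDimnames = FALSE)

#' @rdname cohort-accessors
#' @export
observedMask <- function(x) SummarizedExperiment::assay(x, "observed", withDimnames = FALSE)

#' @rdname cohort-accessors
#' @export
imputedMask <- function(x) SummarizedExperiment::assay(x, "imputed", withDimnames = FALSE)

#' @rdname cohort-accessors
#' @export
featureSpecs <- function(x)
    as.data.frame(SummarizedExperiment::rowData(x))

#' @rdname cohort-accessors
#' @export
scoreSchemas <- function(x) S4Vectors::metadata(x)$scoreSchemas

#' @rdname cohort-accessors
#' @export
sampleIds <- function(x) colnames(x)

#' @rdname cohort-accessors
#' @export
clinicalScores <- function(x) {
    rd <- SummarizedExperiment::rowData(x)
    rownames(x)[rd$role == "clinical_score"]
}

#' @rdname cohort-accessors
#' @export
isNormalized <- function(x) isTRUE(S4Vectors::metadata(x)$normalized)

## feature names belonging to a feature-vector form
.formFeatures <- function(x, form = c("hybrid", "morphometrics", "demographics")) {
    form <- match.arg(form)
    rd <- SummarizedExperiment::rowData(x)
    keep <- switch(form,
        hybrid         = rep(TRUE, nrow(x)),
        morphometrics  = rd$role == "morphometric",
        demographics   = rd$role %in% c("demographic", "clinical_score"))
    rownames(x)[keep]
}

## one-shot assay replacement (much cheaper than repeated `assay<-`)
.replaceAssays <- function(x, v, o, im) {
    SummarizedExperiment::assays(x, withDimnames = FALSE) <-
        S4Vectors::SimpleList(values = v, observed = o, imputed = im)
    x
}

## replace the values/observed assays, preserving everything else
.setCells <- function(x, feature, samples, values, imputed = TRUE) {
    v <- SummarizedExperiment::assay(x, "values", withDimnames = FALSE)
    o <- SummarizedExperiment::assay(x, "observed", withDimnames = FALSE)
    im <- SummarizedExperiment::assay(x, "imputed", withDimnames = FALSE)
    v[feature, samples] <- values
    o[feature, samples] <- TRUE
    im[feature, samples] <- imputed
    .replaceAssays(x, v, o, im)
}

## hide cells (used by the masking protocol)
.maskCells <- function(x, feature, samples) {
    v <- SummarizedExperiment::assay(x, "values", withDimnames = FALSE)
    o <- SummarizedExperiment::assay(x, "observed", withDimnames = FALSE)
    v[feature, samples] <- NA_real_
    o[feature, samples] <- FALSE
    .replaceAssays(x, v, o, SummarizedExperiment::assay(x, "imputed", withDimnames = FALSE))
}

## deterministic seeding that does not disturb the caller's RNG stream
.withSeed <- function(seed, code) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        stats::runif(1)
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    code
}
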