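#' Drop anomalous rows and columns before imputation
#'
#' Removes morphometric features with more than `col_missing_frac` missing
#' entries (or, optionally, zero variance among observed entries) and samples
#' missing more than `row_missing_frac` of the surviving morphometrics.
#' Demographic and clinical-score features are never dropped here: their
#' missingness is what the imputer exists for.
#'
#' @param x a [DementiaCohort-class].
#' @param row_missing_frac,col_missing_frac maximum tolerated missing
#'   fraction for samples / morphometric features, in \[0, 1\].
#' @param zero_variance drop morphometric features constant over observed
#'   entries?
#' @return list with `cohort` (filtered) and `report` (a list with
#'   `dropped_features` and `dropped_samples`).
#' @export
filterAnomalies <- function(x, row_missing_frac = 0.5,
                            col_missing_frac = 0.2, zero_variance = TRUE) {
    stopifnot(row_missing_frac >= 0, row_missing_frac <= 1,
              col_missing_frac >= 0, col_missing_frac <= 1)
    rd <- SummarizedExperiment::rowData(x)
    obs <- observedMask(x)
    v <- featureValues(x)
    morpho <- rd$role == "morphometric"
    colMiss <- 1 - rowMeans(obs)         # per feature
    dropF <- morpho & colMiss > col_missing_frac
    if (zero_variance) {
        zv <- vapply(seq_len(nrow(v)), function(i) {
            vi <- v[i, obs[i, ]]
            length(vi) > 0L && (length(unique(vi)) == 1L)
        }, logical(1))
        dropF <- dropF | (morpho & zv)
    }
    keepF <- !dropF
    morphoKept <- morpho & keepF
    if (any(morphoKept)) {
        rowMiss <- 1 - colMeans(obs[morphoKept, , drop = FALSE])
        dropS <- rowMiss > row_missing_frac
    } else dropS <- rep(FALSE, ncol(x))
    if (all(dropS)) stop("all samples dropped by anomaly filter")
    out <- x[keepF, !dropS]
    list(cohort = out,
         report = list(dropped_features = rownames(x)[dropF],
                       dropped_samples = colnames(x)[dropS]))
}

.HEMI_PREFIX <- "^(left[-_ ]|right[-_ ]|lh[-_.]|rh[-_.])"

#' Average left- and right-hemisphere morphometrics
#'
#' Pairs of features that share a base name after stripping a
#' `Left-`/`Right-`/`lh`/`rh` prefix (case-insensitive) are replaced by a
#' single bilateral feature holding their per-sample arithmetic mean.  When
#' one side is missing for a sample, the observed side's value is kept and
#' the cell stays observed; both sides missing leaves the cell missing.
#' Unpaired features pass through unchanged and feature order is preserved
#' (a merged pair sits at the position of its left member).
#'
#' @param x a [DementiaCohort-class].
#' @return a [DementiaCohort-class] with paired features merged.
#' @export
averageHemispheres <- function(x) {
    rd <- SummarizedExperiment::rowData(x)
    nm <- rownames(x)
    base <- sub(.HEMI_PREFIX, "", nm, ignore.case = TRUE)
    isL <- rd$hemisphere == "left"
    isR <- rd$hemisphere == "right"
    pairedBase <- intersect(base[isL], base[isR])
    if (!length(pairedBase)) return(x)
    clash <- intersect(pairedBase, nm[!(isL | isR)])
    if (length(clash))
        stop("hemisphere merge would collide with existing features: ",
             paste(clash, collapse = ", "))
    v <- featureValues(x); obs <- observedMask(x); imp <- imputedMask(x)
    keep <- rep(TRUE, nrow(x))
    for (b in pairedBase) {
        li <- which(isL & base == b)
        ri <- which(isR & base == b)
        if (length(li) != 1L || length(ri) != 1L)
            stop("ambiguous hemisphere pair for base name '", b, "'")
        lv <- v[li, ]; rv <- v[ri, ]
        merged <- ifelse(is.na(lv), rv, ifelse(is.na(rv), lv, (lv + rv) / 2))
        v[li, ] <- merged
        obs[li, ] <- !is.na(merged)
        imp[li, ] <- imp[li, ] | imp[ri, ]
        keep[ri] <- FALSE
        rownames(v)[li] <- b
    }
    rownames(obs) <- rownames(imp) <- rownames(v)
    specs <- featureSpecs(x)
    specs$name <- rownames(v)
    specs$hemisphere[specs$name %in% pairedBase] <- "bilateral"
    specs <- specs[keep, , drop = FALSE]
    out <- SummarizedExperiment::SummarizedExperiment(
        assays = list(values = v[keep, , drop = FALSE],
                      observed = obs[keep, , drop = FALSE],
                      imputed = imp[keep, , drop = FALSE]),
        rowData = S4Vectors::DataFrame(specs, row.names = specs$name))
    out <- methods::new("DementiaCohort", out)
    S4Vectors::metadata(out) <- S4Vectors::metadata(x)
    validObject(out)
    out
}

#' Keep morphometrics of selected keyword classes
#'
#' Retains morphometric features whose keyword class is in `keywords`, plus
#' every demographic and clinical-score feature; order is preserved.
#'
#' @param x a [DementiaCohort-class].
#' @param keywords character subset of the eight FreeSurfer-stats keyword
#'   classes (`general`, `volumemm3`, `area`, `thickavg`, `grayvol`,
#'   `nvoxels`, `numvert`, `nvertices`).
#' @return the filtered [DementiaCohort-class].
#' @export
selectMorphometrics <- function(x, keywords = .KEYWORD_CLASSES) {
    bad <- setdiff(keywords, .KEYWORD_CLASSES)
    if (length(bad))
        stop("unknown keyword class: ", paste(bad, collapse = ", "))
    rd <- SummarizedExperiment::rowData(x)
    keep <- rd$role != "morphometric" | rd$keyword_class %in% keywords
    if (!any(keep)) stop("no features selected")
    x[keep, ]
}

#' Build the default normalisation plan
#'
#' Volume features (`volumemm3`) are divided by the intracranial-volume
#' reference, gray-volume features (`grayvol`) by the total-gray-volume
#' reference; nominal features are left alone; everything else, clinical
#' scores included, is min-max scaled.  Clinical scores use their schema's
#' observed range rather than the column min/max so that normalised scores
#' are comparable across cohorts.
#'
#' @param x a [DementiaCohort-class].
#' @param icv_col,graytotal_col names of the reference features; `NULL`
#'   auto-detects names containing `IntraCranialVol` / `TotalGrayVol`.
#' @return a named character vector, one rule per feature:
#'   `"minmax"`, `"none"`, or `"ref:<reference feature>"`.
#' @export
makeNormalizationPlan <- function(x, icv_col = NULL, graytotal_col = NULL) {
    nm <- rownames(x)
    rd <- SummarizedExperiment::rowData(x)
    if (is.null(icv_col)) {
        hit <- grep("intracranialvol", nm, ignore.case = TRUE, value = TRUE)
        icv_col <- if (length(hit)) hit[[1L]] else NULL
    }
    if (is.null(graytotal_col)) {
        hit <- grep("totalgrayvol", nm, ignore.case = TRUE, value = TRUE)
        graytotal_col <- if (length(hit)) hit[[1L]] else NULL
    }
    plan <- rep("minmax", length(nm))
    names(plan) <- nm
    plan[rd$nominal] <- "none"
    if (!is.null(icv_col)) {
        plan[rd$keyword_class == "volumemm3"] <- paste0("ref:", icv_col)
        plan[icv_col] <- "minmax"
    }
    if (!is.null(graytotal_col)) {
        plan[rd$keyword_class == "grayvol"] <- paste0("ref:", graytotal_col)
        plan[graytotal_col] <- "minmax"
    }
    attr(plan, "references") <- c(icv_col, graytotal_col)
    plan
}

#' Functionally normalise a cohort to \[0, 1\]
#'
#' Applies a [makeNormalizationPlan()]-style plan: `ref:`-ruled features are
#' first divided per sample by their reference feature and then min-max
#' rescaled; `minmax` features are rescaled by their observed column range;
#' nominal (`none`) features are untouched; clinical scores are rescaled
#' using the observed range recorded in the score schema.  The observation
#' mask is unchanged.  A constant column is flagged with a warning and set
#' to 0 for all samples.
#'
#' @param x a [DementiaCohort-class].
#' @param plan normalisation plan; `NULL` builds the default plan.
#' @param drop_references remove the reference denominators from the output
#'   feature set after use (they are denominators, not predictors)?
#' @return normalised [DementiaCohort-class] (`isNormalized()` is `TRUE`).
#' @export
normalizeCohort <- function(x, plan = NULL, drop_references = TRUE) {
    if (is.null(plan)) plan <- makeNormalizationPlan(x)
    v <- featureValues(x)
    obs <- observedMask(x)
    rd <- SummarizedExperiment::rowData(x)
    schemas <- scoreSchemas(x)
    refs <- attr(plan, "references")
    for (i in seq_len(nrow(v))) {
        nm <- rownames(v)[i]
        rule <- plan[[nm]]
        if (identical(rule, "none")) next
        vi <- v[i, ]
        if (startsWith(rule, "ref:")) {
            refnm <- sub("^ref:", "", rule)
            if (!refnm %in% rownames(v))
                stop("reference feature not found: ", refnm)
            ref <- v[refnm, ]
            need <- !is.na(vi)
            if (any(need & (is.na(ref) | ref <= 0)))
                stop("reference value missing or <= 0 in '", refnm,
                     "' for feature '", nm, "'")
            vi[need] <- vi[need] / ref[need]
        }
        if (rd$role[i] == "clinical_score") {
            sch <- schemas[toupper(schemas$name) == toupper(nm), , drop = FALSE]
            lo <- sch$observed_min[1L]; hi <- sch$observed_max[1L]
        } else {
            lo <- suppressWarnings(min(vi, na.rm = TRUE))
            hi <- suppressWarnings(max(vi, na.rm = TRUE))
        }
        if (!is.finite(lo) || !is.finite(hi) || hi - lo < 1e-12) {
            warning("constant column '", nm, "' set to 0")
            vi[!is.na(vi)] <- 0
        } else vi <- (vi - lo) / (hi - lo)
        v[i, ] <- vi
    }
    SummarizedExperiment::assay(x, "values") <- v
    S4Vectors::metadata(x)$normalized <- TRUE
    if (drop_references && length(refs))
        x <- x[!rownames(x) %in% refs, ]
    validObject(x)
    x
}

#' Run the standard preprocessing pipeline
#'
#' Convenience wrapper applying, in order, [filterAnomalies()],
#' [averageHemispheres()], [selectMorphometrics()] and [normalizeCohort()].
#'
#' @param x a raw [DementiaCohort-class].
#' @param keywords keyword classes to retain (default: all eight).
#' @param ... further arguments for [filterAnomalies()] /
#'   [normalizeCohort()].
#' @inheritParams filterAnomalies
#' @inheritParams normalizeCohort
#' @return normalised [DementiaCohort-class].
#' @export
preprocessCohort <- function(x, keywords = .KEYWORD_CLASSES,
                             row_missing_frac = 0.5, col_missing_frac = 0.2,
                             zero_variance = TRUE, drop_references = TRUE) {
    x <- filterAnomalies(x, row_missing_frac, col_missing_frac,
                         zero_variance)$cohort
    x <- averageHemispheres(x)
    x <- selectMorphometrics(x, keywords)
    normalizeCohort(x, drop_references = drop_references)
}
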