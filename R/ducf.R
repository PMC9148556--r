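#' Select the best-neighbour-count most similar patients
#'
#' Candidates are all other samples that (a) have the target score observed
#' (an unobserved score cannot contribute to the weighted average) and
#' (b) carry a valid, resolved similarity weight to the target.  They are
#' sorted by weight, descending, ties broken by ascending sample id, and
#' truncated to the best neighbour count (BNC); fewer candidates than BNC
#' means all are kept.
#'
#' @param target sample id of the patient of interest.
#' @param score_type name of the clinical score feature being predicted.
#' @param W resolved similarity matrix ([similarityMatrix()] +
#'   [resolveInfinite()]).
#' @param x the [DementiaCohort-class] supplying observed scores.
#' @param bnc best neighbour count, a positive integer.
#' @return object of class `NeighborSet`: list with `target`, `score_type`,
#'   `ids`, `weights`, `scores` (sorted, length <= bnc) and `bnc`.
#' @export
selectNeighbors <- function(target, score_type, W, x, bnc) {
    stopifnot(bnc >= 1)
    obs <- observedMask(x)[score_type, ]
    w <- W[target, ]
    cand <- setdiff(colnames(x)[obs], target)
    cand <- cand[!is.na(w[cand]) & is.finite(w[cand])]
    if (!length(cand))
        stop("no candidate neighbours with observed '", score_type,
             "' for sample ", target)
    o <- order(-w[cand], cand, method = "radix")
    keep <- cand[o][seq_len(min(bnc, length(cand)))]
    structure(list(target = target, score_type = score_type,
                   ids = keep, weights = unname(w[keep]),
                   scores = unname(featureValues(x)[score_type, keep]),
                   bnc = as.integer(bnc)),
              class = "NeighborSet")
}

#' Weighted-average score prediction from a neighbour set
#'
#' The prediction for patient \eqn{x} and score \eqn{cs} is
#' \deqn{p_{x,cs} = \frac{\sum_{y} y_{cs} \, w_{x,y}}{\sum_{y} w_{x,y}}}
#' over the neighbour set.  The signed weights appear in both numerator and
#' denominator as printed; when the denominator is within `1e-12` of zero
#' (cancelling positive and negative correlations) the prediction falls back
#' to the unweighted mean of the neighbour scores and is flagged.  An
#' absolute-weight denominator is available via `denominator = "absolute"`.
#'
#' @param ns a `NeighborSet` from [selectNeighbors()].
#' @param denominator `"signed"` (the printed formula, default) or
#'   `"absolute"`.
#' @return object of class `Prediction`: list with `target`, `score_type`,
#'   `value`, `n_neighbors`, `fallback`.
#' @export
predictScore <- function(ns, denominator = c("signed", "absolute")) {
    denominator <- match.arg(denominator)
    stopifnot(length(ns$ids) >= 1L)
    w <- ns$weights
    den <- if (denominator == "absolute") sum(abs(w)) else sum(w)
    if (abs(den) < 1e-12) {
        value <- mean(ns$scores)
        fallback <- TRUE
    } else {
        value <- sum(ns$scores * w) / den
        fallback <- FALSE
    }
    structure(list(target = ns$target, score_type = ns$score_type,
                   value = value, n_neighbors = length(ns$ids),
                   fallback = fallback),
              class = "Prediction")
}

#' Impute missing clinical scores by user-based collaborative filtering
#'
#' For every clinical-score cell with `observed = FALSE`, computes
#' similarities between the patient of interest and all other samples over
#' the chosen feature-vector form (always excluding the score being
#' predicted, so the target never leaks into its own similarity), selects
#' the top-BNC neighbours among samples with that score observed, and fills
#' the cell with the weighted-average prediction.  Neighbour scores are
#' always taken from the original observed data: values imputed within the
#' same run are never reused.
#'
#' @param x a preprocessed/normalised [DementiaCohort-class].
#' @param measure similarity measure (`pcc`, `mrc`, `cos`, `man`, `euc`).
#' @param bnc best neighbour count.
#' @param feature_form `"hybrid"` (all features), `"morphometrics"` or
#'   `"demographics"` (demographic + other clinical scores).
#' @param min_overlap minimum pairwise overlap for a valid weight.
#' @param resolve_scope see [resolveInfinite()].
#' @param denominator see [predictScore()].
#' @return list with `cohort` (filled, `imputedMask()` flags the new
#'   cells), `predictions` (`data.frame`: sample, score_type, value,
#'   n_neighbors, fallback) and `failures` (`data.frame`: sample,
#'   score_type, reason).
#' @examples
#' coh <- simulateCohort(n_samples = 30, n_morphometrics = 20, seed = 1)
#' norm <- preprocessCohort(coh)
#' fit <- imputeScores(norm, measure = "man", bnc = 3)
#' head(fit$predictions)
#' @export
imputeScores <- function(x, measure = "man", bnc = 6L,
                         feature_form = c("hybrid", "morphometrics",
                                          "demographics"),
                         min_overlap = 2L,
                         resolve_scope = c("matrix", "row"),
                         denominator = c("signed", "absolute")) {
    measure <- match.arg(tolower(measure), .MEASURES)
    feature_form <- match.arg(feature_form)
    resolve_scope <- match.arg(resolve_scope)
    denominator <- match.arg(denominator)
    scores <- clinicalScores(x)
    obs <- observedMask(x)
    v <- featureValues(x)
    ids_all <- colnames(x)
    out <- x
    preds <- list(); fails <- list()
    for (cs in scores) {
        missing_ids <- ids_all[!obs[cs, ]]
        if (!length(missing_ids)) next
        feats <- setdiff(.formFeatures(x, feature_form), cs)
        W <- similarityMatrix(x, measure, features = feats,
                              min_overlap = min_overlap)
        if (any(is.infinite(W))) W <- resolveInfinite(W, resolve_scope)
        obs_cs <- ids_all[obs[cs, ]]
        y_cs <- v[cs, ]
        fill_ids <- character(0); fill_vals <- numeric(0)
        for (id in missing_ids) {
            w <- W[id, ]
            cand <- setdiff(obs_cs, id)
            cand <- cand[!is.na(w[cand])]
            if (!length(cand)) {
                fails[[length(fails) + 1L]] <-
                    data.frame(sample = id, score_type = cs,
                               reason = paste0("no candidate neighbours ",
                                               "with observed '", cs, "'"),
                               stringsAsFactors = FALSE)
                next
            }
            o <- order(-w[cand], cand, method = "radix")
            keep <- cand[o][seq_len(min(bnc, length(cand)))]
            ws <- w[keep]; ys <- y_cs[keep]
            den <- if (denominator == "absolute") sum(abs(ws)) else sum(ws)
            fallback <- abs(den) < 1e-12
            value <- if (fallback) mean(ys) else sum(ys * ws) / den
            preds[[length(preds) + 1L]] <-
                data.frame(sample = id, score_type = cs, value = value,
                           n_neighbors = length(keep), measure = measure,
                           fallback = fallback, stringsAsFactors = FALSE)
            fill_ids <- c(fill_ids, id); fill_vals <- c(fill_vals, value)
        }
        if (length(fill_ids))
            out <- .setCells(out, cs, fill_ids, fill_vals)
    }
    empty_p <- data.frame(sample = character(), score_type = character(),
                          value = numeric(), n_neighbors = integer(),
                          measure = character(), fallback = logical(),
                          stringsAsFactors = FALSE)
    empty_f <- data.frame(sample = character(), score_type = character(),
                          reason = character(), stringsAsFactors = FALSE)
    list(cohort = out,
         predictions = if (length(preds)) do.call(rbind, preds) else empty_p,
         failures = if (length(fails)) do.call(rbind, fails) else empty_f)
}
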