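#' Random masking plan over observed clinical-score cells
#'
#' For each clinical score, draws `k` samples uniformly without replacement
#' among the samples with that score observed (all of them when fewer than
#' `k` are available); the selected cells are emptied for one evaluation
#' trial.  A score column with zero observed values is excluded with a
#' warning.  The plan is fully reproducible from `seed`.
#'
#' @param x a [DementiaCohort-class].
#' @param k samples to mask per score (the benchmark protocol uses 250 per
#'   score at cohort scale).
#' @param seed integer seed.
#' @return object of class `MaskingPlan`: list with `cells` (named list,
#'   score -> sample ids), `k`, `seed`.
#' @export
makeMaskingPlan <- function(x, k, seed) {
    stopifnot(k >= 1)
    obs <- observedMask(x)
    scores <- clinicalScores(x)
    cells <- .withSeed(seed, {
        out <- list()
        for (cs in scores) {
            ids <- colnames(x)[obs[cs, ]]
            if (!length(ids)) {
                warning("score '", cs, "' has no observed values; excluded")
                next
            }
            out[[cs]] <- sort(sample(ids, min(k, length(ids))))
        }
        out
    })
    structure(list(cells = cells, k = as.integer(k), seed = as.integer(seed)),
              class = "MaskingPlan")
}

#' @export
print.MaskingPlan <- function(x, ...) {
    cat(sprintf("MaskingPlan: %d cells over %d scores (k = %d, seed = %d)\n",
                sum(lengths(x$cells)), length(x$cells), x$k, x$seed))
    invisible(x)
}

#' Apply a masking plan, recording the hidden ground truth
#'
#' @param x a [DementiaCohort-class].
#' @param plan a `MaskingPlan` from [makeMaskingPlan()].
#' @return list with `cohort` (cells emptied) and `actual` (`data.frame`:
#'   score_type, sample, value -- the hidden values).
#' @export
applyMaskingPlan <- function(x, plan) {
    v <- featureValues(x)
    actual <- list()
    out <- x
    for (cs in names(plan$cells)) {
        ids <- plan$cells[[cs]]
        actual[[cs]] <- data.frame(score_type = cs, sample = ids,
                                   value = unname(v[cs, ids]),
                                   stringsAsFactors = FALSE)
        out <- .maskCells(out, cs, ids)
    }
    list(cohort = out, actual = do.call(rbind, c(actual, make.row.names = FALSE)))
}

#' Imputation performance metrics
#'
#' Mean absolute error, mean squared error, root mean squared error and
#' R-squared of imputed values against the hidden actual values:
#' \deqn{R^2 = 1 - \sum_i (y_i - x_i)^2 / \sum_i (\bar{x} - x_i)^2}
#' with \eqn{x} the actual and \eqn{y} the imputed values.  Zero variance
#' in the actual values makes R-squared undefined (`NA`).
#'
#' @param actual,imputed numeric vectors of equal length.
#' @return one-row `data.frame`: `mae`, `mse`, `rmse`, `r_squared`, `n`.
#' @examples
#' imputationMetrics(c(0, 0), c(3, 4))   # rmse = sqrt(12.5)
#' @export
imputationMetrics <- function(actual, imputed) {
    stopifnot(length(actual) == length(imputed), length(actual) >= 1L)
    e <- imputed - actual
    mse <- mean(e^2)
    sst <- sum((mean(actual) - actual)^2)
    r2 <- if (length(actual) >= 2L && sst > 0) 1 - sum(e^2) / sst else NA_real_
    data.frame(mae = mean(abs(e)), mse = mse, rmse = sqrt(mse),
               r_squared = r2, n = length(actual))
}

#' Correlation and paired-comparison statistics of actual vs imputed values
#'
#' Pearson correlation of the pairs and a paired-samples t-test on the
#' differences `actual - imputed` (via [stats::t.test()]), with
#' `df = n - 1`.  Zero variance of the differences leaves the t statistic
#' undefined (`NA`, flagged).
#'
#' @param actual,imputed numeric vectors of equal length, `n >= 3`.
#' @return list of class `ComparisonStats`: `pearson_r`, `df`,
#'   `t_statistic`, `p_value`, `mean_actual`, `sd_actual`, `mean_imputed`,
#'   `sd_imputed`, `degenerate`.
#' @export
compareActualImputed <- function(actual, imputed) {
    stopifnot(length(actual) == length(imputed), length(actual) >= 3L)
    n <- length(actual)
    d <- actual - imputed
    r <- if (stats::sd(actual) > 0 && stats::sd(imputed) > 0)
        stats::cor(actual, imputed) else NA_real_
    if (stats::sd(d) > 0) {
        tt <- stats::t.test(actual, imputed, paired = TRUE)
        tstat <- unname(tt$statistic); p <- tt$p.value; degen <- FALSE
    } else {
        tstat <- NA_real_; p <- NA_real_; degen <- TRUE
    }
    structure(list(pearson_r = r, df = n - 1L, t_statistic = tstat,
                   p_value = p,
                   mean_actual = mean(actual), sd_actual = stats::sd(actual),
                   mean_imputed = mean(imputed),
                   sd_imputed = stats::sd(imputed), degenerate = degen),
              class = "ComparisonStats")
}

#' @export
print.ComparisonStats <- function(x, ...) {
    cat(sprintf("r(%d) = %.3f; paired t(%d) = %s, p = %s\n",
                x$df + 1L, x$pearson_r, x$df,
                if (x$degenerate) "undefined" else sprintf("%.3f", x$t_statistic),
                if (x$degenerate) "-" else format.pval(x$p_value, digits = 3)))
    invisible(x)
}

#' Build a configuration table for the evaluation harness
#'
#' @param ducf named list with `measures`, `feature_forms`, `bnc` vectors;
#'   their full crossing enters the table.  `NULL` adds no collaborative
#'   filtering rows.
#' @param baselines character vector of baseline method names.
#' @return `data.frame` with columns `technique`, `feature_form`,
#'   `measure`, `bnc`.
#' @export
experimentConfigs <- function(ducf = list(measures = "man",
                                          feature_forms = "hybrid",
                                          bnc = 1:10),
                              baselines = character()) {
    rows <- list()
    if (!is.null(ducf)) {
        grid <- expand.grid(measure = ducf$measures,
                            feature_form = ducf$feature_forms,
                            bnc = ducf$bnc, stringsAsFactors = FALSE)
        rows[[1L]] <- data.frame(technique = "ducf",
                                 feature_form = grid$feature_form,
                                 measure = grid$measure, bnc = grid$bnc,
                                 stringsAsFactors = FALSE)
    }
    if (length(baselines))
        rows[[length(rows) + 1L]] <-
            data.frame(technique = baselines, feature_form = NA_character_,
                       measure = NA_character_, bnc = NA_integer_,
                       stringsAsFactors = FALSE)
    do.call(rbind, rows)
}

#' Run the masking benchmark over repeated trials
#'
#' For each repeat: a fresh [makeMaskingPlan()] (seed = `base_seed` +
#' repeat index) empties `k` observed cells per score; every configuration
#' imputes those cells on the masked cohort (masked cells are hidden from
#' the similarity vectors as well, so nothing leaks); the metrics of
#' [imputationMetrics()] are computed per configuration, then averaged over
#' repeats.  Collaborative-filtering configurations sharing a feature form
#' and measure reuse one similarity matrix per score, so sweeping BNC is
#' cheap.
#'
#' @param x a normalised [DementiaCohort-class].
#' @param configs configuration table from [experimentConfigs()].
#' @param k masked samples per score and repeat.
#' @param n_repeats number of masking repetitions.
#' @param base_seed integer; repeat `r` uses seed `base_seed + r`.
#' @param min_overlap,resolve_scope,denominator forwarded to the
#'   collaborative-filtering imputer.
#' @param winsor_fraction,lrmc_rank forwarded to [imputeBaseline()].
#' @return `data.frame`, one row per configuration: the config columns plus
#'   averaged `mae`, `mse`, `rmse`, `r_squared`, total `n_cells`,
#'   `n_repeats`, total `n_failures`.
#' @export
runExperiment <- function(x, configs, k = 25L, n_repeats = 20L,
                          base_seed = 1L, min_overlap = 2L,
                          resolve_scope = "matrix", denominator = "signed",
                          winsor_fraction = 0.05, lrmc_rank = 3L) {
    stopifnot(nrow(configs) >= 1L)
    cfgKey <- function(i) paste(configs$technique[i], configs$feature_form[i],
                                configs$measure[i], configs$bnc[i], sep = "|")
    keys <- vapply(seq_len(nrow(configs)), cfgKey, character(1))
    acc <- lapply(keys, function(k.) list(metrics = list(), fails = 0L))
    names(acc) <- keys
    isDucf <- configs$technique == "ducf"
    ducfGroups <- unique(configs[isDucf, c("feature_form", "measure")])
    for (r in seq_len(n_repeats)) {
        plan <- makeMaskingPlan(x, k, seed = base_seed + r)
        masked <- applyMaskingPlan(x, plan)
        mc <- masked$cohort
        actual <- masked$actual
        cellKey <- paste(actual$score_type, actual$sample)
        ## collaborative filtering, grouped by (form, measure)
        if (any(isDucf)) for (g in seq_len(nrow(ducfGroups))) {
            form <- ducfGroups$feature_form[g]
            meas <- ducfGroups$measure[g]
            sel <- which(isDucf & configs$feature_form == form &
                         configs$measure == meas)
            bncs <- configs$bnc[sel]
            pred <- matrix(NA_real_, nrow(actual), length(sel))
            for (cs in unique(actual$score_type)) {
                feats <- setdiff(.formFeatures(mc, form), cs)
                W <- similarityMatrix(mc, meas, features = feats,
                                      min_overlap = min_overlap)
                if (any(is.infinite(W)))
                    W <- resolveInfinite(W, resolve_scope)
                obsRow <- observedMask(mc)[cs, ]
                yAll <- featureValues(mc)[cs, ]
                rows <- which(actual$score_type == cs)
                for (ri in rows) {
                    id <- actual$sample[ri]
                    w <- W[id, ]
                    cand <- setdiff(colnames(mc)[obsRow], id)
                    cand <- cand[!is.na(w[cand])]
                    m <- length(cand)
                    if (m == 0L) next
                    o <- order(-w[cand], cand, method = "radix")
                    ws <- unname(w[cand][o]); ys <- unname(yAll[cand][o])
                    cw <- cumsum(ws); cwy <- cumsum(ws * ys)
                    cm <- cumsum(ys) / seq_len(m)
                    idx <- pmin(bncs, m)
                    den <- cw[idx]
                    pred[ri, ] <- ifelse(abs(den) < 1e-12, cm[idx],
                                         cwy[idx] / den)
                }
            }
            for (j in seq_along(sel)) {
                ok <- !is.na(pred[, j])
                key <- keys[sel[j]]
                acc[[key]]$fails <- acc[[key]]$fails + sum(!ok)
                acc[[key]]$metrics[[r]] <-
                    imputationMetrics(actual$value[ok], pred[ok, j])
            }
        }
        ## baselines
        for (i in which(!isDucf)) {
            bl <- imputeBaseline(mc, configs$technique[i],
                                 winsor_fraction = winsor_fraction,
                                 lrmc_rank = lrmc_rank)
            v <- featureValues(bl$cohort)
            imp <- v[cbind(match(actual$score_type, rownames(v)),
                           match(actual$sample, colnames(v)))]
            ok <- !is.na(imp)
            key <- keys[i]
            acc[[key]]$fails <- acc[[key]]$fails + sum(!ok)
            acc[[key]]$metrics[[r]] <-
                imputationMetrics(actual$value[ok], imp[ok])
        }
    }
    res <- configs
    for (col in c("mae", "mse", "rmse", "r_squared")) res[[col]] <- NA_real_
    res$n_cells <- 0L; res$n_repeats <- as.integer(n_repeats)
    res$n_failures <- 0L
    for (i in seq_len(nrow(configs))) {
        a <- acc[[keys[i]]]
        mdf <- do.call(rbind, a$metrics)
        for (col in c("mae", "mse", "rmse", "r_squared"))
            res[[col]][i] <- mean(mdf[[col]], na.rm = TRUE)
        res$n_cells[i] <- sum(mdf$n)
        res$n_failures[i] <- a$fails
    }
    res
}

#' Rank configurations by summed per-metric ranks
#'
#' Within each metric -- MAE ascending, RMSE ascending, R-squared
#' descending -- configurations receive ranks 1..K (average rank for ties;
#' an invalid R-squared ranks last with a warning); configurations are then
#' ordered by the sum of their three ranks, ties broken by MAE, remaining
#' ties keep the input order.
#'
#' @param reports `data.frame` with at least `mae`, `rmse`, `r_squared`
#'   columns (e.g. from [runExperiment()]).
#' @return `reports` reordered, with `rank_mae`, `rank_rmse`, `rank_r2` and
#'   `rank_sum` columns appended.
#' @export
rankConfigs <- function(reports) {
    stopifnot(nrow(reports) >= 1L)
    r2 <- reports$r_squared
    if (anyNA(r2)) {
        warning("invalid R-squared ranked last")
        r2[is.na(r2)] <- -Inf
    }
    reports$rank_mae <- rank(reports$mae, ties.method = "average")
    reports$rank_rmse <- rank(reports$rmse, ties.method = "average")
    reports$rank_r2 <- rank(-r2, ties.method = "average")
    reports$rank_sum <- reports$rank_mae + reports$rank_rmse + reports$rank_r2
    reports[order(reports$rank_sum, reports$mae), , drop = FALSE]
}
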