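#' Reference imputers: zero, mean, winsorized mean, median, LRMC
#'
#' Fills masked cells with a per-column statistic over the observed entries
#' (`zero`, `mean`, `winsorized_mean`, `median`) or by low-rank matrix
#' completion (`lrmc`), the soft-impute-style iteration: initialise missing
#' cells at the column mean, then repeat truncated-SVD reconstruction of the
#' completed matrix and refill only the missing positions until the largest
#' change is below `lrmc_tol` or `lrmc_max_iter` is hit (non-convergence
#' returns the last iterate with a warning).  Observed cells are never
#' altered by any method.
#'
#' Winsorization clamps the `winsor_fraction` tail order statistics on each
#' side to the nearest retained value before averaging
#' (`k = floor(winsor_fraction * n)` values per tail), so
#' `winsor_fraction = 0` reproduces the plain mean exactly.
#'
#' @param x a normalised [DementiaCohort-class].
#' @param method one of `"zero"`, `"mean"`, `"winsorized_mean"`,
#'   `"median"`, `"lrmc"`.
#' @param winsor_fraction tail fraction in \[0, 0.5) for
#'   `winsorized_mean` (default 0.05 per tail).
#' @param lrmc_rank target rank for the truncated SVD (default 3); ignored
#'   when `lrmc_lambda` is given.
#' @param lrmc_lambda optional soft-threshold applied to the singular
#'   values instead of hard rank truncation.
#' @param lrmc_max_iter,lrmc_tol iteration controls for `lrmc`.
#' @param targets `"scores"` (default: fill only clinical-score cells, the
#'   quantity the benchmark imputes) or `"all"` masked cells.
#' @return list with `cohort` (filled) and `predictions` (`data.frame`:
#'   sample, score_type/feature, value).
#' @examples
#' coh <- simulateCohort(n_samples = 20, n_morphometrics = 12,
#'                       missing_frac = 0.2, seed = 3)
#' norm <- preprocessCohort(coh)
#' fit <- imputeBaseline(norm, "median")
#' @export
imputeBaseline <- function(x, method = c("zero", "mean", "winsorized_mean",
                                         "median", "lrmc"),
                           winsor_fraction = 0.05, lrmc_rank = 3L,
                           lrmc_lambda = NULL, lrmc_max_iter = 200L,
                           lrmc_tol = 1e-6, targets = c("scores", "all")) {
    method <- match.arg(method)
    targets <- match.arg(targets)
    stopifnot(winsor_fraction >= 0, winsor_fraction < 0.5)
    v <- featureValues(x)
    obs <- observedMask(x)
    featSel <- if (targets == "scores") clinicalScores(x) else rownames(x)
    fill <- matrix(NA_real_, nrow(v), ncol(v), dimnames = dimnames(v))
    if (method == "lrmc") {
        Z <- .lrmcComplete(v, rank = lrmc_rank, lambda = lrmc_lambda,
                           max_iter = lrmc_max_iter, tol = lrmc_tol)
        fill <- Z
    } else {
        for (f in featSel) {
            vi <- v[f, obs[f, ]]
            if (!length(vi) && method != "zero")
                stop("column '", f, "' has no observed values")
            stat <- switch(method,
                zero = 0,
                mean = mean(vi),
                median = stats::median(vi),
                winsorized_mean = .winsorizedMean(vi, winsor_fraction))
            fill[f, ] <- stat
        }
    }
    out <- x
    preds <- list()
    for (f in featSel) {
        miss <- colnames(x)[!obs[f, ]]
        if (!length(miss)) next
        vals <- fill[f, miss]
        if (anyNA(vals))
            stop("column '", f, "' has no observed values")
        out <- .setCells(out, f, miss, vals)
        preds[[length(preds) + 1L]] <-
            data.frame(sample = miss, score_type = f, value = unname(vals),
                       stringsAsFactors = FALSE)
    }
    list(cohort = out,
         predictions = if (length(preds)) do.call(rbind, preds)
                       else data.frame(sample = character(),
                                       score_type = character(),
                                       value = numeric()))
}

## order-statistic winsorized mean: clamp k = floor(f*n) values per tail
.winsorizedMean <- function(v, frac) {
    n <- length(v)
    k <- floor(frac * n)
    if (k == 0L) return(mean(v))
    s <- sort(v)
    s[seq_len(k)] <- s[k + 1L]
    s[(n - k + 1L):n] <- s[n - k]
    mean(s)
}

## iterative truncated-SVD completion (features x samples orientation is
## irrelevant to the algorithm)
.lrmcComplete <- function(v, rank = 3L, lambda = NULL, max_iter = 200L,
                          tol = 1e-6) {
    miss <- is.na(v)
    if (!any(miss)) return(v)
    colMeanFill <- apply(v, 1L, function(r) mean(r, na.rm = TRUE))
    if (anyNA(colMeanFill)) {
        bad <- rownames(v)[is.na(colMeanFill)]
        stop("column '", bad[1L], "' has no observed values")
    }
    Z <- v
    Z[miss] <- colMeanFill[row(v)[miss]]
    converged <- FALSE
    for (it in seq_len(max_iter)) {
        sv <- svd(Z)
        d <- sv$d
        if (is.null(lambda)) {
            r <- min(rank, length(d))
            d[-seq_len(r)] <- 0
        } else d <- pmax(d - lambda, 0)
        R <- sv$u %*% (d * t(sv$v))
        delta <- max(abs(R[miss] - Z[miss]))
        Z[miss] <- R[miss]
        if (delta < tol) { converged <- TRUE; break }
    }
    if (!converged)
        warning("LRMC did not converge within ", max_iter, " iterations")
    Z[!miss] <- v[!miss]
    Z
}
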