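#' Restrict two sample vectors to features observed in both
#'
#' The similarity weights assume complete vectors; real cohorts have missing
#' score cells, so each pair is first reduced to the features observed in
#' both samples (pairwise-complete handling).
#'
#' @param x,y numeric vectors of equal length; `NA` marks a missing cell.
#' @param min_overlap smallest overlap for which a weight is considered
#'   valid (default 2).
#' @return list with `x`, `y` (the aligned sub-vectors), `n_overlap` and
#'   `valid` (`FALSE` when the overlap is below `min_overlap`).
#' @examples
#' pairwiseComplete(c(1, 2, NA), c(4, NA, 6))
#' @export
pairwiseComplete <- function(x, y, min_overlap = 2L) {
    stopifnot(length(x) == length(y))
    keep <- !is.na(x) & !is.na(y)
    n <- sum(keep)
    if (n == 0L)
        stop("similarity undefined: no overlapping observed features")
    list(x = x[keep], y = y[keep], n_overlap = n, valid = n >= min_overlap)
}

## core scalar similarity on complete vectors; NA = invalid, Inf = the
## distance-based "identical vectors" sentinel
.simValue <- function(x, y, measure) {
    n <- length(x)
    switch(measure,
        pcc = {
            if (n < 2L) return(NA_real_)
            dx <- x - mean(x); dy <- y - mean(y)
            sx <- sqrt(sum(dx^2)); sy <- sqrt(sum(dy^2))
            if (sx < 1e-12 || sy < 1e-12) NA_real_ else sum(dx * dy) / (sx * sy)
        },
        mrc = {
            if (n < 2L) return(NA_real_)
            dx <- x - stats::median(x); dy <- y - stats::median(y)
            sx <- sqrt(sum(dx^2)); sy <- sqrt(sum(dy^2))
            if (sx < 1e-12 || sy < 1e-12) NA_real_ else sum(dx * dy) / (sx * sy)
        },
        cos = {
            sx <- sqrt(sum(x^2)); sy <- sqrt(sum(y^2))
            if (sx < 1e-12 || sy < 1e-12) NA_real_ else sum(x * y) / (sx * sy)
        },
        man = {
            d <- sum(abs(x - y))
            if (d == 0) Inf else 1 / d
        },
        euc = {
            d <- sqrt(sum((x - y)^2))
            if (d == 0) Inf else 1 / d
        },
        stop("unknown measure: ", measure))
}

#' Similarity weight between two sample vectors
#'
#' Computes one of the five user-based similarity weights: Pearson
#' correlation (`pcc`), median-based robust correlation (`mrc`; Pearson's
#' formula with medians replacing means), cosine similarity (`cos`), inverse
#' Manhattan distance (`man`, \eqn{1/\sum_i |x_i - y_i|}) and inverse
#' Euclidean distance (`euc`, \eqn{1/\sqrt{\sum_i (x_i - y_i)^2}}).
#' Correlation-type weights live in \[-1, +1\]; distance-type weights are
#' positive, with identical vectors yielding an infinite sentinel resolved
#' at matrix level by [resolveInfinite()].  A zero-variance vector under
#' `pcc`/`mrc`, a zero-norm vector under `cos`, or an overlap below
#' `min_overlap` invalidates the weight (`value = NA`, `valid = FALSE`).
#'
#' @param x,y numeric sample vectors (`NA` allowed; handled pairwise
#'   complete).
#' @param measure one of `"pcc"`, `"mrc"`, `"cos"`, `"man"`, `"euc"`
#'   (case-insensitive).
#' @param min_overlap see [pairwiseComplete()].
#' @return object of class `SimilarityWeight`: list with `value`, `measure`,
#'   `n_overlap`, `valid`.
#' @examples
#' similarityWeight(c(1, 2, 3), c(3, 2, 1), "pcc")   # -1
#' similarityWeight(c(0, 0), c(3, 4), "euc")         # 1/5
#' @export
similarityWeight <- function(x, y, measure, min_overlap = 2L) {
    measure <- match.arg(tolower(measure), .MEASURES)
    pc <- pairwiseComplete(x, y, min_overlap)
    value <- if (pc$valid) .simValue(pc$x, pc$y, measure) else NA_real_
    structure(list(value = value, measure = measure,
                   n_overlap = pc$n_overlap,
                   valid = pc$valid && !is.na(value)),
              class = "SimilarityWeight")
}

#' @export
print.SimilarityWeight <- function(x, ...) {
    cat(sprintf("SimilarityWeight[%s] = %s (n_overlap = %d%s)\n",
                x$measure, format(x$value), x$n_overlap,
                if (x$valid) "" else ", invalid"))
    invisible(x)
}

#' Pairwise similarity matrix over all samples
#'
#' Computes the symmetric sample-by-sample weight matrix for one measure,
#' handling missing cells pairwise complete.  Invalid weights are `NA`;
#' identical pairs under a distance measure are `Inf` until
#' [resolveInfinite()] is applied.  The diagonal is `NA` (a sample is never
#' its own neighbour).
#'
#' @param x a [DementiaCohort-class] or a numeric samples-by-features
#'   matrix (`NA` = missing).
#' @param measure similarity measure name (see [similarityWeight()]).
#' @param features optional character vector restricting the feature set
#'   (cohort input only).
#' @param min_overlap minimum pairwise overlap for a valid weight.
#' @return numeric matrix with `measure` attribute.
#' @export
similarityMatrix <- function(x, measure, features = NULL, min_overlap = 2L) {
    measure <- match.arg(tolower(measure), .MEASURES)
    M <- if (methods::is(x, "DementiaCohort")) {
        v <- featureValues(x)
        if (!is.null(features)) v <- v[features, , drop = FALSE]
        t(v)
    } else as.matrix(x)
    W <- .simMatrix(M, measure, min_overlap)
    attr(W, "measure") <- measure
    W
}

.simMatrix <- function(M, measure, min_overlap = 2L) {
    n <- nrow(M)
    ids <- rownames(M)
    O <- !is.na(M)
    Nov <- tcrossprod(O * 1)            # pairwise overlap counts
    if (measure %in% c("pcc", "cos")) {
        if (measure == "pcc") {
            ## Pearson over any overlap is invariant to a per-vector shift;
            ## pre-centering by the global row mean tames the cancellation
            ## in the one-pass product formula
            M <- M - rowMeans(M, na.rm = TRUE)
        }
        V <- M; V[!O] <- 0
        Sxy <- tcrossprod(V)
        Sxx <- tcrossprod(V * V, O * 1) # sum x^2 over overlap with each y
        if (measure == "cos") {
            den <- sqrt(Sxx * t(Sxx))
            W <- ifelse(den < 1e-12, NA_real_, Sxy / den)
        } else {
            Sx <- tcrossprod(V, O * 1)  # sum x over overlap with each y
            Cxy <- Sxy - Sx * t(Sx) / pmax(Nov, 1)
            Vx <- Sxx - Sx^2 / pmax(Nov, 1)
            Vy <- t(Vx)
            W <- ifelse(Vx < 1e-12 | Vy < 1e-12 | Nov < 2, NA_real_,
                        Cxy / sqrt(pmax(Vx, 0) * pmax(Vy, 0)))
        }
    } else if (measure %in% c("man", "euc")) {
        W <- matrix(NA_real_, n, n)
        for (i in seq_len(n)) {
            D <- sweep(M, 2L, M[i, ])   # NA propagates => pairwise complete
            d <- if (measure == "man") rowSums(abs(D), na.rm = TRUE)
                 else sqrt(rowSums(D * D, na.rm = TRUE))
            W[i, ] <- ifelse(d == 0, Inf, 1 / d)
        }
    } else {                             # mrc: per-pair medians over overlap
        W <- matrix(NA_real_, n, n)
        for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
            keep <- O[i, ] & O[j, ]
            if (sum(keep) < 2L) next
            W[i, j] <- W[j, i] <- .simValue(M[i, keep], M[j, keep], "mrc")
        }
    }
    W[Nov < min_overlap] <- NA_real_
    diag(W) <- NA_real_
    dimnames(W) <- list(ids, ids)
    W
}

#' Resolve infinite distance-based weights
#'
#' When two samples coincide on every compared feature, the inverse-distance
#' weight is infinite; such sentinels are replaced by the highest similarity
#' computed as a real number.  By default the maximum is taken over the
#' whole matrix; `scope = "row"` uses, for each infinite cell, the larger of
#' the two row maxima (preserving symmetry).
#'
#' @param W similarity matrix from [similarityMatrix()].
#' @param scope `"matrix"` (default) or `"row"`.
#' @return the matrix with all infinities replaced.
#' @export
resolveInfinite <- function(W, scope = c("matrix", "row")) {
    scope <- match.arg(scope)
    inf <- is.infinite(W)
    if (!any(inf)) return(W)
    fin <- W[is.finite(W)]
    if (!length(fin))
        stop("degenerate cohort: all pairwise similarities are infinite")
    if (scope == "matrix") {
        W[inf] <- max(fin)
    } else {
        rowMax <- apply(W, 1L, function(r) {
            f <- r[is.finite(r)]
            if (length(f)) max(f) else NA_real_
        })
        idx <- which(inf, arr.ind = TRUE)
        repl <- pmax(rowMax[idx[, 1L]], rowMax[idx[, 2L]], na.rm = TRUE)
        repl[is.na(repl)] <- max(fin)
        W[inf] <- repl
    }
    W
}
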