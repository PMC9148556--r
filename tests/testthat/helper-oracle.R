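# Independent brute-force oracles: direct transliterations of the printed
# similarity, prediction and metric formulas, written with plain loops and
# kept free of any package internals.

oracle_sim <- function(x, y, measure) {
    n <- length(x)
    switch(measure,
        pcc = {
            mx <- mean(x); my <- mean(y)      # the formula's x-bar, y-bar
            num <- 0; dx2 <- 0; dy2 <- 0
            for (i in seq_len(n)) {
                num <- num + (x[i] - mx) * (y[i] - my)
                dx2 <- dx2 + (x[i] - mx)^2
                dy2 <- dy2 + (y[i] - my)^2
            }
            num / (sqrt(dx2) * sqrt(dy2))
        },
        mrc = {
            mx <- median(x); my <- median(y)  # the formula's x-tilde, y-tilde
            num <- 0; dx2 <- 0; dy2 <- 0
            for (i in seq_len(n)) {
                num <- num + (x[i] - mx) * (y[i] - my)
                dx2 <- dx2 + (x[i] - mx)^2
                dy2 <- dy2 + (y[i] - my)^2
            }
            num / (sqrt(dx2) * sqrt(dy2))
        },
        cos = {
            num <- 0; dx2 <- 0; dy2 <- 0
            for (i in seq_len(n)) {
                num <- num + x[i] * y[i]
                dx2 <- dx2 + x[i]^2
                dy2 <- dy2 + y[i]^2
            }
            num / (sqrt(dx2) * sqrt(dy2))
        },
        man = {
            s <- 0
            for (i in seq_len(n)) s <- s + abs(x[i] - y[i])
            1 / s
        },
        euc = {
            s <- 0
            for (i in seq_len(n)) s <- s + (x[i] - y[i])^2
            1 / sqrt(s)
        })
}

oracle_metrics <- function(actual, imputed) {
    n <- length(actual)
    mae <- 0; mse <- 0; sst <- 0
    for (i in seq_len(n)) {
        mae <- mae + abs(imputed[i] - actual[i])
        mse <- mse + (imputed[i] - actual[i])^2
        sst <- sst + (mean(actual) - actual[i])^2
    }
    list(mae = mae / n, mse = mse / n, rmse = sqrt(mse / n),
         r_squared = 1 - mse / sst)
}

# Brute-force collaborative-filtering imputation on a small samples x
# features matrix `M` (NA = missing) with score columns `score_cols`:
# recompute every pairwise similarity from scratch, replace infinities by
# the matrix-wide finite maximum, sort (ties by ascending sample id),
# truncate to bnc, weighted-average.  `bncs` may be a vector; the result is
# a list indexed by as.character(bnc) of named prediction lists.
oracle_impute <- function(M, score_cols, measure, bncs, min_overlap = 2) {
    n <- nrow(M)
    ids <- rownames(M)
    preds <- lapply(bncs, function(b) list())
    names(preds) <- as.character(bncs)
    for (cs in score_cols) {
        W <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
        for (i in seq_len(n)) for (j in seq_len(n)) {
            if (i == j) next
            feats <- setdiff(colnames(M), cs)
            xi <- M[i, feats]; yj <- M[j, feats]
            keep <- !is.na(xi) & !is.na(yj)
            if (sum(keep) < min_overlap) next
            xv <- xi[keep]; yv <- yj[keep]
            v <- switch(measure,
                pcc = if (sd(xv) == 0 || sd(yv) == 0) NA_real_
                      else oracle_sim(xv, yv, "pcc"),
                mrc = {
                    dx <- sqrt(sum((xv - median(xv))^2))
                    dy <- sqrt(sum((yv - median(yv))^2))
                    if (dx == 0 || dy == 0) NA_real_
                    else oracle_sim(xv, yv, "mrc")
                },
                cos = if (sqrt(sum(xv^2)) == 0 || sqrt(sum(yv^2)) == 0)
                          NA_real_ else oracle_sim(xv, yv, "cos"),
                man = if (sum(abs(xv - yv)) == 0) Inf
                      else oracle_sim(xv, yv, "man"),
                euc = if (sum((xv - yv)^2) == 0) Inf
                      else oracle_sim(xv, yv, "euc"))
            W[i, j] <- v
        }
        if (any(is.infinite(W), na.rm = TRUE)) {
            fin <- W[is.finite(W)]
            W[!is.na(W) & is.infinite(W)] <- max(fin)
        }
        for (i in which(is.na(M[, cs]))) {
            w <- W[i, ]
            cand <- which(!is.na(M[, cs]) & !is.na(w))
            cand <- setdiff(cand, i)
            if (!length(cand)) next
            o <- cand[order(-w[cand], ids[cand], method = "radix")]
            for (b in bncs) {
                top <- o[seq_len(min(b, length(o)))]
                ws <- w[top]; ys <- M[top, cs]
                p <- if (abs(sum(ws)) < 1e-12) mean(ys)
                     else sum(ys * ws) / sum(ws)
                preds[[as.character(b)]][[paste(cs, ids[i])]] <- p
            }
        }
    }
    if (length(bncs) == 1L) preds[[1L]] else preds
}
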