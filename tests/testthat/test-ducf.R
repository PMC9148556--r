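# cohort where weights to target "t" are controlled exactly via one feature
neighbor_fixture <- function() {
    ## MAN similarity on the single Struct column gives weights
    ## 1/|x_t - x_j|; Struct values chosen for weights A:10, B:2, C:1, D:2
    m <- rbind(t = c(0.5,  NA),
               A = c(0.6,  0.2),
               B = c(1.0,  0.4),
               C = c(1.5,  0.6),
               D = c(0.0,  0.8))
    colnames(m) <- c("Struct01_area", "MMSE")
    toy_cohort(m)
}

test_that("neighbour selection takes top-BNC by weight with id tie-breaks", {
    coh <- neighbor_fixture()
    W <- similarityMatrix(coh, "man", features = "Struct01_area",
                          min_overlap = 1)
    ns <- selectNeighbors("t", "MMSE", W, coh, bnc = 2)
    expect_identical(ns$ids, c("A", "B"))     # 10 > 2 = 2 > 1; tie B/D -> B
    expect_equal(ns$weights, c(10, 2))
    ns3 <- selectNeighbors("t", "MMSE", W, coh, bnc = 3)
    expect_identical(ns3$ids, c("A", "B", "D"))  # ascending id within tie
    ## bnc beyond the candidate pool returns everyone
    all4 <- selectNeighbors("t", "MMSE", W, coh, bnc = 100)
    expect_identical(all4$ids, c("A", "B", "D", "C"))
    ## candidates must have the score observed
    coh2 <- neighbor_fixture()
    coh2 <- ducf:::.maskCells(coh2, "MMSE", c("A", "B", "C", "D"))
    expect_error(selectNeighbors("t", "MMSE", W, coh2, 2), "no candidate")
})

test_that("the weighted-average prediction follows the printed formula", {
    ns <- structure(list(target = "t", score_type = "MMSE",
                         ids = c("A", "B"), weights = c(3, 1),
                         scores = c(1, 0), bnc = 2L), class = "NeighborSet")
    expect_equal(predictScore(ns)$value, 0.75)
    ns$ids <- "A"; ns$weights <- 7; ns$scores <- 0.42
    expect_equal(predictScore(ns)$value, 0.42)    # single neighbour
    ns$ids <- c("A", "B", "C"); ns$weights <- c(2, 2, 2)
    ns$scores <- c(0.2, 0.4, 0.6)
    expect_equal(predictScore(ns)$value, 0.4)     # equal weights: plain mean
    ## cancelling signed weights fall back to the unweighted mean
    ns$weights <- c(1, -1, 1e-14)
    p <- predictScore(ns)
    expect_true(p$fallback)
    expect_equal(p$value, 0.4)
    ## absolute-denominator variant
    ns$weights <- c(1, -1, 2)
    expect_equal(predictScore(ns, denominator = "absolute")$value,
                 (0.2 - 0.4 + 2 * 0.6) / 4)
})

test_that("imputation fills exactly the missing score cells", {
    coh <- neighbor_fixture()
    fit <- imputeScores(coh, "man", bnc = 2, min_overlap = 1)
    expect_equal(nrow(fit$predictions), 1L)
    expect_equal(sum(imputedMask(fit$cohort)), 1L)
    v <- featureValues(fit$cohort)
    expect_equal(v["MMSE", "t"], fit$predictions$value, ignore_attr = TRUE)
    ## observed cells untouched
    keep <- observedMask(coh)
    expect_identical(v[keep], featureValues(coh)[keep])
    ## no missing cells: identity with empty prediction list
    full <- toy_cohort(cbind(Struct01_area = c(1, 2, 3),
                             MMSE = c(20, 22, 24)))
    fit0 <- imputeScores(full, "man", 2)
    expect_identical(featureValues(fit0$cohort), featureValues(full))
    expect_equal(nrow(fit0$predictions), 0L)
    ## all potential neighbours missing the score: recorded failure
    lone <- toy_cohort(cbind(Struct01_area = c(1, 2, 3),
                             MMSE = c(NA, NA, NA)))
    fitf <- imputeScores(lone, "man", 2)
    expect_equal(nrow(fitf$failures), 3L)
    expect_equal(nrow(fitf$predictions), 0L)
})

test_that("imputation matches the brute-force oracle on random small cohorts", {
    set.seed(500)
    for (rep in 1:25) {
        n <- sample(6:12, 1)
        M <- random_small_matrix(n, sample(4:7, 1),
                                 n_scores = sample(1:2, 1), n_miss = 2)
        coh <- toy_cohort(M)
        for (meas in c("pcc", "cos", "man")) {
            bnc <- sample(1:8, 1)
            fit <- imputeScores(coh, meas, bnc)
            want <- oracle_impute(M, clinicalScores(coh), meas, bnc)
            got <- setNames(fit$predictions$value,
                            paste(fit$predictions$score_type,
                                  fit$predictions$sample))
            expect_equal(sort(names(got)), sort(names(want)))
            for (k in names(want))
                expect_equal(got[[k]], want[[k]], tolerance = 1e-10)
        }
    }
})

test_that("predictions are convex combinations under positive weights", {
    set.seed(42)
    for (rep in 1:20) {
        M <- random_small_matrix(10, 5, n_miss = 3)
        coh <- toy_cohort(M)
        for (meas in c("man", "euc", "cos")) {   # positive-weight measures
            fit <- imputeScores(coh, meas, bnc = 4)
            obs <- M[!is.na(M[, "MMSE"]), "MMSE"]
            expect_true(all(fit$predictions$value >= min(obs) - 1e-12))
            expect_true(all(fit$predictions$value <= max(obs) + 1e-12))
        }
    }
})

test_that("shuffling sample order changes no prediction", {
    set.seed(77)
    M <- random_small_matrix(12, 6, n_scores = 2, n_miss = 3)
    coh <- toy_cohort(M)
    perm <- sample(nrow(M))
    cohP <- toy_cohort(M[perm, ])
    for (meas in c("man", "pcc")) {
        a <- imputeScores(coh, meas, 3)$predictions
        b <- imputeScores(cohP, meas, 3)$predictions
        a <- a[order(a$score_type, a$sample), ]
        b <- b[order(b$score_type, b$sample), ]
        expect_equal(a$sample, b$sample)
        expect_equal(a$value, b$value, tolerance = 1e-12)
    }
})

test_that("with all candidates and constant weights the prediction is the attribute mean", {
    ## samples equidistant from the target in the similarity feature
    m <- rbind(t = c(0.5, NA),
               A = c(0.4, 0.2),
               B = c(0.6, 0.5),
               C = c(0.4, 0.8))
    colnames(m) <- c("Struct01_area", "MMSE")
    fit <- imputeScores(toy_cohort(m), "man", bnc = 3, min_overlap = 1)
    expect_equal(fit$predictions$value, mean(c(0.2, 0.5, 0.8)))
})
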