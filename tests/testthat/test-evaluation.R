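test_that("masking plans hit the requested cell counts and are reproducible", {
    coh <- simulateCohort(n_samples = 10, n_morphometrics = 10,
                          missing_frac = 0, seed = 3)
    two <- coh[featureSpecs(coh)$role != "clinical_score" |
               rownames(coh) %in% c("MMSE", "GDS"), ]
    plan <- makeMaskingPlan(two, k = 4, seed = 99)
    expect_equal(sum(lengths(plan$cells)), 8L)          # 2 scores x 4
    expect_identical(makeMaskingPlan(two, 4, 99)$cells, plan$cells)
    expect_false(identical(makeMaskingPlan(two, 4, 100)$cells, plan$cells))
    ## masked cells were all observed, and applying the plan hides them
    masked <- applyMaskingPlan(two, plan)
    expect_equal(nrow(masked$actual), 8L)
    expect_true(all(!is.na(masked$actual$value)))
    for (cs in names(plan$cells))
        expect_true(all(!observedMask(masked$cohort)[cs, plan$cells[[cs]]]))
})

test_that("the protocol at cohort scale yields 250 cells per score (750 pairs, df 749)", {
    coh <- simulateCohort(n_samples = 300, n_morphometrics = 10,
                          missing_frac = 0, seed = 8)
    three <- coh[featureSpecs(coh)$role != "clinical_score" |
                 rownames(coh) %in% c("MMSE", "GDS", "CDR"), ]
    plan <- makeMaskingPlan(three, k = 250, seed = 1)
    expect_identical(unname(lengths(plan$cells)), c(250L, 250L, 250L))
    expect_equal(sum(lengths(plan$cells)), 750L)
    masked <- applyMaskingPlan(three, plan)
    stats <- compareActualImputed(masked$actual$value,
                                  masked$actual$value +
                                  rnorm(750, 0, 1e-3))
    expect_equal(stats$df, 749L)
})

test_that("error metrics follow the printed formulas", {
    m <- imputationMetrics(c(0, 0), c(1, 1))
    expect_equal(m$mae, 1); expect_equal(m$mse, 1); expect_equal(m$rmse, 1)
    perfect <- imputationMetrics(c(1, 2, 3), c(1, 2, 3))
    expect_equal(perfect$mae, 0)
    expect_equal(perfect$r_squared, 1)
    expect_equal(imputationMetrics(c(0, 0), c(3, 4))$rmse, sqrt(12.5))
    ## zero variance in the actual values: R^2 undefined
    expect_true(is.na(imputationMetrics(c(2, 2), c(1, 3))$r_squared))
    ## random-vector agreement with the transliterated formulas
    set.seed(55)
    for (rep in 1:25) {
        n <- sample(3:30, 1)
        a <- runif(n); b <- runif(n)
        got <- imputationMetrics(a, b)
        want <- oracle_metrics(a, b)
        for (f in c("mae", "mse", "rmse", "r_squared"))
            expect_equal(got[[f]], want[[f]], tolerance = 1e-12)
        expect_lte(got$mae, got$rmse + 1e-12)
        expect_equal(got$rmse, sqrt(got$mse), tolerance = 1e-12)
    }
})

test_that("doubling every error doubles MAE and RMSE", {
    a <- runif(20); e <- rnorm(20, 0, 0.2)
    m1 <- imputationMetrics(a, a + e)
    m2 <- imputationMetrics(a, a + 2 * e)
    expect_equal(m2$mae, 2 * m1$mae)
    expect_equal(m2$rmse, 2 * m1$rmse)
})

test_that("actual-vs-imputed comparison reports r, paired t and df", {
    a <- c(1, 2, 3, 4, 5)
    same <- compareActualImputed(a, a + 0)
    expect_equal(same$pearson_r, 1)
    ## identical pairs: zero-variance differences are flagged, not crashed
    expect_true(same$degenerate)
    sym <- compareActualImputed(c(2, 1, 2, 1), c(1, 2, 1, 2))
    expect_equal(sym$t_statistic, 0, tolerance = 1e-12)  # d = (+1,-1,+1,-1)
    expect_equal(sym$df, 3L)
    const <- compareActualImputed(c(2, 3, 4, 5), c(1, 2, 3, 4))
    expect_true(const$degenerate)                        # d = (1,1,1,1)
    ## against the textbook formula on random data
    set.seed(12)
    x <- rnorm(30); y <- x + rnorm(30, 0, 0.5)
    got <- compareActualImputed(x, y)
    d <- x - y
    expect_equal(got$t_statistic, mean(d) / (sd(d) / sqrt(30)),
                 tolerance = 1e-12)
    expect_equal(got$pearson_r, cor(x, y))
})

test_that("rank-sum ordering combines the three printed metrics", {
    reports <- data.frame(
        config = c("A", "B"),
        mae = c(0.06, 0.07), rmse = c(0.10, 0.09),
        r_squared = c(0.90, 0.92))
    ranked <- rankConfigs(reports)
    expect_identical(ranked$config, c("B", "A"))     # sums 4 vs 5
    expect_equal(ranked$rank_sum, c(4, 5))
    ## single report is itself; identical reports keep input order
    expect_equal(nrow(rankConfigs(reports[1, ])), 1L)
    same <- data.frame(config = c("x", "y"), mae = 0.1, rmse = 0.2,
                       r_squared = 0.5)
    expect_identical(rankConfigs(same)$config, c("x", "y"))
    ## invalid R^2 ranks last, with a warning
    inv <- data.frame(config = c("good", "bad"), mae = c(0.2, 0.1),
                      rmse = c(0.3, 0.2), r_squared = c(0.5, NA))
    expect_warning(rk <- rankConfigs(inv), "invalid R-squared")
    expect_equal(rk$rank_r2[rk$config == "bad"], 2)
})

test_that("uniform error scaling leaves the rank ordering unchanged", {
    set.seed(4)
    reports <- data.frame(mae = runif(5), rmse = NA, r_squared = runif(5))
    reports$rmse <- reports$mae * runif(5, 1, 1.5)
    doubled <- reports
    doubled$mae <- 2 * doubled$mae; doubled$rmse <- 2 * doubled$rmse
    expect_identical(rownames(rankConfigs(reports)),
                     rownames(rankConfigs(doubled)))
})

test_that("the experiment harness accounts cells and is deterministic", {
    coh <- simulateCohort(n_samples = 24, n_morphometrics = 14,
                          missing_frac = 0, seed = 6)
    norm <- preprocessCohort(coh)
    cfg <- experimentConfigs(ducf = list(measures = "man",
                                         feature_forms = "hybrid",
                                         bnc = c(2, 4)),
                             baselines = "mean")
    res <- runExperiment(norm, cfg, k = 5, n_repeats = 2, base_seed = 42)
    expect_equal(nrow(res), 3L)
    ## 5 scores x k=5 x 2 repeats
    expect_equal(res$n_cells, rep(50L, 3))
    expect_equal(res$n_failures, rep(0L, 3))
    res2 <- runExperiment(norm, cfg, k = 5, n_repeats = 2, base_seed = 42)
    expect_identical(res, res2)
})

test_that("neighbourhood structure beats the attribute mean on clustered cohorts", {
    coh <- simulateCohort(n_samples = 60, n_morphometrics = 20,
                          missing_frac = 0, seed = 13)
    norm <- preprocessCohort(coh)
    cfg <- experimentConfigs(ducf = list(measures = "man",
                                         feature_forms = "hybrid",
                                         bnc = 4),
                             baselines = "mean")
    res <- runExperiment(norm, cfg, k = 10, n_repeats = 5, base_seed = 7)
    expect_lt(res$mae[res$technique == "ducf"],
              res$mae[res$technique == "mean"])
})
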