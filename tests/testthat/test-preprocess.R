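make_hemi_cohort <- function() {
    m <- matrix(c(2, 4, 1, 28,
                  6, NA, 2, 22,
                  NA, NA, 3, 25), 3, 4, byrow = TRUE,
                dimnames = list(c("a", "b", "c"),
                                c("Left-Hip_volumemm3", "Right-Hip_volumemm3",
                                  "Struct01_area", "MMSE")))
    toy_cohort(m)
}

test_that("hemisphere averaging merges pairs and falls back to the observed side", {
    coh <- averageHemispheres(make_hemi_cohort())
    expect_true("Hip_volumemm3" %in% rownames(coh))
    expect_false(any(c("Left-Hip_volumemm3", "Right-Hip_volumemm3") %in%
                     rownames(coh)))
    v <- featureValues(coh)["Hip_volumemm3", ]
    expect_equal(unname(v), c(3, 6, NA))          # mean; one-sided; both gone
    expect_identical(unname(observedMask(coh)["Hip_volumemm3", ]),
                     c(TRUE, TRUE, FALSE))
    specs <- featureSpecs(coh)
    expect_equal(specs$hemisphere[specs$name == "Hip_volumemm3"], "bilateral")
})

test_that("hemisphere averaging halves paired features and is identity without pairs", {
    coh <- simulateCohort(n_samples = 10, n_morphometrics = 30, seed = 2)
    hemi <- featureSpecs(coh)$hemisphere
    n_pairs <- sum(hemi == "left")
    merged <- averageHemispheres(coh)
    expect_equal(nrow(merged), nrow(coh) - n_pairs)
    expect_false(any(featureSpecs(merged)$hemisphere %in% c("left", "right")))
    unpaired <- coh[featureSpecs(coh)$hemisphere != "right" &
                    featureSpecs(coh)$hemisphere != "left", ]
    expect_identical(featureValues(averageHemispheres(unpaired)),
                     featureValues(unpaired))
})

test_that("keyword selection keeps the chosen classes plus non-morphometrics", {
    m <- matrix(runif(21), 3, 7,
                dimnames = list(NULL, c("A_volumemm3", "B_volumemm3",
                                        "C_volumemm3", "D_area", "E_area",
                                        "age", "MMSE")))
    coh <- toy_cohort(m)
    vol <- selectMorphometrics(coh, "volumemm3")
    expect_identical(rownames(vol),
                     c("A_volumemm3", "B_volumemm3", "C_volumemm3",
                       "age", "MMSE"))
    expect_identical(rownames(selectMorphometrics(coh)), rownames(coh))
    none <- selectMorphometrics(coh, character(0))
    expect_identical(rownames(none), c("age", "MMSE"))
    expect_error(selectMorphometrics(coh, "volume"), "unknown keyword")
})

test_that("normalisation applies reference division then min-max", {
    m <- matrix(c(100, 1000, 5, 19,
                  400, 2000, 0, 30,
                  150, 1000, 10, 8), 3, 4, byrow = TRUE,
                dimnames = list(NULL,
                                c("A_volumemm3",
                                  "EstimatedTotalIntraCranialVol_general",
                                  "B_area", "MMSE")))
    coh <- toy_cohort(m)
    norm <- normalizeCohort(coh)
    expect_false("EstimatedTotalIntraCranialVol_general" %in% rownames(norm))
    # ratios (0.1, 0.2, 0.15) -> min-max (0, 1, 0.5)
    expect_equal(unname(featureValues(norm)["A_volumemm3", ]), c(0, 1, 0.5))
    # plain min-max midpoint
    expect_equal(unname(featureValues(norm)["B_area", ]), c(0.5, 0, 1))
    # MMSE 19 on observed range [8, 30] -> 0.5
    expect_equal(unname(featureValues(norm)["MMSE", ]), c(0.5, 1, 0))
    expect_true(isNormalized(norm))
})

test_that("normalisation flags constant columns and rejects bad references", {
    m <- matrix(c(1, 1, 2, 5, 3, 9), 3, 2,
                dimnames = list(NULL, c("A_area", "B_area")))
    m[, "A_area"] <- 7
    expect_warning(norm <- normalizeCohort(toy_cohort(m)), "constant column")
    expect_equal(unname(featureValues(norm)["A_area", ]), c(0, 0, 0))
    m2 <- matrix(c(10, 0, 20, 1000), 2, 2,
                 dimnames = list(NULL,
                                 c("A_volumemm3",
                                   "EstimatedTotalIntraCranialVol_general")))
    m2[1, 2] <- 0
    expect_error(normalizeCohort(toy_cohort(m2)), "reference value")
})

test_that("observed non-nominal cells lie in [0,1] after the pipeline and min-max is idempotent", {
    coh <- simulateCohort(n_samples = 25, n_morphometrics = 20,
                          missing_frac = 0.1, seed = 9)
    norm <- preprocessCohort(coh)
    rd <- featureSpecs(norm)
    v <- featureValues(norm)[!rd$nominal, ]
    v <- v[!is.na(v)]
    expect_true(all(v >= -1e-12 & v <= 1 + 1e-12))
    ## re-applying plain min-max changes nothing
    mm <- norm[featureSpecs(norm)$role == "morphometric", ]
    again <- normalizeCohort(mm, drop_references = FALSE)
    expect_equal(featureValues(again), featureValues(mm), tolerance = 1e-12)
})

test_that("anomaly filtering drops over-missing columns and rows", {
    m <- matrix(runif(40), 10, 4,
                dimnames = list(sprintf("s%02d", 1:10),
                                c("A_area", "B_area", "C_area", "MMSE")))
    m[, "B_area"] <- NA                      # 100% missing column
    m[1, c("A_area", "C_area")] <- NA        # row 1: 2/2 missing among kept
    coh <- toy_cohort(m)
    res <- filterAnomalies(coh, row_missing_frac = 0.5,
                           col_missing_frac = 0.5, zero_variance = FALSE)
    expect_identical(res$report$dropped_features, "B_area")
    expect_identical(res$report$dropped_samples, "s01")
    expect_equal(ncol(res$cohort), 9L)
    ## permissive thresholds drop nothing
    res2 <- filterAnomalies(coh, 1, 1, zero_variance = FALSE)
    expect_identical(dim(res2$cohort), dim(coh))
    ## zero-variance morphometrics go when asked
    m2 <- m; m2[, "B_area"] <- 3
    res3 <- filterAnomalies(toy_cohort(m2), 1, 1, zero_variance = TRUE)
    expect_identical(res3$report$dropped_features, "B_area")
})
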