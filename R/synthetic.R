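#' Simulate a screening cohort with neighbourhood structure
#'
#' Generates a raw (unnormalised) cohort whose statistical structure matches
#' the premise of user-based collaborative filtering: patients fall into
#' latent severity clusters; morphometrics are cluster centroids with
#' multiplicative jitter, tagged with the eight FreeSurfer-stats keyword
#' classes, including left/right pairs and the two reference volumes
#' (intracranial volume and total gray volume) that the volume and
#' gray-volume features are proportional to; demographics are sex, age and
#' two apoE allele codes; each clinical score is a deterministic
#' cluster-level value plus Gaussian noise, clipped to its instrument range
#' and (by default) snapped to the instrument's grid (integers; half points
#' for CDR).  A fraction of each score column is masked at random; the
#' complete ground truth is retained in `metadata()`.
#'
#' The default dimensions mirror a screening cohort at one-eighth scale:
#' 102 samples, 74 morphometric features, 5 clusters.
#'
#' @param n_samples number of patients.
#' @param n_morphometrics number of morphometric features (including the
#'   two reference volumes).
#' @param n_clusters number of latent severity clusters.
#' @param score_schemas schema table for the clinical scores.
#' @param noise_sd per-score Gaussian noise in test points; default 5% of
#'   each instrument range.
#' @param missing_frac fraction of each score column masked at random.
#' @param jitter_cv within-cluster coefficient of variation of the
#'   morphometrics.
#' @param separation ratio of between-cluster to within-cluster spread.
#' @param severity_cor correlation between a patient's within-cluster
#'   severity gradient (which drives the morphometric jitter) and the
#'   score noise: patients more atrophied than their cluster's centre also
#'   score slightly worse, the premise that makes the nearest neighbours
#'   more informative than the cluster at large.  0 makes score noise
#'   independent of the morphometrics.
#' @param discretize snap scores to the instrument grid?
#' @param seed integer seed; the cohort is bit-reproducible from it.
#' @return a [DementiaCohort-class]; `metadata()` carries `groundTruth`
#'   (scores-by-samples matrix in test points, complete), `clusters`
#'   (integer cluster per sample) and `simSpec` (the arguments used).
#' @examples
#' coh <- simulateCohort(n_samples = 40, n_morphometrics = 30, seed = 7)
#' coh
#' @export
simulateCohort <- function(n_samples = 102L, n_morphometrics = 74L,
                           n_clusters = 5L,
                           score_schemas = defaultScoreSchemas(),
                           noise_sd = NULL, missing_frac = 0.05,
                           jitter_cv = 0.03, separation = 3,
                           severity_cor = 0.8, discretize = TRUE,
                           seed = 1L) {
    if (n_clusters < 1L) stop("n_clusters must be >= 1")
    if (n_clusters > n_samples)
        stop("infeasible spec: n_clusters > n_samples")
    if (n_morphometrics < 6L)
        stop("need at least 6 morphometric features")
    if (any(missing_frac < 0) || any(missing_frac >= 1))
        stop("missing_frac must lie in [0, 1)")
    width <- score_schemas$instrument_max - score_schemas$instrument_min
    if (is.null(noise_sd)) noise_sd <- 0.05 * width
    noise_sd <- rep_len(noise_sd, nrow(score_schemas))
    if (any(noise_sd < 0)) stop("noise_sd must be >= 0")
    stopifnot(severity_cor >= 0, severity_cor <= 1)
    missing_frac <- rep_len(missing_frac, nrow(score_schemas))
    .withSeed(seed, .simulateCohortImpl(
        n_samples, n_morphometrics, n_clusters, score_schemas, noise_sd,
        missing_frac, jitter_cv, separation, severity_cor, discretize,
        seed))
}

.simulateCohortImpl <- function(n, m, G, schemas, noise_sd, missing_frac,
                                jitter_cv, separation, severity_cor,
                                discretize, seed) {
    cluster <- sort(rep_len(seq_len(G), n))[sample.int(n)]
    sev <- if (G > 1) (cluster - 1) / (G - 1) else rep(0, n)
    u <- stats::rnorm(n)                 # within-cluster severity gradient
    ids <- sprintf("S%03d", seq_len(n))

    ## ---- morphometrics ---------------------------------------------------
    nPairs <- floor((m - 2) * 0.42)
    nSingle <- m - 2L - 2L * nPairs
    pairKw <- rep_len(c("volumemm3", "area", "thickavg", "grayvol",
                        "nvoxels", "numvert", "nvertices", "volumemm3",
                        "grayvol", "area"), nPairs)
    singleKw <- rep_len(c("general", "volumemm3", "area", "thickavg",
                          "nvoxels"), nSingle)
    icv <- stats::rnorm(n, 1.5e6, 1.2e5)
    tgv <- (6.5e5 - 4e4 * sev) * (1 + stats::rnorm(n, 0, 0.04))
    baseScale <- function(kw) switch(kw,
        volumemm3 = stats::runif(1, 5e-4, 1e-2),     # ratio to ICV
        grayvol   = stats::runif(1, 5e-3, 5e-2),     # ratio to total gray
        area      = stats::runif(1, 300, 3000),
        thickavg  = stats::runif(1, 1.8, 3.2),
        nvoxels   = stats::runif(1, 500, 2e4),
        numvert   = stats::runif(1, 800, 1.5e4),
        nvertices = stats::runif(1, 800, 1.5e4),
        general   = stats::runif(1, 0.2, 1.5))
    featVal <- function(kw, delta) {
        ## delta: per-cluster multiplicative offsets, one per sample; the
        ## jitter loads partly on the shared severity gradient u
        w <- stats::runif(1, 0.5, 0.9)
        z <- w * u + sqrt(1 - w^2) * stats::rnorm(n)
        v <- (1 + delta) * (1 + jitter_cv * z)
        switch(kw,
               volumemm3 = v * icv,
               grayvol   = v * tgv,
               v)
    }
    cols <- list(); specsName <- character(0)
    for (p in seq_len(nPairs)) {
        kw <- pairKw[p]
        sc <- baseScale(kw)
        deltaG <- stats::rnorm(G, 0, separation * jitter_cv)
        asym <- stats::runif(1, 0, 0.04)
        lv <- sc * (1 + asym / 2) * featVal(kw, deltaG[cluster])
        rv <- sc * (1 - asym / 2) * featVal(kw, deltaG[cluster])
        cols[[sprintf("Left-Region%02d_%s", p, kw)]] <- lv
        cols[[sprintf("Right-Region%02d_%s", p, kw)]] <- rv
    }
    for (s in seq_len(nSingle)) {
        kw <- singleKw[s]
        sc <- baseScale(kw)
        deltaG <- stats::rnorm(G, 0, separation * jitter_cv)
        cols[[sprintf("Struct%02d_%s", s, kw)]] <-
            sc * featVal(kw, deltaG[cluster])
    }
    cols[["EstimatedTotalIntraCranialVol_general"]] <- icv
    cols[["TotalGrayVol_general"]] <- tgv

    ## ---- demographics ----------------------------------------------------
    cols[["age"]] <- round(68 + 8 * sev + stats::rnorm(n, 0, 4), 1)
    cols[["sex"]] <- stats::rbinom(n, 1, 0.5)
    p4 <- 0.15 + 0.25 * sev
    drawApoe <- function() vapply(seq_len(n), function(i)
        sample(c(2, 3, 4), 1L,
               prob = c(0.08, 1 - 0.08 - p4[i], p4[i])), numeric(1))
    cols[["apoE_A1"]] <- drawApoe()
    cols[["apoE_A2"]] <- drawApoe()

    ## ---- clinical scores -------------------------------------------------
    nS <- nrow(schemas)
    baseLo <- c(MMSE = 29, GDS = 1, CDR = 0, NIQ = 1, FAQ = 1)
    baseHi <- c(MMSE = 12, GDS = 10, CDR = 2, NIQ = 21, FAQ = 25)
    truth <- matrix(NA_real_, nS, n, dimnames = list(schemas$name, ids))
    for (si in seq_len(nS)) {
        nm <- schemas$name[si]
        lo <- if (nm %in% names(baseLo)) baseLo[[nm]] else schemas$observed_min[si]
        hi <- if (nm %in% names(baseHi)) baseHi[[nm]] else schemas$observed_max[si]
        eps <- noise_sd[si] * (severity_cor * u +
                               sqrt(1 - severity_cor^2) * stats::rnorm(n))
        val <- lo + (hi - lo) * sev + eps
        ## clip to the observed range (a subset of the instrument range):
        ## the schema's observed range is, by construction, what screening
        ## cohorts contain, and it is also the scale normalisation uses
        val <- pmin(pmax(val, schemas$observed_min[si]),
                    schemas$observed_max[si])
        if (discretize) {
            step <- if (nm == "CDR") 0.5 else 1
            val <- round(val / step) * step
        }
        truth[si, ] <- val
        cols[[nm]] <- val
    }

    values <- do.call(cbind, cols)
    rownames(values) <- ids
    coh <- DementiaCohort(values, scoreSchemas = schemas, sampleIds = ids)

    ## ---- score missingness ----------------------------------------------
    for (si in seq_len(nS)) {
        if (missing_frac[si] <= 0) next
        nm <- schemas$name[si]
        hide <- which(stats::runif(n) < missing_frac[si])
        if (length(hide)) coh <- .maskCells(coh, nm, ids[hide])
    }
    S4Vectors::metadata(coh)$groundTruth <- truth
    S4Vectors::metadata(coh)$clusters <- stats::setNames(cluster, ids)
    S4Vectors::metadata(coh)$simSpec <-
        list(n_samples = n, n_morphometrics = m, n_clusters = G,
             noise_sd = noise_sd, missing_frac = missing_frac,
             jitter_cv = jitter_cv, separation = separation,
             severity_cor = severity_cor, discretize = discretize,
             seed = seed)
    coh
}

#' Simulate a low-rank cohort (a favourable regime for matrix completion)
#'
#' Generates an already-normalised cohort whose feature matrix is a rank-`r`
#' product plus Gaussian noise, with no cluster structure -- the regime
#' where low-rank matrix completion, rather than neighbourhood averaging,
#' is the natural imputer.  Features and normalised clinical scores are all
#' linear in the same latent factors.
#'
#' @param n_samples,n_features cohort dimensions (features beyond the five
#'   clinical scores are tagged morphometric/general).
#' @param rank latent dimension.
#' @param noise_sd additive Gaussian noise on the \[0, 1\] scale.
#' @param missing_frac fraction of each score column masked.
#' @param seed integer seed.
#' @return a normalised [DementiaCohort-class] with `groundTruth` (in
#'   normalised units) in `metadata()`.
#' @export
simulateLowRankCohort <- function(n_samples = 60L, n_features = 30L,
                                  rank = 3L, noise_sd = 0.02,
                                  missing_frac = 0.1, seed = 1L) {
    schemas <- defaultScoreSchemas()
    .withSeed(seed, {
        n <- n_samples; p <- n_features + nrow(schemas)
        U <- matrix(stats::rnorm(n * rank), n, rank)
        V <- matrix(stats::rnorm(p * rank), p, rank)
        X <- U %*% t(V)
        X <- X + stats::rnorm(length(X), 0, noise_sd)
        X <- apply(X, 2L, function(col) (col - min(col)) /
                                        (max(col) - min(col)))
        colnames(X) <- c(sprintf("Factor%02d_general", seq_len(n_features)),
                         schemas$name)
        ids <- sprintf("S%03d", seq_len(n))
        rownames(X) <- ids
        coh <- DementiaCohort(X, scoreSchemas = schemas, sampleIds = ids,
                              normalized = TRUE)
        truth <- featureValues(coh)[schemas$name, , drop = FALSE]
        for (nm in schemas$name) {
            hide <- which(stats::runif(n) < missing_frac)
            if (length(hide)) coh <- .maskCells(coh, nm, ids[hide])
        }
        S4Vectors::metadata(coh)$groundTruth <- truth
        coh
    })
}
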