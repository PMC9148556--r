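# Small in-code fixtures shared across test files.

# samples x features matrix -> DementiaCohort, names inferred
toy_cohort <- function(values, ...) {
    DementiaCohort(as.matrix(values), ...)
}

# random small cohort matrix (samples x features) with morphometric-style
# columns plus `n_scores` score columns carrying `n_miss` missing cells each
random_small_matrix <- function(n, p, n_scores = 1L, n_miss = 1L) {
    score_names <- c("MMSE", "GDS", "CDR", "NIQ", "FAQ")[seq_len(n_scores)]
    M <- matrix(runif(n * (p + n_scores)), n, p + n_scores,
                dimnames = list(sprintf("S%02d", seq_len(n)),
                                c(sprintf("Struct%02d_area", seq_len(p)),
                                  score_names)))
    for (cs in score_names)
        M[sample(n, n_miss), cs] <- NA
    M
}

# write a small csv fixture, returning the path
write_csv_fixture <- function(text) {
    path <- withr::local_tempfile(fileext = ".csv",
                                  .local_envir = parent.frame())
    writeLines(text, path)
    path
}
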