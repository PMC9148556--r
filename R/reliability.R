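#' Absolute error percentage of a prediction against a clinical score
#'
#' \eqn{100 \cdot |score - prediction| / R}, where \eqn{R} is the width of
#' the test's instrument range (e.g. 30 for MMSE on \[0, 30\], 4 for CDR on
#' \[-1, 3\]); reported to two decimals.  Symmetric in score and
#' prediction.
#'
#' @param score,prediction clinical test score and computer-aided
#'   prediction, in test points (vectorised).
#' @param range_r positive range width in test points.
#' @return numeric percentage(s), rounded to two decimals.
#' @examples
#' errorPercentage(20, 22.555, 30)   # 8.52
#' errorPercentage(1, 0.166, 4)      # 20.85
#' @export
errorPercentage <- function(score, prediction, range_r) {
    if (any(range_r <= 0)) stop("range_r must be positive")
    round(100 * abs(score - prediction) / range_r, 2)
}

#' Fit two-sigma reliability thresholds from imputation errors
#'
#' For each clinical test, the trusted and moderate bounds on
#' `|actual - predicted|` (in denormalised test points) are multiples of
#' the standard deviation of the observed imputation errors:
#' `trusted = sigma_multiplier_trusted * sd`, `moderate =
#' sigma_multiplier_moderate * sd`.  The default trusted multiplier of 2
#' is the classical two-sigma rule (about 95% coverage under Gaussian
#' errors); the default moderate multiplier of 2.724 extends the band by
#' the trusted-to-moderate ratio the two-tier scale exhibits.
#'
#' @param errors named list, one numeric vector of errors
#'   (`actual - predicted`, test points) per score type; at least `min_n`
#'   errors each.
#' @param sigma_multiplier_trusted,sigma_multiplier_moderate positive
#'   multipliers, trusted < moderate.
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @param min_n minimum errors per score (default 10).
#' @return object of class `ReliabilityThresholds`: `data.frame` with
#'   columns `score_type`, `trusted`, `moderate`, `n`, `sd`; provenance
#'   (multipliers, sd type) in attributes.
#' @export
fitReliabilityThresholds <- function(errors, sigma_multiplier_trusted = 2,
                                     sigma_multiplier_moderate = 2.724,
                                     sd_type = c("sample", "population"),
                                     min_n = 10L) {
    sd_type <- match.arg(sd_type)
    stopifnot(sigma_multiplier_trusted > 0,
              sigma_multiplier_moderate > sigma_multiplier_trusted)
    rows <- lapply(names(errors), function(cs) {
        e <- errors[[cs]]
        if (length(e) < min_n)
            stop("need at least ", min_n, " errors for '", cs, "', got ",
                 length(e))
        s <- stats::sd(e)
        if (sd_type == "population") s <- s * sqrt((length(e) - 1) / length(e))
        if (!is.finite(s) || s <= 0)
            stop("degenerate errors for '", cs, "': zero spread")
        data.frame(score_type = cs,
                   trusted = sigma_multiplier_trusted * s,
                   moderate = sigma_multiplier_moderate * s,
                   n = length(e), sd = s, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    attr(out, "sigma_multipliers") <- c(trusted = sigma_multiplier_trusted,
                                        moderate = sigma_multiplier_moderate)
    attr(out, "sd_type") <- sd_type
    class(out) <- c("ReliabilityThresholds", "data.frame")
    out
}

#' Build a thresholds table from explicit trusted/moderate bounds
#'
#' Convenience constructor when the bounds are given directly (e.g. a
#' published threshold table) rather than fitted from errors.
#'
#' @param score_type character score names.
#' @param trusted,moderate positive bounds in test points,
#'   `0 < trusted < moderate` per row.
#' @return a `ReliabilityThresholds` object.
#' @export
reliabilityThresholds <- function(score_type, trusted, moderate) {
    stopifnot(all(trusted > 0), all(moderate > trusted))
    out <- data.frame(score_type = score_type, trusted = trusted,
                      moderate = moderate, n = NA_integer_, sd = NA_real_,
                      stringsAsFactors = FALSE)
    attr(out, "sd_type") <- "external"
    class(out) <- c("ReliabilityThresholds", "data.frame")
    out
}

#' Classify clinical scores on the reliability scale
#'
#' With `d = |score - prediction|`: `d <= trusted` is `trusted`,
#' `trusted < d <= moderate` is `moderate`, `d > moderate` is
#' `not_trusted` (the clinical test should be repeated).
#'
#' @param score,prediction clinical score and prediction in test points
#'   (vectorised).
#' @param thresholds a `ReliabilityThresholds` object covering
#'   `score_type`.
#' @param score_type character score name(s), recycled to the input length.
#' @param schemas score schema table used for the error-percentage column
#'   (instrument range); default [defaultScoreSchemas()].
#' @return object of class `ReliabilityVerdict`: `data.frame` with
#'   `score_type`, `clinical`, `predicted`, `abs_error_pct`, `label`.
#' @examples
#' th <- reliabilityThresholds("MMSE", 2.162, 2.945)
#' classifyReliability(28, 27.977, th, "MMSE")$label   # "trusted"
#' @export
classifyReliability <- function(score, prediction, thresholds, score_type,
                                schemas = defaultScoreSchemas()) {
    n <- max(length(score), length(prediction), length(score_type))
    score <- rep_len(score, n); prediction <- rep_len(prediction, n)
    score_type <- rep_len(score_type, n)
    i <- match(score_type, thresholds$score_type)
    if (anyNA(i))
        stop("no thresholds fitted for score type: ",
             paste(unique(score_type[is.na(i)]), collapse = ", "))
    d <- abs(score - prediction)
    label <- ifelse(d <= thresholds$trusted[i], "trusted",
                    ifelse(d <= thresholds$moderate[i], "moderate",
                           "not_trusted"))
    j <- match(toupper(score_type), toupper(schemas$name))
    rng <- schemas$instrument_max[j] - schemas$instrument_min[j]
    pct <- ifelse(is.na(rng), NA_real_,
                  errorPercentage(score, prediction, ifelse(is.na(rng), 1, rng)))
    out <- data.frame(score_type = score_type, clinical = score,
                      predicted = prediction, abs_error_pct = pct,
                      label = label, stringsAsFactors = FALSE)
    class(out) <- c("ReliabilityVerdict", "data.frame")
    out
}

#' Reliability report table
#'
#' Formats verdicts as the standard report: one row per tested score with
#' the test type, its instrument range, the clinical score, the
#' computer-aided prediction, the absolute error percentage and the
#' reliability label.
#'
#' @param verdicts a `ReliabilityVerdict` (rows may be concatenated with
#'   `rbind`).
#' @param schemas score schema table supplying the printed ranges.
#' @return `data.frame` with columns `test_type`, `range`,
#'   `clinical_score`, `prediction`, `abs_error_pct`, `reliability`.
#' @export
reliabilityReport <- function(verdicts, schemas = defaultScoreSchemas()) {
    if (!nrow(verdicts))
        return(data.frame(test_type = character(), range = character(),
                          clinical_score = numeric(), prediction = numeric(),
                          abs_error_pct = numeric(),
                          reliability = character()))
    j <- match(toupper(verdicts$score_type), toupper(schemas$name))
    rng <- sprintf("[%g, %g]", schemas$instrument_min[j],
                   schemas$instrument_max[j])
    data.frame(test_type = verdicts$score_type, range = rng,
               clinical_score = verdicts$clinical,
               prediction = verdicts$predicted,
               abs_error_pct = verdicts$abs_error_pct,
               reliability = sub("not_trusted", "not trusted",
                                 verdicts$label),
               stringsAsFactors = FALSE)
}

#' Denormalise \[0, 1\] score values back to test points
#'
#' Inverse of the score normalisation applied by [normalizeCohort()]
#' (min-max over the schema's observed range).
#'
#' @param value normalised value(s).
#' @param score_type score name(s), recycled.
#' @param schemas score schema table.
#' @return value(s) in test points.
#' @export
denormalizeScore <- function(value, score_type,
                             schemas = defaultScoreSchemas()) {
    j <- match(toupper(score_type), toupper(schemas$name))
    if (anyNA(j)) stop("unknown score type")
    schemas$observed_min[j] + value *
        (schemas$observed_max[j] - schemas$observed_min[j])
}
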