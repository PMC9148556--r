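#' Read a samples-by-features table into a DementiaCohort
#'
#' Reads a delimited text table (CSV or TSV, header row required, one row per
#' sample).  Empty cells, `NA` and `NaN` all count as missing and end up with
#' `observed = FALSE`.  Feature roles, keyword classes and hemispheres are
#' inferred from the header names (see [inferFeatureSpecs()]) unless a
#' sidecar schema written by [writeCohort()] or an explicit `role_map`
#' overrides them.
#'
#' @param path path to the delimited file.
#' @param scoreSchemas score schema table; defaults to [defaultScoreSchemas()].
#' @param role_map optional `data.frame` of feature specs (columns as in
#'   [inferFeatureSpecs()]) overriding inference for the named features.
#' @param id_col name of the sample-id column; when `NULL` a column named
#'   `sample_id` (case-insensitive) is used if present, otherwise the 0-based
#'   row index.
#' @param sep field separator; `NULL` auto-detects between `,` and tab.
#' @param schema_path optional path to a JSON sidecar (as written by
#'   [writeCohort()]) supplying feature specs, score schemas and the
#'   normalisation flag.
#' @return A [DementiaCohort-class].
#' @export
readFeatureTable <- function(path, scoreSchemas = defaultScoreSchemas(),
                             role_map = NULL, id_col = NULL, sep = NULL,
                             schema_path = NULL) {
    if (!file.exists(path)) stop("no such file: ", path)
    if (is.null(sep)) {
        first <- readLines(path, n = 1L)
        sep <- if (grepl("\t", first)) "\t" else ","
    }
    dt <- data.table::fread(path, sep = sep, header = TRUE,
                            na.strings = c("", "NA", "NaN"),
                            colClasses = NULL, data.table = FALSE,
                            keepLeadingZeros = TRUE)
    if (nrow(dt) == 0L) stop("empty table: ", path)
    normalized <- FALSE
    if (!is.null(schema_path)) {
        sc <- jsonlite::read_json(schema_path, simplifyVector = TRUE)
        if (!is.null(sc$featureSpecs)) role_map <- sc$featureSpecs
        if (!is.null(sc$scoreSchemas)) scoreSchemas <- sc$scoreSchemas
        if (!is.null(sc$normalized)) normalized <- isTRUE(sc$normalized)
    }
    if (is.null(id_col)) {
        hit <- which(tolower(names(dt)) %in% c("sample_id", "sampleid", "id"))
        if (length(hit)) id_col <- names(dt)[hit[1L]]
    }
    if (!is.null(id_col)) {
        ids <- as.character(dt[[id_col]])
        dt[[id_col]] <- NULL
    } else ids <- as.character(seq_len(nrow(dt)) - 1L)
    if (anyDuplicated(ids))
        stop("duplicate sample id: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    for (j in seq_along(dt)) {
        col <- dt[[j]]
        if (!is.numeric(col)) {
            suppressWarnings(num <- as.numeric(col))
            bad <- which(!is.na(col) & is.na(num))
            if (length(bad))
                stop(sprintf("non-numeric cell in column '%s', row %d: '%s'",
                             names(dt)[j], bad[1L], col[bad[1L]]))
            dt[[j]] <- num
        }
    }
    values <- as.matrix(dt)
    rownames(values) <- ids
    specs <- inferFeatureSpecs(colnames(values), scoreSchemas)
    if (!is.null(role_map)) {
        i <- match(role_map$name, specs$name)
        ok <- !is.na(i)
        for (col in intersect(colnames(role_map), colnames(specs)))
            specs[[col]][i[ok]] <- role_map[[col]][ok]
    }
    DementiaCohort(values, featureSpecs = specs, scoreSchemas = scoreSchemas,
                   sampleIds = ids, normalized = normalized)
}

#' Write a DementiaCohort to CSV (plus JSON schema sidecar)
#'
#' Writes the samples-by-features table with empty cells at unobserved
#' positions and, optionally, a JSON sidecar carrying the feature specs,
#' score schemas and normalisation flag so that
#' `readFeatureTable(path, schema_path = ...)` round-trips the object
#' exactly.
#'
#' @param x a [DementiaCohort-class].
#' @param path output CSV path.
#' @param schema_path optional JSON sidecar path.
#' @param sep field separator (default comma).
#' @return `path`, invisibly.
#' @export
writeCohort <- function(x, path, schema_path = NULL, sep = ",") {
    v <- t(featureValues(x))             # samples x features
    ## 17 significant digits so finite doubles round-trip bit-exactly
    chr <- apply(v, 2L, function(col)
        ifelse(is.na(col), "", sprintf("%.17g", col)))
    df <- data.frame(sample_id = sampleIds(x), chr, check.names = FALSE,
                     stringsAsFactors = FALSE)
    data.table::fwrite(df, path, sep = sep, na = "", quote = FALSE)
    if (!is.null(schema_path))
        jsonlite::write_json(
            list(featureSpecs = featureSpecs(x),
                 scoreSchemas = scoreSchemas(x),
                 normalized = isNormalized(x)),
            schema_path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}
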