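## Readers and writers for the shared file formats. CSV dialect:
## comma-separated, UTF-8, header row, sequences unquoted. All
## coordinates in outputs are 0-based half-open.

.readCsvChecked <- function(path, required, what) {
    if (!file.exists(path))
        stop("cannot read ", what, " file: ", path, call. = FALSE)
    df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                   error = function(e)
                       stop("malformed ", what, " CSV ", path, ": ",
                            conditionMessage(e), call. = FALSE))
    missing <- setdiff(required, colnames(df))
    if (length(missing))
        stop(what, " CSV ", path, " lacks column(s): ",
             paste(missing, collapse = ", "), call. = FALSE)
    df
}

#' Read a CDR3 table (sample_id, chain, cdr3_aa)
#'
#' Rows with invalid CDR3 sequences raise an error naming the file and
#' line number (header is line 1).
#'
#' @param path CSV path.
#' @param validate check the CDR3 contract per row.
#' @return data.frame with at least `sample_id`, `chain`, `cdr3_aa`.
#' @export
readCdr3Csv <- function(path, validate = TRUE) {
    df <- .readCsvChecked(path, c("sample_id", "chain", "cdr3_aa"), "CDR3")
    if (validate && nrow(df)) {
        bad <- which(!vapply(df$cdr3_aa, isValidCdr3, logical(1)))
        if (length(bad))
            stop("invalid CDR3 '", df$cdr3_aa[bad[1]], "' in ", path,
                 " line ", bad[1] + 1L, call. = FALSE)
    }
    df
}

#' Write a CDR3 table
#' @param cdr3 data.frame as produced by [recoverRepertoire()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeCdr3Csv <- function(cdr3, path) {
    utils::write.csv(cdr3, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read antigens from FASTA or CSV
#'
#' FASTA headers become antigen ids; the CSV layout is two columns
#' `antigen_id`, `sequence`.
#'
#' @param path `.fa`/`.fasta` or `.csv` file.
#' @return named character vector of antigen sequences.
#' @export
readAntigens <- function(path) {
    if (grepl("\\.(fa|fasta)(\\.gz)?$", path, ignore.case = TRUE)) {
        seqs <- Biostrings::readAAStringSet(path)
        if (length(seqs) == 0L)
            stop("no antigens in ", path, call. = FALSE)
        names(seqs) <- sub("\\s.*$", "", names(seqs))
        asAntigenVector(seqs)
    } else {
        df <- .readCsvChecked(path, c("antigen_id", "sequence"), "antigen")
        if (nrow(df) == 0L) stop("no antigens in ", path, call. = FALSE)
        asAntigenVector(df)
    }
}

#' Write antigens to FASTA
#' @param antigens named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAntigensFasta <- function(antigens, path) {
    antigens <- asAntigenVector(antigens)
    x <- Biostrings::AAStringSet(antigens)
    Biostrings::writeXStringSet(x, path)
    invisible(path)
}

#' Read the survival table (sample_id, dfs_months, dfs_event)
#' @param path CSV path.
#' @return data.frame.
#' @export
readSurvivalCsv <- function(path) {
    df <- .readCsvChecked(path, c("sample_id", "dfs_months", "dfs_event"),
                          "survival")
    if (any(df$dfs_months < 0, na.rm = TRUE))
        stop("negative dfs_months in ", path, call. = FALSE)
    if (!all(df$dfs_event %in% c(0L, 1L)))
        stop("dfs_event must be 0/1 in ", path, call. = FALSE)
    df
}

#' Read an expression matrix CSV (sample_id plus one column per gene)
#' @param path CSV path.
#' @return data.frame.
#' @export
readExpressionCsv <- function(path) {
    df <- .readCsvChecked(path, "sample_id", "expression")
    genes <- setdiff(colnames(df), "sample_id")
    for (g in genes)
        if (any(df[[g]] < 0, na.rm = TRUE))
            stop("negative expression for gene ", g, " in ", path,
                 call. = FALSE)
    df
}

#' Read the methylation table (sample_id, beta)
#' @param path CSV path.
#' @return data.frame.
#' @export
readMethylationCsv <- function(path) {
    df <- .readCsvChecked(path, c("sample_id", "beta"), "methylation")
    if (any(df$beta < 0 | df$beta > 1, na.rm = TRUE))
        stop("beta values outside [0, 1] in ", path, call. = FALSE)
    df
}

#' Read the covariates table (sample_id plus named covariate columns)
#' @param path CSV path.
#' @return data.frame.
#' @export
readCovariatesCsv <- function(path) {
    .readCsvChecked(path, "sample_id", "covariates")
}

.reportAsList <- function(report) {
    odds <- report@oddsRatio
    if (length(odds)) odds$table <- as.data.frame.matrix(odds$table)
    list(n_samples = nrow(report@samples),
         groups = as.data.frame(table(report@samples$group)),
         km = report@km,
         cox_univariate = report@coxUnivariate,
         cox_bivariate = report@coxBivariate,
         odds_ratio = odds,
         methylation = report@methylation,
         correlations = report@correlations,
         missing_sections = report@missingSections)
}

#' Write a cohort report to disk
#'
#' Emits `report.json` (machine readable), `report.txt` (the show()
#' rendering) and `km.png` (the two-arm KM plot) under `dir`.
#'
#' @param report a [CohortReport-class].
#' @param dir output directory (created if absent).
#' @return the directory, invisibly.
#' @export
writeCohortReport <- function(report, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(.reportAsList(report),
                         file.path(dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
    txt <- utils::capture.output(show(report))
    writeLines(txt, file.path(dir, "report.txt"))
    grDevices::png(file.path(dir, "km.png"), width = 700, height = 560)
    on.exit(grDevices::dev.off())
    plotKM(report)
    invisible(dir)
}

#' Write all tables of a synthetic cohort
#'
#' Emits the four CSV layouts the pipeline reads (CDR3s, survival,
#' expression, methylation, covariates), the antigen FASTA and a
#' ground-truth JSON.
#'
#' @param cohort the list returned by [genCohort()].
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
writeCohortCsvs <- function(cohort, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeCdr3Csv(cohort$cdr3, file.path(dir, "cdr3.csv"))
    utils::write.csv(cohort$survival, file.path(dir, "survival.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(cohort$expression, file.path(dir, "expression.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(cohort$methylation, file.path(dir, "methylation.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(cohort$covariates, file.path(dir, "covariates.csv"),
                     row.names = FALSE, quote = FALSE)
    writeAntigensFasta(cohort$antigen, file.path(dir, "antigens.fasta"))
    jsonlite::write_json(cohort$truth, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
    invisible(dir)
}

#' Write a run manifest
#'
#' Records the tool version, seed, configuration and input checksums —
#' enough to reproduce the run byte for byte.
#'
#' @param dir output directory.
#' @param config list of run parameters.
#' @param seed the seed in force.
#' @param inputs character vector of input paths to checksum.
#' @return path of the manifest, invisibly.
#' @export
writeRunManifest <- function(dir, config = list(), seed = NA_integer_,
                             inputs = character(0)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    inputs <- inputs[file.exists(inputs)]
    manifest <- list(
        tool = "TCRcta",
        version = as.character(utils::packageVersion("TCRcta")),
        seed = seed,
        config = config,
        inputs = if (length(inputs))
            data.frame(path = inputs, md5 = unname(tools::md5sum(inputs)),
                       stringsAsFactors = FALSE)
        else NULL)
    path <- file.path(dir, "manifest.json")
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
    invisible(path)
}
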