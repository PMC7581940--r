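# Table schemas shared by the pipeline: required columns and their types.
.schemas <- list(
  time_course = c(replicate_id = "character", species_id = "character",
                  time_min = "numeric", fraction = "numeric"),
  pools = c(replicate_id = "character", species_id = "character",
            total_pool_nmol_gDW = "numeric", final_enrichment = "numeric"),
  spectra_long = c(replicate_id = "character", species_id = "character",
                   mass_shift = "numeric", intensity = "numeric"),
  ptrms = c(time_min = "numeric", mz69 = "numeric", mz70 = "numeric",
            mz71 = "numeric", mz72 = "numeric", mz73 = "numeric",
            mz74 = "numeric", primary = "numeric",
            water_cluster = "numeric", pressure = "numeric"),
  pot_weights = c(tree_id = "character", day = "numeric",
                  weight_g = "numeric"),
  pot_anchors = c(tree_id = "character", initial_g = "numeric",
                  final_g = "numeric"),
  measurements = c(variable_id = "character", treatment = "character",
                   tree_id = "character", value = "numeric"),
  calibration = c(concentration = "numeric", signal = "numeric")
)

#' Table schemas understood by [read_table()]
#'
#' @return Named list: for each schema id, the required columns and their
#'   types.
#' @export
table_schemas <- function() .schemas

#' Read and validate a pipeline input table
#'
#' Reads a CSV (or TSV, by extension) with a header row, UTF-8 encoding and
#' `.` decimal separator, then validates it against one of the package's
#' schemas: all required columns present, numeric columns fully parseable.
#' Errors name the offending column and row.
#'
#' @param path File path; `.tsv`/`.txt` are read tab-separated, anything
#'   else comma-separated.
#' @param schema_id One of `names(table_schemas())`.
#' @return A tibble with at least the schema's columns, types coerced.
#' @export
read_table <- function(path, schema_id) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  schema <- .schemas[[schema_id]]
  if (is.null(schema)) {
    stop("unknown schema '", schema_id, "'; see table_schemas()",
         call. = FALSE)
  }
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                 check.names = TRUE, fileEncoding = "UTF-8")
  miss <- setdiff(names(schema), names(df))
  if (length(miss)) {
    stop(path, ": missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (col in names(schema)) {
    if (schema[[col]] == "numeric") {
      v <- df[[col]]
      if (!is.numeric(v)) {
        suppressWarnings(num <- as.numeric(v))
        bad <- which(is.na(num) & !is.na(v) & nzchar(trimws(v)))
        if (length(bad)) {
          stop(path, ": non-numeric value in column `", col, "`, row ",
               bad[1L], " ('", v[bad[1L]], "')", call. = FALSE)
        }
        df[[col]] <- num
      }
    } else {
      df[[col]] <- as.character(df[[col]])
    }
  }
  tibble::as_tibble(df)
}

#' Write a pipeline table
#'
#' CSV with header, UTF-8, `.` decimal separator, missing values as empty
#' cells — the exact format [read_table()] consumes.
#'
#' @param x Data frame.
#' @param path Output path (`.tsv`/`.txt` for tab-separated).
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(x, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a simulated experiment to pipeline input files
#'
#' Materializes a [simulate_experiment()] bundle as the CSV files the
#' pipeline stages read, plus the ground-truth manifest.
#'
#' @param experiment An `mep_experiment`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "mep_experiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    time_courses = file.path(dir, "time_courses.csv"),
    spectra = file.path(dir, "spectra.csv"),
    pools = file.path(dir, "pools.csv"),
    pot_weights = file.path(dir, "pot_weights.csv"),
    pot_anchors = file.path(dir, "pot_anchors.csv"),
    reference_weights = file.path(dir, "reference_weights.csv"),
    measurements = file.path(dir, "measurements.csv"),
    manifest = file.path(dir, "manifest.csv")
  )
  for (nm in names(paths)) write_table(experiment[[nm]], paths[[nm]])
  invisible(paths)
}
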