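#' Read a thermal/pH stability time-course CSV
#'
#' Expected columns: `form`, `temperature_C` (or `ph`), `time_min`,
#' `residual_pct`. Comma-separated, UTF-8, dot decimal separator,
#' header row required. Row-level validation failures are collected and
#' reported together with their line numbers.
#'
#' @param path path to the CSV file.
#' @return a validated [tibble::tibble] ready for
#'   [summarize_inactivation()].
#' @export
read_thermal_csv <- function(path) {
  df <- read_csv_checked(path, c("form", "time_min", "residual_pct"))
  if (!("temperature_C" %in% names(df)) && !("ph" %in% names(df))) {
    stop(sprintf("%s: need a `temperature_C` or `ph` column", path),
         call. = FALSE)
  }
  level_col <- intersect(c("temperature_C", "ph"), names(df))[1]
  problems <- character()
  for (col in c(level_col, "time_min", "residual_pct")) {
    bad <- which(!is.finite(df[[col]]))
    if (length(bad)) {
      problems <- c(problems, sprintf("row %d: `%s` is not numeric",
                                      bad + 1L, col))
    }
  }
  neg <- which(is.finite(df$time_min) & df$time_min < 0)
  if (length(neg)) {
    problems <- c(problems, sprintf("row %d: negative `time_min`", neg + 1L))
  }
  if (length(problems)) {
    stop(sprintf("%s: %s", path, paste(problems, collapse = "; ")),
         call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Read a clotting-assay CSV
#'
#' Expected columns: `sample`, `clot_time_s`, `dilution`. Returns the
#' table with an added `su_per_ml` column computed by
#' [soxhlet_units()].
#'
#' @param path path to the CSV file.
#' @param milk_volume_ml,enzyme_volume_ml,reference_time_s assay
#'   constants, see [soxhlet_units()].
#' @return a [tibble::tibble] with `sample`, `clot_time_s`, `dilution`,
#'   `su_per_ml`.
#' @export
read_clotting_csv <- function(path, milk_volume_ml = 5,
                              enzyme_volume_ml = 0.5,
                              reference_time_s = 2400) {
  df <- read_csv_checked(path, c("sample", "clot_time_s", "dilution"))
  bad <- which(!is.finite(df$clot_time_s) | df$clot_time_s <= 0)
  if (length(bad)) {
    stop(sprintf("%s: row %s: `clot_time_s` must be a positive number",
                 path, paste(bad + 1L, collapse = ", ")), call. = FALSE)
  }
  df$su_per_ml <- soxhlet_units(df$clot_time_s, df$dilution,
                                milk_volume_ml, enzyme_volume_ml,
                                reference_time_s)
  tibble::as_tibble(df)
}

#' Read a condition-profile CSV
#'
#' Long-format table of activity across a swept condition. Expected
#' columns: `form`, `variable`, `level`, `value`; optional `spread`
#' (the printed "+/-" column, kept verbatim as text since published
#' spread notation is often ambiguous).
#'
#' @param path path to the CSV file.
#' @param variable optional filter: keep only rows whose `variable`
#'   matches.
#' @return a [tibble::tibble] with columns `form`, `variable`, `level`,
#'   `activity` (renamed from `value`) and any extras.
#' @export
read_profile_csv <- function(path, variable = NULL) {
  df <- read_csv_checked(path, c("form", "variable", "level", "value"))
  if (!is.null(variable)) {
    df <- df[df$variable == variable, ]
    if (nrow(df) == 0L) {
      stop(sprintf("%s: no rows with variable = '%s'", path, variable),
           call. = FALSE)
    }
  }
  names(df)[names(df) == "value"] <- "activity"
  bad <- which(!is.finite(df$activity) | df$activity < 0)
  if (length(bad)) {
    stop(sprintf("%s: row %s: `value` must be a non-negative number",
                 path, paste(bad + 1L, collapse = ", ")), call. = FALSE)
  }
  tibble::as_tibble(df)
}

# Shared CSV reader: header + required-column checks.
read_csv_checked <- function(path, required) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  if (nrow(df) == 0L) {
    stop(sprintf("%s: file has no data rows", path), call. = FALSE)
  }
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Mean and standard error over replicates
#'
#' Replicated measurements are reported as mean +/- standard error of
#' the mean, `SE = sd / sqrt(n)`. A single replicate yields `SE = 0`
#' with `single_replicate = TRUE` so downstream reports can mark it.
#'
#' @param values numeric vector of replicate measurements (n >= 1).
#' @return list with `mean`, `se`, `n`, `single_replicate`.
#' @examples
#' aggregate_replicates(c(2, 4, 6))  # mean 4, SE 2/sqrt(3)
#' @export
aggregate_replicates <- function(values) {
  if (length(values) == 0L) {
    stop("`values` is empty", call. = FALSE)
  }
  if (!is.numeric(values) || anyNA(values)) {
    stop("`values` must be numeric and non-missing", call. = FALSE)
  }
  n <- length(values)
  list(
    mean = mean(values),
    se = if (n == 1L) 0 else stats::sd(values) / sqrt(n),
    n = n,
    single_replicate = n == 1L
  )
}

#' Assemble and write a JSON analysis report
#'
#' Collects per-stage result blocks (assay statistics, profiles, decay
#' summary, Arrhenius fits, ...) plus run metadata into one
#' deterministic JSON document. Every numeric block should carry its
#' units in its keys (`*_min`, `*_kJ_mol`, `*_pct`, ...). Re-running on
#' identical inputs yields byte-identical files: the timestamp is
#' excluded unless explicitly pinned via `timestamp`.
#'
#' @param blocks named list of result blocks (tibbles, lists, fit
#'   objects unclassed to lists).
#' @param path output file path.
#' @param seed the seed the run used, echoed in metadata (optional).
#' @param config configuration echo (named list, optional).
#' @param warnings character vector of run warnings.
#' @param timestamp optional fixed timestamp string; omitted entirely
#'   when `NULL` so that reports are reproducible.
#' @return the path, invisibly.
#' @export
write_report <- function(blocks, path, seed = NULL, config = NULL,
                         warnings = character(), timestamp = NULL) {
  if (!is.list(blocks) ||
      (length(blocks) > 0L && is.null(names(blocks)))) {
    stop("`blocks` must be a named list", call. = FALSE)
  }
  meta <- list(tool = "thermoclot",
               version = as.character(utils::packageVersion("thermoclot")))
  if (!is.null(timestamp)) meta$timestamp <- timestamp
  if (!is.null(seed)) meta$seed <- seed
  if (!is.null(config)) meta$config <- config
  report <- list(metadata = meta,
                 results = lapply(blocks, strip_classes),
                 warnings = as.list(warnings))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# Fit objects and tibbles serialize as plain lists / data frames.
strip_classes <- function(x) {
  if (inherits(x, c("decay_fit", "arrhenius_fit"))) return(unclass(x))
  if (is.data.frame(x)) return(as.data.frame(x))
  x
}
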