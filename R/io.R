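#' Read an assessment table from CSV
#'
#' Two schemas are accepted. Numeric: columns `unit`, `instance`,
#' `value`, optionally `objective` (a per-row threshold, returned
#' alongside the table). Fuzzy: columns `unit`, `instance`, `failed`
#' (0/1), `rank` (blank unless `failed = 1`). An empty field is the only
#' missing-value token; rows with a missing payload are recorded as
#' unmonitored instances.
#'
#' @param path CSV file path (UTF-8, header row).
#' @param objective_kind `"sharp"` or `"fuzzy"`; selects the schema.
#' @return for `"sharp"`: list with `table` and `thresholds` (the
#'   per-row objective data.frame, or `NULL` when absent); for
#'   `"fuzzy"`: list with `table` only.
#' @export
read_assessment_csv <- function(path,
                                objective_kind = c("sharp", "fuzzy")) {
  objective_kind <- match.arg(objective_kind)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  if (objective_kind == "sharp") {
    need <- c("unit", "instance", "value")
    miss <- setdiff(need, names(raw))
    if (length(miss))
      stop("missing column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    if (!is.numeric(raw$value) && !all(is.na(raw$value)))
      stop("non-numeric 'value' column", call. = FALSE)
    tab <- assessment_table(raw[need], kind = "numeric")
    thresholds <- NULL
    if ("objective" %in% names(raw)) {
      thresholds <- data.frame(unit = as.character(raw$unit),
                               instance = as.character(raw$instance),
                               threshold = as.numeric(raw$objective),
                               stringsAsFactors = FALSE)
    }
    list(table = tab, thresholds = thresholds)
  } else {
    need <- c("unit", "instance", "failed", "rank")
    miss <- setdiff(need, names(raw))
    if (length(miss))
      stop("missing column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    if (any(!is.na(raw$failed) & raw$failed & is.na(raw$rank)))
      stop("rank required where failed = 1", call. = FALSE)
    list(table = assessment_table(raw[need], kind = "fuzzy"))
  }
}

#' Write an assessment table to CSV
#'
#' Raw values are written with full precision (`format = "%.17g"` via R's
#' default numeric formatting), so a write/read round trip is lossless.
#'
#' @param table an [assessment_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_assessment_csv <- function(table, path) {
  stopifnot(inherits(table, "assessment_table"))
  df <- as.data.frame(table)
  if (attr(table, "kind") == "fuzzy") df$failed <- as.integer(df$failed)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Serialise an ESI report as JSON
#'
#' Writes the dimension block (with counts), the score block per method,
#' an echo of the objective and the tool version. Display values are
#' rounded half-away-from-zero to the report's configured decimals; the
#' raw unrounded doubles are co-serialised under `raw` so no precision
#' is lost.
#'
#' @param report an `esi_report` from [esi_assess()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "esi_report"))
  d <- report$dimensions
  disp <- function(x) round_half_away(x, report$rounding)
  doc <- list(
    dimensions = list(
      f1 = disp(d$f1), f2 = disp(d$f2),
      nse = d$nse, moe = d$moe,
      f3_nse = disp(d$f3_nse), f3_moe = disp(d$f3_moe),
      counts = list(n_units = d$n_units,
                    n_failing_units = d$n_failing_units,
                    n_instances = d$n_instances,
                    n_failing_instances = d$n_failing_instances)),
    scores = lapply(report$scores, function(m) lapply(m, disp)),
    raw = list(dimensions = list(f1 = d$f1, f2 = d$f2, f3_nse = d$f3_nse,
                                 f3_moe = d$f3_moe),
               scores = report$scores),
    objective = report$objective_echo,
    rounding = report$rounding,
    tool = list(package = "esindicator",
                version = as.character(utils::packageVersion("esindicator"))))
  # I(17) significant digits: lossless for IEEE doubles, so the raw
  # block survives a write/read round trip bit for bit
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Write study results as CSV
#'
#' One row per simulated table, including discarded ones (flagged by the
#' `discarded` and `discard_reason` columns).
#'
#' @param study an `esi_study` from [run_study()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_study_csv <- function(study, path) {
  stopifnot(inherits(study, "esi_study"))
  df <- study$results
  df$discarded <- as.integer(df$discarded)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read study results back from CSV
#' @param path CSV written by [write_study_csv()].
#' @return results data.frame with logical `discarded`.
#' @export
read_study_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$discarded <- as.logical(df$discarded)
  df$discard_reason <- as.character(df$discard_reason)
  df
}

#' Serialise a study summary as JSON
#'
#' @param summary a `study_summary` from [summarize_study()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_study_summary <- function(summary, path) {
  stopifnot(inherits(summary, "study_summary"))
  doc <- list(n_retained = summary$n_retained,
              percentiles = summary$percentiles,
              r_matrix = as.data.frame(summary$r_matrix),
              r2_pairs = summary$r2_pairs,
              subset_stats = summary$subset_stats,
              grids = summary$grids)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "columns")
  invisible(path)
}
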