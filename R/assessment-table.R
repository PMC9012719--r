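#' Build an assessment table
#'
#' An assessment table holds one observation per (spatial unit, instance)
#' pair. A spatial unit is a discrete subdivision of the study area (a
#' sub-basin, a monitoring station, a municipality-sector); an instance is
#' one monitored observation of that unit (typically a month of a time
#' series). Tables are either *numeric* (each observation is a measured
#' value in the same units as the objective it will be judged against) or
#' *fuzzy* (each observation carries a failure flag and, when failed, a
#' stakeholder-assigned excursion rank on a 1-10 scale). The two payload
#' kinds may not be mixed within one table.
#'
#' Missing observations (`NA` value, or `NA` failure flag) mark instances
#' that were not monitored; they are excluded from every denominator
#' downstream and never count as failures.
#'
#' @param data a data.frame. For a numeric table: columns `unit`,
#'   `instance`, `value` (numeric, `NA` = unmonitored). For a fuzzy table:
#'   columns `unit`, `instance`, `failed` (logical or 0/1), `rank`
#'   (numeric in \[1, 10\], required iff `failed`, otherwise `NA`).
#' @param kind `"numeric"` or `"fuzzy"`. Inferred from the columns when
#'   omitted.
#' @return an object of class `assessment_table`: the input data.frame
#'   with normalised column types, unit/instance label order preserved
#'   first-appearance, and the payload kind recorded.
#' @examples
#' tab <- assessment_table(data.frame(
#'   unit = rep(c("a", "b"), each = 3),
#'   instance = rep(c("m1", "m2", "m3"), 2),
#'   value = c(100, 95, 100, 100, 100, 100)
#' ))
#' tableKind(tab)
#' @export
assessment_table <- function(data, kind = NULL) {
  stopifnot(is.data.frame(data))
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  need <- c("unit", "instance")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0L)
    stop("assessment table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (is.null(kind)) {
    kind <- if ("value" %in% names(data)) "numeric"
            else if ("failed" %in% names(data)) "fuzzy"
            else stop("cannot infer table kind: need a 'value' column ",
                      "(numeric table) or a 'failed' column (fuzzy table)",
                      call. = FALSE)
  }
  kind <- match.arg(kind, c("numeric", "fuzzy"))
  if (nrow(data) < 1L)
    stop("assessment table needs at least one observation", call. = FALSE)

  data$unit <- as.character(data$unit)
  data$instance <- as.character(data$instance)

  if (kind == "numeric") {
    if (!"value" %in% names(data))
      stop("numeric table requires a 'value' column", call. = FALSE)
    if ("failed" %in% names(data) || "rank" %in% names(data))
      stop("mixed payload kinds: numeric table may not carry ",
           "'failed'/'rank' columns", call. = FALSE)
    data$value <- as.numeric(data$value)
    bad <- !is.na(data$value) & !is.finite(data$value)
    if (any(bad))
      stop("non-finite value at (", data$unit[bad][1L], ", ",
           data$instance[bad][1L], ")", call. = FALSE)
    data <- data[c("unit", "instance", "value")]
  } else {
    if (!all(c("failed", "rank") %in% names(data)))
      stop("fuzzy table requires 'failed' and 'rank' columns", call. = FALSE)
    if ("value" %in% names(data))
      stop("mixed payload kinds: fuzzy table may not carry a ",
           "'value' column", call. = FALSE)
    data$failed <- as.logical(data$failed)
    data$rank <- as.numeric(data$rank)
    fl <- !is.na(data$failed) & data$failed
    if (any(fl & is.na(data$rank)))
      stop("rank required for every failed instance", call. = FALSE)
    out_of_range <- fl & (data$rank < 1 | data$rank > 10)
    if (any(out_of_range, na.rm = TRUE))
      stop("rank out of range [1, 10] at (",
           data$unit[out_of_range][1L], ", ",
           data$instance[out_of_range][1L], ")", call. = FALSE)
    if (any(!fl & !is.na(data$rank)))
      stop("rank present on a compliant (or unmonitored) row", call. = FALSE)
    data <- data[c("unit", "instance", "failed", "rank")]
  }

  key <- paste(data$unit, data$instance, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    p <- strsplit(d, "\r", fixed = TRUE)[[1L]]
    stop("duplicate (unit, instance) pair: (", p[1L], ", ", p[2L], ")",
         call. = FALSE)
  }

  rownames(data) <- NULL
  structure(data,
            kind = kind,
            units = unique(data$unit),
            instances = unique(data$instance),
            class = c("assessment_table", "data.frame"))
}

#' @rdname assessment_table
#' @param x an `assessment_table`.
#' @export
tableKind <- function(x) {
  stopifnot(inherits(x, "assessment_table"))
  attr(x, "kind")
}

#' @rdname assessment_table
#' @export
tableUnits <- function(x) {
  stopifnot(inherits(x, "assessment_table"))
  attr(x, "units")
}

#' Observations that were actually monitored
#'
#' Drops rows whose payload is missing (`NA` value or `NA` failure flag):
#' unmonitored instances never enter a denominator.
#' @param x an `assessment_table`.
#' @return the table restricted to monitored rows (plain data.frame).
#' @keywords internal
monitored_rows <- function(x) {
  if (attr(x, "kind") == "numeric") x[!is.na(x$value), , drop = FALSE]
  else x[!is.na(x$failed), , drop = FALSE]
}

#' @export
print.assessment_table <- function(x, ...) {
  cat(sprintf("Assessment table (%s): %d units, %d observations\n",
              attr(x, "kind"), length(attr(x, "units")), nrow(x)))
  NextMethod()
  invisible(x)
}
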