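#' Define a failure objective
#'
#' An objective states the demand a service must meet. A *sharp* objective
#' is a numeric threshold plus a direction: `"must_not_fall_short"` (supply
#' below the threshold fails, e.g. water-supply reliability against 100%)
#' or `"must_not_exceed"` (values above the threshold fail, e.g. soil
#' erosion against 20 t/ha/yr). The threshold is either a single number
#' broadcast to every observation, or a per-observation data.frame with
#' columns `unit`, `instance`, `threshold`. A *fuzzy* objective carries no
#' numeric fields: the failure flags and excursion ranks live in the
#' (fuzzy) assessment table itself.
#'
#' Under `"must_not_fall_short"` the excursion divides by the instance
#' value, so thresholds must be strictly positive.
#'
#' @param threshold positive finite numeric scalar, or data.frame
#'   (`unit`, `instance`, `threshold`).
#' @param direction `"must_not_fall_short"` or `"must_not_exceed"`.
#' @return an object of class `esi_objective`.
#' @examples
#' sharp_objective(100, "must_not_fall_short")
#' sharp_objective(20, "must_not_exceed")
#' fuzzy_objective()
#' @export
sharp_objective <- function(threshold,
                            direction = c("must_not_fall_short",
                                          "must_not_exceed")) {
  direction <- match.arg(direction)
  if (is.data.frame(threshold)) {
    if (!all(c("unit", "instance", "threshold") %in% names(threshold)))
      stop("per-instance threshold table needs columns ",
           "'unit', 'instance', 'threshold'", call. = FALSE)
    threshold$threshold <- as.numeric(threshold$threshold)
    thr_values <- threshold$threshold
  } else {
    if (!is.numeric(threshold) || length(threshold) != 1L)
      stop("threshold must be a numeric scalar or a per-instance ",
           "data.frame", call. = FALSE)
    thr_values <- threshold
  }
  if (any(!is.finite(thr_values)))
    stop("thresholds must be finite", call. = FALSE)
  if (direction == "must_not_fall_short" && any(thr_values <= 0))
    stop("thresholds must be strictly positive under must_not_fall_short",
         call. = FALSE)
  structure(list(kind = "sharp", threshold = threshold,
                 direction = direction),
            class = "esi_objective")
}

#' @rdname sharp_objective
#' @export
fuzzy_objective <- function() {
  structure(list(kind = "fuzzy"), class = "esi_objective")
}

#' @export
print.esi_objective <- function(x, ...) {
  if (x$kind == "sharp") {
    thr <- if (is.data.frame(x$threshold)) "per-instance" else
      format(x$threshold)
    cat(sprintf("Sharp objective: threshold %s, %s\n", thr, x$direction))
  } else {
    cat("Fuzzy objective: failure flags and ranks supplied in the table\n")
  }
  invisible(x)
}

#' Validate a table/objective pair
#'
#' Checks the joint invariants: a numeric table must be paired with a
#' sharp objective and a fuzzy table with a fuzzy objective; a
#' per-instance threshold table must cover every monitored observation.
#' Single-object invariants (payload homogeneity, rank range, threshold
#' positivity, duplicate pairs) are enforced by the constructors, so
#' validation of a constructed pair is idempotent.
#'
#' @param table an `assessment_table`.
#' @param objective an `esi_objective`.
#' @return the pair, invisibly, as `list(table, objective)`, unchanged.
#' @export
validate_table <- function(table, objective) {
  if (!inherits(table, "assessment_table"))
    stop("'table' must be an assessment_table", call. = FALSE)
  if (!inherits(objective, "esi_objective"))
    stop("'objective' must be an esi_objective", call. = FALSE)
  kind <- attr(table, "kind")
  if (kind == "numeric" && objective$kind != "sharp")
    stop("kind mismatch: numeric table requires a sharp objective",
         call. = FALSE)
  if (kind == "fuzzy" && objective$kind != "fuzzy")
    stop("kind mismatch: fuzzy table requires a fuzzy objective",
         call. = FALSE)
  if (objective$kind == "sharp" && is.data.frame(objective$threshold)) {
    mon <- monitored_rows(table)
    have <- paste(objective$threshold$unit, objective$threshold$instance,
                  sep = "\r")
    want <- paste(mon$unit, mon$instance, sep = "\r")
    if (!all(want %in% have)) {
      miss <- mon[!(want %in% have), c("unit", "instance")][1L, ]
      stop("no threshold provided for (", miss$unit, ", ", miss$instance,
           ")", call. = FALSE)
    }
  }
  invisible(list(table = table, objective = objective))
}

# threshold per monitored row, broadcasting a scalar objective
threshold_for <- function(rows, objective) {
  stopifnot(objective$kind == "sharp")
  if (is.data.frame(objective$threshold)) {
    key <- paste(objective$threshold$unit, objective$threshold$instance,
                 sep = "\r")
    idx <- match(paste(rows$unit, rows$instance, sep = "\r"), key)
    objective$threshold$threshold[idx]
  } else {
    rep_len(objective$threshold, nrow(rows))
  }
}
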