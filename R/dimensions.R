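#' Classify per-instance failures
#'
#' Applies the objective to every monitored observation. Under a sharp
#' shortfall objective an instance fails iff its value is strictly below
#' the threshold; under a sharp exceedance objective iff strictly above.
#' A value exactly at the threshold complies (its excursion would be
#' zero). Fuzzy tables carry their own flags, which are copied through.
#'
#' @param table an `assessment_table`.
#' @param objective an `esi_objective` of matching kind.
#' @return data.frame with columns `unit`, `instance`, `failed` — one row
#'   per monitored observation.
#' @export
classify_failures <- function(table, objective) {
  validate_table(table, objective)
  mon <- monitored_rows(table)
  if (nrow(mon) == 0L)
    stop("table has no monitored observations", call. = FALSE)
  if (attr(table, "kind") == "numeric") {
    thr <- threshold_for(mon, objective)
    failed <- if (objective$direction == "must_not_fall_short")
      mon$value < thr else mon$value > thr
  } else {
    failed <- mon$failed
  }
  data.frame(unit = mon$unit, instance = mon$instance, failed = failed,
             stringsAsFactors = FALSE)
}

#' Scope: percentage of spatial units failing at least once
#'
#' @param flags failure flags as returned by [classify_failures()].
#' @return percent in \[0, 100\].
#' @export
compute_scope <- function(flags) {
  stopifnot(is.data.frame(flags), nrow(flags) >= 1L)
  per_unit <- tapply(flags$failed, flags$unit, any)
  100 * sum(per_unit) / length(per_unit)
}

#' Frequency: percentage of monitored instances that fail
#'
#' All units are pooled: the denominator is every monitored instance.
#' @inheritParams compute_scope
#' @return percent in \[0, 100\].
#' @export
compute_frequency <- function(flags) {
  stopifnot(is.data.frame(flags), nrow(flags) >= 1L)
  100 * sum(flags$failed) / nrow(flags)
}

#' Sharp excursion of a failing instance
#'
#' The relative gap between observation and objective:
#' `threshold/value - 1` for a shortfall objective, `value/threshold - 1`
#' for an exceedance objective. Strictly positive for a strict failure,
#' zero when the value sits exactly at the threshold.
#'
#' @param value observed value(s); must be strictly positive under
#'   `must_not_fall_short` (the excursion divides by the value — callers
#'   that may produce values near zero should impose a value floor, as
#'   the simulator does via its `value_floor`).
#' @param threshold objective value(s); strictly positive under
#'   `must_not_exceed`.
#' @param direction `"must_not_fall_short"` or `"must_not_exceed"`.
#' @return non-negative excursion(s).
#' @examples
#' excursion(80, 100, "must_not_fall_short")  # 0.25
#' excursion(30, 20, "must_not_exceed")       # 0.5
#' @export
excursion <- function(value, threshold,
                      direction = c("must_not_fall_short",
                                    "must_not_exceed")) {
  direction <- match.arg(direction)
  if (direction == "must_not_fall_short") {
    if (any(value <= 0))
      stop("excursion undefined for value <= 0 under must_not_fall_short; ",
           "apply a value floor (see simulation_config()$value_floor)",
           call. = FALSE)
    threshold / value - 1
  } else {
    if (any(threshold <= 0))
      stop("excursion requires threshold > 0 under must_not_exceed",
           call. = FALSE)
    value / threshold - 1
  }
}

#' Fuzzy excursion: the stakeholder rank itself
#'
#' Under a fuzzy objective the excursion of a failing instance is its
#' rank on the 1 (low gap) to 10 (high gap) scale, used directly.
#' Non-integer ranks in \[1, 10\] are accepted.
#'
#' @param rank numeric rank(s) in \[1, 10\].
#' @return the rank(s), unchanged.
#' @export
fuzzy_excursion <- function(rank) {
  if (any(is.na(rank)) || any(rank < 1 | rank > 10))
    stop("rank out of range [1, 10]", call. = FALSE)
  rank
}

#' Excursions of all failing instances
#'
#' @param table an `assessment_table`.
#' @param objective an `esi_objective` of matching kind.
#' @return an `excursion_set`: data.frame (`unit`, `instance`, `ex`) over
#'   failing instances, with the total count of monitored instances as
#'   attribute `total_instances`.
#' @export
excursion_set <- function(table, objective) {
  flags <- classify_failures(table, objective)
  mon <- monitored_rows(table)
  fail <- mon[flags$failed, , drop = FALSE]
  if (attr(table, "kind") == "numeric") {
    thr <- threshold_for(fail, objective)
    ex <- if (nrow(fail)) excursion(fail$value, thr, objective$direction)
          else numeric(0)
  } else {
    ex <- if (nrow(fail)) fuzzy_excursion(fail$rank) else numeric(0)
  }
  structure(data.frame(unit = fail$unit, instance = fail$instance,
                       ex = ex, stringsAsFactors = FALSE),
            total_instances = nrow(mon),
            class = c("excursion_set", "data.frame"))
}

#' Normalized sum of excursions (nse)
#'
#' Total excursion divided by the number of *all* monitored instances,
#' failing and compliant alike. Because the denominator counts every
#' instance, nse embeds frequency information alongside amplitude.
#'
#' @param exs an `excursion_set`.
#' @return non-negative real; 0 with no failures.
#' @export
normalized_sum_excursions <- function(exs) {
  total <- attr(exs, "total_instances")
  stopifnot(is.numeric(total), total >= 1)
  sum(exs$ex) / total
}

#' Mean of excursions (moe)
#'
#' Total excursion divided by the number of *failing* instances only — a
#' pure amplitude measure. Defined as 0 when nothing fails, so downstream
#' scores reduce to 100 without special-casing.
#'
#' @param exs an `excursion_set`.
#' @return non-negative real; 0 with no failures.
#' @export
mean_of_excursions <- function(exs) {
  if (nrow(exs) == 0L) return(0)
  mean(exs$ex)
}

#' Scale an excursion aggregate onto 0-100
#'
#' The saturating map `100 * x / (x + 1)`: strictly increasing on
#' x >= 0, 0 at 0, 50 at 1, asymptote 100. Applied to nse or moe to
#' produce the amplitude dimension F3.
#'
#' @param x non-negative real(s).
#' @return percent(s) in \[0, 100).
#' @export
scale_amplitude <- function(x) {
  if (any(x < 0)) stop("amplitude aggregate must be non-negative",
                       call. = FALSE)
  100 * x / (x + 1)
}

#' All three dimensions of an assessment
#'
#' Runs classification, scope, frequency and both amplitude variants:
#' `f3_nse` (normalized sum of excursions, fed to methods M1/M2) and
#' `f3_moe` (mean of excursions, fed to M3). No rounding is applied;
#' display rounding happens only at report serialisation.
#'
#' @param table an `assessment_table`.
#' @param objective an `esi_objective` of matching kind.
#' @return a `dimension_scores` list: `f1`, `f2`, `nse`, `moe`, `f3_nse`,
#'   `f3_moe`, and counts `n_units`, `n_failing_units`, `n_instances`,
#'   `n_failing_instances`.
#' @examples
#' fx <- dongjiang_fixture()
#' dimension_scores(fx$table, fx$objective)
#' @export
dimension_scores <- function(table, objective) {
  flags <- classify_failures(table, objective)
  exs <- excursion_set(table, objective)
  per_unit <- tapply(flags$failed, flags$unit, any)
  nse <- normalized_sum_excursions(exs)
  moe <- mean_of_excursions(exs)
  structure(list(
    f1 = compute_scope(flags),
    f2 = compute_frequency(flags),
    nse = nse,
    moe = moe,
    f3_nse = scale_amplitude(nse),
    f3_moe = scale_amplitude(moe),
    n_units = length(per_unit),
    n_failing_units = sum(per_unit),
    n_instances = nrow(flags),
    n_failing_instances = sum(flags$failed)
  ), class = "dimension_scores")
}

#' @export
print.dimension_scores <- function(x, ...) {
  cat(sprintf(paste0(
    "Dimension scores: F1 = %.1f (%d/%d units), F2 = %.1f (%d/%d ",
    "instances)\n  nse = %.4f -> F3 = %.1f;  moe = %.4f -> F3 = %.1f\n"),
    x$f1, x$n_failing_units, x$n_units, x$f2, x$n_failing_instances,
    x$n_instances, x$nse, x$f3_nse, x$moe, x$f3_moe))
  invisible(x)
}
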