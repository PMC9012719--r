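#' Configuration for the Monte-Carlo reliability study
#'
#' The study generates synthetic water-supply reliability tables under
#' two controls: *probability of failure* (PoF), the per-instance chance
#' of falling below the threshold, and *range of failure* (RoF), the
#' maximum relative depth of a failure below the threshold. With the
#' defaults each table mirrors the worked basin example: 17 spatial
#' units, 12 monthly instances, shortfall threshold 100 (% reliability).
#'
#' Compliant cells sit exactly at the threshold (reliability cannot
#' exceed 100%; any at-or-above-threshold value scores identically).
#' Failing cells are drawn uniformly on
#' `(threshold * (1 - rof/100), threshold)`, rounded to `value_decimals`
#' decimals — which makes a zero-excursion "failure" (a draw rounding up
#' to the threshold) reachable, as in real rounded monitoring data — and
#' floored at `value_floor` so the shortfall excursion never divides by
#' a value near zero.
#'
#' @param n_tables number of tables to simulate.
#' @param n_units,n_instances table geometry (spatial units x instances
#'   per unit).
#' @param threshold shortfall threshold shared by every cell.
#' @param pof_range,rof_range sub-intervals of \[0, 100\] (percent) from
#'   which each table's PoF and RoF are drawn uniformly.
#' @param value_decimals decimals failing values are rounded to.
#' @param value_floor lower bound applied to rounded failing values;
#'   must be below the threshold.
#' @param discard_all_no_failure if `FALSE` (default) the first all-pass
#'   table is retained and only its repetitions are discarded; if `TRUE`
#'   every all-pass table is discarded.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_tables = 10000L, n_units = 17L,
                              n_instances = 12L, threshold = 100,
                              pof_range = c(0, 100),
                              rof_range = c(0, 100),
                              value_decimals = 1L, value_floor = 0.1,
                              discard_all_no_failure = FALSE) {
  stopifnot(n_tables >= 1, n_units >= 1, n_instances >= 1, threshold > 0,
            length(pof_range) == 2L, length(rof_range) == 2L,
            value_decimals >= 0, value_floor > 0,
            value_floor < threshold)
  rng_ok <- function(r) all(r >= 0 & r <= 100) && r[1L] <= r[2L]
  if (!rng_ok(pof_range) || !rng_ok(rof_range))
    stop("pof_range and rof_range must be ordered sub-intervals of [0, 100]",
         call. = FALSE)
  structure(list(n_tables = as.integer(n_tables),
                 n_units = as.integer(n_units),
                 n_instances = as.integer(n_instances),
                 threshold = threshold, pof_range = pof_range,
                 rof_range = rof_range,
                 value_decimals = as.integer(value_decimals),
                 value_floor = value_floor,
                 discard_all_no_failure = isTRUE(discard_all_no_failure)),
            class = "simulation_config")
}

# Draw one table as a units x instances value matrix. Consumes the RNG
# stream in a fixed, documented order: one failure uniform per cell in
# unit-major order, then one value uniform per failing cell in the same
# order. Returns the matrix plus the Bernoulli failure mask (needed by
# the discard rules, which distinguish "nothing failed" from "failures
# all rounded back to the threshold").
draw_value_matrix <- function(pof, rof, config) {
  n <- config$n_units * config$n_instances
  fail <- stats::runif(n) < pof / 100
  values <- rep(config$threshold, n)
  n_fail <- sum(fail)
  if (n_fail > 0L) {
    lo <- config$threshold * (1 - rof / 100)
    v <- stats::runif(n_fail, min = lo, max = config$threshold)
    v <- round(v, config$value_decimals)
    v <- pmax(v, config$value_floor)
    values[fail] <- v
  }
  list(values = matrix(values, nrow = config$n_units, byrow = TRUE),
       fail_mask = matrix(fail, nrow = config$n_units, byrow = TRUE))
}

#' Generate one synthetic reliability table
#'
#' Draws a single table at the given probability and range of failure.
#' Uses the current RNG state; call `set.seed()` beforehand for
#' reproducibility.
#'
#' @param pof,rof probability and range of failure, percent in \[0, 100\].
#' @param config a [simulation_config()].
#' @return an [assessment_table()] (numeric kind) with units `su01` ...
#'   and instances `t01` ....
#' @export
generate_table <- function(pof, rof, config = simulation_config()) {
  stopifnot(pof >= 0, pof <= 100, rof >= 0, rof <= 100)
  m <- draw_value_matrix(pof, rof, config)$values
  units <- sprintf("su%02d", seq_len(config$n_units))
  inst <- sprintf("t%02d", seq_len(config$n_instances))
  assessment_table(data.frame(
    unit = rep(units, each = config$n_instances),
    instance = rep(inst, times = config$n_units),
    value = as.vector(t(m)),
    stringsAsFactors = FALSE))
}

# Dimensions of a value matrix under a scalar shortfall threshold:
# the simulator's fast scoring path. Equivalent, by property test, to
# dimension_scores(assessment_table(...), sharp_objective(...)).
score_value_matrix <- function(values, threshold) {
  flags <- values < threshold
  n_inst <- length(values)
  n_fail <- sum(flags)
  ex <- threshold / values[flags] - 1
  nse <- sum(ex) / n_inst
  moe <- if (n_fail > 0L) mean(ex) else 0
  failing_units <- sum(apply(flags, 1L, any))
  structure(list(
    f1 = 100 * failing_units / nrow(values),
    f2 = 100 * n_fail / n_inst,
    nse = nse, moe = moe,
    f3_nse = scale_amplitude(nse), f3_moe = scale_amplitude(moe),
    n_units = nrow(values), n_failing_units = failing_units,
    n_instances = n_inst, n_failing_instances = n_fail),
    class = "dimension_scores")
}

#' Run the Monte-Carlo sensitivity study
#'
#' For each table: draw PoF and RoF uniformly on their configured
#' ranges, generate the table, score it under all methods and evidence
#' levels, and apply the discard rules — (a) an all-pass table (no cell
#' failed the Bernoulli draw) is kept the first time it occurs and
#' discarded on repetition (it carries no new information; set
#' `discard_all_no_failure` to drop them all); (b) a table whose
#' Bernoulli failures *all* rounded back up to the threshold (every
#' excursion exactly zero) is discarded as an unrealistic artifact of
#' value rounding.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed; the single RNG stream is consumed in a
#'   documented order (per table: PoF, RoF, then cells in unit-major
#'   order), so identical seed and config give identical output.
#' @return an `esi_study` list: `results`, a data.frame with one row per
#'   table (`table_index`, `pof`, `rof`, `f1`, `f2`, `f3_nse`, `f3_moe`,
#'   `esi1`, `esi2`, `esi3_m1`, `esi3_m2`, `esi3_m3`, `discarded`,
#'   `discard_reason`), and `summary` (config echo, seed, counts by
#'   discard reason).
#' @examples
#' st <- run_study(simulation_config(n_tables = 50), seed = 1)
#' st$summary$n_retained
#' @export
run_study <- function(config = simulation_config(), seed = 1L) {
  set.seed(seed)
  n <- config$n_tables
  res <- data.frame(
    table_index = seq_len(n), pof = NA_real_, rof = NA_real_,
    f1 = NA_real_, f2 = NA_real_, f3_nse = NA_real_, f3_moe = NA_real_,
    esi1 = NA_real_, esi2 = NA_real_, esi3_m1 = NA_real_,
    esi3_m2 = NA_real_, esi3_m3 = NA_real_,
    discarded = FALSE, discard_reason = "none",
    stringsAsFactors = FALSE)
  seen_no_failure <- FALSE
  for (i in seq_len(n)) {
    pof <- stats::runif(1L, config$pof_range[1L], config$pof_range[2L])
    rof <- stats::runif(1L, config$rof_range[1L], config$rof_range[2L])
    drawn <- draw_value_matrix(pof, rof, config)
    d <- score_value_matrix(drawn$values, config$threshold)
    n_bernoulli_fail <- sum(drawn$fail_mask)
    if (n_bernoulli_fail == 0L) {
      if (seen_no_failure || config$discard_all_no_failure) {
        res$discarded[i] <- TRUE
        res$discard_reason[i] <- "no_failure_repeat"
      }
      seen_no_failure <- TRUE
    } else if (d$n_failing_instances == 0L) {
      # failures existed but every value rounded back to the threshold
      res$discarded[i] <- TRUE
      res$discard_reason[i] <- "all_zero_excursion"
    }
    res$pof[i] <- pof; res$rof[i] <- rof
    res$f1[i] <- d$f1; res$f2[i] <- d$f2
    res$f3_nse[i] <- d$f3_nse; res$f3_moe[i] <- d$f3_moe
    res$esi1[i] <- esi_m2(d$f1, level = 1)
    res$esi2[i] <- esi_m2(d$f1, d$f2, level = 2)
    res$esi3_m1[i] <- esi_m1(d$f1, d$f2, d$f3_nse)
    res$esi3_m2[i] <- esi_m2(d$f1, f3_nse = d$f3_nse, level = 3)
    res$esi3_m3[i] <- esi_m3(d$f1, d$f2, d$f3_moe, level = 3)
  }
  reasons <- table(factor(res$discard_reason,
                          c("none", "no_failure_repeat",
                            "all_zero_excursion")))
  structure(list(
    results = res,
    summary = list(seed = as.integer(seed), config = unclass(config),
                   n_tables = n, n_retained = sum(!res$discarded),
                   n_discarded = sum(res$discarded),
                   discard_counts = as.list(reasons))),
    class = "esi_study")
}

#' Retained (non-discarded) study rows
#' @param study an `esi_study` from [run_study()].
#' @return the `results` data.frame restricted to retained tables.
#' @export
retained_results <- function(study) {
  stopifnot(inherits(study, "esi_study"))
  study$results[!study$results$discarded, , drop = FALSE]
}

#' @export
print.esi_study <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("Monte-Carlo ESI study: %d tables (%d x %d cells), ",
                     "seed %d\n  retained %d, discarded %d ",
                     "(no-failure repeats %d, all-zero-excursion %d)\n"),
              s$n_tables, s$config$n_units, s$config$n_instances, s$seed,
              s$n_retained, s$n_discarded,
              s$discard_counts$no_failure_repeat,
              s$discard_counts$all_zero_excursion))
  invisible(x)
}
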