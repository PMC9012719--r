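#' ESI combination methods
#'
#' Three ways of collapsing the dimension scores into a single 0 (no
#' delivery) to 100 (full delivery) indicator:
#'
#' * **M1** — root-mean-square of all three dimensions, identical to the
#'   CCME Water Quality Index combination:
#'   `ESI_3 = 100 - sqrt((F1^2 + F2^2 + F3^2) / 3)`. Because its F3 uses
#'   the normalized sum of excursions (which already embeds frequency),
#'   M1 double-counts frequency; it is exposed only at evidence level 3.
#' * **M2** — geometric forms avoiding the double count:
#'   level 1 `100 - F1`; level 2 `100 - sqrt(F1 * F2)`;
#'   level 3 `100 - sqrt(F1 * F3)` with the nse-based F3 (which carries
#'   the frequency signal, so F2 is not combined again).
#' * **M3** — levels 1-2 as M2; level 3
#'   `100 - (F1 * F2 * F3)^(1/3)` with the moe-based F3 (pure amplitude,
#'   so all three dimensions enter once each).
#'
#' The evidence level (1 = scope only, 2 = scope + frequency, 3 = all
#' three dimensions) states how much of the data the score uses. Results
#' are clamped to \[0, 100\] to absorb floating-point representation
#' error at the extremes.
#'
#' @param f1,f2 scope and frequency, percents in \[0, 100\].
#' @param f3_nse amplitude from the normalized sum of excursions
#'   (methods M1 and M2).
#' @param f3_moe amplitude from the mean of excursions (method M3).
#' @param level evidence level, 1, 2 or 3.
#' @return score in \[0, 100\].
#' @examples
#' esi_m1(52.9, 17.6, 33.6)      # ~62.4
#' esi_m2(52.9, 17.6, 33.6, 3)   # ~57.8
#' esi_m3(52.9, 17.6, 74.2, 3)   # ~58.9
#' @name esi_methods
NULL

check_percent <- function(...) {
  vals <- c(...)
  if (any(!is.finite(vals) | vals < 0 | vals > 100))
    stop("dimension inputs must lie in [0, 100]", call. = FALSE)
}

clamp01 <- function(x) pmin(100, pmax(0, x))

#' @rdname esi_methods
#' @export
esi_m1 <- function(f1, f2, f3_nse) {
  check_percent(f1, f2, f3_nse)
  clamp01(100 - sqrt((f1^2 + f2^2 + f3_nse^2) / 3))
}

#' @rdname esi_methods
#' @export
esi_m2 <- function(f1, f2 = NULL, f3_nse = NULL, level = 3) {
  level <- check_level(level, f2, f3_nse)
  check_percent(f1)
  score <- switch(level,
    `1` = 100 - f1,
    `2` = { check_percent(f2); 100 - sqrt(f1 * f2) },
    `3` = { check_percent(f3_nse); 100 - sqrt(f1 * f3_nse) })
  clamp01(score)
}

#' @rdname esi_methods
#' @export
esi_m3 <- function(f1, f2 = NULL, f3_moe = NULL, level = 3) {
  level <- check_level(level, f2, f3_moe, f2_at_level3 = TRUE)
  check_percent(f1)
  score <- switch(level,
    `1` = 100 - f1,
    `2` = { check_percent(f2); 100 - sqrt(f1 * f2) },
    `3` = { check_percent(f2, f3_moe); 100 - (f1 * f2 * f3_moe)^(1 / 3) })
  clamp01(score)
}

check_level <- function(level, f2, f3, f2_at_level3 = FALSE) {
  if (!(length(level) == 1L && level %in% 1:3))
    stop("evidence level must be 1, 2 or 3", call. = FALSE)
  if ((level == 2 || (level == 3 && f2_at_level3)) && is.null(f2))
    stop("evidence level ", level, " requires f2", call. = FALSE)
  if (level == 3 && is.null(f3))
    stop("evidence level 3 requires an amplitude dimension", call. = FALSE)
  as.character(level)
}

#' Score an assessment table
#'
#' The full pipeline: validate, classify failures, compute the three
#' dimensions, and combine them under every method and evidence level the
#' data support. M1 exists only at level 3 (requesting it at level 1-2 is
#' an error by construction: it has no reduced form). M2 and M3 share
#' levels 1 and 2.
#'
#' @param table an `assessment_table`.
#' @param objective an `esi_objective` of matching kind.
#' @param rounding decimals used when the report is displayed or
#'   serialised (internal values stay at full precision).
#' @return an `esi_report`: `dimensions` (a [dimension_scores()] object),
#'   `scores` (nested list `m1$esi3`, `m2$esi1..esi3`, `m3$esi1..esi3`),
#'   `objective_echo` and `rounding`.
#' @examples
#' fx <- dongjiang_fixture()
#' esi_assess(fx$table, fx$objective)
#' @export
esi_assess <- function(table, objective, rounding = 1L) {
  validate_table(table, objective)
  dims <- dimension_scores(table, objective)
  report_from_dimensions(dims, objective, rounding)
}

# shared by esi_assess and the simulator fast path
report_from_dimensions <- function(dims, objective, rounding = 1L) {
  scores <- list(
    m1 = list(esi3 = esi_m1(dims$f1, dims$f2, dims$f3_nse)),
    m2 = list(esi1 = esi_m2(dims$f1, level = 1),
              esi2 = esi_m2(dims$f1, dims$f2, level = 2),
              esi3 = esi_m2(dims$f1, f3_nse = dims$f3_nse, level = 3)),
    m3 = list(esi1 = esi_m3(dims$f1, level = 1),
              esi2 = esi_m3(dims$f1, dims$f2, level = 2),
              esi3 = esi_m3(dims$f1, dims$f2, dims$f3_moe, level = 3)))
  objective_echo <- if (objective$kind == "sharp") {
    list(kind = "sharp",
         threshold = if (is.data.frame(objective$threshold))
           "per-instance" else objective$threshold,
         direction = objective$direction)
  } else list(kind = "fuzzy")
  structure(list(dimensions = dims, scores = scores,
                 objective_echo = objective_echo,
                 rounding = as.integer(rounding)),
            class = "esi_report")
}

# round half away from zero (matches the published tables; base round()
# rounds half to even)
round_half_away <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @export
print.esi_report <- function(x, ...) {
  r <- function(v) format(round_half_away(v, x$rounding), nsmall = x$rounding)
  d <- x$dimensions
  cat("Ecosystem Service Indicator report\n")
  cat(sprintf("  F1 (scope)     %s   F2 (frequency) %s\n", r(d$f1), r(d$f2)))
  cat(sprintf("  F3 nse-based   %s   F3 moe-based   %s\n",
              r(d$f3_nse), r(d$f3_moe)))
  s <- x$scores
  cat(sprintf("  ESI_1 %s  ESI_2 %s  (methods M2/M3)\n",
              r(s$m2$esi1), r(s$m2$esi2)))
  cat(sprintf("  ESI_3: M1 %s  M2 %s  M3 %s\n",
              r(s$m1$esi3), r(s$m2$esi3), r(s$m3$esi3)))
  invisible(x)
}
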