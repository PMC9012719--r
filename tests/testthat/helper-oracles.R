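# Independent oracles and small builders shared across the suite.

# Build a numeric assessment table from a units x instances value matrix
# (NA = unmonitored).
table_from_matrix <- function(values) {
  nu <- nrow(values); ni <- ncol(values)
  assessment_table(data.frame(
    unit = rep(sprintf("u%02d", seq_len(nu)), each = ni),
    instance = rep(sprintf("i%02d", seq_len(ni)), times = nu),
    value = as.vector(t(values)),
    stringsAsFactors = FALSE))
}

# Brute-force dimension scorer: explicit loops over every cell, written
# independently of the package's vectorised path.
brute_force_dimensions <- function(values, threshold, direction) {
  n_units <- 0L  # units with at least one monitored instance
  failing_units <- 0L
  n_instances <- 0L
  exs <- numeric(0)
  for (u in seq_len(nrow(values))) {
    unit_failed <- FALSE
    unit_monitored <- FALSE
    for (i in seq_len(ncol(values))) {
      v <- values[u, i]
      if (is.na(v)) next
      unit_monitored <- TRUE
      n_instances <- n_instances + 1L
      failed <- if (direction == "must_not_fall_short") v < threshold
                else v > threshold
      if (failed) {
        unit_failed <- TRUE
        ex <- if (direction == "must_not_fall_short") threshold / v - 1
              else v / threshold - 1
        exs <- c(exs, ex)
      }
    }
    if (unit_monitored) n_units <- n_units + 1L
    if (unit_failed) failing_units <- failing_units + 1L
  }
  nse <- sum(exs) / n_instances
  moe <- if (length(exs)) mean(exs) else 0
  list(f1 = 100 * failing_units / n_units,
       f2 = 100 * length(exs) / n_instances,
       nse = nse, moe = moe,
       f3_nse = 100 * nse / (nse + 1),
       f3_moe = 100 * moe / (moe + 1))
}

# Textbook two-pass Pearson correlation and simple-regression R^2.
two_pass_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

two_pass_r2 <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  fit <- a + b * x
  1 - sum((y - fit)^2) / sum((y - mean(y))^2)
}

# Run the bundled CLI in a child Rscript; returns list(status, stdout).
run_cli <- function(...) {
  script <- system.file("scripts", "esi-cli.R", package = "esindicator")
  stopifnot(nzchar(script))
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- suppressWarnings(system2(
    rscript, c(shQuote(script), vapply(list(...), as.character, "")),
    stdout = TRUE, stderr = TRUE,
    env = paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))))
  list(status = attr(out, "status") %||% 0L, output = out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
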