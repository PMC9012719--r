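#' Percentile summary of a study
#'
#' The {5, 25, 50, 75, 95}th percentiles of the simulator inputs (PoF,
#' RoF), the three dimensions and every indicator score, over retained
#' tables only.
#'
#' @param study an `esi_study`, or its retained `results` data.frame.
#' @param probs percentile probabilities.
#' @return data.frame: one row per variable, one column per percentile.
#' @export
study_percentiles <- function(study, probs = c(0.05, 0.25, 0.5, 0.75,
                                               0.95)) {
  res <- as_retained_df(study)
  vars <- c("pof", "rof", "f1", "f2", "f3_nse", "f3_moe", "esi1", "esi2",
            "esi3_m1", "esi3_m2", "esi3_m3")
  q <- t(vapply(vars, function(v) stats::quantile(res[[v]], probs = probs,
                                                  names = FALSE),
                numeric(length(probs))))
  out <- data.frame(variable = vars, q, stringsAsFactors = FALSE)
  names(out) <- c("variable", paste0("p", probs * 100))
  rownames(out) <- NULL
  out
}

as_retained_df <- function(study) {
  res <- if (inherits(study, "esi_study")) retained_results(study)
         else study
  stopifnot(is.data.frame(res), nrow(res) >= 1L)
  res
}

#' Pearson correlation coefficient
#'
#' Thin wrapper over [stats::cor()] with the validity checks the study
#' needs (equal lengths of at least 3, both inputs non-constant).
#'
#' @param x,y numeric vectors.
#' @return r in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  check_xy(x, y)
  stats::cor(x, y)
}

#' OLS coefficient of determination
#'
#' R-squared of the ordinary-least-squares fit of `y` on `x`.
#'
#' @param x,y numeric vectors; `x` non-constant.
#' @return R-squared in \[0, 1\].
#' @export
ols_r2 <- function(x, y) {
  check_xy(x, y, require_y_varying = FALSE)
  summary(stats::lm(y ~ x))$r.squared
}

# NA instead of an error when a band-level input is degenerate
safe_r <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

check_xy <- function(x, y, require_y_varying = TRUE) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3L)
    stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("x is constant", call. = FALSE)
  if (require_y_varying && stats::sd(y) == 0)
    stop("y is constant", call. = FALSE)
  invisible(TRUE)
}

#' Full correlation matrix of a study
#'
#' Pearson correlations among the simulator inputs, dimensions and
#' scores over retained tables.
#'
#' @param study an `esi_study` or retained results data.frame.
#' @return symmetric correlation matrix.
#' @export
study_correlations <- function(study) {
  res <- as_retained_df(study)
  vars <- c("pof", "rof", "f1", "f2", "f3_nse", "f3_moe", "esi1", "esi2",
            "esi3_m1", "esi3_m2", "esi3_m3")
  stats::cor(res[vars])
}

#' Evidence-level agreement within probability-of-failure bands
#'
#' For each PoF band and each method (M2, M3): the mean level-3 score
#' and the Pearson correlations of the level-1 and level-2 scores with
#' the level-3 score. Characterises how much is lost by scoring with
#' fewer dimensions, and how that loss grows with failure probability.
#'
#' @param study an `esi_study` or retained results data.frame.
#' @param pof_bands list of `c(lo, hi)` PoF intervals (percent);
#'   half-open `[lo, hi)` except the last, which is closed.
#' @return data.frame: `band`, `method`, `n`, `mean_esi3`,
#'   `r_esi1_esi3`, `r_esi2_esi3`. A correlation is `NA` when one of its
#'   inputs is constant within the band (at high failure probability
#'   every unit fails in nearly every table, so the level-1 score can be
#'   constant in small studies).
#' @export
subset_correlations <- function(study,
                                pof_bands = list(c(0, 10), c(20, 30),
                                                 c(40, 50))) {
  res <- as_retained_df(study)
  rows <- lapply(pof_bands, function(b) {
    stopifnot(length(b) == 2L, b[1L] < b[2L])
    sel <- res$pof >= b[1L] & res$pof <= b[2L]
    sub <- res[sel, , drop = FALSE]
    if (nrow(sub) < 3L)
      stop(sprintf("PoF band [%g, %g] holds fewer than 3 tables",
                   b[1L], b[2L]), call. = FALSE)
    band <- sprintf("%g-%g", b[1L], b[2L])
    do.call(rbind, lapply(c(m2 = "esi3_m2", m3 = "esi3_m3"),
      function(col) data.frame(
        band = band, method = toupper(substr(col, 6L, 7L)), n = nrow(sub),
        mean_esi3 = mean(sub[[col]]),
        r_esi1_esi3 = safe_r(sub$esi1, sub[[col]]),
        r_esi2_esi3 = safe_r(sub$esi2, sub[[col]]),
        stringsAsFactors = FALSE)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Binned grid of mean level-3 scores
#'
#' Bins retained tables on two axes (by default PoF x RoF) into an
#' `n_bins` x `n_bins` rectangular grid and reports the count and the
#' mean of a score column per cell — the tabular equivalent of a binned
#' bivariate histogram.
#'
#' @param study an `esi_study` or retained results data.frame.
#' @param score column to average (e.g. `"esi3_m2"`).
#' @param x,y binning axes (column names).
#' @param n_bins number of equal-width bins per axis (>= 2), spanning
#'   the observed range of each axis.
#' @return data.frame: `x_bin`, `y_bin` (1-based indices), `x_mid`,
#'   `y_mid` (bin midpoints), `n`, `mean_score`; empty cells included
#'   with `n = 0` and `NA` mean. Cell counts sum to the number of
#'   retained tables.
#' @export
binned_grid <- function(study, score = "esi3_m2", x = "pof", y = "rof",
                        n_bins = 10L) {
  res <- as_retained_df(study)
  stopifnot(n_bins >= 2L, score %in% names(res), x %in% names(res),
            y %in% names(res))
  cut_idx <- function(v) {
    br <- seq(min(v), max(v), length.out = n_bins + 1L)
    i <- findInterval(v, br, rightmost.closed = TRUE)
    list(idx = pmin(i, n_bins), mids = (br[-1L] + br[-(n_bins + 1L)]) / 2)
  }
  cx <- cut_idx(res[[x]]); cy <- cut_idx(res[[y]])
  grid <- expand.grid(x_bin = seq_len(n_bins), y_bin = seq_len(n_bins))
  cell <- paste(cx$idx, cy$idx)
  key <- paste(grid$x_bin, grid$y_bin)
  counts <- table(factor(cell, levels = key))
  means <- tapply(res[[score]], factor(cell, levels = key), mean)
  data.frame(x_bin = grid$x_bin, y_bin = grid$y_bin,
             x_mid = cx$mids[grid$x_bin], y_mid = cy$mids[grid$y_bin],
             n = as.integer(counts), mean_score = as.numeric(means),
             stringsAsFactors = FALSE)
}

#' Summarise a full study
#'
#' Bundles the percentile table, correlation matrix, the designated
#' regression R-squared values, the PoF-band subset statistics and a
#' PoF x RoF grid per method into one object, serialisable as JSON via
#' [write_study_summary()].
#'
#' @param study an `esi_study` or retained results data.frame.
#' @param n_bins grid resolution passed to [binned_grid()].
#' @return a `study_summary` list with elements `percentiles`,
#'   `r_matrix`, `r2_pairs`, `subset_stats`, `grids`, `n_retained`.
#' @export
summarize_study <- function(study, n_bins = 10L) {
  res <- as_retained_df(study)
  r2p <- data.frame(
    x = c("pof", "pof", "pof", "rof"),
    y = c("f1", "f2", "f3_moe", "f3_moe"),
    r2 = c(ols_r2(res$pof, res$f1), ols_r2(res$pof, res$f2),
           ols_r2(res$pof, res$f3_moe), ols_r2(res$rof, res$f3_moe)),
    stringsAsFactors = FALSE)
  grids <- lapply(c(esi3_m1 = "esi3_m1", esi3_m2 = "esi3_m2",
                    esi3_m3 = "esi3_m3"),
                  function(s) binned_grid(res, score = s, n_bins = n_bins))
  structure(list(percentiles = study_percentiles(res),
                 r_matrix = study_correlations(res),
                 r2_pairs = r2p,
                 subset_stats = subset_correlations(res),
                 grids = grids,
                 n_retained = nrow(res)),
            class = "study_summary")
}
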