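test_that("config validation catches bad geometry and ranges", {
  expect_error(simulation_config(pof_range = c(50, 10)), "sub-intervals")
  expect_error(simulation_config(rof_range = c(-5, 50)), "sub-intervals")
  expect_error(simulation_config(value_floor = 0))
  expect_error(simulation_config(value_floor = 200, threshold = 100))
  cfg <- simulation_config(n_tables = 5)
  expect_s3_class(cfg, "simulation_config")
})

test_that("generated values respect floor, ceiling and rof bound", {
  set.seed(3)
  cfg <- simulation_config(n_units = 10, n_instances = 12,
                           value_decimals = 1, value_floor = 0.1)
  for (rof in c(5, 40, 100)) {
    tab <- generate_table(80, rof, cfg)
    v <- tab$value
    expect_true(all(v >= cfg$value_floor))
    expect_true(all(v <= cfg$threshold))
    # failing draws live within rof% of the threshold (plus rounding)
    failing <- v[v < cfg$threshold]
    if (length(failing))
      expect_true(all(failing >=
        max(cfg$threshold * (1 - rof / 100) - 0.05, cfg$value_floor)))
  }
})

test_that("limiting cases: pof 0 gives a perfect table, pof 100 fails everywhere", {
  set.seed(5)
  cfg <- simulation_config(n_units = 6, n_instances = 6)
  tab0 <- generate_table(0, 50, cfg)
  r0 <- esi_assess(tab0, sharp_objective(100))
  expect_true(all(unlist(r0$scores) == 100))

  tab1 <- generate_table(100, 90, cfg)
  d1 <- dimension_scores(tab1, sharp_objective(100))
  expect_equal(d1$f1, 100)
  expect_equal(d1$f2, 100)
})

test_that("identical seed and config reproduce the study bit for bit", {
  cfg <- simulation_config(n_tables = 60)
  a <- run_study(cfg, seed = 123)
  b <- run_study(cfg, seed = 123)
  expect_identical(a, b)
  c <- run_study(cfg, seed = 124)
  expect_false(identical(a$results, c$results))
})

test_that("the fast scoring path agrees exactly with the full pipeline", {
  set.seed(31)
  cfg <- simulation_config(n_units = 17, n_instances = 12)
  obj <- sharp_objective(cfg$threshold)
  for (k in 1:25) {
    drawn <- esindicator:::draw_value_matrix(runif(1, 0, 100),
                                             runif(1, 0, 100), cfg)
    fast <- esindicator:::score_value_matrix(drawn$values, cfg$threshold)
    units <- sprintf("u%02d", seq_len(nrow(drawn$values)))
    tab <- table_from_matrix(drawn$values)
    full <- dimension_scores(tab, obj)
    for (f in c("f1", "f2", "nse", "moe", "f3_nse", "f3_moe",
                "n_failing_instances"))
      expect_identical(fast[[f]], full[[f]])
  }
})

test_that("frequency is unbiased for the probability of failure", {
  # E[F2 | pof] = pof; with m tables of 204 cells the batch mean of F2
  # is binomial-normal with sd = 100 * sqrt(p(1-p) / (204 m))
  m <- 400
  cfg <- simulation_config(n_tables = m, pof_range = c(50, 50))
  st <- run_study(cfg, seed = 9)
  f2 <- st$results$f2
  se <- 100 * sqrt(0.5 * 0.5 / (204 * m))
  expect_lt(abs(mean(f2) - 50), 3 * se)
})

test_that("mean dimensions respond monotonically to the stress controls", {
  cfg_at <- function(pof, rof, n) simulation_config(
    n_tables = n, pof_range = c(pof, pof), rof_range = c(rof, rof))
  # F1, F2 non-decreasing in pof at fixed rof
  mean_f <- vapply(c(2, 10, 40), function(p) {
    r <- retained_results(run_study(cfg_at(p, 50, 500), seed = 21))
    c(mean(r$f1), mean(r$f2))
  }, numeric(2))
  expect_true(all(diff(mean_f[1, ]) > 0))
  expect_true(all(diff(mean_f[2, ]) > 0))
  # f3_moe non-decreasing in rof at fixed pof
  mean_moe <- vapply(c(10, 40, 90), function(ro) {
    r <- retained_results(run_study(cfg_at(30, ro, 500), seed = 22))
    mean(r$f3_moe)
  }, 1)
  expect_true(all(diff(mean_moe) > 0))
})

test_that("discard rules separate no-failure repeats from rounded-out excursions", {
  # low pof: many all-pass tables; first kept, repeats discarded
  cfg <- simulation_config(n_tables = 200, pof_range = c(0, 1))
  st <- run_study(cfg, seed = 2)
  res <- st$results
  pure_pass <- res$f2 == 0 & res$discard_reason != "all_zero_excursion"
  expect_gt(sum(pure_pass), 2L)
  first <- which(pure_pass)[1L]
  expect_false(res$discarded[first])
  later <- setdiff(which(pure_pass), first)
  expect_true(all(res$discarded[later]))
  expect_true(all(res$discard_reason[later] == "no_failure_repeat"))

  # discard_all_no_failure drops every all-pass table
  st2 <- run_study(simulation_config(n_tables = 200, pof_range = c(0, 1),
                                     discard_all_no_failure = TRUE),
                   seed = 2)
  res2 <- st2$results
  pure_pass <- res2$f2 == 0 & res2$discard_reason != "all_zero_excursion"
  expect_true(all(res2$discarded[pure_pass]))

  # without rounding, a zero excursion has measure zero
  st3 <- run_study(simulation_config(n_tables = 300, value_decimals = 6),
                   seed = 4)
  expect_equal(st3$summary$discard_counts$all_zero_excursion, 0L)

  # tight rof + coarse rounding makes zero-excursion discards common
  st4 <- run_study(simulation_config(n_tables = 100,
                                     pof_range = c(1, 3),
                                     rof_range = c(0.001, 0.02),
                                     value_decimals = 1), seed = 6)
  expect_gt(st4$summary$discard_counts$all_zero_excursion, 0L)
  expect_true(all(st4$results$discard_reason[st4$results$discarded]
                  != "none"))
})

test_that("the worked-example fixture carries its designed failure layout", {
  fx <- dongjiang_fixture()
  expect_length(tableUnits(fx$table), 17L)
  expect_equal(nrow(fx$table), 204L)
  flags <- classify_failures(fx$table, fx$objective)
  expect_equal(sum(flags$failed), 36L)
  per_unit <- tapply(flags$failed, flags$unit, any)
  expect_equal(sum(per_unit), 9L)
  months <- unique(flags$instance[flags$failed])
  expect_setequal(months, c("Feb", "Mar", "Apr", "May"))
  expect_true(all(fx$table$value %in% c(25.85, 100)))
})
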