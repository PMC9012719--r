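test_that("failure classification uses strict inequality at the threshold", {
  tab <- table_from_matrix(matrix(c(99.9, 100, 100.1), 1, 3))
  short <- classify_failures(tab, sharp_objective(100,
                                                  "must_not_fall_short"))
  expect_identical(short$failed, c(TRUE, FALSE, FALSE))
  exceed <- classify_failures(tab, sharp_objective(100, "must_not_exceed"))
  expect_identical(exceed$failed, c(FALSE, FALSE, TRUE))

  # soil-erosion style exceedance objective: 30 t/ha/yr against 20
  ero <- table_from_matrix(matrix(c(30, 10), 1, 2))
  fl <- classify_failures(ero, sharp_objective(20, "must_not_exceed"))
  expect_identical(fl$failed, c(TRUE, FALSE))
})

test_that("scope and frequency are failing shares in percent", {
  fx <- dongjiang_fixture()
  flags <- classify_failures(fx$table, fx$objective)
  expect_equal(compute_scope(flags), 100 * 9 / 17)
  expect_equal(compute_frequency(flags), 100 * 36 / 204)

  none <- table_from_matrix(matrix(100, 3, 4))
  fl0 <- classify_failures(none, sharp_objective(100))
  expect_equal(compute_scope(fl0), 0)
  expect_equal(compute_frequency(fl0), 0)

  all_fail <- table_from_matrix(matrix(1, 3, 4))
  fl1 <- classify_failures(all_fail, sharp_objective(100))
  expect_equal(compute_scope(fl1), 100)
  expect_equal(compute_frequency(fl1), 100)
})

test_that("excursions follow the relative-gap formulas", {
  expect_equal(excursion(80, 100, "must_not_fall_short"), 0.25)
  expect_equal(excursion(100, 100, "must_not_fall_short"), 0)
  expect_equal(excursion(30, 20, "must_not_exceed"), 0.5)
  expect_error(excursion(0, 100, "must_not_fall_short"), "value floor")
  expect_error(excursion(-1, 100, "must_not_fall_short"), "value floor")
  expect_error(excursion(5, 0, "must_not_exceed"), "threshold > 0")

  expect_equal(fuzzy_excursion(1), 1)
  expect_equal(fuzzy_excursion(10), 10)
  expect_equal(fuzzy_excursion(5.5), 5.5)
  expect_error(fuzzy_excursion(0.5), "out of range")
  expect_error(fuzzy_excursion(10.01), "out of range")
})

test_that("nse and moe aggregate excursions with different denominators", {
  fz <- dongjiang_fuzzy_fixture(1)
  exs <- excursion_set(fz$table, fz$objective)
  expect_equal(nrow(exs), 36L)
  expect_equal(attr(exs, "total_instances"), 204L)
  expect_equal(normalized_sum_excursions(exs), 36 / 204)
  expect_equal(mean_of_excursions(exs), 1)

  fx <- dongjiang_fixture()
  exs2 <- excursion_set(fx$table, fx$objective)
  # failing value 25.85 against threshold 100: Ex = 100/25.85 - 1
  expect_equal(normalized_sum_excursions(exs2),
               36 * (100 / 25.85 - 1) / 204)
  expect_equal(mean_of_excursions(exs2), 100 / 25.85 - 1)

  empty <- excursion_set(table_from_matrix(matrix(100, 2, 2)),
                         sharp_objective(100))
  expect_equal(nrow(empty), 0L)
  expect_equal(normalized_sum_excursions(empty), 0)
  expect_equal(mean_of_excursions(empty), 0)
})

test_that("amplitude scaling is the saturating map x/(x+1)", {
  expect_equal(scale_amplitude(0), 0)
  expect_equal(scale_amplitude(1), 50)
  expect_equal(scale_amplitude(10), 1000 / 11)
  expect_equal(scale_amplitude(0.50601), 100 * 0.50601 / 1.50601)
  expect_error(scale_amplitude(-0.1), "non-negative")
  x <- seq(0, 50, by = 0.5)
  expect_true(all(diff(scale_amplitude(x)) > 0))
  expect_true(all(scale_amplitude(x) < 100))
})

test_that("dimension invariants hold on randomly generated tables", {
  set.seed(42)
  cfg <- simulation_config(n_units = 6, n_instances = 8,
                           value_decimals = 1)
  obj <- sharp_objective(100)
  for (k in 1:40) {
    tab <- generate_table(runif(1, 0, 100), runif(1, 0, 100), cfg)
    d <- dimension_scores(tab, obj)
    expect_gte(d$f1, 0); expect_lte(d$f1, 100)
    expect_gte(d$f2, 0); expect_lte(d$f2, 100)
    expect_gte(d$nse, 0); expect_gte(d$moe, d$nse)
    expect_gte(d$f3_moe, d$f3_nse)
    expect_lt(d$f3_nse, 100); expect_lt(d$f3_moe, 100)
    # equal instance counts per unit: each failing unit contributes at
    # most its full share of instances
    expect_lte(d$f2, d$f1)
    # zero-failure coupling
    expect_equal(d$f1 == 0, d$f2 == 0)
    if (d$n_failing_instances == 0L) {
      expect_equal(d$nse, 0); expect_equal(d$moe, 0)
      expect_equal(d$f3_nse, 0); expect_equal(d$f3_moe, 0)
    }
  }
})

test_that("vectorised dimensions match a brute-force enumeration", {
  set.seed(7)
  value_grid <- c(0.5, 1, 25.85, 50, 99.9, 100, 130, NA)
  for (k in 1:60) {
    nu <- sample(1:3, 1); ni <- sample(1:3, 1)
    m <- matrix(sample(value_grid, nu * ni, replace = TRUE), nu, ni)
    if (all(is.na(m))) next
    # keep at least one monitored instance per table
    if (all(is.na(m[1, ]))) m[1, 1] <- 100
    direction <- sample(c("must_not_fall_short", "must_not_exceed"), 1)
    tab <- table_from_matrix(m)
    d <- dimension_scores(tab, sharp_objective(100, direction))
    o <- brute_force_dimensions(m, 100, direction)
    expect_equal(d$f1, o$f1)
    expect_equal(d$f2, o$f2)
    expect_equal(d$nse, o$nse)
    expect_equal(d$moe, o$moe)
    expect_equal(d$f3_nse, o$f3_nse)
    expect_equal(d$f3_moe, o$f3_moe)
  }
})
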