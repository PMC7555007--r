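# a plan small and short enough for structural tests
tiny_plan <- function(...) {
  experiment_plan(
    pmhc_grid = c(5, 10, 20, 40),
    tcr_grid = 18,
    n_replicates = 2,
    base_seed = 7,
    duration = 5,
    measurement_times = c(2, 5),
    config = small_config(),
    ...
  )
}

test_that("experiment_plan validates grids and times", {
  expect_error(experiment_plan(pmhc_grid = numeric(0)), "non-empty")
  expect_error(experiment_plan(pmhc_grid = c(-1, 2)), "positive")
  expect_error(experiment_plan(tcr_grid = numeric(0)), "non-empty")
  expect_error(experiment_plan(n_replicates = 0), ">= 1")
  expect_error(experiment_plan(measurement_times = c(60, 700),
                               duration = 600), "must not exceed")
})

test_that("condition seeds are deterministic, paired across arms, distinct otherwise", {
  s <- condition_seed(1, 10, 18, 1)
  expect_identical(s, condition_seed(1, 10, 18, 1))
  expect_true(s >= 1 && s < 2^31)
  # pairing: B and coupling are not part of the hash, so arms share seeds
  # by construction; different densities and replicates must differ
  expect_false(s == condition_seed(1, 20, 18, 1))
  expect_false(s == condition_seed(1, 10, 36, 1))
  expect_false(s == condition_seed(1, 10, 18, 2))
  expect_false(s == condition_seed(2, 10, 18, 1))
})

test_that("run_condition is reproducible and honours duration 0", {
  plan <- tiny_plan()
  r1 <- run_condition(plan, pmhc = 10, replicate = 1)
  r2 <- run_condition(plan, pmhc = 10, replicate = 1)
  expect_identical(r1$observations, r2$observations)
  expect_identical(r1$state$node, r2$state$node)
  plan0 <- tiny_plan()
  plan0$duration <- 0
  plan0$measurement_times <- 0
  r0 <- run_condition(plan0, pmhc = 10)
  expect_equal(nrow(r0$observations), 1)
  expect_equal(r0$observations$time, 0)
})

test_that("feature flags are inert when their mechanism is disabled", {
  plan <- tiny_plan()
  # with coupling off, the centripetal strength value cannot matter
  a <- run_condition(plan, pmhc = 20, coupling = FALSE)
  plan2 <- tiny_plan(forces = force_params(centripetal_strength = 0.9))
  b <- run_condition(plan2, pmhc = 20, coupling = FALSE)
  expect_identical(a$observations, b$observations)
  # foci disabled vs enabled with B = 1: identical molecular trajectory
  c0 <- run_condition(plan, pmhc = 20)
  c1 <- run_condition(plan, pmhc = 20, B = 1)
  mol <- !grepl("^foci", names(c0$observations))
  expect_identical(c0$observations[, mol], c1$observations[, mol])
})

test_that("pmhc_titration summarises replicates per density and time", {
  plan <- tiny_plan()
  ts <- pmhc_titration(plan)
  expect_s3_class(ts, "titration_summary")
  expect_equal(nrow(ts$summary), 4 * 2) # densities x times
  expect_equal(nrow(ts$per_replicate), 4 * 2 * 2)
  expect_true(all(ts$summary$n == 2))
  expect_true(all(ts$summary$sd_cell_kd >= 0, na.rm = TRUE))
  # summary means equal manual replicate means
  man <- ts$per_replicate |>
    dplyr::filter(.data$pmhc == 20, .data$time == 5) |>
    dplyr::pull(.data$cell_kd)
  got <- ts$summary |>
    dplyr::filter(.data$pmhc == 20, .data$time == 5) |>
    dplyr::pull(.data$mean_cell_kd)
  expect_equal(got, mean(man))
  # rerunning the same plan reproduces every cell exactly
  ts2 <- pmhc_titration(plan)
  expect_identical(ts$summary, ts2$summary)
  # tidiers
  expect_identical(tidy(ts), ts$summary)
  expect_identical(glance(ts), ts$minima)
  expect_s3_class(autoplot(ts), "ggplot")
})

test_that("flagged densities are excluded from minimum finding", {
  plan <- tiny_plan()
  plan$flag_density <- 5 # flags the first grid point
  ts <- pmhc_titration(plan)
  s5 <- dplyr::filter(ts$summary, .data$time == 5)
  expect_true(s5$flagged[s5$pmhc == 5])
  expect_false(any(s5$flagged[s5$pmhc > 5]))
  expect_true(all(ts$minima$n_usable == 3))
  expect_true(is.na(ts$minima$present[1])) # < 4 usable points
})

test_that("tcr_titration degenerates to pmhc_titration for one density", {
  plan <- tiny_plan()
  single <- tcr_titration(plan)
  direct <- pmhc_titration(plan)
  expect_identical(single$summary, direct$summary)
  expect_identical(single$minima, direct$minima)
})

test_that("b_sweep shares seeds across arms and reports one curve per B", {
  plan <- tiny_plan(b_grid = c(1, 2))
  sw <- b_sweep(plan)
  expect_setequal(unique(sw$summary$B), c(1, 2))
  expect_equal(nrow(sw$minima), 2 * 2) # B x times
  # paired seeds: the B = 1 arm equals a plain foci-off titration on
  # molecular outcomes
  plain <- pmhc_titration(plan)
  b1 <- dplyr::filter(sw$per_replicate, .data$B == 1)
  expect_equal(b1$n_bound_tcr_pmhc, plain$per_replicate$n_bound_tcr_pmhc)
  expect_equal(b1$cell_kd, plain$per_replicate$cell_kd)
})

test_that("detect_interior_minimum implements the pooled-SD rule", {
  # strictly decreasing: no interior minimum
  d <- c(1, 3, 10, 30, 100)
  out <- detect_interior_minimum(d, c(9, 7, 5, 3, 1), rep(0.1, 5))
  expect_false(out$present)
  # V-shape with small SDs: present at the trough
  out2 <- detect_interior_minimum(d, c(9, 4, 1, 4, 9), rep(0.5, 5))
  expect_true(out2$present)
  expect_equal(out2$argmin_density, 10)
  expect_equal(out2$min_value, 1)
  # flat curve with SD much larger than the range: noise guard
  out3 <- detect_interior_minimum(d, c(5, 4.9, 4.7, 4.9, 5), rep(3, 5))
  expect_false(out3$present)
  # insufficient data
  out4 <- detect_interior_minimum(d[1:3], c(3, 1, 3), rep(0.1, 3))
  expect_true(is.na(out4$present))
  expect_equal(out4$n_usable, 3)
  # NA points are dropped before the rule applies
  out5 <- detect_interior_minimum(d, c(9, 4, 1, 4, NA), rep(0.5, 5))
  expect_equal(out5$n_usable, 4)
})

test_that("windowed cellKD estimates average trailing recordings", {
  plan <- tiny_plan(kd_window = 2, kd_samples = 3)
  r <- run_condition(plan, pmhc = 20, replicate = 1)
  expect_true("cell_kd_instant" %in% names(r$observations))
  expect_equal(nrow(r$observations), 2)
  # the windowed value at t = 5 is the mean over recordings in (3, 5]
  plain <- tiny_plan()
  plain$measurement_times <- c(3, 4, 5)
  rr <- run_condition(plain, pmhc = 20, replicate = 1)
  expect_equal(r$observations$cell_kd[2],
               mean(rr$observations$cell_kd, na.rm = TRUE))
})
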