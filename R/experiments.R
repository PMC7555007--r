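#' Plan a batch of in silico synapse experiments
#'
#' Collects everything a titration or sweep needs: the density grids, the
#' number of replicate simulations per condition, the run duration and
#' measurement times, and the model parameter objects. Replicate `r` of a
#' condition gets a seed derived deterministically from `base_seed`, the
#' pMHC and TCR densities and `r` only, so arms that differ in the
#' binding coefficient or in coupling share seeds and are paired.
#'
#' Densities at or below `flag_density` (molecules/um^2) are simulated
#' but flagged: at such sparse pMHC the replicate-to-replicate spread of
#' `cellKD` is very large, so flagged points are excluded from
#' minimum-finding.
#'
#' @param pmhc_grid pMHC densities (molecules/um^2); default 8 log-spaced
#'   points spanning 1-100.
#' @param tcr_grid TCR densities; default the reference 18/um^2.
#' @param lfa1_density,icam1_density Adhesion-species densities, held
#'   fixed across sweeps.
#' @param b_grid Binding coefficients for [b_sweep()].
#' @param n_replicates Replicate simulations per condition.
#' @param base_seed Integer base seed.
#' @param duration Simulated time per run (s).
#' @param measurement_times Observation times (s).
#' @param config,rules,forces,foci Model components; see
#'   [lattice_config()], [default_binding_rules()], [force_params()],
#'   [foci_params()].
#' @param flag_density High-variance flagging threshold (molecules/um^2).
#' @param kd_window Trailing averaging window (s) for the per-replicate
#'   `cellKD` estimate at each measurement time: the reported value is the
#'   mean of `kd_samples` recordings spaced evenly over
#'   `(t - kd_window, t]`. 0 (the default) uses the instantaneous value at
#'   `t`. On small lattices molecule-number shot noise dominates the
#'   replicate spread, and a window much shorter than the pattern-forming
#'   timescale but a few complex lifetimes long averages it down without
#'   blurring the dynamics.
#' @param kd_samples Number of recordings per window.
#' @return An `experiment_plan` list.
#' @export
experiment_plan <- function(pmhc_grid = signif(10^seq(0, 2, length.out = 8), 3),
                            tcr_grid = 18,
                            lfa1_density = 50,
                            icam1_density = 50,
                            b_grid = c(0.1, 0.5, 1, 2, 10),
                            n_replicates = 10L,
                            base_seed = 1L,
                            duration = 600,
                            measurement_times = c(60, 120, 300, 600),
                            config = lattice_config(),
                            rules = default_binding_rules(),
                            forces = force_params(),
                            foci = foci_params(),
                            flag_density = 1,
                            kd_window = 0,
                            kd_samples = 5L) {
  if (length(pmhc_grid) == 0 || any(pmhc_grid <= 0)) {
    stop("`pmhc_grid` must be non-empty with positive densities",
         call. = FALSE)
  }
  if (length(tcr_grid) == 0 || any(tcr_grid <= 0)) {
    stop("`tcr_grid` must be non-empty with positive densities",
         call. = FALSE)
  }
  if (n_replicates < 1) stop("`n_replicates` must be >= 1", call. = FALSE)
  if (max(measurement_times) > duration + 1e-9) {
    stop("`measurement_times` must not exceed `duration`", call. = FALSE)
  }
  structure(
    list(pmhc_grid = sort(pmhc_grid), tcr_grid = sort(tcr_grid),
         lfa1_density = lfa1_density, icam1_density = icam1_density,
         b_grid = b_grid, n_replicates = as.integer(n_replicates),
         base_seed = as.integer(base_seed), duration = duration,
         measurement_times = sort(measurement_times),
         config = config, rules = rules, forces = forces, foci = foci,
         flag_density = flag_density,
         kd_window = kd_window, kd_samples = as.integer(kd_samples)),
    class = "experiment_plan"
  )
}

#' Deterministic replicate seed for a condition
#'
#' Hashes `(base_seed, pmhc, tcr, replicate)` into `[1, 2^31 - 2]`. The
#' binding coefficient and the coupling flag are deliberately excluded so
#' that sweep arms share seeds and are paired.
#'
#' @param base_seed Integer base seed.
#' @param pmhc,tcr Condition densities.
#' @param replicate Replicate number (1-based).
#' @return Integer seed.
#' @export
condition_seed <- function(base_seed, pmhc, tcr, replicate) {
  m <- 2147483629 # largest prime < 2^31
  h <- (round(pmhc * 1e6) %% m)
  h <- (h * 7919 + round(tcr * 1e6)) %% m
  h <- (h * 104729 + replicate * 7907) %% m
  h <- (h + base_seed * 31) %% m
  as.integer(h + 1)
}

plan_params <- function(plan, coupling = NULL, B = NULL) {
  forces <- plan$forces
  if (!is.null(coupling)) forces$coupling_enabled <- isTRUE(coupling)
  foci <- plan$foci
  if (!is.null(B)) {
    foci$B <- B
    foci$enabled <- TRUE
  }
  sim_params(config = plan$config, species = default_species(),
             rules = plan$rules, forces = forces, foci = foci)
}

#' Run one condition of an experiment plan
#'
#' Builds the initial state for the given densities, runs the simulation
#' to the plan's duration and records at the measurement times.
#' Deterministic for a given seed.
#'
#' @param plan An [experiment_plan()].
#' @param pmhc,tcr Densities for this condition (molecules/um^2).
#' @param replicate Replicate index (used for the seed).
#' @param coupling Optional override of the plan's coupling flag.
#' @param B Optional binding coefficient; supplying it enables the focus
#'   model for this run.
#' @param seed Optional explicit seed (otherwise [condition_seed()]).
#' @return A `synapse_run` (see [run_simulation()]) whose observations
#'   carry `pmhc`, `tcr`, `replicate`, `coupling` and `B` columns.
#' @export
run_condition <- function(plan, pmhc, tcr = plan$tcr_grid[1],
                          replicate = 1L, coupling = NULL, B = NULL,
                          seed = NULL) {
  params <- plan_params(plan, coupling, B)
  species <- default_species(tcr = tcr, pmhc = pmhc,
                             lfa1 = plan$lfa1_density,
                             icam1 = plan$icam1_density)
  params$species <- species
  seed <- seed %||% condition_seed(plan$base_seed, pmhc, tcr, replicate)
  state <- build_initial_state(plan$config, species, seed = seed)
  rec <- plan$measurement_times
  if (plan$kd_window > 0) {
    offs <- seq(plan$kd_window, 0, length.out = plan$kd_samples)
    rec <- unlist(lapply(plan$measurement_times, function(t) pmax(t - offs, 0)))
    rec <- sort(unique(rec))
  }
  run <- run_simulation(state, params, duration = plan$duration,
                        record_times = rec)
  obs <- run$observations
  if (plan$kd_window > 0) {
    # windowed cellKD estimate per requested time; other fields at t itself
    win_kd <- vapply(plan$measurement_times, function(t) {
      sel <- obs$time > t - plan$kd_window - 1e-9 & obs$time <= t + 1e-9
      mean(obs$cell_kd[sel], na.rm = TRUE)
    }, 0)
    win_kd[is.nan(win_kd)] <- NA_real_
    obs <- obs[match_times(obs$time, plan$measurement_times), , drop = FALSE]
    obs$cell_kd_instant <- obs$cell_kd
    obs$cell_kd <- win_kd
  }
  run$observations <- dplyr::mutate(
    obs,
    pmhc = pmhc, tcr = tcr, replicate = as.integer(replicate),
    coupling = params$forces$coupling_enabled, B = params$foci$B,
    .before = 1
  )
  run
}

# indices of the observation rows nearest at-or-after each requested time
match_times <- function(have, want) {
  vapply(want, function(t) which(have >= t - 1e-9)[1], integer(1))
}

summarise_replicates <- function(per_replicate, flag_density) {
  per_replicate |>
    dplyr::group_by(.data$pmhc, .data$tcr, .data$coupling, .data$B,
                    .data$time) |>
    dplyr::summarise(
      mean_cell_kd = mean(.data$cell_kd, na.rm = TRUE),
      sd_cell_kd = stats::sd(.data$cell_kd, na.rm = TRUE),
      n = dplyr::n(),
      n_defined = sum(!is.na(.data$cell_kd)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      mean_cell_kd = ifelse(.data$n_defined == 0, NA_real_,
                            .data$mean_cell_kd),
      flagged = .data$pmhc <= flag_density | .data$n_defined == 0
    )
}

titration_result <- function(summary, per_replicate, plan) {
  minima <- summary |>
    dplyr::group_by(.data$tcr, .data$coupling, .data$B, .data$time) |>
    dplyr::group_modify(function(df, key) {
      usable <- df[!df$flagged, ]
      dm <- detect_interior_minimum(usable$pmhc, usable$mean_cell_kd,
                                    usable$sd_cell_kd)
      tibble::tibble(
        present = dm$present, argmin_pmhc = dm$argmin_density,
        min_cell_kd = dm$min_value, pooled_sd = dm$pooled_sd,
        n_usable = dm$n_usable
      )
    }) |>
    dplyr::ungroup()
  structure(
    list(summary = summary, per_replicate = per_replicate, minima = minima,
         plan = plan),
    class = "titration_summary"
  )
}

#' pMHC titration at fixed TCR density
#'
#' Runs every (pMHC density x replicate) condition of the plan, summarises
#' `cellKD` per density and measurement time as the mean and SD of the
#' per-replicate values, and locates an interior minimum of the
#' mean-`cellKD` curve when one is present (see
#' [detect_interior_minimum()]).
#'
#' @param plan An [experiment_plan()].
#' @param tcr TCR density (defaults to the first entry of the plan's
#'   grid).
#' @param coupling,B Optional overrides passed to [run_condition()].
#' @param .progress Print one line per condition as the batch runs.
#' @return A `titration_summary`: list with tibbles `summary` (one row per
#'   density x time), `per_replicate`, and `minima` (one row per curve),
#'   plus the plan. Use [tidy()][generics::tidy] / `glance()` /
#'   `autoplot()` on it.
#' @export
pmhc_titration <- function(plan, tcr = plan$tcr_grid[1], coupling = NULL,
                           B = NULL, .progress = FALSE) {
  if (length(plan$pmhc_grid) < 4) {
    stop("`pmhc_grid` needs at least 4 densities to characterise a curve",
         call. = FALSE)
  }
  grid <- tidyr::expand_grid(pmhc = plan$pmhc_grid,
                             replicate = seq_len(plan$n_replicates))
  per_replicate <- purrr::pmap_dfr(grid, function(pmhc, replicate) {
    if (.progress) {
      message(sprintf("pmhc %.3g rep %d", pmhc, replicate))
    }
    run_condition(plan, pmhc = pmhc, tcr = tcr, replicate = replicate,
                  coupling = coupling, B = B)$observations
  })
  summary <- summarise_replicates(per_replicate, plan$flag_density)
  titration_result(summary, per_replicate, plan)
}

#' TCR titration: repeated pMHC titrations
#'
#' Repeats [pmhc_titration()] at every TCR density of the plan's grid and
#' reports, per TCR density, where the minimum `cellKD` falls (the argmin
#' pMHC density) and its value.
#'
#' @inheritParams pmhc_titration
#' @return A `titration_summary` whose tables carry a `tcr` column; its
#'   `minima` table holds one `(argmin_pmhc, min_cell_kd)` row per TCR
#'   density and measurement time.
#' @export
tcr_titration <- function(plan, coupling = NULL, B = NULL,
                          .progress = FALSE) {
  parts <- purrr::map(plan$tcr_grid, function(tcr) {
    pmhc_titration(plan, tcr = tcr, coupling = coupling, B = B,
                   .progress = .progress)
  })
  titration_result(
    purrr::map_dfr(parts, "summary"),
    purrr::map_dfr(parts, "per_replicate"),
    plan
  )
}

#' Binding-coefficient sweep
#'
#' Runs a pMHC titration for every binding coefficient in the plan's
#' `b_grid` with the focus model enabled, under shared (paired) replicate
#' seeds, and reports the minimum `cellKD` per `B`. Because the focus
#' automaton draws from its own random stream, the `B = 1` arm reproduces
#' the no-feedback kinetics exactly and serves as the control.
#'
#' @inheritParams pmhc_titration
#' @return A `titration_summary` whose tables carry a `B` column.
#' @export
b_sweep <- function(plan, tcr = plan$tcr_grid[1], coupling = NULL,
                    .progress = FALSE) {
  parts <- purrr::map(plan$b_grid, function(b) {
    pmhc_titration(plan, tcr = tcr, coupling = coupling, B = b,
                   .progress = .progress)
  })
  titration_result(
    purrr::map_dfr(parts, "summary"),
    purrr::map_dfr(parts, "per_replicate"),
    plan
  )
}

#' Detect an interior minimum of a cellKD-versus-density curve
#'
#' The minimum is called "interior" when the argmin is not an endpoint of
#' the usable grid and both the first and the last usable points exceed
#' the minimum by more than one pooled SD (the root mean square of the
#' per-point replicate SDs). This operationalises the visual judgement of
#' a curve that falls, reaches a minimum and rises again, with the pooled
#' SD guarding against calling noise on a flat curve.
#'
#' @param density Densities of the usable points (ascending).
#' @param mean_kd Mean `cellKD` per point.
#' @param sd_kd Replicate SD per point.
#' @return List with `present` (logical; `NA` when fewer than 4 usable
#'   points), `argmin_density`, `min_value`, `pooled_sd`, `n_usable`.
#' @examples
#' detect_interior_minimum(c(1, 3, 10, 30), c(5, 2, 1, 4), rep(0.3, 4))
#' @export
detect_interior_minimum <- function(density, mean_kd, sd_kd) {
  ok <- !is.na(mean_kd)
  density <- density[ok]
  mean_kd <- mean_kd[ok]
  sd_kd <- sd_kd[ok]
  n <- length(density)
  if (n < 4) {
    return(list(present = NA, argmin_density = NA_real_,
                min_value = NA_real_, pooled_sd = NA_real_, n_usable = n))
  }
  o <- order(density)
  density <- density[o]; mean_kd <- mean_kd[o]; sd_kd <- sd_kd[o]
  i <- which.min(mean_kd)
  pooled <- sqrt(mean(sd_kd^2, na.rm = TRUE))
  present <- i != 1 && i != n &&
    (mean_kd[1] - mean_kd[i]) > pooled &&
    (mean_kd[n] - mean_kd[i]) > pooled
  list(present = present, argmin_density = density[i],
       min_value = mean_kd[i], pooled_sd = pooled, n_usable = n)
}

#' @export
print.titration_summary <- function(x, ...) {
  cat("<titration_summary> ", nrow(x$per_replicate), " replicate rows, ",
      nrow(x$summary), " summary rows\n", sep = "")
  print(x$minima)
  invisible(x)
}
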