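#' In situ dissociation constant from surface densities
#'
#' `cellKD = [TCR_free] * [pMHC_free] / [TCR-pMHC]`, the inverse of the
#' observed TCR-pMHC affinity, in molecules per um^2. Vectorised; the
#' value is undefined (`NA`) when no complexes are present, and propagates
#' as missing data rather than raising an error.
#'
#' @param free_tcr,free_pmhc,bound Densities (or counts over a common
#'   area) of free TCR, free pMHC and TCR-pMHC complexes; all `>= 0`.
#' @return `free_tcr * free_pmhc / bound`, `NA_real_` where `bound == 0`.
#' @examples
#' compute_cell_kd(10, 5, 25) # 2
#' compute_cell_kd(10, 5, 0)  # NA: undefined without complexes
#' @export
compute_cell_kd <- function(free_tcr, free_pmhc, bound) {
  stopifnot(all(free_tcr >= 0, na.rm = TRUE),
            all(free_pmhc >= 0, na.rm = TRUE),
            all(bound >= 0, na.rm = TRUE))
  out <- free_tcr * free_pmhc / bound
  out[!is.na(bound) & bound == 0] <- NA_real_
  out
}

obs_tibble <- function(time, counts, config, foci) {
  area <- config$active_area
  dens <- counts / area
  tibble::tibble(
    time = time,
    free_tcr = dens[1], free_pmhc = dens[2], bound_tcr_pmhc = dens[3],
    free_lfa1 = dens[4], free_icam1 = dens[5], bound_lfa1_icam1 = dens[6],
    cell_kd = compute_cell_kd(dens[1], dens[2], dens[3]),
    n_free_tcr = counts[1], n_free_pmhc = counts[2],
    n_bound_tcr_pmhc = counts[3], n_free_lfa1 = counts[4],
    n_free_icam1 = counts[5], n_bound_lfa1_icam1 = counts[6],
    foci_nucleation = foci[1], foci_nucleation_polymerized = foci[2],
    foci_polymerization = foci[3], foci_clusters = foci[4]
  )
}

# convert the engine's observation matrix into the tidy observation table
engine_obs_tibble <- function(obs, config) {
  if (nrow(obs) == 0) {
    return(obs_tibble(numeric(0), matrix(0, 0, 6), config, numeric(0))[0, ])
  }
  dplyr::bind_rows(lapply(seq_len(nrow(obs)), function(i) {
    obs_tibble(obs[i, 1], obs[i, 2:7], config, obs[i, 8:11])
  }))
}

#' Record an observation from a state
#'
#' Counts agents per species and bond status over the active area,
#' converts to densities (molecules/um^2), computes [compute_cell_kd()]
#' and attaches the focus-lattice summary and the clock.
#'
#' @param state A `synapse_state`.
#' @return A one-row tibble: `time`, densities `free_tcr`, `free_pmhc`,
#'   `bound_tcr_pmhc`, `free_lfa1`, `free_icam1`, `bound_lfa1_icam1`,
#'   `cell_kd`, the matching raw counts `n_*`, and focus-state counts.
#' @export
record_observation <- function(state) {
  sp <- state$species_code
  bound <- state$partner >= 0L
  counts <- c(
    sum(sp == 0L & !bound), sum(sp == 1L & !bound), sum(sp == 0L & bound),
    sum(sp == 2L & !bound), sum(sp == 3L & !bound), sum(sp == 2L & bound)
  )
  fs <- foci_summary(state)
  obs_tibble(state$clock, counts, state$config,
             c(fs$nucleation, fs$nucleation_polymerized, fs$polymerization,
               fs$foci_clusters))
}

#' Radial occupancy profile
#'
#' Bins the active disk into `n_bins` equal-width annuli from the centre
#' to `synapse_radius` and reports, per annulus and per population,
#' counts and densities. Annulus areas are measured as (number of active
#' nodes in the annulus) x node area, so a uniformly occupied lattice
#' gives equal densities in expectation and per-annulus counts always sum
#' to the whole-domain counts.
#'
#' @param state A `synapse_state`.
#' @param n_bins Number of annuli (>= 2).
#' @return Tibble with columns `bin`, `r_inner`, `r_outer`, `r_mid` (um),
#'   `population` (`free_TCR`, `free_pMHC`, `bound_TCR_pMHC`, `free_LFA1`,
#'   `free_ICAM1`, `bound_LFA1_ICAM1`), `count`, `area` (um^2), `density`.
#' @export
radial_profile <- function(state, n_bins = 7L) {
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("`n_bins` must be >= 2", call. = FALSE)
  cfg <- state$config
  L <- cfg$nodes_per_side
  centre <- (L - 1) / 2
  breaks <- seq(0, cfg$synapse_radius, length.out = n_bins + 1L)

  node_r <- function(n0) {
    sqrt((n0 %% L - centre)^2 + (n0 %/% L - centre)^2) * cfg$node_spacing
  }
  bin_of <- function(r) pmin(pmax(findInterval(r, breaks,
                                               rightmost.closed = TRUE), 1L),
                             n_bins)
  # areas from active-node membership
  act_r <- node_r(which(cfg$active) - 1L)
  nodes_per_bin <- tabulate(bin_of(act_r), nbins = n_bins)
  area <- nodes_per_bin * cfg$node_spacing^2

  sp <- state$species_code
  bound <- state$partner >= 0L
  pops <- list(
    free_TCR = sp == 0L & !bound, free_pMHC = sp == 1L & !bound,
    bound_TCR_pMHC = sp == 0L & bound, free_LFA1 = sp == 2L & !bound,
    free_ICAM1 = sp == 3L & !bound, bound_LFA1_ICAM1 = sp == 2L & bound
  )
  r_all <- node_r(state$node)
  purrr::map_dfr(names(pops), function(p) {
    cnt <- tabulate(bin_of(r_all[pops[[p]]]), nbins = n_bins)
    tibble::tibble(
      bin = seq_len(n_bins),
      r_inner = breaks[-(n_bins + 1L)], r_outer = breaks[-1L],
      r_mid = (breaks[-(n_bins + 1L)] + breaks[-1L]) / 2,
      population = p, count = cnt, area = area,
      density = ifelse(area > 0, cnt / area, NA_real_)
    )
  })
}

#' Extract observations at given measurement times
#'
#' @param trajectory Observation tibble of a [run_simulation()] result (or
#'   the result itself), with recordings at least as late as every
#'   requested time.
#' @param times Measurement times in seconds; the recording at the nearest
#'   recorded time at or after each requested time is returned. Defaults
#'   to the 1/2/5/10-minute readouts.
#' @return Tibble of observations, strictly increasing in `time`, with a
#'   `requested_time` column.
#' @export
measure_at_times <- function(trajectory, times = c(60, 120, 300, 600)) {
  obs <- if (inherits(trajectory, "synapse_run")) {
    trajectory$observations
  } else trajectory
  obs <- dplyr::arrange(obs, .data$time)
  if (any(times > max(obs$time) + 1e-9)) {
    stop("requested time beyond the recorded trajectory (max ",
         max(obs$time), " s)", call. = FALSE)
  }
  rows <- vapply(times, function(t) {
    which(obs$time >= t - 1e-9)[1]
  }, integer(1))
  out <- obs[rows, , drop = FALSE]
  out$requested_time <- times
  dplyr::relocate(out, "requested_time")
}
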