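#' Per-step kinetic probabilities
#'
#' Derives the per-step probabilities the engine consumes from physical
#' parameters: move probabilities `p_move = 4 * D * tau / node_spacing^2`
#' per species (and per complex, using the slower partner's diffusion
#' coefficient unless overridden), association probabilities
#' `p_on = tau / tau_on` per rule (before any binding-coefficient
#' multiplier), and dissociation probabilities
#' `p_off = 1 - exp(-koff * tau)`.
#'
#' @param config A [lattice_config()].
#' @param species Species tibble ([default_species()]).
#' @param rules Rules tibble ([default_binding_rules()]).
#' @param complex_diffusion Optional named numeric,
#'   `c("TCR:pMHC" = ..., "LFA1:ICAM1" = ...)` in um^2/s. Bound complexes
#'   engage the actin cortex and are nearly immobile diffusively compared
#'   with free molecules; the default is 0.005 um^2/s for both pairs.
#' @return List with `p_move_species` (named, TCR/pMHC/LFA1/ICAM1 order),
#'   `p_move_complex`, `p_on`, `p_off`, `tau_on`.
#' @examples
#' kinetics_params(lattice_config(), default_species(), default_binding_rules())
#' @export
kinetics_params <- function(config, species, rules,
                            complex_diffusion = NULL) {
  a2 <- config$node_spacing^2
  D <- stats::setNames(rep(0, 4), SPECIES_NAMES)
  D[species$name] <- species$diffusion_coefficient
  p_move <- 4 * D * config$tau / a2
  if (any(p_move > 1 + 1e-12)) {
    stop("diffusion stability bound violated: 4*D*tau/node_spacing^2 > 1 for ",
         paste(names(p_move)[p_move > 1], collapse = ", "),
         "; reduce tau or D, or enlarge node_spacing", call. = FALSE)
  }
  pairs <- c("TCR:pMHC", "LFA1:ICAM1")
  Dcx <- stats::setNames(c(0.005, 0.005), pairs)
  if (!is.null(complex_diffusion)) {
    Dcx[names(complex_diffusion)] <- complex_diffusion
  }
  p_move_cx <- pmin(4 * Dcx * config$tau / a2, 1)
  t_on <- stats::setNames(rep(Inf, 2), pairs)
  p_off <- stats::setNames(rep(0, 2), pairs)
  for (i in seq_len(nrow(rules))) {
    t_on[rules$pair[i]] <- tau_on(rules$kon[i], config)
    p_off[rules$pair[i]] <- 1 - exp(-rules$koff[i] * config$tau)
  }
  p_on <- config$tau / t_on
  list(
    p_move_species = p_move,
    p_move_complex = p_move_cx,
    p_on = p_on,
    p_off = p_off,
    tau_on = t_on
  )
}

#' Bundle all simulation parameters
#'
#' A single object carrying the lattice configuration, species, binding
#' rules, force and focus parameters, and the global binding-coefficient
#' multiplier. All stepping functions and experiment drivers take one of
#' these.
#'
#' @param config A [lattice_config()].
#' @param species Species tibble.
#' @param rules Binding rules tibble.
#' @param forces A [force_params()].
#' @param foci A [foci_params()].
#' @param B_global Global multiplier on association probabilities
#'   (applied to both pairs; the focus feedback field additionally
#'   multiplies the TCR-pMHC probability at focus nodes).
#' @param complex_diffusion See [kinetics_params()].
#' @return A `sim_params` object.
#' @export
sim_params <- function(config = lattice_config(),
                       species = default_species(),
                       rules = default_binding_rules(),
                       forces = force_params(),
                       foci = foci_params(),
                       B_global = 1,
                       complex_diffusion = NULL) {
  stopifnot(inherits(config, "lattice_config"))
  if (B_global < 0) stop("`B_global` must be >= 0", call. = FALSE)
  kin <- kinetics_params(config, species, rules, complex_diffusion)
  p <- list(
    config = config, species = species, rules = rules,
    forces = forces, foci = foci, B_global = B_global,
    kinetics = kin
  )
  class(p) <- "sim_params"
  p
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params> p_on:",
      paste(sprintf("%s %.3g", names(x$kinetics$p_on), x$kinetics$p_on),
            collapse = ", "),
      "| p_off:",
      paste(sprintf("%.3g", x$kinetics$p_off), collapse = ", "),
      "| coupling", if (x$forces$coupling_enabled) "on" else "off",
      "| foci", if (x$foci$enabled) sprintf("on (B = %g)", x$foci$B) else "off",
      "\n")
  invisible(x)
}

# engine plumbing ----------------------------------------------------------

engine_state <- function(state) {
  cfg <- state$config
  list(
    L = cfg$nodes_per_side,
    spacing = cfg$node_spacing,
    radius = cfg$synapse_radius,
    tau = cfg$tau,
    active = as.integer(cfg$active),
    species = state$species_code,
    node = state$node,
    partner = state$partner,
    fstate = state$fstate,
    fage = state$fage,
    step = as.numeric(state$step)
  )
}

engine_params <- function(params, seed, b_field = NULL,
                          check_invariants = FALSE,
                          collect_lifetimes = FALSE,
                          track_nodes = FALSE) {
  list(
    p_move_species = unname(params$kinetics$p_move_species),
    p_move_complex = unname(params$kinetics$p_move_complex),
    p_on = unname(params$kinetics$p_on),
    p_off = unname(params$kinetics$p_off),
    B_global = params$B_global,
    coupling_enabled = params$forces$coupling_enabled,
    sbs_strength = params$forces$sbs_strength,
    centripetal_strength = c(params$forces$centripetal_strength,
                             params$forces$centripetal_strength_adhesion %||%
                               params$forces$centripetal_strength),
    R_force = params$forces$R_force,
    sbs_inverse_r = identical(params$forces$kernel, "inverse_r"),
    force_update_interval = params$forces$force_update_interval,
    foci_enabled = params$foci$enabled,
    feedback_all_states = params$foci$feedback_all_states,
    p_nucleate = params$foci$p_nucleate,
    p_nuc_polymerize = params$foci$p_nuc_polymerize,
    p_polymerize = params$foci$p_polymerize,
    p_decay = params$foci$p_decay,
    B = params$foci$B,
    R_neighborhood = params$foci$R_neighborhood,
    b_field = b_field,
    seed = as.numeric(seed),
    check_invariants = check_invariants,
    collect_lifetimes = collect_lifetimes,
    track_nodes = track_nodes
  )
}

apply_engine_result <- function(state, res) {
  state$node <- res$node
  state$partner <- res$partner
  state$fstate <- res$fstate
  state$fage <- res$fage
  state$step <- res$step
  state$clock <- res$step * state$config$tau
  state
}

run_engine <- function(state, params, n_steps, record_steps = integer(0),
                       phases = c("move", "unbind", "bind", "foci"),
                       seed = NULL, b_field = NULL,
                       check_invariants = FALSE, collect_lifetimes = FALSE,
                       track_nodes = FALSE) {
  seed <- seed %||% state$seed
  ph <- list(
    move = "move" %in% phases,
    unbind = "unbind" %in% phases,
    bind = "bind" %in% phases,
    foci = "foci" %in% phases
  )
  res <- cpp_run(
    engine_state(state),
    engine_params(params, seed, b_field, check_invariants,
                  collect_lifetimes, track_nodes),
    as.integer(n_steps),
    as.integer(record_steps),
    ph
  )
  list(state = apply_engine_result(state, res), raw = res)
}

# stepping operations ------------------------------------------------------

#' Advance diffusion by one timestep
#'
#' Every mobile unit (free agent, or bound pair moving as one unit on both
#' lattices) attempts a move with its per-step move probability. Free
#' agents pick a uniformly random von Neumann neighbour; bound complexes
#' draw their direction from the combined force-biased distribution over
#' the candidate set stay + 4 neighbours (see [sbs_bias()],
#' [centripetal_bias()]), so their unbiased effective diffusivity is 4/5
#' of the nominal complex coefficient. Moves onto occupied or inactive
#' nodes are rejected, preserving one-agent-per-node exclusion; units are
#' updated in a fresh random order each step.
#'
#' @param state A `synapse_state`.
#' @param params A [sim_params()].
#' @param seed Stream seed (defaults to the state's stored seed; the
#'   current step number is mixed in, so repeated calls draw fresh
#'   randomness).
#' @return The advanced state.
#' @export
step_diffusion <- function(state, params, seed = NULL) {
  run_engine(state, params, 1L, phases = "move", seed = seed)$state
}

#' Attempt complex formation at colocalised nodes
#'
#' For every node where a free receptor sits opposite its free ligand
#' (identical node index on the two lattices), a complex forms with
#' probability `clamp(b * B_global * tau / tau_on, 0, 1)`, where `b` is the
#' focus feedback multiplier at that node (TCR-pMHC only; 1 everywhere for
#' the adhesion pair or when the focus model is disabled).
#'
#' @inheritParams step_diffusion
#' @param b_field Optional explicit per-node multiplier vector (length
#'   `nodes_per_side^2`) overriding the focus feedback field.
#' @return The state after one binding sweep (clock advanced by one step).
#' @export
attempt_binding <- function(state, params, seed = NULL, b_field = NULL) {
  run_engine(state, params, 1L, phases = "bind", seed = seed,
             b_field = b_field)$state
}

#' Attempt complex dissociation
#'
#' Each bound pair dissociates with probability `1 - exp(-koff * tau)`;
#' both members become free at their shared node.
#'
#' @inheritParams step_diffusion
#' @return The state after one unbinding sweep.
#' @export
attempt_unbinding <- function(state, params, seed = NULL) {
  run_engine(state, params, 1L, phases = "unbind", seed = seed)$state
}

#' One full simulation step
#'
#' Applies, in order: force-biased movement, unbinding, binding (with the
#' current focus feedback field), and the focus automaton update; then
#' advances the clock by `tau`.
#'
#' @inheritParams step_diffusion
#' @return The advanced state.
#' @export
simulation_step <- function(state, params, seed = NULL) {
  run_engine(state, params, 1L, seed = seed)$state
}

#' Run a simulation for a given duration
#'
#' Advances the state by `round(duration / tau)` steps and records an
#' observation at each requested time (nearest step at or after the time).
#'
#' @inheritParams step_diffusion
#' @param duration Simulated time in seconds.
#' @param record_times Numeric vector of times (s) at which to record
#'   observations; defaults to the endpoint only. Time 0 records the
#'   initial state.
#' @param check_invariants If `TRUE` the engine asserts exclusion,
#'   conservation and pair-consistency after every step (slow; for tests).
#' @param collect_lifetimes If `TRUE`, returns the lifetime (s) of every
#'   TCR-pMHC complex that dissociated during the run.
#' @param track_times Optional times at which to snapshot every agent's
#'   node index (for displacement analyses); returned as a matrix.
#' @return A list of class `synapse_run`: `state` (final), `observations`
#'   (tibble, one row per recorded time; see [record_observation()]),
#'   `lifetimes`, `tracked` (agents x times matrix of 1-based node
#'   indices, when requested), and `clamp_events` (number of association
#'   draws whose probability had to be clamped to 1).
#' @examples
#' cfg <- lattice_config(nodes_per_side = 32, synapse_radius = 1.1)
#' st <- build_initial_state(cfg, default_species(pmhc = 10), seed = 1)
#' pars <- sim_params(config = cfg)
#' run <- run_simulation(st, pars, duration = 1, record_times = c(0.5, 1))
#' run$observations
#' @export
run_simulation <- function(state, params, duration,
                           record_times = NULL, seed = NULL,
                           check_invariants = FALSE,
                           collect_lifetimes = FALSE,
                           track_times = NULL) {
  tau <- state$config$tau
  n_steps <- round(duration / tau)
  record_times <- record_times %||% duration
  rec0 <- any(record_times <= 0)
  rec_steps <- sort(unique(pmin(ceiling(record_times[record_times > 0] / tau -
                                          1e-9), n_steps)))
  track_steps <- if (!is.null(track_times)) {
    sort(unique(pmin(ceiling(track_times / tau - 1e-9), n_steps)))
  } else NULL
  all_steps <- sort(unique(c(rec_steps, track_steps)))

  obs0 <- if (rec0) record_observation(state) else NULL
  step0 <- state$step
  out <- run_engine(state, params, n_steps, record_steps = all_steps,
                    seed = seed, check_invariants = check_invariants,
                    collect_lifetimes = collect_lifetimes,
                    track_nodes = !is.null(track_times))
  obs <- engine_obs_tibble(out$raw$obs, state$config)
  keep <- obs$time %in% ((step0 + rec_steps) * tau)
  obs <- obs[keep, , drop = FALSE]
  if (!is.null(obs0)) obs <- dplyr::bind_rows(obs0, obs)

  tracked <- NULL
  if (!is.null(track_times)) {
    tracked <- out$raw$tracked[, match(track_steps, all_steps), drop = FALSE] + 1L
    colnames(tracked) <- as.character(track_steps * tau)
  }
  structure(
    list(state = out$state, observations = obs,
         lifetimes = out$raw$lifetimes, tracked = tracked,
         clamp_events = out$raw$clamp_events),
    class = "synapse_run"
  )
}

#' @export
print.synapse_run <- function(x, ...) {
  cat("<synapse_run> ", nrow(x$observations), " observation(s), final t = ",
      x$state$clock, " s\n", sep = "")
  print(x$observations)
  invisible(x)
}
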