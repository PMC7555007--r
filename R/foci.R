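#' F-actin focus automaton parameters
#'
#' A third lattice carries a per-node state machine with states `empty`,
#' `nucleation`, `nucleation_polymerized` and `polymerization`, driven by
#' the complexes on the molecular lattices:
#'
#' * `empty -> nucleation` with `p_nucleate` per step when a TCR-pMHC
#'   complex occupies the node;
#' * `nucleation -> nucleation_polymerized` with `p_nuc_polymerize` when
#'   an LFA-1-ICAM-1 complex is colocalised at the identical node;
#' * `nucleation` or `nucleation_polymerized -> polymerization` with
#'   `p_polymerize` when at least one LFA-1-ICAM-1 complex lies within
#'   `R_neighborhood` of the node;
#' * every non-empty state self-inhibits back to `empty` with `p_decay`.
#'
#' Clusters of `polymerization` nodes are the model's F-actin foci. Formed
#' foci feed back on TCR-pMHC association: the binding probability at a
#' focus node is multiplied by the binding coefficient `B` (`B > 1`
#' positive feedback, `B < 1` negative feedback, `B = 1` no feedback).
#'
#' The automaton consumes a dedicated random stream, so a run with the
#' focus model enabled at `B = 1` reproduces the exact kinetic trajectory
#' of a run with it disabled.
#'
#' @param enabled Logical master switch.
#' @param R_neighborhood Neighbourhood radius in micrometres for the
#'   polymerisation rule.
#' @param p_nucleate,p_nuc_polymerize,p_polymerize,p_decay Per-step
#'   transition probabilities.
#' @param B Binding coefficient applied at focus nodes.
#' @param feedback_all_states If `TRUE`, every non-empty focus state (not
#'   only `polymerization`) exerts the feedback.
#' @return A `foci_params` list.
#' @export
foci_params <- function(enabled = FALSE,
                        R_neighborhood = 0.35,
                        p_nucleate = 0.1,
                        p_nuc_polymerize = 0.1,
                        p_polymerize = 0.05,
                        p_decay = 0.01,
                        B = 1,
                        feedback_all_states = FALSE) {
  probs <- c(p_nucleate, p_nuc_polymerize, p_polymerize, p_decay)
  if (any(probs < 0 | probs > 1)) {
    stop("focus transition probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (R_neighborhood < 0) stop("`R_neighborhood` must be >= 0", call. = FALSE)
  if (B < 0) stop("`B` must be >= 0", call. = FALSE)
  structure(
    list(enabled = isTRUE(enabled), R_neighborhood = R_neighborhood,
         p_nucleate = p_nucleate, p_nuc_polymerize = p_nuc_polymerize,
         p_polymerize = p_polymerize, p_decay = p_decay, B = B,
         feedback_all_states = isTRUE(feedback_all_states)),
    class = "foci_params"
  )
}

FOCI_STATES <- c("empty", "nucleation", "nucleation_polymerized",
                 "polymerization")

#' Advance the focus automaton by one step
#'
#' Applies the transition rules of [foci_params()] once, per node, reading
#' the current complex configuration; the molecular lattices are not
#' modified. Requires `params$foci$enabled`.
#'
#' @inheritParams step_diffusion
#' @return The state with updated focus lattice (clock advanced one step).
#' @export
update_foci <- function(state, params, seed = NULL) {
  if (!params$foci$enabled) {
    stop("the focus model is disabled in `params`; set ",
         "`foci_params(enabled = TRUE)`", call. = FALSE)
  }
  run_engine(state, params, 1L, phases = "foci", seed = seed)$state
}

#' Focus feedback field
#'
#' Per-node multiplier on the TCR-pMHC association probability: `B` at
#' every node whose focus state exerts feedback (by default only
#' `polymerization`, the formed foci), 1 elsewhere.
#'
#' @param state A `synapse_state` (or an integer focus-state vector).
#' @param params A [foci_params()] (or a [sim_params()], whose `foci`
#'   component is used).
#' @return Numeric vector of per-node multipliers (row-major node order).
#' @export
feedback_field <- function(state, params) {
  fp <- if (inherits(params, "sim_params")) params$foci else params
  fstate <- if (inherits(state, "synapse_state")) state$fstate else state
  field <- rep(1, length(fstate))
  sel <- if (fp$feedback_all_states) fstate > 0L else fstate == 3L
  field[sel] <- fp$B
  field
}

#' Summarise the focus lattice
#'
#' @param state A `synapse_state` (or an integer focus-state vector, in
#'   which case `L` must be given).
#' @param L Lattice side when a bare vector is passed.
#' @return A one-row tibble with per-state node counts and the number of
#'   4-connected clusters of `polymerization` nodes (the focus count).
#' @export
foci_summary <- function(state, L = NULL) {
  if (inherits(state, "synapse_state")) {
    fstate <- state$fstate
    L <- state$config$nodes_per_side
  } else {
    fstate <- state
    if (is.null(L)) L <- as.integer(sqrt(length(fstate)))
  }
  counts <- tabulate(fstate + 1L, nbins = 4L)
  tibble::tibble(
    empty = counts[1], nucleation = counts[2],
    nucleation_polymerized = counts[3], polymerization = counts[4],
    foci_clusters = cpp_cluster_count(as.integer(fstate), as.integer(L), 3L)
  )
}
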