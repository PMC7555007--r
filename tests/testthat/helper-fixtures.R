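# Small deterministic fixtures built in code.

# a compact lattice for cheap runs (odd side so the centre is a node)
small_config <- function(nodes_per_side = 33, synapse_radius = 1.1,
                         tau = 0.01, ...) {
  lattice_config(nodes_per_side = nodes_per_side,
                 synapse_radius = synapse_radius, tau = tau, ...)
}

# 0-based node index at offset (dx, dy) nodes from the lattice centre;
# requires an odd lattice side
node_at <- function(config, dx = 0, dy = 0) {
  L <- config$nodes_per_side
  stopifnot(L %% 2 == 1)
  c0 <- (L - 1) / 2
  as.integer((c0 + dy) * L + (c0 + dx))
}

# build a state with hand-placed agents.
# `agents`: data.frame with columns species (name), node (0-based), and
# optionally partner (1-based row index of the partner agent, NA if free)
make_state <- function(config, agents, species_table = default_species(0, 0, 0, 0),
                       seed = 1L) {
  st <- build_initial_state(config, species_table, seed = seed)
  code <- match(agents$species, c("TCR", "pMHC", "LFA1", "ICAM1")) - 1L
  stopifnot(!anyNA(code))
  st$species_code <- as.integer(code)
  st$node <- as.integer(agents$node)
  partner <- if ("partner" %in% names(agents)) agents$partner else {
    rep(NA_integer_, nrow(agents))
  }
  st$partner <- as.integer(ifelse(is.na(partner), -1L, partner - 1L))
  st
}

# agents data.frame for a bound pair of the given kind at a node
bound_pair <- function(node, kind = c("TCR:pMHC", "LFA1:ICAM1"), offset = 0L) {
  kind <- match.arg(kind)
  sp <- if (kind == "TCR:pMHC") c("TCR", "pMHC") else c("LFA1", "ICAM1")
  data.frame(species = sp, node = c(node, node),
             partner = c(2L, 1L) + offset)
}

# many bound TCR-pMHC pairs on distinct nodes of a config
bound_pairs_state <- function(config, n_pairs, kind = "TCR:pMHC", seed = 5L) {
  nodes <- which(config$active)[seq_len(n_pairs)] - 1L
  rows <- do.call(rbind, lapply(seq_len(n_pairs), function(i) {
    bound_pair(nodes[i], kind, offset = 2L * (i - 1L))
  }))
  make_state(config, rows, seed = seed)
}

# params with everything inert unless switched on
quiet_params <- function(config,
                         species = default_species(0, 0, 0, 0),
                         rules = default_binding_rules(),
                         forces = force_params(sbs_strength = 0,
                                               centripetal_strength = 0,
                                               coupling_enabled = FALSE),
                         foci = foci_params(enabled = FALSE),
                         ...) {
  sim_params(config = config, species = species, rules = rules,
             forces = forces, foci = foci, ...)
}

expect_valid_weights <- function(w) {
  expect_true(all(w >= 0))
  expect_equal(sum(w), 1, tolerance = 1e-12)
}
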