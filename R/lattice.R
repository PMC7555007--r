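#' Lattice geometry and timestep configuration
#'
#' Defines the paired square lattices on which the synapse model runs: a
#' grid of `nodes_per_side` x `nodes_per_side` nodes with physical spacing
#' `node_spacing` (micrometres), of which only the disk of radius
#' `synapse_radius` around the centre is active. The same geometry is
#' shared by the T cell lattice, the bilayer (APC) lattice and the F-actin
#' focus lattice. The timestep `tau` converts rate constants into per-step
#' probabilities, and `membrane_gap_height` closes the inter-membrane
#' interaction volume `V = node_spacing^2 * membrane_gap_height` used to
#' turn a molar on-rate into the characteristic association time
#' `tau_on = V * N_A / kon`.
#'
#' @param nodes_per_side Integer, nodes per lattice side (>= 8).
#' @param node_spacing Node spacing in micrometres. The default 0.081 um
#'   corresponds to one coarse-grained molecular footprint per node and
#'   puts the bilayer lattice close to single-occupancy packing at the
#'   top of the experimentally explored density range (around 150
#'   molecules/um^2 of pMHC plus ICAM-1), so that molecular crowding
#'   becomes rate-limiting exactly where excessive ligand densities are
#'   being simulated.
#' @param synapse_radius Radius of the circular active domain in
#'   micrometres. Must fit inside the square lattice.
#' @param tau Timestep in seconds.
#' @param membrane_gap_height Inter-membrane gap in micrometres used to
#'   form the interaction volume.
#' @return A `lattice_config` object (list) with the supplied fields plus
#'   derived quantities: `interaction_volume_l` (litres), `active` (logical
#'   occupancy mask as a vector in row-major node order), `n_active`, and
#'   `active_area` (um^2 covered by active nodes).
#' @examples
#' cfg <- lattice_config(nodes_per_side = 32, synapse_radius = 1.1)
#' cfg$n_active
#' @export
lattice_config <- function(nodes_per_side = 89L,
                           node_spacing = 0.081,
                           synapse_radius = 3.5,
                           tau = 0.01,
                           membrane_gap_height = 0.015) {
  nodes_per_side <- as.integer(nodes_per_side)
  if (nodes_per_side < 8L) {
    stop("`nodes_per_side` must be at least 8", call. = FALSE)
  }
  if (node_spacing <= 0 || tau <= 0 || membrane_gap_height <= 0) {
    stop("`node_spacing`, `tau` and `membrane_gap_height` must be positive",
         call. = FALSE)
  }
  if (synapse_radius > nodes_per_side * node_spacing / 2) {
    stop("`synapse_radius` exceeds half the lattice side; enlarge ",
         "`nodes_per_side` or shrink the radius", call. = FALSE)
  }
  L <- nodes_per_side
  centre <- (L - 1) / 2
  xy <- node_grid_xy(L)
  r_nodes <- sqrt((xy$x - centre)^2 + (xy$y - centre)^2)
  active <- r_nodes * node_spacing <= synapse_radius
  cfg <- list(
    nodes_per_side = L,
    node_spacing = node_spacing,
    synapse_radius = synapse_radius,
    tau = tau,
    membrane_gap_height = membrane_gap_height,
    # V in litres: um^3 -> L is 1e-15
    interaction_volume_l = node_spacing^2 * membrane_gap_height * 1e-15,
    active = active,
    n_active = sum(active),
    active_area = sum(active) * node_spacing^2
  )
  class(cfg) <- "lattice_config"
  cfg
}

# row-major 0-based node coordinates for a lattice of side L
node_grid_xy <- function(L) {
  n <- seq_len(L * L) - 1L
  list(x = n %% L, y = n %/% L)
}

#' @export
print.lattice_config <- function(x, ...) {
  cat("<lattice_config> ", x$nodes_per_side, "x", x$nodes_per_side,
      " nodes, spacing ", x$node_spacing, " um, synapse radius ",
      x$synapse_radius, " um (", x$n_active, " active nodes, ",
      signif(x$active_area, 4), " um^2), tau ", x$tau, " s\n", sep = "")
  invisible(x)
}

# species bookkeeping ------------------------------------------------------

SPECIES_NAMES <- c("TCR", "pMHC", "LFA1", "ICAM1")
SPECIES_SIDE <- c(TCR = "tcell", pMHC = "apc", LFA1 = "tcell", ICAM1 = "apc")
SPECIES_SIZE <- c(TCR = "short", pMHC = "short", LFA1 = "long", ICAM1 = "long")
# defaults: TCR/LFA-1 diffuse slower on the T cell membrane than their
# ligands on the supported bilayer
SPECIES_D <- c(TCR = 0.05, pMHC = 0.11, LFA1 = 0.05, ICAM1 = 0.11)

#' Specify one membrane species
#'
#' Each species lives on one of the two lattices (TCR and LFA-1 on the T
#' cell side, pMHC and ICAM-1 on the bilayer side), carries a lateral
#' diffusion coefficient and an initial surface density. The per-step move
#' probability `4 * D * tau / node_spacing^2` must not exceed 1 for the
#' random walk to reproduce the requested diffusion coefficient; this is
#' validated when kinetic parameters are assembled.
#'
#' @param name One of `"TCR"`, `"pMHC"`, `"LFA1"`, `"ICAM1"`.
#' @param initial_density Initial density in molecules per um^2.
#' @param diffusion_coefficient Lateral diffusion coefficient in um^2/s;
#'   defaults to a species-typical value.
#' @return A one-row tibble with columns `name`, `side`, `size_class`,
#'   `diffusion_coefficient`, `initial_density`.
#' @examples
#' species_spec("TCR", initial_density = 18)
#' @export
species_spec <- function(name, initial_density,
                         diffusion_coefficient = NULL) {
  if (!name %in% SPECIES_NAMES) {
    stop("unknown species name: ", name, " (expected one of ",
         paste(SPECIES_NAMES, collapse = ", "), ")", call. = FALSE)
  }
  if (initial_density < 0) stop("`initial_density` must be >= 0", call. = FALSE)
  D <- diffusion_coefficient %||% unname(SPECIES_D[name])
  if (D < 0) stop("`diffusion_coefficient` must be >= 0", call. = FALSE)
  tibble::tibble(
    name = name,
    side = unname(SPECIES_SIDE[name]),
    size_class = unname(SPECIES_SIZE[name]),
    diffusion_coefficient = D,
    initial_density = initial_density
  )
}

#' Default species table
#'
#' The reference condition of the model: TCR at 18/um^2 opposite a
#' moderate pMHC density, with the adhesion pair LFA-1/ICAM-1 at 50/um^2
#' each. Densities are arguments so titration drivers can rewrite them.
#'
#' @param tcr,pmhc,lfa1,icam1 Initial densities in molecules/um^2.
#' @return A four-row species tibble (see [species_spec()]).
#' @export
default_species <- function(tcr = 18, pmhc = 30, lfa1 = 50, icam1 = 50) {
  dplyr::bind_rows(
    species_spec("TCR", tcr),
    species_spec("pMHC", pmhc),
    species_spec("LFA1", lfa1),
    species_spec("ICAM1", icam1)
  )
}

#' Receptor-ligand binding rule
#'
#' Converts a molar association rate into the characteristic association
#' time `tau_on = V * N_A / kon`, where `V` is the inter-membrane
#' interaction volume of the lattice configuration and `N_A` Avogadro's
#' number. The per-step association probability is then
#' `p_on = B * tau / tau_on` and the per-step dissociation probability
#' `p_off = 1 - exp(-koff * tau)`.
#'
#' @param pair `"TCR:pMHC"` or `"LFA1:ICAM1"`.
#' @param kon Association rate in 1/(M s); 0 disables association for the
#'   pair.
#' @param koff Dissociation rate in 1/s.
#' @return One-row tibble with `pair`, `kon`, `koff`.
#' @examples
#' binding_rule("TCR:pMHC", kon = 1e5, koff = 0.1)
#' @export
binding_rule <- function(pair, kon, koff) {
  if (!pair %in% c("TCR:pMHC", "LFA1:ICAM1")) {
    stop("`pair` must be \"TCR:pMHC\" or \"LFA1:ICAM1\"", call. = FALSE)
  }
  if (kon < 0) stop("`kon` must be >= 0", call. = FALSE)
  if (koff < 0) stop("`koff` must be >= 0", call. = FALSE)
  tibble::tibble(pair = pair, kon = kon, koff = koff)
}

#' Default binding rules
#'
#' Literature-typical magnitudes for TCR-pMHC (fast turnover, dwell time
#' of seconds) and LFA-1-ICAM-1 (longer-lived adhesion bond).
#'
#' @param tcr_kon,tcr_koff,adhesion_kon,adhesion_koff Rates; see
#'   [binding_rule()].
#' @return Two-row rules tibble.
#' @export
default_binding_rules <- function(tcr_kon = 2e5, tcr_koff = 0.1,
                                  adhesion_kon = 2e5, adhesion_koff = 0.03) {
  dplyr::bind_rows(
    binding_rule("TCR:pMHC", tcr_kon, tcr_koff),
    binding_rule("LFA1:ICAM1", adhesion_kon, adhesion_koff)
  )
}

#' Avogadro's number (1/mol)
#' @keywords internal
AVOGADRO <- 6.02214076e23

#' Characteristic association time of a binding rule
#'
#' @param kon Association rate in 1/(M s).
#' @param config A [lattice_config()].
#' @return `tau_on = V * N_A / kon` in seconds.
#' @export
tau_on <- function(kon, config) {
  config$interaction_volume_l * AVOGADRO / kon
}

# state construction -------------------------------------------------------

species_code <- function(name) match(name, SPECIES_NAMES) - 1L

#' Build an initial simulation state
#'
#' Places `round(density * pi * synapse_radius^2)` agents of each species
#' uniformly at random on unoccupied active nodes of its lattice. The
#' placement uses an internal, seed-restored RNG so identical
#' `(config, species, seed)` always yield the identical state and the
#' caller's RNG stream is untouched.
#'
#' @param config A [lattice_config()].
#' @param species Species tibble as returned by [default_species()].
#' @param seed Integer seed; also stored in the state and reused as the
#'   default stream seed by the stepping functions.
#' @return A `synapse_state` object: a list holding the configuration, the
#'   species table and flat vectors `species_code` (0 TCR, 1 pMHC, 2 LFA1,
#'   3 ICAM1), `node` (0-based row-major node index), `partner` (0-based
#'   agent index or -1 when free), the focus lattice `fstate`
#'   (0 empty, 1 nucleation, 2 nucleation-polymerised, 3 polymerisation)
#'   with per-node ages `fage`, and the step/clock counters.
#' @examples
#' cfg <- lattice_config(nodes_per_side = 32, synapse_radius = 1.1)
#' st <- build_initial_state(cfg, default_species(pmhc = 10), seed = 1)
#' table(st$species_code)
#' @export
build_initial_state <- function(config, species, seed = 1L) {
  stopifnot(inherits(config, "lattice_config"))
  bad <- setdiff(species$name, SPECIES_NAMES)
  if (length(bad) > 0) {
    stop("unknown species name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(species$name)) {
    stop("duplicated species in the species table", call. = FALSE)
  }
  area <- pi * config$synapse_radius^2
  counts <- round(species$initial_density * area)
  for (side in c("tcell", "apc")) {
    need <- sum(counts[species$side == side])
    if (need > config$n_active) {
      over <- species$name[species$side == side][
        which.max(counts[species$side == side])]
      stop("requested densities exceed lattice capacity on the ", side,
           " lattice (", need, " agents for ", config$n_active,
           " active nodes); largest contributor: ", over, call. = FALSE)
    }
  }

  sp_code <- integer(0)
  node <- integer(0)
  active_nodes <- which(config$active) # 1-based
  with_preserved_rng(seed, {
    for (side in c("tcell", "apc")) {
      rows <- which(species$side == side)
      n_side <- sum(counts[rows])
      if (n_side == 0) next
      chosen <- sample(active_nodes, n_side, replace = FALSE)
      sp_code <- c(sp_code, rep(species_code(species$name[rows]),
                                times = counts[rows]))
      node <- c(node, chosen - 1L)
    }
  })

  state <- list(
    config = config,
    species = species,
    species_code = as.integer(sp_code),
    node = as.integer(node),
    partner = rep(-1L, length(node)),
    fstate = integer(config$nodes_per_side^2),
    fage = integer(config$nodes_per_side^2),
    step = 0,
    clock = 0,
    seed = as.integer(seed)
  )
  class(state) <- "synapse_state"
  state
}

# evaluate `expr` under a fixed seed without disturbing the caller's RNG
with_preserved_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' @export
print.synapse_state <- function(x, ...) {
  n_bound <- sum(x$partner >= 0) / 2
  cat("<synapse_state> t = ", x$clock, " s, ", length(x$node), " agents (",
      n_bound, " bound pairs), ", sum(x$fstate > 0),
      " non-empty focus nodes\n", sep = "")
  invisible(x)
}

#' Agent table of a state
#'
#' @param state A `synapse_state`.
#' @return Tibble with one row per agent: `id`, `species`, `side`, `node`
#'   (1-based), `x`, `y` (um relative to the lattice centre), `bound`,
#'   `partner` (1-based id or `NA`).
#' @export
agent_table <- function(state) {
  L <- state$config$nodes_per_side
  a <- state$config$node_spacing
  centre <- (L - 1) / 2
  nm <- SPECIES_NAMES[state$species_code + 1L]
  tibble::tibble(
    id = seq_along(state$node),
    species = nm,
    side = unname(SPECIES_SIDE[nm]),
    node = state$node + 1L,
    x = (state$node %% L - centre) * a,
    y = (state$node %/% L - centre) * a,
    bound = state$partner >= 0L,
    partner = ifelse(state$partner >= 0L, state$partner + 1L, NA_integer_)
  )
}

# geometry operations ------------------------------------------------------

#' Von Neumann neighbours of a node inside the active domain
#'
#' @param node 1-based node index (row-major).
#' @param config A [lattice_config()].
#' @return Integer vector of 1-based neighbour indices (deterministic
#'   order: up, down, left, right), restricted to the active disk.
#' @export
node_neighbors <- function(node, config) {
  L <- config$nodes_per_side
  if (node < 1 || node > L * L || !config$active[node]) {
    stop("`node` is outside the active domain", call. = FALSE)
  }
  n0 <- node - 1L
  x <- n0 %% L
  y <- n0 %/% L
  cand <- c(
    if (y > 0L) n0 - L,
    if (y < L - 1L) n0 + L,
    if (x > 0L) n0 - 1L,
    if (x < L - 1L) n0 + 1L
  )
  cand <- cand + 1L
  cand[config$active[cand]]
}

#' Euclidean distance between two node centres
#'
#' @param node_a,node_b 1-based node indices.
#' @param config A [lattice_config()].
#' @return Distance in micrometres.
#' @export
distance_um <- function(node_a, node_b, config) {
  L <- config$nodes_per_side
  a0 <- node_a - 1L
  b0 <- node_b - 1L
  dx <- (a0 %% L) - (b0 %% L)
  dy <- (a0 %/% L) - (b0 %/% L)
  sqrt(dx^2 + dy^2) * config$node_spacing
}
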