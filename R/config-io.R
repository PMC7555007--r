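#' Read a simulation configuration file
#'
#' Plain-text YAML (JSON is valid YAML) with blocks `lattice`, `species`,
#' `rules`, `forces`, `foci`, and optional scalars `B_global`, `seed`,
#' `duration`. Any omitted field falls back to the package default, so a
#' minimal file can override a single parameter. See
#' `system.file("extdata", "example-config.yaml", package = "synapsim")`.
#'
#' @param path File path.
#' @return A list with `params` (a [sim_params()]), `seed` and `duration`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  lat <- raw$lattice %||% list()
  config <- do.call(lattice_config, lat)
  species <- if (!is.null(raw$species)) {
    purrr::map_dfr(names(raw$species), function(nm) {
      s <- raw$species[[nm]]
      species_spec(nm, initial_density = s$density,
                   diffusion_coefficient = s$D)
    })
  } else default_species()
  rules <- if (!is.null(raw$rules)) {
    purrr::map_dfr(names(raw$rules), function(nm) {
      r <- raw$rules[[nm]]
      binding_rule(nm, kon = r$kon, koff = r$koff)
    })
  } else default_binding_rules()
  forces <- do.call(force_params, raw$forces %||% list())
  foci <- do.call(foci_params, raw$foci %||% list())
  params <- sim_params(config = config, species = species, rules = rules,
                       forces = forces, foci = foci,
                       B_global = raw$B_global %||% 1)
  list(params = params,
       seed = as.integer(raw$seed %||% 1L),
       duration = raw$duration %||% 600)
}

#' Write a resolved simulation configuration
#'
#' @param params A [sim_params()].
#' @param path Output file path (YAML).
#' @param seed,duration Run settings to record alongside the parameters.
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(params, path, seed = 1L, duration = 600) {
  cfg <- params$config
  out <- list(
    lattice = list(nodes_per_side = cfg$nodes_per_side,
                   node_spacing = cfg$node_spacing,
                   synapse_radius = cfg$synapse_radius,
                   tau = cfg$tau,
                   membrane_gap_height = cfg$membrane_gap_height),
    species = stats::setNames(
      lapply(seq_len(nrow(params$species)), function(i) {
        list(density = params$species$initial_density[i],
             D = params$species$diffusion_coefficient[i])
      }),
      params$species$name),
    rules = stats::setNames(
      lapply(seq_len(nrow(params$rules)), function(i) {
        list(kon = params$rules$kon[i], koff = params$rules$koff[i])
      }),
      params$rules$pair),
    forces = unclass(params$forces),
    foci = unclass(params$foci),
    B_global = params$B_global,
    seed = seed,
    duration = duration
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

# integer codes used in snapshot files
SNAPSHOT_CODES <- c(
  "0 empty", "1 free TCR", "2 free pMHC", "3 free LFA1", "4 free ICAM1",
  "5 TCR-pMHC complex member", "6 LFA1-ICAM1 complex member", "-1 inactive"
)

#' Export a state snapshot as plain text
#'
#' Writes three integer matrices (T cell lattice, APC lattice, focus
#' lattice), one row of space-separated codes per lattice row, each
#' preceded by a `#` header documenting the codes. Suitable for diffing
#' in tests.
#'
#' @param state A `synapse_state`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_state_snapshot <- function(state, path) {
  cfg <- state$config
  L <- cfg$nodes_per_side
  code_grid <- function(side_code) {
    g <- integer(L * L)
    g[!cfg$active] <- -1L
    sel <- SPECIES_SIDE[SPECIES_NAMES[state$species_code + 1L]] == side_code
    sp <- state$species_code[sel]
    bound <- state$partner[sel] >= 0L
    code <- ifelse(bound, ifelse(sp <= 1L, 5L, 6L), sp + 1L)
    g[state$node[sel] + 1L] <- code
    matrix(g, nrow = L, byrow = TRUE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("# synapsim state snapshot; t =", state$clock, "s; codes:",
          paste(SNAPSHOT_CODES, collapse = ", ")),
    paste("# lattice:", L, "x", L, "; spacing", cfg$node_spacing,
          "um; radius", cfg$synapse_radius, "um")
  ), con)
  for (nm in c("tcell", "apc")) {
    writeLines(paste0("# ", nm, " lattice"), con)
    utils::write.table(code_grid(nm), con, row.names = FALSE,
                       col.names = FALSE)
  }
  writeLines("# foci lattice (0 empty, 1 nucleation, 2 nucleation-polymerized, 3 polymerization)",
             con)
  utils::write.table(matrix(state$fstate, nrow = L, byrow = TRUE), con,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
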