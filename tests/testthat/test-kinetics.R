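test_that("p_on reproduces the direct tau/tau_on arithmetic", {
  # hand computation with V = a^2 * h = 7.35e-17 L
  cfg <- lattice_config(nodes_per_side = 16, node_spacing = 0.7,
                        synapse_radius = 5, tau = 0.01,
                        membrane_gap_height = 0.15)
  expect_equal(cfg$interaction_volume_l, 7.35e-17)
  kon <- 1e5
  rules <- dplyr::bind_rows(binding_rule("TCR:pMHC", kon, 0.1),
                            binding_rule("LFA1:ICAM1", 1e5, 0.03))
  kin <- kinetics_params(cfg, default_species(), rules)
  oracle <- 0.01 * kon / (7.35e-17 * 6.02214076e23)
  expect_equal(unname(kin$p_on["TCR:pMHC"]), oracle, tolerance = 1e-12)
  expect_equal(unname(kin$tau_on["TCR:pMHC"]),
               7.35e-17 * 6.02214076e23 / kon)
  # p_on scales linearly with kon
  kin2 <- kinetics_params(cfg, default_species(),
                          dplyr::bind_rows(binding_rule("TCR:pMHC", 3 * kon, 0.1),
                                           binding_rule("LFA1:ICAM1", 1e5, 0.03)))
  expect_equal(unname(kin2$p_on["TCR:pMHC"] / kin$p_on["TCR:pMHC"]), 3)
})

test_that("p_off is the exact exponential with the linear small-tau limit", {
  cfg <- small_config(tau = 0.01)
  kin <- kinetics_params(cfg, default_species(), default_binding_rules())
  expect_equal(unname(kin$p_off["TCR:pMHC"]), 1 - exp(-0.1 * 0.01))
  tiny <- kinetics_params(small_config(tau = 1e-5), default_species(),
                          default_binding_rules())
  expect_equal(unname(tiny$p_off["TCR:pMHC"]), 0.1 * 1e-5, tolerance = 1e-4)
})

test_that("the diffusion stability bound is enforced", {
  cfg <- small_config(tau = 0.05) # 4*D*tau/a^2 > 1 for D = 0.11
  expect_error(kinetics_params(cfg, default_species(),
                               default_binding_rules()),
               "stability bound")
})

test_that("immobile species do not move; the clock still advances", {
  cfg <- small_config()
  sp <- default_species(pmhc = 20)
  sp$diffusion_coefficient <- 0
  st <- build_initial_state(cfg, sp, seed = 2)
  pars <- quiet_params(cfg, species = sp)
  st2 <- step_diffusion(st, pars)
  expect_identical(st2$node, st$node)
  expect_equal(st2$clock, cfg$tau)
})

test_that("a fully packed lattice cannot move (exclusion)", {
  cfg <- small_config()
  nodes <- which(cfg$active) - 1L
  agents <- data.frame(species = "TCR", node = nodes)
  st <- make_state(cfg, agents)
  pars <- quiet_params(cfg)
  st2 <- step_diffusion(st, pars)
  expect_setequal(st2$node, st$node)
  expect_identical(sort(st2$node), sort(st$node))
})

test_that("free-molecule MSD grows as 4 D t on a sparse lattice", {
  # 20 sparse lattices x 100 walkers each, started in the central region
  cfg <- lattice_config(nodes_per_side = 201, synapse_radius = 7)
  D <- 0.05
  sp <- species_spec("TCR", initial_density = 0) # densities set by hand
  inner <- which(cfg$active) - 1L
  L <- cfg$nodes_per_side
  c0 <- (L - 1) / 2
  r_nodes <- sqrt((inner %% L - c0)^2 + (inner %/% L - c0)^2)
  inner <- inner[r_nodes * cfg$node_spacing < 4]
  times <- c(1, 2, 3, 4, 5)
  msd_sum <- numeric(length(times))
  n_tot <- 0
  pars <- quiet_params(cfg, species = sp)
  for (rep in 1:20) {
    # spread walkers thinly over the placement disk (<1% occupancy)
    pick <- inner[seq(rep, length(inner), by = floor(length(inner) / 50))][1:50]
    st <- make_state(cfg, data.frame(species = "TCR", node = pick),
                     seed = rep)
    run <- run_simulation(st, pars, duration = max(times),
                          track_times = times, seed = 1000 + rep)
    x0 <- (pick %% L); y0 <- (pick %/% L)
    for (k in seq_along(times)) {
      nd <- run$tracked[, k] - 1L
      dx <- (nd %% L - x0) * cfg$node_spacing
      dy <- (nd %/% L - y0) * cfg$node_spacing
      msd_sum[k] <- msd_sum[k] + sum(dx^2 + dy^2)
    }
    n_tot <- n_tot + 50
  }
  msd <- msd_sum / n_tot
  slope <- sum(msd * times) / sum(times^2) # least squares through origin
  expect_equal(slope, 4 * D, tolerance = 0.05)
})

test_that("complex lifetimes are exponential with mean 1/koff", {
  # 2000 pre-bound immobile pairs, rebinding structurally disabled
  cfg <- lattice_config(nodes_per_side = 81, synapse_radius = 2.8)
  st <- bound_pairs_state(cfg, 2000)
  koff <- 0.1
  rules <- dplyr::bind_rows(binding_rule("TCR:pMHC", 1e5, koff),
                            binding_rule("LFA1:ICAM1", 1e5, 0.03))
  pars <- quiet_params(cfg, rules = rules)
  out <- synapsim:::run_engine(st, pars, n_steps = 60000L,
                               phases = "unbind", seed = 99,
                               collect_lifetimes = TRUE)
  lt <- out$raw$lifetimes
  expect_gte(length(lt), 1990) # nearly all dissociate within 600 s
  expect_equal(mean(lt), 1 / koff, tolerance = 0.05)
  ks <- suppressWarnings(stats::ks.test(lt, "pexp", rate = koff))
  expect_gt(ks$p.value, 0.01)
})

test_that("binding requires colocalisation and B > 0", {
  cfg <- small_config()
  # free TCR with no pMHC opposite: nothing can bind
  st <- make_state(cfg, data.frame(species = c("TCR", "pMHC"),
                                   node = c(node_at(cfg), node_at(cfg, 3))))
  pars <- quiet_params(cfg)
  st2 <- attempt_binding(st, pars)
  expect_true(all(st2$partner == -1L))
  # colocalised with certain binding: forms a pair
  stc <- make_state(cfg, data.frame(species = c("TCR", "pMHC"),
                                    node = rep(node_at(cfg), 2)))
  sure <- quiet_params(cfg, rules = default_binding_rules())
  sure$kinetics$p_on["TCR:pMHC"] <- 1
  st3 <- attempt_binding(stc, sure)
  expect_identical(st3$partner, c(1L, 0L))
  # B_global = 0 blocks formation even with p_on = 1
  zero <- sure
  zero$B_global <- 0
  st4 <- attempt_binding(stc, zero)
  expect_true(all(st4$partner == -1L))
  # an explicit per-node multiplier field overrides the focus feedback
  bf <- rep(1, cfg$nodes_per_side^2)
  bf[node_at(cfg) + 1L] <- 0
  st5 <- attempt_binding(stc, sure, b_field = bf)
  expect_true(all(st5$partner == -1L))
})

test_that("koff = 0 complexes never dissociate", {
  cfg <- small_config()
  st <- bound_pairs_state(cfg, 50)
  rules <- dplyr::bind_rows(binding_rule("TCR:pMHC", 1e5, 0),
                            binding_rule("LFA1:ICAM1", 1e5, 0.03))
  pars <- quiet_params(cfg, rules = rules)
  run <- run_simulation(st, pars, duration = 10)
  expect_equal(run$observations$n_bound_tcr_pmhc, 50)
})

test_that("a dead system is a fixed point of simulation_step", {
  cfg <- small_config()
  st <- make_state(cfg, data.frame(species = c("TCR", "pMHC", "LFA1"),
                                   node = c(node_at(cfg), node_at(cfg, 1),
                                            node_at(cfg, 0, 2))))
  sp <- default_species(0, 0, 0, 0)
  sp$diffusion_coefficient <- 0
  rules <- dplyr::bind_rows(binding_rule("TCR:pMHC", 0, 0),
                            binding_rule("LFA1:ICAM1", 0, 0))
  pars <- quiet_params(cfg, species = sp, rules = rules)
  pars$kinetics$p_move_complex[] <- 0
  st2 <- simulation_step(st, pars)
  expect_identical(st2$node, st$node)
  expect_identical(st2$partner, st$partner)
  expect_equal(st2$clock, cfg$tau)
})

test_that("duration maps exactly onto steps of size tau", {
  cfg <- small_config()
  st <- build_initial_state(cfg, default_species(0, 0, 0, 0), seed = 1)
  pars <- quiet_params(cfg)
  run <- run_simulation(st, pars, duration = 600)
  expect_equal(run$state$step, 60000)
  expect_equal(run$state$clock, 600)
})

test_that("invariants hold through a busy run on a small lattice", {
  cfg <- small_config()
  st <- build_initial_state(cfg, default_species(pmhc = 30), seed = 3)
  pars <- sim_params(config = cfg, foci = foci_params(enabled = TRUE, B = 2))
  before <- table(st$species_code)
  run <- run_simulation(st, pars, duration = 60, check_invariants = TRUE)
  expect_identical(table(run$state$species_code), before)
  # engine-independent recheck of pair consistency at the endpoint
  bnd <- which(run$state$partner >= 0L)
  expect_true(all(run$state$node[bnd] ==
                    run$state$node[run$state$partner[bnd] + 1L]))
})
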