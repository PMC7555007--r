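test_that("foci_params validates inputs", {
  expect_error(foci_params(p_nucleate = 1.2), "\\[0, 1\\]")
  expect_error(foci_params(B = -1), ">= 0")
  expect_error(foci_params(R_neighborhood = -0.1), ">= 0")
})

test_that("update_foci requires the focus model to be enabled", {
  cfg <- small_config()
  st <- build_initial_state(cfg, default_species(0, 0, 0, 0), seed = 1)
  expect_error(update_foci(st, quiet_params(cfg)), "disabled")
})

test_that("without TCR-pMHC complexes the focus lattice stays empty", {
  cfg <- small_config()
  # plenty of free molecules and adhesion complexes, but no TCR-pMHC
  agents <- rbind(
    data.frame(species = "TCR", node = node_at(cfg, -3, 0), partner = NA),
    data.frame(species = "pMHC", node = node_at(cfg, 3, 0), partner = NA),
    bound_pair(node_at(cfg, 0, 2), "LFA1:ICAM1", offset = 2L)
  )
  st <- make_state(cfg, agents)
  pars <- quiet_params(cfg, foci = foci_params(enabled = TRUE, p_nucleate = 1,
                                               p_nuc_polymerize = 1,
                                               p_polymerize = 1, p_decay = 0))
  pars$kinetics$p_move_species[] <- 0
  pars$kinetics$p_move_complex[] <- 0
  for (i in 1:20) st <- update_foci(st, pars, seed = i)
  expect_true(all(st$fstate == 0L))
})

test_that("the nucleation -> polymerisation chain follows forced transitions", {
  cfg <- small_config()
  n <- node_at(cfg)
  pars <- quiet_params(cfg, foci = foci_params(enabled = TRUE, p_nucleate = 1,
                                               p_nuc_polymerize = 1,
                                               p_polymerize = 1, p_decay = 0,
                                               R_neighborhood = 0.35))
  # TCR-pMHC at n nucleates in one update
  st <- make_state(cfg, bound_pair(n))
  st <- update_foci(st, pars, seed = 1)
  expect_equal(st$fstate[n + 1L], 1L)
  # nucleation + colocalised LFA1-ICAM1 -> nucleation_polymerized
  st2 <- make_state(cfg, bound_pair(n, "LFA1:ICAM1"))
  st2$fstate[n + 1L] <- 1L
  st2 <- update_foci(st2, pars, seed = 2)
  expect_equal(st2$fstate[n + 1L], 2L)
  # ... and with a second LFA1-ICAM1 in the neighbourhood, polymerization
  st3 <- make_state(cfg, rbind(bound_pair(n, "LFA1:ICAM1"),
                               bound_pair(node_at(cfg, 2), "LFA1:ICAM1",
                                          offset = 2L)))
  st3$fstate[n + 1L] <- 2L
  st3 <- update_foci(st3, pars, seed = 3)
  expect_equal(st3$fstate[n + 1L], 3L)
  # without any LFA1-ICAM1 within R_neighborhood, nucleation cannot
  # polymerise even at p = 1
  st4 <- make_state(cfg, rbind(bound_pair(n),
                               bound_pair(node_at(cfg, 10), "LFA1:ICAM1",
                                          offset = 2L)))
  st4$fstate[n + 1L] <- 1L
  st4 <- update_foci(st4, pars, seed = 4)
  expect_equal(st4$fstate[n + 1L], 1L)
})

test_that("self-inhibition empties nodes with geometric lifetimes", {
  cfg <- lattice_config(nodes_per_side = 51, synapse_radius = 1.7)
  st <- build_initial_state(cfg, default_species(0, 0, 0, 0), seed = 1)
  nodes <- which(cfg$active)
  st$fstate[nodes] <- 1L
  p_decay <- 0.2
  pars <- quiet_params(cfg,
                       foci = foci_params(enabled = TRUE, p_decay = p_decay,
                                          p_nucleate = 0, p_nuc_polymerize = 0,
                                          p_polymerize = 0))
  life <- rep(NA_integer_, length(nodes))
  alive <- rep(TRUE, length(nodes))
  for (step in 1:60) {
    st <- update_foci(st, pars, seed = step)
    died <- alive & st$fstate[nodes] == 0L
    life[died] <- step
    alive <- alive & !died
  }
  expect_false(any(alive)) # all decayed well before 60 steps
  # chi-squared against the geometric law on 1..8+ pooled tail
  n <- length(life)
  obs <- c(tabulate(pmin(life, 8), nbins = 8))
  pr <- dgeom(0:7, prob = p_decay)
  pr[8] <- 1 - pgeom(6, prob = p_decay)
  chi <- suppressWarnings(stats::chisq.test(obs, p = pr))
  expect_gt(chi$p.value, 0.01)
  expect_equal(mean(life), 1 / p_decay, tolerance = 0.1)
})

test_that("feedback_field marks formed foci only", {
  cfg <- small_config()
  st <- build_initial_state(cfg, default_species(0, 0, 0, 0), seed = 1)
  fp <- foci_params(enabled = TRUE, B = 2)
  expect_true(all(feedback_field(st, fp) == 1))
  n <- node_at(cfg)
  st$fstate[n + 1L] <- 3L
  st$fstate[n + 5L] <- 1L # nucleation does not feed back by default
  fld <- feedback_field(st, fp)
  expect_equal(fld[n + 1L], 2)
  expect_equal(fld[n + 5L], 1)
  expect_equal(sum(fld != 1), 1)
  half <- feedback_field(st, foci_params(enabled = TRUE, B = 0.5))
  expect_equal(half[n + 1L], 0.5)
  all_states <- feedback_field(st, foci_params(enabled = TRUE, B = 2,
                                               feedback_all_states = TRUE))
  expect_equal(all_states[n + 5L], 2)
})

test_that("foci_summary counts states and 4-connected clusters", {
  cfg <- small_config()
  st <- build_initial_state(cfg, default_species(0, 0, 0, 0), seed = 1)
  expect_equal(foci_summary(st)$foci_clusters, 0)
  n <- node_at(cfg)
  st$fstate[n + 1L] <- 3L
  expect_equal(foci_summary(st)$foci_clusters, 1)
  # lattice distance 2: two clusters; distance 1: one cluster
  st$fstate[n + 3L] <- 3L
  expect_equal(foci_summary(st)$foci_clusters, 2)
  st$fstate[n + 2L] <- 3L
  sm <- foci_summary(st)
  expect_equal(sm$foci_clusters, 1)
  expect_equal(sm$polymerization, 3)
  st$fstate[n + 10L] <- 1L
  expect_equal(foci_summary(st)$nucleation, 1)
})

test_that("B = 1 reproduces the no-foci molecular trajectory exactly", {
  cfg <- small_config()
  sp <- default_species(pmhc = 20)
  mk <- function() build_initial_state(cfg, sp, seed = 31)
  p_off <- sim_params(config = cfg, species = sp,
                      foci = foci_params(enabled = FALSE))
  p_b1 <- sim_params(config = cfg, species = sp,
                     foci = foci_params(enabled = TRUE, B = 1))
  r_off <- run_simulation(mk(), p_off, duration = 30,
                          record_times = c(10, 20, 30), seed = 7)
  r_b1 <- run_simulation(mk(), p_b1, duration = 30,
                         record_times = c(10, 20, 30), seed = 7)
  expect_identical(r_off$state$node, r_b1$state$node)
  expect_identical(r_off$state$partner, r_b1$state$partner)
  mol <- !grepl("^foci", names(r_off$observations))
  expect_identical(r_off$observations[, mol], r_b1$observations[, mol])
  # the focus lattice itself was active in the B = 1 run
  expect_gt(sum(r_b1$state$fstate > 0), 0)
})
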