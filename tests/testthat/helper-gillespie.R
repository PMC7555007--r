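# Independent well-mixed oracle: exact stochastic simulation of
#   T + P <-> TP
# with per-encounter rates matched to the lattice rules. On the lattice a
# colocalised free pair binds with probability p_on per step tau, i.e. at
# rate -log(1 - p_on)/tau; under well-mixed conditions with M nodes the
# chance of colocalisation of a given (T, P) pair is 1/M, so the total
# binding propensity is r_pair * Tf * Pf / M. Dissociation occurs at koff
# per complex (p_off = 1 - exp(-koff * tau) is the exact discretisation).
# This implementation deliberately shares no code with the lattice engine.
gillespie_mean_kd <- function(n_tcr, n_pmhc, n_nodes, p_on, koff, tau,
                              t_end, sample_times, area) {
  r_pair <- -log(1 - p_on) / tau
  tf <- n_tcr; pf <- n_pmhc; tp <- 0
  t <- 0
  samples <- numeric(0)
  next_i <- 1
  while (t < t_end && next_i <= length(sample_times)) {
    a_bind <- r_pair * tf * pf / n_nodes
    a_unbind <- koff * tp
    a0 <- a_bind + a_unbind
    dt <- if (a0 > 0) stats::rexp(1, a0) else Inf
    while (next_i <= length(sample_times) && sample_times[next_i] <= t + dt) {
      samples <- c(samples, if (tp > 0) (tf / area) * (pf / area) / (tp / area)
                   else NA_real_)
      next_i <- next_i + 1
    }
    if (!is.finite(dt)) break
    t <- t + dt
    if (stats::runif(1) * a0 < a_bind) {
      tf <- tf - 1; pf <- pf - 1; tp <- tp + 1
    } else {
      tf <- tf + 1; pf <- pf + 1; tp <- tp - 1
    }
  }
  mean(samples, na.rm = TRUE)
}
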