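# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths for the quantity they check.

# Direct evaluation of the Benjamini-Hochberg step-up definition:
# with p sorted ascending, padj_(i) = min_{j >= i} p_(j) * m / j, capped at 1,
# reported in the original order.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- ps * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Simple steady-state window builder: constant DCW x, dilution rate d, broth
# concentrations conc, feed concentrations feed, over dt hours.
steady_window <- function(x = 5, d = 0.05, dt = 10, v = 2,
                          conc = c(s = 1), feed = c(s = 10),
                          co2 = NA_real_, gas = NA_real_) {
  p1 <- sample_point(0, x, conc, v, co2_offgas = co2, gas_flow = gas)
  p2 <- sample_point(dt, x, conc, v, co2_offgas = co2, gas_flow = gas)
  vol <- d * v * dt
  condition_window(p1, p2, v_in = vol, v_out = vol, v_bleed = vol,
                   feed_conc = feed)
}

# Fast scenario for recovery tests: single substrate, one product, steady
# state, adjustable noise and sink.
simple_scenario <- function(sink = 0, noise_cv = list(dcw = 0, conc = 0, offgas = 0),
                            grid = seq(0, 20, by = 5), seed = 1L, ...) {
  chemostat_scenario(
    name = "simple", v_reactor = 2, tfr = 100, sfr = 25, wfr = 75,
    evaporation = 0, feed_stock = c(glucose = 40),
    true_mu = 0.05, q_uptake = c(glucose = 0.12),
    q_production = c(trehalose = 0.004),
    unmeasured_sink_fraction = sink, x0 = 4, grid = grid,
    noise_cv = noise_cv, seed = seed, ...)
}

expect_fluxes_balanced <- function(solution, model, tol = 1e-6) {
  S <- build_stoichiometric_matrix(model)
  expect_lt(max(abs(S %*% solution$fluxes[colnames(S)])), tol)
  b <- chemoflux:::model_bounds(model)
  v <- solution$fluxes[colnames(S)]
  expect_true(all(v >= b$lb - tol & v <= b$ub + tol))
}
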