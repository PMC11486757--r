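test_that("growth rate obeys the steady-state identity and no-growth limit", {
  # constant biomass, no bleed: nothing grew
  w0 <- steady_window(x = 5, d = 0, dt = 8)
  expect_equal(specific_growth_rate(w0), 0)

  # constant biomass with bleed at dilution rate D: mu = D exactly
  for (d in c(0.01, 0.05, 0.2)) {
    w <- steady_window(x = 5, d = d, dt = 10)
    expect_equal(specific_growth_rate(w), d, tolerance = 1e-12)
  }
})

test_that("growth rate errors on zero biomass and bad windows", {
  p1 <- sample_point(0, 0, c(s = 1), 2)
  p2 <- sample_point(10, 0, c(s = 1), 2)
  w <- condition_window(p1, p2, 1, 1)
  expect_error(specific_growth_rate(w), class = "chemoflux_rate_error")
  expect_error(condition_window(p2, p1, 1, 1), class = "chemoflux_window_error")
  expect_error(sample_point(0, -1, c(s = 1), 2), class = "chemoflux_window_error")
})

test_that("uptake rate recovers the full-consumption algebra", {
  # substrate absent throughout, nothing fed
  w <- steady_window(conc = c(s = 0), feed = c(s = 0), d = 0.05)
  expect_equal(specific_uptake_rate(w, "s"), 0)

  # s = 0 in broth, s_in = 10 g/L, V_in = 1 L, xbar = 10, V = 2 L, dt = 10 h
  p1 <- sample_point(0, 10, c(s = 0), 2)
  p2 <- sample_point(10, 10, c(s = 0), 2)
  w2 <- condition_window(p1, p2, v_in = 1, v_out = 1, feed_conc = c(s = 10))
  expect_equal(specific_uptake_rate(w2, "s"), 0.05)
  # volumetric rate is the same numerator over dt only: r = q * xbar * V
  expect_equal(volumetric_uptake_rate(w2, "s"), 1.0)
})

test_that("verbatim and mass-balance uptake forms differ exactly by the accumulation term", {
  p1 <- sample_point(0, 10, c(s = 1.0), 2)
  p2 <- sample_point(10, 10, c(s = 2.0), 2)   # substrate accumulating
  w <- condition_window(p1, p2, v_in = 1, v_out = 1, feed_conc = c(s = 10))
  q_mb <- specific_uptake_rate(w, "s")
  q_vb <- specific_uptake_rate(w, "s", verbatim = TRUE)
  # verbatim - mass-balance = 2 * ds * V / (xbar V dt)
  expect_equal(q_vb - q_mb, 2 * 1.0 * 2 / (10 * 2 * 10))
  # at steady state the two forms agree
  ws <- steady_window()
  expect_equal(specific_uptake_rate(ws, "s"),
               specific_uptake_rate(ws, "s", verbatim = TRUE))
})

test_that("production rate closed form holds at steady state", {
  # p constant, p_in = 0, V_out = D V dt  =>  q_P = pbar * D / xbar
  x <- 8; d <- 0.04; pconc <- 1.5
  w <- steady_window(x = x, d = d, dt = 12, conc = c(prod = pconc),
                     feed = c(prod = 0))
  expect_equal(specific_production_rate(w, "prod"), pconc * d / x, tolerance = 1e-12)
  # nothing present, nothing produced
  w0 <- steady_window(conc = c(prod = 0), feed = c(prod = 0))
  expect_equal(specific_production_rate(w0, "prod"), 0)
})

test_that("accumulation rate is the concentration slope", {
  p1 <- sample_point(0, 5, c(s = 1.0), 2)
  p2 <- sample_point(2, 5, c(s = 1.5), 2)
  w <- condition_window(p1, p2, 0.1, 0.1)
  expect_equal(accumulation_rate(w, "s"), 0.25)
  expect_equal(accumulation_rate(steady_window(), "s"), 0)
})

test_that("CO2 evolution rate converts off-gas readings and flags missing data", {
  # constant 1% CO2 at 30 L/h, xbar*V = 10 g, molar volume 24 -> 0.00125 Cmol/g/h
  w <- steady_window(x = 5, d = 0.05, dt = 10, co2 = 0.01, gas = 30)
  expect_equal(co2_evolution_rate(w, molar_volume = 24, baseline = 0), 0.00125)
  # zero off-gas CO2 -> 0
  w0 <- steady_window(co2 = 0, gas = 30)
  expect_equal(co2_evolution_rate(w0, baseline = 0), 0)
  # missing channel -> NA with a warning, not an error
  wna <- steady_window()
  expect_warning(r <- co2_evolution_rate(wna), "off-gas")
  expect_true(is.na(r))
})

test_that("yields sum to the carbon balance and zero products leave Y_x/s alone", {
  reg <- default_species_registry()
  y <- yields_and_cbalance(mu = 0.05, q_uptake = list(glucose = 0.1),
                           q_trehalose = 0, q_aa = list(), q_co2 = 0,
                           registry = reg)
  expect_equal(y$c_balance, y$y_xs)
  expect_error(yields_and_cbalance(0.05, list(glucose = 0)),
               class = "chemoflux_rate_error")
})

test_that("specific rates are invariant under scaling of volumes", {
  p1 <- sample_point(0, 6, c(s = 2, prod = 0.5), 2)
  p2 <- sample_point(8, 6.6, c(s = 1.8, prod = 0.6), 2)
  w1 <- condition_window(p1, p2, v_in = 0.9, v_out = 0.8, v_bleed = 0.8,
                         feed_conc = c(s = 15, prod = 0))
  k <- 2
  p1k <- sample_point(0, 6, c(s = 2, prod = 0.5), 2 * k)
  p2k <- sample_point(8, 6.6, c(s = 1.8, prod = 0.6), 2 * k)
  wk <- condition_window(p1k, p2k, v_in = 0.9 * k, v_out = 0.8 * k,
                         v_bleed = 0.8 * k, feed_conc = c(s = 15, prod = 0))
  expect_equal(specific_growth_rate(wk), specific_growth_rate(w1))
  expect_equal(specific_uptake_rate(wk, "s"), specific_uptake_rate(w1, "s"))
  expect_equal(specific_production_rate(wk, "prod"),
               specific_production_rate(w1, "prod"))
  # volumetric rate scales linearly instead
  expect_equal(volumetric_uptake_rate(wk, "s"), k * volumetric_uptake_rate(w1, "s"))
})

test_that("q * xbar * V equals the volumetric rate on simulated windows", {
  sim <- simulate_chemostat(chemostat_preset("low"), seed = 11)
  for (w in windows_from_samples(sim$samples)) {
    q <- specific_uptake_rate(w, "msg")
    r <- volumetric_uptake_rate(w, "msg")
    xbar <- (w$start$x + w$end$x) / 2
    expect_equal(r, q * xbar * w$start$v_reactor, tolerance = 1e-10)
  }
})

test_that("to_cmol applies stoichiometric arithmetic and rejects unknown species", {
  reg <- default_species_registry()
  expect_equal(to_cmol(1, "glucose", reg), 6 / 180.16)
  expect_equal(to_cmol(5, species_card("x", 100, 0)), 0)
  expect_error(to_cmol(1, "unobtainium", reg), class = "chemoflux_registry_error")
  # mmol adapter: 0.18 g/g/h of glucose = 1 mmol/gDW/h
  expect_equal(to_mmol(0.18016, "glucose", reg), 1)
})

test_that("condition summaries report mean, SD and replicate count", {
  panels <- tibble::tibble(mu = c(1, 2, 3), q = c(4, 4, 4))
  s <- summarize_condition(panels)
  expect_equal(s$mean[s$quantity == "mu"], 2)
  expect_equal(s$sd[s$quantity == "mu"], 1)
  expect_equal(unique(s$n), 3)
  s1 <- summarize_condition(panels[1, ])
  expect_equal(s1$sd, c(0, 0))
  expect_equal(unique(s1$n), 1)
  expect_error(summarize_condition(panels[0, ]), class = "chemoflux_summary_error")
})

test_that("replicate means land near generator truth within sampling error", {
  sc <- simple_scenario(noise_cv = list(dcw = 0.01, conc = 0.01, offgas = 0.01))
  panels <- do.call(rbind, lapply(1:5, function(r) {
    sim <- simulate_chemostat(sc, seed = 100 + r, replicate = r)
    w <- windows_from_samples(sim$samples)
    do.call(rbind, lapply(w, window_rate_panel,
                          substrates = "glucose", products = "trehalose"))
  }))
  s <- summarize_condition(panels)
  mu_hat <- s[s$quantity == "mu", ]
  expect_lt(abs(mu_hat$mean - 0.05), 2 * mu_hat$sd / sqrt(5) + 1e-4)
})
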