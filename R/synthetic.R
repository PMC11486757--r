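#' Chemostat scenario with known true rates
#'
#' Defines a continuous cultivation whose biology is summarized by constant
#' true rates: specific growth rate `true_mu`, biomass-specific uptake rates
#' of the carbon sources, production rates of the secreted products, and an
#' unmeasured carbon sink taking a fixed fraction of the consumed carbon
#' (emulating unquantified metabolites or changing biomass composition, i.e. a
#' non-closing carbon balance). The CO2 evolution rate is derived from exact
#' carbon closure: consumed = biomass + products + CO2 + sink.
#'
#' Flows are stated as the mass flow rates of the dual-feed setup (substrate
#' feed `sfr` plus water feed `wfr` summing to the total `tfr`, all in g/h,
#' density taken as 1 g/mL); the bleed removes broth at fixed height so the
#' working volume stays constant, and an evaporation rate accounts for the
#' difference between inflow and bleed at high cultivation temperature.
#'
#' @param name scenario label
#' @param v_reactor working volume [L]
#' @param tfr,sfr,wfr total / substrate / water feed mass flow [g/h]
#' @param evaporation evaporative loss [g/h] (reduces the bleed, not the feed)
#' @param feed_stock named concentrations in the substrate feed [g/L]
#' @param true_mu specific growth rate [1/h]
#' @param q_uptake named specific uptake rates [g/g/h], positive = consumed
#' @param q_production named specific production rates [g/g/h], positive =
#'   produced
#' @param unmeasured_sink_fraction fraction of consumed carbon routed to an
#'   unmeasured sink, in [0, 1)
#' @param x0 initial dry cell weight [g/L]
#' @param s0 named initial broth concentrations of the substrates [g/L];
#'   `NULL` = start at the steady-state concentrations
#' @param p0 named initial product concentrations [g/L]; `NULL` = steady state
#' @param grid strictly increasing sampling times [h]
#' @param noise_cv list with per-channel coefficients of variation
#'   (`dcw`, `conc`, `offgas`) for multiplicative Gaussian measurement noise
#' @param gas_flow aeration [L/h]; `molar_volume` [L/mol] and `co2_baseline`
#'   (inlet CO2 mole fraction) configure the off-gas channel
#' @param biomass_cmol_mass g DCW per Cmol biomass
#' @param registry species registry with cards for every species used
#' @param seed default RNG seed for [simulate_chemostat()]
#' @return a `chemostat_scenario`
#' @export
chemostat_scenario <- function(name = "scenario", v_reactor = 2,
                               tfr = 90, sfr = 22.5, wfr = 67.5,
                               evaporation = 0,
                               feed_stock = c(msg = 76, glucose = 36),
                               true_mu = 0.03,
                               q_uptake = c(msg = 0.1, glucose = 0.05),
                               q_production = c(trehalose = 0.003),
                               unmeasured_sink_fraction = 0,
                               x0 = 5, s0 = NULL, p0 = NULL,
                               grid = seq(0, 24, by = 6),
                               noise_cv = list(dcw = 0.01, conc = 0.02, offgas = 0.01),
                               gas_flow = 30, molar_volume = 24.0,
                               co2_baseline = 4e-4,
                               biomass_cmol_mass = 24.6,
                               registry = default_species_registry(biomass_cmol_mass),
                               seed = 1L) {
  if (abs(sfr + wfr - tfr) > 1e-9)
    stop_chemoflux("sfr + wfr must equal tfr", "chemoflux_scenario_error")
  if (any(c(tfr, sfr, wfr) < 0) || evaporation < 0 || evaporation >= tfr)
    stop_chemoflux("flows must be >= 0 and evaporation < tfr", "chemoflux_scenario_error")
  if (unmeasured_sink_fraction < 0 || unmeasured_sink_fraction >= 1)
    stop_chemoflux("sink fraction must lie in [0, 1)", "chemoflux_scenario_error")
  if (any(diff(grid) <= 0) || length(grid) < 2)
    stop_chemoflux("sampling grid must be strictly increasing with >= 2 points",
                   "chemoflux_scenario_error")
  if (any(q_uptake < 0) || any(q_production < 0))
    stop_chemoflux("q_uptake and q_production are magnitudes and must be >= 0",
                   "chemoflux_scenario_error")

  flow_in <- tfr / 1000                     # L/h at density 1 g/mL
  flow_out <- (tfr - evaporation) / 1000    # bleed keeps volume constant
  d_in <- flow_in / v_reactor
  d_out <- flow_out / v_reactor
  if (d_out <= 0)
    stop_chemoflux("bleed flow must be positive", "chemoflux_scenario_error")
  feed_conc <- feed_stock * sfr / tfr       # after in-line dilution with water

  substrates <- names(q_uptake)
  products <- names(q_production)
  missing_feed <- setdiff(substrates, names(feed_conc))
  if (length(missing_feed))
    stop_chemoflux(paste("feed_stock lacks substrates:", paste(missing_feed, collapse = ", ")),
                   "chemoflux_scenario_error")

  # exact carbon ledger [Cmol/gDW/h]
  c_in <- sum(vapply(substrates, function(sp) to_cmol(q_uptake[[sp]], sp, registry), 0))
  c_x <- to_cmol(true_mu, "biomass", registry)
  c_prod <- if (length(products))
    sum(vapply(products, function(sp) to_cmol(q_production[[sp]], sp, registry), 0)) else 0
  c_sink <- unmeasured_sink_fraction * c_in
  q_co2 <- c_in - c_x - c_prod - c_sink
  if (q_co2 < -1e-12)
    stop_chemoflux(sprintf(
      "carbon ledger does not close: biomass + products + sink exceed consumed carbon by %.3g Cmol/g/h",
      -q_co2), "chemoflux_scenario_error")
  q_co2 <- max(q_co2, 0)

  # steady-state broth concentrations for the given rates
  s_ss <- vapply(substrates, function(sp)
    (d_in * feed_conc[[sp]] - q_uptake[[sp]] * x0) / d_out, 0)
  p_ss <- vapply(products, function(sp) q_production[[sp]] * x0 / d_out, 0)
  s0 <- if (is.null(s0)) stats::setNames(s_ss, substrates) else s0[substrates]
  p0 <- if (is.null(p0)) stats::setNames(p_ss, products) else p0[products]
  if (any(s0 < 0))
    stop_chemoflux("initial/steady-state substrate concentration negative: uptake exceeds supply",
                   "chemoflux_scenario_error")

  structure(list(
    name = name, v_reactor = v_reactor, tfr = tfr, sfr = sfr, wfr = wfr,
    evaporation = evaporation, flow_in = flow_in, flow_out = flow_out,
    d_in = d_in, d_out = d_out, feed_conc = feed_conc,
    true_mu = true_mu, q_uptake = q_uptake, q_production = q_production,
    q_co2 = q_co2, unmeasured_sink_fraction = unmeasured_sink_fraction,
    x0 = x0, s0 = s0, p0 = p0, grid = grid, noise_cv = noise_cv,
    gas_flow = gas_flow, molar_volume = molar_volume, co2_baseline = co2_baseline,
    biomass_cmol_mass = biomass_cmol_mass, registry = registry, seed = seed,
    carbon_ledger = c(consumed = c_in, biomass = c_x, products = c_prod,
                      co2 = q_co2, sink = c_sink)
  ), class = "chemostat_scenario")
}

# closed-form broth concentration at time t for a species with constant
# specific conversion rate `rate` (negative = consumed) and feed conc s_in:
#   ds/dt = d_in*s_in - d_out*s + rate*x0*exp(g t),   g = mu - d_out
conc_closed_form <- function(t, s0, s_in, rate, x0, mu, d_in, d_out) {
  g <- mu - d_out
  base <- exp(-d_out * t) * s0 + (d_in * s_in / d_out) * (1 - exp(-d_out * t))
  conv <- if (abs(mu) < 1e-12) {
    rate * x0 * t * exp(-d_out * t)
  } else {
    rate * x0 * (exp(g * t) - exp(-d_out * t)) / mu
  }
  base + conv
}

scenario_state <- function(scenario, t) {
  sc <- scenario
  x <- sc$x0 * exp((sc$true_mu - sc$d_out) * t)
  s <- vapply(names(sc$q_uptake), function(sp)
    conc_closed_form(t, sc$s0[[sp]], sc$feed_conc[[sp]], -sc$q_uptake[[sp]],
                     sc$x0, sc$true_mu, sc$d_in, sc$d_out), numeric(length(t)))
  p <- vapply(names(sc$q_production), function(sp)
    conc_closed_form(t, sc$p0[[sp]], 0, sc$q_production[[sp]],
                     sc$x0, sc$true_mu, sc$d_in, sc$d_out), numeric(length(t)))
  co2_frac <- sc$co2_baseline +
    sc$q_co2 * x * sc$v_reactor * sc$molar_volume / sc$gas_flow
  list(x = x, s = matrix(s, nrow = length(t), dimnames = list(NULL, names(sc$q_uptake))),
       p = matrix(p, nrow = length(t), dimnames = list(NULL, names(sc$q_production))),
       co2_frac = co2_frac)
}

#' Simulate a chemostat measurement series
#'
#' Evaluates the exact closed-form solution of the reactor balances
#' (`d(xV)/dt = mu xV - D_out xV`, `d(sV)/dt = F_in s_in - F_out s - q_s x V`
#' per species, constant volume via the fixed-height bleed) on the sampling
#' grid and overlays multiplicative Gaussian measurement noise per channel.
#' Returns both the noisy observation table (long format, the [read_samples()]
#' schema) and a truth ledger with the exact rates and the carbon allocation.
#'
#' @param scenario a [chemostat_scenario()]
#' @param seed RNG seed (defaults to the scenario's); the same seed yields an
#'   identical series
#' @param replicate replicate label stored in the table
#' @param noise set `FALSE` to disable measurement noise regardless of the
#'   scenario's `noise_cv`
#' @return list with `samples` (tibble) and `truth` (list: `mu`, `q_uptake`,
#'   `q_production`, `q_co2`, `carbon_ledger`, `c_balance_true`, `d_out`,
#'   `scenario`)
#' @export
simulate_chemostat <- function(scenario, seed = scenario$seed, replicate = 1L,
                               noise = TRUE) {
  stopifnot(inherits(scenario, "chemostat_scenario"))
  sc <- scenario
  # positivity check on a fine grid across the sampled horizon
  fine <- seq(min(sc$grid), max(sc$grid), by = 0.01)
  st_fine <- scenario_state(sc, fine)
  if (any(st_fine$s < -1e-9) || any(st_fine$p < -1e-9)) {
    bad <- fine[which(rowSums(cbind(st_fine$s, st_fine$p) < -1e-9) > 0)[1]]
    stop_chemoflux(sprintf(
      "scenario '%s' depletes a species below zero near t = %.2f h; shorten the grid or lower the uptake rates",
      sc$name, bad), "chemoflux_scenario_error")
  }
  st <- scenario_state(sc, sc$grid)

  species <- c(names(sc$q_uptake), names(sc$q_production))
  conc_true <- cbind(st$s, st$p)
  feed <- c(sc$feed_conc[names(sc$q_uptake)],
            stats::setNames(rep(0, length(sc$q_production)), names(sc$q_production)))

  obs <- with_seed(seed, {
    cv <- sc$noise_cv
    f_noise <- function(v, cvv) if (noise && cvv > 0) v * (1 + stats::rnorm(length(v), 0, cvv)) else v
    list(
      x = pmax(f_noise(st$x, cv$dcw %||% 0), 0),
      conc = pmax(matrix(f_noise(as.numeric(conc_true), cv$conc %||% 0),
                         nrow = nrow(conc_true), dimnames = dimnames(conc_true)), 0),
      co2 = sc$co2_baseline + pmax((st$co2_frac - sc$co2_baseline) *
                                     (1 + (if (noise && (cv$offgas %||% 0) > 0)
                                       stats::rnorm(length(st$co2_frac), 0, cv$offgas) else 0)), 0)
    )
  })

  dt <- c(NA_real_, diff(sc$grid))
  rows <- list()
  for (k in seq_along(sc$grid)) {
    rows[[k]] <- tibble::tibble(
      condition = sc$name, replicate = replicate, t_h = sc$grid[k],
      dcw_g_per_L = obs$x[k], volume_L = sc$v_reactor,
      species = species,
      conc_g_per_L = as.numeric(obs$conc[k, species]),
      feed_conc_g_per_L = as.numeric(feed[species]),
      v_in_L = sc$flow_in * dt[k], v_out_L = sc$flow_out * dt[k],
      v_bleed_L = sc$flow_out * dt[k],
      co2_frac = obs$co2[k], gas_flow_L_per_h = sc$gas_flow
    )
  }
  ledger <- sc$carbon_ledger
  truth <- list(
    mu = sc$true_mu, q_uptake = sc$q_uptake, q_production = sc$q_production,
    q_co2 = sc$q_co2, d_out = sc$d_out,
    carbon_ledger = ledger,
    c_balance_true = unname((ledger[["biomass"]] + ledger[["products"]] + ledger[["co2"]]) /
                              ledger[["consumed"]]),
    scenario = sc
  )
  list(samples = do.call(rbind, rows), truth = truth)
}

#' Preset scenarios for the three nutrient-availability conditions
#'
#' Ships the low / high / overfeed process settings (dual-feed flow rates,
#' feed composition, working volume) with true rates chosen so that the
#' presets reproduce the qualitative physiology of increasing nutrient
#' excess: rising cell density and growth rate, a falling MSG/glucose uptake
#' ratio, enhanced trehalose and amino-acid secretion, substrate accumulation
#' only under overfeeding, and a carbon balance that stops closing as the
#' unmeasured sink grows. Values live in
#' `inst/extdata/scenarios/<name>.yaml`.
#'
#' @param name `"low"`, `"high"` or `"overfeed"`
#' @param ... overrides passed on to [chemostat_scenario()]
#' @return a [chemostat_scenario()]
#' @export
chemostat_preset <- function(name = c("low", "high", "overfeed"), ...) {
  name <- match.arg(name)
  path <- system.file("extdata", "scenarios", paste0(name, ".yaml"),
                      package = "chemoflux", mustWork = TRUE)
  cfg <- yaml::read_yaml(path)
  args <- list(
    name = cfg$name, v_reactor = cfg$v_reactor,
    tfr = cfg$tfr, sfr = cfg$sfr, wfr = cfg$wfr,
    evaporation = cfg$evaporation,
    feed_stock = unlist(cfg$feed_stock),
    true_mu = cfg$true_mu,
    q_uptake = unlist(cfg$q_uptake),
    q_production = unlist(cfg$q_production),
    unmeasured_sink_fraction = cfg$unmeasured_sink_fraction,
    x0 = cfg$x0,
    grid = seq(cfg$grid$from, cfg$grid$to, by = cfg$grid$by)
  )
  if (!is.null(cfg$s0)) args$s0 <- unlist(cfg$s0)
  if (!is.null(cfg$p0)) args$p0 <- unlist(cfg$p0)
  over <- list(...)
  args[names(over)] <- over
  do.call(chemostat_scenario, args)
}

#' Toy metabolic models with hand-solvable optima
#'
#' Three desk-scale stoichiometric networks whose FBA/pFBA optima are known in
#' closed form, committed together with those solutions:
#' * `chain` — linear route: glucose uptake (bound 10) feeding a biomass sink
#'   with yield 0.5; optimum 5.
#' * `dual_substrate` — two carbon sources feeding a biomass reaction that
#'   also needs ATP; glutamate can be oxidized completely (deamination `GDH`
#'   or transamination `AAT`, 2 ATP) or incompletely with acetate secretion
#'   (`OVF`, 3 ATP). Without constraints the optimum secretes acetate; fixing
#'   the acetate exchange to zero (as measured) forces complete oxidation.
#' * `branched_tca` — one substrate entering via a non-phosphorylative
#'   shortcut (`ED_NP`, no ATP) or a two-step semi-phosphorylative branch
#'   (`ED_SP1`/`ED_SP2`, 1 ATP), a TCA-like reaction burning precursor to
#'   ATP, biomass requiring precursor + ATP, and an NGAM ATP drain.
#'
#' @param topology network family
#' @param uptake_bound magnitude of the substrate uptake bound [mmol/gDW/h]
#' @param include_ngam include the maintenance drain with `ngam_lb`
#' @param ngam_lb maintenance lower bound (default 1.9 mmol/gDW/h)
#' @return list with `model` ([metabolic_model()]) and `known_solution`
#'   (list `objective_value`, `fluxes`) verified against `S v = 0` and the
#'   bounds at construction time
#' @export
make_toy_model <- function(topology = c("chain", "dual_substrate", "branched_tca"),
                           uptake_bound = 10, include_ngam = TRUE, ngam_lb = 1.9) {
  topology <- match.arg(topology)
  u <- uptake_bound
  if (topology == "chain") {
    model <- metabolic_model(
      list(metabolite("GLC"), metabolite("A")),
      list(
        reaction("EX_glc", c(GLC = -1), lb = -u, ub = 0),
        reaction("UPT", c(GLC = -1, A = 1)),
        reaction("BIOMASS", c(A = -2))
      ),
      objective_id = "BIOMASS", model_id = "toy_chain")
    known <- list(objective_value = u / 2,
                  fluxes = c(EX_glc = -u, UPT = u, BIOMASS = u / 2))
  } else if (topology == "dual_substrate") {
    ngam <- if (include_ngam) ngam_lb else 0
    model <- metabolic_model(
      list(metabolite("GLC"), metabolite("GLU"), metabolite("ATP"), metabolite("ACE")),
      list(
        reaction("EX_glc", c(GLC = -1), lb = -u, ub = 0),
        reaction("EX_glu", c(GLU = -1), lb = -u, ub = 0),
        reaction("EX_ace", c(ACE = -1), lb = 0, ub = 1000),
        reaction("GDH", c(GLU = -1, ATP = 2)),
        reaction("AAT", c(GLU = -1, ATP = 2)),
        reaction("OVF", c(GLU = -1, ACE = 1, ATP = 3)),
        reaction("BIOMASS", c(GLC = -0.5, GLU = -0.5, ATP = -1)),
        reaction("NGAM", c(ATP = -1), lb = ngam, ub = 1000)
      ),
      objective_id = "BIOMASS", ngam_id = "NGAM", model_id = "toy_dual_substrate")
    # all glutamate through the acetate-secreting route at the optimum:
    # o + bm/2 = u and 3 o = bm + ngam  =>  bm = (6u - 2*ngam)/5
    bm <- (6 * u - 2 * ngam) / 5
    o <- (bm + ngam) / 3
    known <- list(objective_value = bm,
                  fluxes = c(EX_glc = -bm / 2, EX_glu = -(o + bm / 2), EX_ace = o,
                             GDH = 0, AAT = 0, OVF = o, BIOMASS = bm, NGAM = ngam))
  } else {
    ngam <- if (include_ngam) ngam_lb else 0
    model <- metabolic_model(
      list(metabolite("S"), metabolite("M"), metabolite("P"), metabolite("ATP")),
      list(
        reaction("EX_s", c(S = -1), lb = -u, ub = 0),
        reaction("ED_NP", c(S = -1, P = 1)),
        reaction("ED_SP1", c(S = -1, M = 1)),
        reaction("ED_SP2", c(M = -1, P = 1, ATP = 1)),
        reaction("TCA", c(P = -1, ATP = 2)),
        reaction("BIOMASS", c(P = -1, ATP = -1)),
        reaction("NGAM", c(ATP = -1), lb = ngam, ub = 1000)
      ),
      objective_id = "BIOMASS", ngam_id = "NGAM", model_id = "toy_branched_tca")
    # all uptake through the ATP-yielding branch; TCA burns just enough
    # precursor to cover maintenance: bm = u - ngam/3
    bm <- u - ngam / 3
    known <- list(objective_value = bm,
                  fluxes = c(EX_s = -u, ED_NP = 0, ED_SP1 = u, ED_SP2 = u,
                             TCA = ngam / 3, BIOMASS = bm, NGAM = ngam))
  }
  S <- build_stoichiometric_matrix(model)
  v <- known$fluxes[colnames(S)]
  b <- model_bounds(model)
  stopifnot(max(abs(S %*% v)) < 1e-9, all(v >= b$lb - 1e-9), all(v <= b$ub + 1e-9))
  list(model = model, known_solution = known)
}

#' Simulate a per-gene statistics table with planted truth
#'
#' Null genes get p-values from a standard-normal test statistic and small
#' log2 fold changes; planted true positives get a shifted statistic (mean
#' `3 * effect`) and |log2FC| centred on `effect` with random sign. Intended
#' to exercise FDR control and DEG classification against known labels.
#'
#' @param n_genes total genes
#' @param n_true planted differentially expressed genes
#' @param effect mean absolute log2 fold change of the planted genes
#' @param seed RNG seed
#' @return tibble with `gene_id`, `log2fc`, `pvalue`, `arcog`, `is_true`
#' @export
simulate_de_table <- function(n_genes = 2000, n_true = 50, effect = 2, seed = 1L) {
  stopifnot(n_true <= n_genes)
  with_seed(seed, {
    is_true <- c(rep(TRUE, n_true), rep(FALSE, n_genes - n_true))
    z <- stats::rnorm(n_genes) + ifelse(is_true, 3 * effect, 0)
    sgn <- sample(c(-1, 1), n_genes, replace = TRUE)
    lfc <- ifelse(is_true,
                  sgn * (effect + stats::rnorm(n_genes, 0, 0.15)),
                  stats::rnorm(n_genes, 0, 0.25))
    tibble::tibble(
      gene_id = sprintf("saci_%04d", seq_len(n_genes)),
      log2fc = lfc,
      pvalue = 2 * stats::pnorm(-abs(z)),
      arcog = sample(c("C", "E", "G", "I", "S", "R"), n_genes, replace = TRUE),
      is_true = is_true
    )
  })
}
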