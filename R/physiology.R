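#' Reactor sample points and condition windows
#'
#' A sample point is one timestamped set of reactor-state measurements; a
#' condition window pairs two sample points with the liquid volumes that moved
#' through the reactor between them. All specific rates are evaluated on
#' windows. Concentrations are broth concentrations in g/L; volumes in L;
#' times in h.
#'
#' @param t sampling time [h]
#' @param x volumetric dry cell weight [g/L]
#' @param conc named numeric vector of species concentrations in broth [g/L]
#' @param v_reactor working volume [L]
#' @param co2_offgas CO2 mole fraction in the exhaust gas (optional)
#' @param gas_flow aeration rate [L/h] (optional)
#' @return a `sample_point` object
#' @export
sample_point <- function(t, x, conc = numeric(), v_reactor = 2,
                         co2_offgas = NA_real_, gas_flow = NA_real_) {
  if (!is.finite(t)) stop_chemoflux("t must be finite", "chemoflux_window_error")
  if (!is.finite(x) || x < 0) stop_chemoflux("x must be >= 0", "chemoflux_window_error")
  if (length(conc) && (is.null(names(conc)) || any(!nzchar(names(conc)))))
    stop_chemoflux("conc must be a named vector", "chemoflux_window_error")
  if (any(conc < 0)) stop_chemoflux("concentrations must be >= 0", "chemoflux_window_error")
  if (!is.finite(v_reactor) || v_reactor <= 0)
    stop_chemoflux("v_reactor must be > 0", "chemoflux_window_error")
  structure(list(t = t, x = x, conc = conc, v_reactor = v_reactor,
                 co2_offgas = co2_offgas, gas_flow = gas_flow),
            class = "sample_point")
}

#' @rdname sample_point
#' @param start,end `sample_point`s delimiting the window (`end$t > start$t`)
#' @param v_in volume supplied to the reactor in the window [L]
#' @param v_out volume discharged in the window [L]
#' @param v_bleed bleed volume removed in the window [L]
#' @param feed_conc named species concentrations in the (mixed) feed [g/L]
#' @export
condition_window <- function(start, end, v_in, v_out, v_bleed = v_out,
                             feed_conc = numeric()) {
  stopifnot(inherits(start, "sample_point"), inherits(end, "sample_point"))
  if (end$t <= start$t)
    stop_chemoflux("window must have end$t > start$t", "chemoflux_window_error")
  if (any(c(v_in, v_out, v_bleed) < 0))
    stop_chemoflux("window volumes must be >= 0", "chemoflux_window_error")
  structure(list(start = start, end = end, v_in = v_in, v_out = v_out,
                 v_bleed = v_bleed, feed_conc = feed_conc),
            class = "condition_window")
}

window_dt <- function(w) w$end$t - w$start$t
window_xbar <- function(w) (w$start$x + w$end$x) / 2

conc_at <- function(point, species) {
  v <- point$conc[[species]]
  if (is.null(v)) 0 else v
}

#' Specific growth rate from a condition window
#'
#' Biomass balance over the window: growth must account for both the change in
#' reactor biomass and the biomass carried out with the bleed,
#' \deqn{\mu = \frac{(x_{end}-x_{start})V_R + \bar{x}\,\Delta V_{bleed}}
#'                 {\bar{x}\,V_R\,\Delta t}}
#' where \eqn{\bar{x}} is the arithmetic mean of the endpoint dry cell
#' weights. In a chemostat at steady state this reduces to the dilution rate.
#'
#' @param w a [condition_window()]
#' @return specific growth rate [1/h]
#' @export
specific_growth_rate <- function(w) {
  stopifnot(inherits(w, "condition_window"))
  dt <- window_dt(w)
  xbar <- window_xbar(w)
  if (xbar <= 0)
    stop_chemoflux("mean DCW is zero: growth rate undefined", "chemoflux_rate_error")
  v <- w$start$v_reactor
  ((w$end$x - w$start$x) * v + xbar * w$v_bleed) / (xbar * v * dt)
}

uptake_numerator <- function(w, species, verbatim = FALSE) {
  v <- w$start$v_reactor
  s0 <- conc_at(w$start, species)
  s1 <- conc_at(w$end, species)
  sbar <- (s0 + s1) / 2
  s_in <- if (is.null(w$feed_conc[[species]])) 0 else w$feed_conc[[species]]
  if (verbatim) {
    # as-printed form: adds broth accumulation to the supply term
    (s1 - s0) * v + s_in * w$v_in - sbar * w$v_out
  } else {
    # mass-balance form: consumed = supplied - discharged - accumulated
    s_in * w$v_in - sbar * w$v_out - (s1 - s0) * v
  }
}

#' Specific substrate uptake rate
#'
#' Substrate balance over the window: consumption equals supply with the feed
#' minus discharge with the bleed minus accumulation in the broth, normalized
#' by mean biomass, reactor volume and window length. Positive values mean the
#' substrate was consumed. `verbatim = TRUE` reproduces the alternative
#' published algebra in which the accumulation term is added to the supply
#' term instead of subtracted; the two agree whenever the broth concentration
#' is unchanged across the window.
#'
#' @param w a [condition_window()]
#' @param species species name present in the broth/feed concentration maps
#' @param xbar mean DCW over the window [g/L]; defaults to the endpoint mean
#' @param verbatim use the as-printed (accumulation-added) numerator
#' @return specific uptake rate [g/g/h], positive = consumed
#' @export
specific_uptake_rate <- function(w, species, xbar = window_xbar(w),
                                 verbatim = FALSE) {
  stopifnot(inherits(w, "condition_window"))
  if (xbar <= 0)
    stop_chemoflux("mean DCW is zero: uptake rate undefined", "chemoflux_rate_error")
  uptake_numerator(w, species, verbatim) /
    (xbar * w$start$v_reactor * window_dt(w))
}

#' Specific production rate
#'
#' Product balance over the window: production equals accumulation in the
#' broth plus discharge with the bleed minus any product supplied with the
#' feed (feed and discharge concentrations enter as masses, i.e. multiplied by
#' the respective volumes). Positive values mean the product was formed.
#'
#' @inheritParams specific_uptake_rate
#' @return specific production rate [g/g/h], positive = produced
#' @export
specific_production_rate <- function(w, species, xbar = window_xbar(w)) {
  stopifnot(inherits(w, "condition_window"))
  if (xbar <= 0)
    stop_chemoflux("mean DCW is zero: production rate undefined", "chemoflux_rate_error")
  v <- w$start$v_reactor
  p0 <- conc_at(w$start, species)
  p1 <- conc_at(w$end, species)
  pbar <- (p0 + p1) / 2
  p_in <- if (is.null(w$feed_conc[[species]])) 0 else w$feed_conc[[species]]
  ((p1 - p0) * v + pbar * w$v_out - p_in * w$v_in) /
    (xbar * v * window_dt(w))
}

#' Substrate accumulation rate
#'
#' Rate of change of the broth concentration between the two sampling points,
#' \eqn{(s_{end}-s_{start})/\Delta t}.
#'
#' @inheritParams specific_uptake_rate
#' @return accumulation rate [g/L/h]
#' @export
accumulation_rate <- function(w, species) {
  stopifnot(inherits(w, "condition_window"))
  (conc_at(w$end, species) - conc_at(w$start, species)) / window_dt(w)
}

#' Volumetric substrate uptake rate
#'
#' The specific uptake-rate numerator divided by the window length only
#' (no biomass normalization): \eqn{r_S = q_S \bar{x} V_R}.
#'
#' @inheritParams specific_uptake_rate
#' @return volumetric uptake rate [g/h]
#' @export
volumetric_uptake_rate <- function(w, species, verbatim = FALSE) {
  stopifnot(inherits(w, "condition_window"))
  uptake_numerator(w, species, verbatim) / window_dt(w)
}

#' Specific CO2 evolution rate from off-gas data
#'
#' Converts the exhaust CO2 mole fraction and aeration rate into a molar CO2
#' stream via the configured molar volume, subtracts the inlet baseline,
#' integrates over the window (trapezoid on the endpoints) and normalizes by
#' mean biomass and reactor volume. One mole of CO2 is one Cmol.
#'
#' @param w a [condition_window()] whose endpoints carry `co2_offgas` and
#'   `gas_flow`
#' @param molar_volume molar gas volume at off-gas analyzer conditions [L/mol]
#' @param baseline inlet CO2 mole fraction subtracted from the exhaust reading
#' @param xbar mean DCW over the window [g/L]
#' @return specific CO2 evolution rate [Cmol/g/h], or `NA` with a warning when
#'   the off-gas channel is missing (the carbon balance is then partial)
#' @export
co2_evolution_rate <- function(w, molar_volume = 24.0, baseline = 4e-4,
                               xbar = window_xbar(w)) {
  stopifnot(inherits(w, "condition_window"))
  pts <- list(w$start, w$end)
  if (any(vapply(pts, function(p) !is.finite(p$co2_offgas) || !is.finite(p$gas_flow), TRUE))) {
    warning("off-gas data missing: CO2 evolution rate not available, C-balance will be partial",
            call. = FALSE)
    return(NA_real_)
  }
  if (xbar <= 0)
    stop_chemoflux("mean DCW is zero: CO2 evolution rate undefined", "chemoflux_rate_error")
  rate_mol <- vapply(pts, function(p) p$gas_flow * (p$co2_offgas - baseline) / molar_volume, 0)
  mean(rate_mol) / (xbar * w$start$v_reactor)
}

#' Cmol yields and carbon balance
#'
#' Converts the specific rates of a window to a Cmol basis and forms the
#' yields on consumed substrate carbon: biomass yield Y_x/s = mu(Cmol)/q_S,
#' CO2 yield Y_CO2/s, trehalose yield Y_Tre/s and the summed amino acid yield
#' Y_AA/s. The carbon balance is their sum; 1.0 means all consumed carbon is
#' recovered in the measured sinks.
#'
#' @param mu specific growth rate [1/h]
#' @param q_uptake named specific uptake rates of the carbon sources [g/g/h]
#' @param q_trehalose specific trehalose production rate [g/g/h]
#' @param q_aa named specific amino-acid production rates [g/g/h]
#' @param q_co2 specific CO2 evolution rate [Cmol/g/h] (may be `NA` for a
#'   partial balance)
#' @param registry species registry from [default_species_registry()]
#' @return one-row tibble with `y_xs`, `y_co2s`, `y_tres`, `y_aas`,
#'   `c_balance` (all Cmol/Cmol) and `q_s_cmol` [Cmol/g/h]
#' @export
yields_and_cbalance <- function(mu, q_uptake, q_trehalose = 0, q_aa = numeric(),
                                q_co2 = NA_real_,
                                registry = default_species_registry()) {
  q_s_cmol <- sum(vapply(names(q_uptake), function(sp)
    to_cmol(q_uptake[[sp]], sp, registry), 0))
  if (!is.finite(q_s_cmol) || q_s_cmol <= 0)
    stop_chemoflux("total substrate uptake is zero: yields undefined", "chemoflux_rate_error")
  y_xs <- to_cmol(mu, "biomass", registry) / q_s_cmol
  y_co2s <- if (is.finite(q_co2)) q_co2 / q_s_cmol else NA_real_
  y_tres <- to_cmol(q_trehalose, "trehalose", registry) / q_s_cmol
  y_aas <- if (length(q_aa))
    sum(vapply(names(q_aa), function(sp) to_cmol(q_aa[[sp]], sp, registry), 0)) / q_s_cmol
  else 0
  tibble::tibble(y_xs = y_xs, y_co2s = y_co2s, y_tres = y_tres, y_aas = y_aas,
                 c_balance = y_xs + y_co2s + y_tres + y_aas,
                 q_s_cmol = q_s_cmol)
}

#' Full rate and yield panel for one window
#'
#' Convenience wrapper evaluating the growth, uptake, production, accumulation,
#' volumetric and CO2 rates of a window plus the Cmol yields, given the roles
#' of the measured species.
#'
#' @param w a [condition_window()]
#' @param substrates character vector of substrate species names
#' @param products character vector of product species names (trehalose plus
#'   amino acids; species named `"trehalose"` feeds the trehalose yield, all
#'   other products count as amino acids)
#' @param registry species registry
#' @param molar_volume,baseline passed to [co2_evolution_rate()]
#' @param verbatim use the as-printed uptake numerator
#' @return one-row tibble with columns `mu`, `q_<species>`, `r_<substrate>`,
#'   `accum_<substrate>`, `q_co2`, and the yield columns of
#'   [yields_and_cbalance()]
#' @export
window_rate_panel <- function(w, substrates, products = character(),
                              registry = default_species_registry(),
                              molar_volume = 24.0, baseline = 4e-4,
                              verbatim = FALSE) {
  mu <- specific_growth_rate(w)
  q_up <- stats::setNames(
    vapply(substrates, function(sp) specific_uptake_rate(w, sp, verbatim = verbatim), 0),
    substrates)
  q_pr <- stats::setNames(
    vapply(products, function(sp) specific_production_rate(w, sp), 0), products)
  r_up <- stats::setNames(
    vapply(substrates, function(sp) volumetric_uptake_rate(w, sp, verbatim = verbatim), 0),
    substrates)
  acc <- stats::setNames(
    vapply(substrates, function(sp) accumulation_rate(w, sp), 0), substrates)
  q_co2 <- suppressWarnings(
    co2_evolution_rate(w, molar_volume = molar_volume, baseline = baseline))
  q_tre <- if ("trehalose" %in% products) q_pr[["trehalose"]] else 0
  q_aa <- q_pr[setdiff(products, "trehalose")]
  yields <- yields_and_cbalance(mu, as.list(q_up), q_tre, as.list(q_aa), q_co2,
                                registry = registry)
  out <- tibble::tibble(mu = mu)
  for (sp in substrates) out[[paste0("q_", sp)]] <- q_up[[sp]]
  for (sp in products) out[[paste0("q_", sp)]] <- q_pr[[sp]]
  for (sp in substrates) out[[paste0("r_", sp)]] <- r_up[[sp]]
  for (sp in substrates) out[[paste0("accum_", sp)]] <- acc[[sp]]
  out$q_s <- sum(q_up)
  out$r_s <- sum(r_up)
  out$q_co2 <- q_co2
  cbind(out, yields)
}

#' Summarize replicate panels as mean and standard deviation
#'
#' Aggregates per-replicate rate/yield panels into a long table of per-quantity
#' mean, sample standard deviation and replicate count. A single replicate is
#' reported with SD 0 and `n = 1` so downstream consumers can flag it.
#'
#' @param panels data frame with one row per replicate and numeric columns
#' @return tibble with columns `quantity`, `mean`, `sd`, `n`
#' @export
summarize_condition <- function(panels) {
  if (is.null(dim(panels)) || nrow(panels) < 1L)
    stop_chemoflux("need at least one replicate", "chemoflux_summary_error")
  num <- vapply(panels, is.numeric, TRUE)
  panels <- panels[, num, drop = FALSE]
  n <- nrow(panels)
  tibble::tibble(
    quantity = names(panels),
    mean = unname(vapply(panels, function(col) mean(col), 0)),
    sd = if (n == 1L) rep(0, ncol(panels)) else unname(vapply(panels, stats::sd, 0)),
    n = n
  )
}

#' Read a long-format sample table and build condition windows
#'
#' The on-disk schema is one row per (sample point, species):
#' `condition, replicate, t_h, dcw_g_per_L, volume_L, species, conc_g_per_L,
#' feed_conc_g_per_L, v_in_L, v_out_L, v_bleed_L, co2_frac, gas_flow_L_per_h`.
#' The per-interval volumes on a row are the volumes moved since the previous
#' sample of the same replicate (NA on the first row).
#'
#' @param path CSV or TSV file
#' @return tibble of sample rows
#' @export
read_samples <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  required <- c("condition", "replicate", "t_h", "dcw_g_per_L", "volume_L",
                "species", "conc_g_per_L")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop_chemoflux(paste("sample table lacks columns:", paste(missing, collapse = ", ")),
                   "chemoflux_schema_error")
  tibble::as_tibble(df)
}

#' @rdname read_samples
#' @param samples tibble in the [read_samples()] schema
#' @return `windows_from_samples()`: list of [condition_window()]s, one per
#'   consecutive sample pair per (condition, replicate), with attributes
#'   `condition` and `replicate` on each window
#' @export
windows_from_samples <- function(samples) {
  groups <- split(samples, interaction(samples$condition, samples$replicate, drop = TRUE))
  out <- list()
  for (g in groups) {
    times <- sort(unique(g$t_h))
    if (any(diff(times) <= 0) || length(times) < 2L) next
    pts <- lapply(times, function(tt) {
      rows <- g[g$t_h == tt, ]
      sample_point(
        t = tt, x = rows$dcw_g_per_L[1], v_reactor = rows$volume_L[1],
        conc = stats::setNames(rows$conc_g_per_L, rows$species),
        co2_offgas = if ("co2_frac" %in% names(rows)) rows$co2_frac[1] else NA_real_,
        gas_flow = if ("gas_flow_L_per_h" %in% names(rows)) rows$gas_flow_L_per_h[1] else NA_real_
      )
    })
    for (i in seq_len(length(times) - 1L)) {
      rows_end <- g[g$t_h == times[i + 1L], ]
      feed <- if ("feed_conc_g_per_L" %in% names(rows_end))
        stats::setNames(rows_end$feed_conc_g_per_L, rows_end$species) else numeric()
      w <- condition_window(
        pts[[i]], pts[[i + 1L]],
        v_in = rows_end$v_in_L[1], v_out = rows_end$v_out_L[1],
        v_bleed = if ("v_bleed_L" %in% names(rows_end)) rows_end$v_bleed_L[1] else rows_end$v_out_L[1],
        feed_conc = feed)
      attr(w, "condition") <- g$condition[1]
      attr(w, "replicate") <- g$replicate[1]
      out[[length(out) + 1L]] <- w
    }
  }
  out
}
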