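#' Sampling specification for exchange-bound uncertainty
#'
#' Describes the Monte-Carlo scheme propagating measurement uncertainty of the
#' exchange rates into the flux solution: each non-fixed measured exchange is
#' drawn independently and uniformly from `[rate - 2 sd, rate + 2 sd]`,
#' the constrained pFBA is re-solved per draw, and growth rates and fluxes are
#' averaged over the feasible draws. Uniform sampling on the stated interval
#' is the minimal assumption and is recorded in the result metadata.
#'
#' @param n_samples number of Monte-Carlo draws (default 1000)
#' @param seed integer RNG seed
#' @param independent_bounds if `TRUE`, two values are drawn per exchange and
#'   applied as an interval `[min, max]` instead of fixing `lb = ub` at one
#'   draw
#' @return a `sampling_spec` object
#' @export
sampling_spec <- function(n_samples = 1000, seed = 1, independent_bounds = FALSE) {
  if (n_samples < 1) stop_chemoflux("n_samples must be >= 1", "chemoflux_sampling_error")
  structure(list(n_samples = as.integer(n_samples), seed = seed,
                 distribution = "uniform(rate - 2*sd, rate + 2*sd)",
                 independent_bounds = isTRUE(independent_bounds),
                 infeasible_policy = "drop-and-record"),
            class = "sampling_spec")
}

#' Sample measured-exchange constraint sets
#'
#' Draws `spec$n_samples` constraint sets. Fixed-zero exchanges are untouched
#' (lb = ub = 0 in every set); exchanges with `sd = 0` yield constant draws.
#' The same seed reproduces the same list.
#'
#' @param exchanges list of [measured_exchange()]s
#' @param spec a [sampling_spec()]
#' @return list of data frames (`reaction_id`, `lb`, `ub`), one per draw
#' @export
sample_constraint_sets <- function(exchanges, spec = sampling_spec()) {
  stopifnot(inherits(spec, "sampling_spec"))
  ids <- vapply(exchanges, `[[`, "", "reaction_id")
  rates <- vapply(exchanges, `[[`, 0, "rate")
  sds <- vapply(exchanges, `[[`, 0, "sd")
  fixed <- vapply(exchanges, `[[`, TRUE, "fixed_zero")
  with_seed(spec$seed, {
    lapply(seq_len(spec$n_samples), function(i) {
      draw <- function() ifelse(fixed, 0, stats::runif(length(rates),
                                                       rates - 2 * sds,
                                                       rates + 2 * sds))
      if (spec$independent_bounds) {
        d1 <- draw(); d2 <- draw()
        data.frame(reaction_id = ids, lb = pmin(d1, d2), ub = pmax(d1, d2),
                   stringsAsFactors = FALSE)
      } else {
        d <- draw()
        data.frame(reaction_id = ids, lb = d, ub = d, stringsAsFactors = FALSE)
      }
    })
  })
}

#' Ensemble pFBA over sampled exchange constraints
#'
#' Runs [pfba()] for every sampled constraint set, drops infeasible draws
#' (recording their fraction), and averages the growth rate (objective flux)
#' and every reaction flux over the feasible draws.
#'
#' @param model a [metabolic_model()]; NGAM and zero-fixing should already be
#'   applied (see [apply_measured_exchanges()]) — the sampled sets override
#'   only the bounds of the sampled exchanges
#' @param exchanges list of [measured_exchange()]s to sample
#' @param spec a [sampling_spec()]
#' @param ngam_lb maintenance lower bound applied before solving
#' @return an `ensemble_result`: `mean_growth`, `sd_growth`, `mean_fluxes`,
#'   `sd_fluxes`, `feasible_fraction`, `samples` (per-draw log), `spec`
#' @export
ensemble_pfba <- function(model, exchanges, spec = sampling_spec(), ngam_lb = 1.9) {
  model <- apply_measured_exchanges(model, exchanges, ngam_lb = ngam_lb)
  sets <- sample_constraint_sets(exchanges, spec)
  n <- length(sets)
  growth <- rep(NA_real_, n)
  status <- character(n)
  flux_mat <- matrix(NA_real_, n, length(model$reactions),
                     dimnames = list(NULL, names(model$reactions)))
  for (i in seq_len(n)) {
    m_i <- apply_exchange_bounds(model, sets[[i]])
    sol <- pfba(m_i)
    status[i] <- sol$status
    if (sol$status == "optimal") {
      growth[i] <- sol$objective_value
      flux_mat[i, ] <- sol$fluxes[colnames(flux_mat)]
    }
  }
  feasible <- status == "optimal"
  if (!any(feasible)) {
    diag_set <- sets[[1]]
    stop_chemoflux(paste0(
      "all ", n, " sampled constraint sets were infeasible; first sampled set: ",
      paste(sprintf("%s=[%.4g,%.4g]", diag_set$reaction_id, diag_set$lb, diag_set$ub),
            collapse = ", ")), "chemoflux_ensemble_error")
  }
  g <- growth[feasible]
  structure(list(
    mean_growth = mean(g),
    sd_growth = if (sum(feasible) > 1) stats::sd(g) else 0,
    mean_fluxes = colMeans(flux_mat[feasible, , drop = FALSE]),
    sd_fluxes = apply(flux_mat[feasible, , drop = FALSE], 2,
                      function(col) if (length(col) > 1) stats::sd(col) else 0),
    growth = growth,
    feasible_fraction = mean(feasible),
    samples = tibble::tibble(sample = seq_len(n), status = status, growth = growth),
    spec = spec
  ), class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("<ensemble_result: %d draws, feasible %.1f%%, growth %.4g +/- %.4g>\n",
              nrow(x$samples), 100 * x$feasible_fraction, x$mean_growth, x$sd_growth))
  invisible(x)
}
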