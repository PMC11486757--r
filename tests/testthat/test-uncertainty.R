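chain_exchange <- function(sd = 0.5) list(measured_exchange("EX_glc", rate = -10, sd = sd))

test_that("constraint sampling is seeded, bounded and centred on the rate", {
  ex <- chain_exchange(sd = 0.5)
  spec <- sampling_spec(n_samples = 10000, seed = 9)
  sets <- sample_constraint_sets(ex, spec)
  draws <- vapply(sets, function(s) s$lb[1], 0)
  # every draw inside [rate - 2sd, rate + 2sd]
  expect_gte(min(draws), -11)
  expect_lte(max(draws), -9)
  # mean within 3 standard errors of the rate (uniform: sd = width/sqrt(12))
  se <- (2 / sqrt(12)) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - (-10)), 3 * se)

  # determinism contract
  sets2 <- sample_constraint_sets(ex, sampling_spec(n_samples = 10000, seed = 9))
  expect_identical(sets, sets2)
  sets3 <- sample_constraint_sets(ex, sampling_spec(n_samples = 10000, seed = 10))
  expect_false(identical(sets, sets3))
})

test_that("sd = 0 and fixed_zero exchanges yield constant draws", {
  ex <- list(measured_exchange("EX_glc", rate = -7, sd = 0),
             measured_exchange("EX_ace", fixed_zero = TRUE))
  sets <- sample_constraint_sets(ex, sampling_spec(n_samples = 50, seed = 2))
  for (s in sets) {
    expect_equal(s$lb, c(-7, 0))
    expect_equal(s$ub, c(-7, 0))
  }
})

test_that("independent lb/ub sampling produces ordered intervals", {
  ex <- chain_exchange(sd = 1)
  sets <- sample_constraint_sets(ex, sampling_spec(n_samples = 200, seed = 5,
                                                   independent_bounds = TRUE))
  widths <- vapply(sets, function(s) s$ub[1] - s$lb[1], 0)
  expect_true(all(widths >= 0))
  expect_gt(mean(widths), 0)   # genuinely an interval, not a point
})

test_that("ensemble with sd = 0 equals the single pFBA run exactly", {
  tm <- make_toy_model("chain")
  ex <- list(measured_exchange("EX_glc", rate = -8, sd = 0))
  er <- ensemble_pfba(tm$model, ex, sampling_spec(n_samples = 6, seed = 4), ngam_lb = 0)
  single <- pfba(apply_measured_exchanges(tm$model, ex, ngam_lb = 0))
  expect_identical(er$mean_growth, single$objective_value)
  expect_equal(er$mean_fluxes[names(single$fluxes)], single$fluxes)
  expect_equal(er$feasible_fraction, 1)
  expect_equal(er$sd_growth, 0)
})

test_that("n_samples = 1 degenerates to one pfba run and seeds reproduce results", {
  tm <- make_toy_model("chain")
  ex <- chain_exchange()
  e1 <- ensemble_pfba(tm$model, ex, sampling_spec(n_samples = 1, seed = 3), ngam_lb = 0)
  expect_equal(nrow(e1$samples), 1)
  expect_equal(e1$mean_growth, e1$samples$growth[1])

  e2 <- ensemble_pfba(tm$model, ex, sampling_spec(n_samples = 40, seed = 8), ngam_lb = 0)
  e3 <- ensemble_pfba(tm$model, ex, sampling_spec(n_samples = 40, seed = 8), ngam_lb = 0)
  expect_identical(e2$mean_fluxes, e3$mean_fluxes)
  expect_identical(e2$mean_growth, e3$mean_growth)
})

test_that("mean growth matches the closed-form expectation when growth is linear in uptake", {
  # chain: growth = |uptake| / 2, uptake ~ U(-11, -9)  =>  E[growth] = 5
  tm <- make_toy_model("chain")
  er <- ensemble_pfba(tm$model, chain_exchange(sd = 0.5),
                      sampling_spec(n_samples = 400, seed = 21), ngam_lb = 0)
  se <- er$sd_growth / sqrt(sum(er$samples$status == "optimal"))
  expect_lt(abs(er$mean_growth - 5), 3 * se)
  # mean lies within the per-sample range
  g <- er$samples$growth[er$samples$status == "optimal"]
  expect_gte(er$mean_growth, min(g))
  expect_lte(er$mean_growth, max(g))
})

test_that("shrinking measurement sds cannot inflate growth spread", {
  tm <- make_toy_model("chain")
  sds <- c(1, 0.5, 0.1, 0)
  spread <- vapply(sds, function(s) {
    er <- ensemble_pfba(tm$model, chain_exchange(sd = s),
                        sampling_spec(n_samples = 150, seed = 31), ngam_lb = 0)
    er$sd_growth
  }, 0)
  expect_true(all(diff(spread) <= 1e-9))
})

test_that("infeasible draws are dropped and counted; all-infeasible errors loudly", {
  td <- make_toy_model("dual_substrate")
  base <- apply_measured_exchanges(td$model,
                                   list(measured_exchange("EX_ace", fixed_zero = TRUE)))
  # feasibility needs |glu| >= 2|glc| + 0.95; straddle the boundary
  ex <- list(measured_exchange("EX_ace", fixed_zero = TRUE),
             measured_exchange("EX_glc", rate = -3, sd = 0.4),
             measured_exchange("EX_glu", rate = -7.2, sd = 0.4))
  er <- ensemble_pfba(td$model, ex, sampling_spec(n_samples = 120, seed = 13))
  expect_lt(er$feasible_fraction, 1)
  expect_gt(er$feasible_fraction, 0)
  expect_equal(er$feasible_fraction, mean(er$samples$status == "optimal"))

  ex_bad <- list(measured_exchange("EX_ace", fixed_zero = TRUE),
                 measured_exchange("EX_glc", rate = -5, sd = 0),
                 measured_exchange("EX_glu", rate = -5, sd = 0))
  expect_error(ensemble_pfba(td$model, ex_bad, sampling_spec(n_samples = 3, seed = 1)),
               class = "chemoflux_ensemble_error")
})
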