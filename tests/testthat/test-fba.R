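test_that("stoichiometric matrix follows declaration order and signs", {
  m <- metabolic_model(
    list(metabolite("A"), metabolite("B")),
    list(reaction("EX_a", c(A = -1), lb = -10, ub = 0),
         reaction("R1", c(A = -1, B = 1)),
         reaction("SINK", c(B = -1))),
    objective_id = "SINK")
  S <- build_stoichiometric_matrix(m)
  expect_equal(dimnames(S), list(c("A", "B"), c("EX_a", "R1", "SINK")))
  expect_equal(unname(S[, "R1"]), c(-1, 1))

  # permuting reaction declaration order permutes columns identically
  m2 <- metabolic_model(
    list(metabolite("A"), metabolite("B")),
    list(reaction("SINK", c(B = -1)),
         reaction("EX_a", c(A = -1), lb = -10, ub = 0),
         reaction("R1", c(A = -1, B = 1))),
    objective_id = "SINK")
  S2 <- build_stoichiometric_matrix(m2)
  expect_equal(S2[, colnames(S)], S)
})

test_that("FBA solves the hand linear programs of the toy networks", {
  # linear chain, uptake <= 10, yield 0.5 -> objective 5
  tc <- make_toy_model("chain")
  sol <- fba(tc$model)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 5, tolerance = 1e-9)
  expect_fluxes_balanced(sol, tc$model)

  # all exchanges closed -> objective 0
  m0 <- tc$model
  m0$reactions$EX_glc$lb <- 0
  expect_equal(fba(m0)$objective_value, 0, tolerance = 1e-12)
})

test_that("FBA objectives equal the exhaustive vertex-enumeration optimum", {
  for (topo in c("chain", "dual_substrate", "branched_tca")) {
    tm <- make_toy_model(topo)
    lp <- fba(tm$model)
    enum <- fba_enumerate(tm$model)
    expect_equal(lp$objective_value, enum$objective_value, tolerance = 1e-6,
                 label = paste("LP vs vertex enumeration on", topo))
    expect_equal(lp$objective_value, tm$known_solution$objective_value,
                 tolerance = 1e-6, label = paste("LP vs known optimum on", topo))
  }
})

test_that("measured exchanges pin fluxes and NGAM limits feasibility", {
  td <- make_toy_model("dual_substrate")
  m <- apply_measured_exchanges(
    td$model,
    list(measured_exchange("EX_ace", fixed_zero = TRUE),
         measured_exchange("EX_glc", rate = -4),
         measured_exchange("EX_glu", rate = -10)),
    ngam_lb = 1.9)
  sol <- pfba(m)
  expect_equal(sol$status, "optimal")
  expect_equal(unname(sol$fluxes["EX_ace"]), 0, tolerance = 1e-9)
  expect_equal(unname(sol$fluxes["EX_glc"]), -4, tolerance = 1e-6)
  expect_equal(unname(sol$fluxes["EX_glu"]), -10, tolerance = 1e-6)

  # uptake_positive convention flips the sign on entry
  m2 <- apply_measured_exchanges(td$model,
                                 list(measured_exchange("EX_glc", rate = 4)),
                                 sign_convention = "uptake_positive", ngam_lb = 0)
  expect_equal(m2$reactions$EX_glc$lb, -4)

  # NGAM above the network's maximal ATP regeneration (20 with acetate shut):
  # infeasible, surfaced as status
  m3 <- apply_measured_exchanges(td$model,
                                 list(measured_exchange("EX_ace", fixed_zero = TRUE)),
                                 ngam_lb = 25)
  expect_equal(fba(m3)$status, "infeasible")

  expect_error(apply_measured_exchanges(td$model,
                                        list(measured_exchange("EX_nope", -1))),
               "EX_glc", class = "chemoflux_mapping_error")
})

test_that("zero-secretion constraints force complete oxidation in the dual-substrate net", {
  td <- make_toy_model("dual_substrate")
  free <- fba(td$model)
  expect_equal(free$objective_value, 11.24, tolerance = 1e-6) # secretes acetate
  closed <- apply_measured_exchanges(td$model,
                                     list(measured_exchange("EX_ace", fixed_zero = TRUE)),
                                     ngam_lb = 1.9)
  sol <- pfba(closed)
  # bm/2 + bm/2 + 0.95 = 10  =>  bm = 9.05 via the 2-ATP routes only
  expect_equal(sol$objective_value, 9.05, tolerance = 1e-5)
  expect_equal(unname(sol$fluxes["OVF"]), 0, tolerance = 1e-8)
})

test_that("pFBA prefers the shorter of two equal-yield routes", {
  m <- metabolic_model(
    list(metabolite("S"), metabolite("M"), metabolite("P")),
    list(reaction("EX_s", c(S = -1), lb = -10, ub = 0),
         reaction("DIRECT", c(S = -1, P = 1)),
         reaction("LONG1", c(S = -1, M = 1)),
         reaction("LONG2", c(M = -1, P = 1)),
         reaction("BIOMASS", c(P = -2))),
    objective_id = "BIOMASS")
  sol <- pfba(m)
  expect_equal(sol$objective_value, 5, tolerance = 1e-5)
  expect_equal(unname(sol$fluxes["LONG1"]), 0, tolerance = 1e-8)
  expect_equal(unname(sol$fluxes["DIRECT"]), 10, tolerance = 1e-4)

  # unique optimal flux vector: pFBA equals FBA
  tcm <- make_toy_model("chain")$model
  expect_equal(pfba(tcm, epsilon = 1e-9)$fluxes, fba(tcm)$fluxes, tolerance = 1e-6)
})

test_that("pFBA satisfies the optimality sandwich and mass balance on all toys", {
  for (topo in c("chain", "dual_substrate", "branched_tca")) {
    tm <- make_toy_model(topo)
    opt <- fba(tm$model)$objective_value
    sol <- pfba(tm$model)
    expect_fluxes_balanced(sol, tm$model)
    expect_gte(sol$objective_value, opt * (1 - 1e-6) - 1e-8)
    expect_lte(sol$objective_value, opt + 1e-8)
    expect_lte(sol$total_abs_flux, fba(tm$model)$total_abs_flux + 1e-6)
  }
})

test_that("pFBA total flux is minimal among randomized alternative optima", {
  withr::local_seed(42)
  for (topo in c("chain", "dual_substrate", "branched_tca")) {
    tm <- make_toy_model(topo)
    opt <- fba(tm$model)$objective_value
    psol <- pfba(tm$model)
    for (i in 1:25) {
      alt <- alternative_optimum(tm$model, opt)
      expect_equal(alt$status, "optimal")
      expect_lte(psol$total_abs_flux, alt$total_abs_flux + 1e-5)
    }
  }
})

test_that("optimal objective scales linearly with all bounds (no fixed NGAM)", {
  tm <- make_toy_model("dual_substrate", include_ngam = FALSE)
  base <- fba(tm$model)$objective_value
  for (k in c(0.5, 2, 7)) {
    mk <- tm$model
    for (id in names(mk$reactions)) {
      mk$reactions[[id]]$lb <- mk$reactions[[id]]$lb * k
      mk$reactions[[id]]$ub <- mk$reactions[[id]]$ub * k
    }
    expect_equal(fba(mk)$objective_value, k * base, tolerance = 1e-8)
  }
})

test_that("results agree with an independent constraint-based implementation", {
  # cross-check oracle: cobrapy/GLPK via the system python, fed the same model
  tm <- make_toy_model("branched_tca")
  f <- withr::local_tempfile(fileext = ".json")
  out <- withr::local_tempfile(fileext = ".json")
  write_cobra_json(tm$model, f)
  script <- sprintf(paste0(
    "import json, cobra\n",
    "from cobra.io import load_json_model\n",
    "m = load_json_model('%s')\n",
    "fba = m.optimize()\n",
    "p = cobra.flux_analysis.pfba(m)\n",
    "json.dump({'fba': fba.objective_value, 'pfba_l1': float(sum(abs(p.fluxes))),\n",
    "           'fluxes': {k: float(v) for k, v in p.fluxes.items()}},\n",
    "          open('%s', 'w'))\n"), f, out)
  status <- system2("python", "-", input = script)
  expect_equal(status, 0L)
  ref <- jsonlite::read_json(out)
  ours_fba <- fba(tm$model)
  ours_pfba <- pfba(tm$model, epsilon = 1e-9)
  expect_equal(ours_fba$objective_value, ref$fba, tolerance = 1e-6)
  expect_equal(ours_pfba$total_abs_flux, ref$pfba_l1, tolerance = 1e-5)
  for (id in names(ours_pfba$fluxes))
    expect_equal(unname(ours_pfba$fluxes[id]), ref$fluxes[[id]], tolerance = 1e-5,
                 label = paste("flux", id))
})
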