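#' Stoichiometric matrix of a model
#'
#' Rows are metabolites, columns are reactions, both in declaration order;
#' entry (i, j) is the coefficient of metabolite i in reaction j (negative =
#' consumed).
#'
#' @param model a [metabolic_model()]
#' @return numeric matrix with dimnames (metabolite ids, reaction ids)
#' @export
build_stoichiometric_matrix <- function(model) {
  met_ids <- unname(vapply(model$metabolites, `[[`, "", "id"))
  rxn_ids <- unname(vapply(model$reactions, `[[`, "", "id"))
  S <- matrix(0, length(met_ids), length(rxn_ids),
              dimnames = list(met_ids, rxn_ids))
  for (j in seq_along(model$reactions)) {
    st <- model$reactions[[j]]$stoich
    S[names(st), j] <- st
  }
  S
}

model_bounds <- function(model) {
  list(lb = vapply(model$reactions, `[[`, 0, "lb"),
       ub = vapply(model$reactions, `[[`, 0, "ub"))
}

#' Measured exchange-rate constraint
#'
#' One measured exchange reaction with its rate, standard deviation and an
#' optional zero-fixing flag (for secretion products shown to be absent).
#' Rates follow the exchange-flux convention: negative = uptake,
#' positive = secretion.
#'
#' @param reaction_id exchange reaction id in the model
#' @param rate measured exchange flux [mmol/gDW/h] (signed)
#' @param sd standard deviation of the rate, >= 0
#' @param fixed_zero if `TRUE` the exchange is clamped to exactly zero
#'   (implies `rate = 0`)
#' @return a `measured_exchange` object
#' @export
measured_exchange <- function(reaction_id, rate = 0, sd = 0, fixed_zero = FALSE) {
  if (sd < 0) stop_chemoflux("sd must be >= 0", "chemoflux_constraint_error")
  if (fixed_zero && rate != 0)
    stop_chemoflux("fixed_zero exchanges must have rate = 0", "chemoflux_constraint_error")
  structure(list(reaction_id = reaction_id, rate = rate, sd = sd,
                 fixed_zero = fixed_zero), class = "measured_exchange")
}

#' Constrain a model with measured exchange rates
#'
#' Fixes each measured exchange at its rate (`lb = ub = signed rate`; zero for
#' `fixed_zero` entries) and raises the lower bound of the maintenance (NGAM)
#' reaction, when the model declares one, to `ngam_lb`. With
#' `sign_convention = "uptake_positive"` the rates are negated on entry so
#' that uptake measurements reported as positive magnitudes land on the
#' negative exchange-flux convention.
#'
#' @param model a [metabolic_model()]
#' @param exchanges list of [measured_exchange()]s
#' @param sign_convention `"uptake_negative"` (rates already signed as
#'   exchange fluxes, default) or `"uptake_positive"`
#' @param ngam_lb maintenance lower bound [mmol/gDW/h]; default 1.9
#' @return the constrained model
#' @export
apply_measured_exchanges <- function(model, exchanges,
                                     sign_convention = c("uptake_negative", "uptake_positive"),
                                     ngam_lb = 1.9) {
  sign_convention <- match.arg(sign_convention)
  rxn_ids <- names(model$reactions)
  for (ex in exchanges) {
    if (!ex$reaction_id %in% rxn_ids) {
      guess <- rxn_ids[vapply(model$reactions, function(r) isTRUE(r$is_exchange), TRUE)]
      stop_chemoflux(sprintf(
        "unknown exchange reaction '%s'; model exchanges: %s",
        ex$reaction_id, paste(guess, collapse = ", ")), "chemoflux_mapping_error")
    }
    rate <- if (ex$fixed_zero) 0
            else if (sign_convention == "uptake_positive") -ex$rate
            else ex$rate
    model$reactions[[ex$reaction_id]]$lb <- rate
    model$reactions[[ex$reaction_id]]$ub <- rate
  }
  if (!is.null(model$ngam_id) && model$ngam_id %in% rxn_ids) {
    model$reactions[[model$ngam_id]]$lb <- max(model$reactions[[model$ngam_id]]$lb, ngam_lb)
  }
  model
}

apply_exchange_bounds <- function(model, bounds_df) {
  for (i in seq_len(nrow(bounds_df))) {
    rid <- bounds_df$reaction_id[i]
    if (!rid %in% names(model$reactions))
      stop_chemoflux(sprintf("unknown exchange reaction '%s'", rid), "chemoflux_mapping_error")
    model$reactions[[rid]]$lb <- bounds_df$lb[i]
    model$reactions[[rid]]$ub <- bounds_df$ub[i]
  }
  model
}

# Core LP over the flux polytope {S v = 0, lb <= v <= ub}.
#
# The simplex backend wants non-negative variables, so fluxes are
# re-expressed before solving: a pinned flux (lb == ub) is eliminated and
# folded into the constraint constants; a flux with lb >= 0 is shifted
# (v = lb + w); one with ub <= 0 is reflected (v = ub - w); only
# sign-indefinite fluxes (lb < 0 < ub) are split into v = w+ - w-. The split
# pair doubles as the exact linearization of |v| for the L1 stage of pFBA
# (`l1 = TRUE` minimizes sum(|v|) up to a constant).
#
# objective: vector in flux space; extra: list(A, dir, rhs) additional rows in
# flux space with dir in {'<=','>='}. Returns the flux vector, not the raw
# solver value.
solve_lp <- function(S, lb, ub, objective = NULL, l1 = FALSE,
                     maximize = TRUE, extra = NULL) {
  n <- ncol(S)
  cols <- list(); consts <- numeric(n); ranges <- numeric(0)
  owner <- integer(0)    # reaction index per variable
  sign_of <- numeric(0)  # +1 for shifted, -1 for reflected, +/-1 for split halves
  for (j in seq_len(n)) {
    if (is.finite(lb[j]) && lb[j] == ub[j]) {
      consts[j] <- lb[j]
    } else if (lb[j] >= 0) {
      consts[j] <- lb[j]
      owner <- c(owner, j); sign_of <- c(sign_of, 1)
      ranges <- c(ranges, ub[j] - lb[j])
    } else if (ub[j] <= 0) {
      consts[j] <- ub[j]
      owner <- c(owner, j); sign_of <- c(sign_of, -1)
      ranges <- c(ranges, ub[j] - lb[j])
    } else {
      owner <- c(owner, j, j); sign_of <- c(sign_of, 1, -1)
      ranges <- c(ranges, ub[j], -lb[j])
    }
  }
  nv <- length(owner)
  if (nv == 0L) {  # fully pinned system: feasibility is a direct check
    v <- stats::setNames(consts, colnames(S))
    feasible <- max(abs(S %*% consts)) <= 1e-9 &&
      (is.null(extra) || all(ifelse(extra$dir == "<=", 1, -1) *
                               (as.numeric(extra$A %*% consts) - extra$rhs) <= 1e-9))
    if (!feasible) return(list(status = "infeasible", value = NA_real_, v = NULL))
    value <- if (l1) sum(abs(v)) else sum(objective * v)
    return(list(status = "optimal", value = value, v = v))
  }
  Mmat <- matrix(0, n, nv)
  for (k in seq_len(nv)) Mmat[owner[k], k] <- sign_of[k]

  rows <- list(); rhs <- numeric(0); dir <- character(0)
  for (k in seq_len(nv)) {
    if (is.finite(ranges[k])) {
      row <- numeric(nv); row[k] <- 1
      rows[[length(rows) + 1L]] <- row; rhs <- c(rhs, ranges[k]); dir <- c(dir, "<=")
    }
  }
  if (!is.null(extra)) {
    for (i in seq_along(extra$rhs)) {
      rowv <- extra$A[i, ]
      rows[[length(rows) + 1L]] <- as.numeric(rowv %*% Mmat)
      rhs <- c(rhs, extra$rhs[i] - sum(rowv * consts))
      dir <- c(dir, extra$dir[i])
    }
  }
  Aeq <- S %*% Mmat
  A <- rbind(do.call(rbind, rows), Aeq)
  bvec <- c(rhs, as.numeric(-S %*% consts))
  dvec <- c(dir, rep("=", nrow(Aeq)))

  a <- if (l1) rep(1, nv) else as.numeric(objective %*% Mmat)
  if (maximize && !l1) a <- -a
  res <- simplex_core(a, A, bvec, dvec)
  if (res$status != "optimal")
    return(list(status = res$status, value = NA_real_, v = NULL))
  v <- consts + as.numeric(Mmat %*% res$x)
  names(v) <- colnames(S)
  value <- if (l1) sum(abs(v)) else sum(objective * v)
  list(status = "optimal", value = value, v = v)
}

flux_solution <- function(status, objective_value = NA_real_, fluxes = NULL) {
  structure(list(status = status, objective_value = objective_value,
                 fluxes = fluxes,
                 total_abs_flux = if (is.null(fluxes)) NA_real_ else sum(abs(fluxes))),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat(sprintf("<flux_solution: %s, objective %.6g, total |v| %.6g>\n",
              x$status, x$objective_value, x$total_abs_flux))
  invisible(x)
}

#' Flux balance analysis
#'
#' Maximizes the flux through the model's objective reaction subject to the
#' steady-state constraint `S v = 0` and the flux bounds. Infeasibility and
#' unboundedness are reported in the solution status, never silently.
#'
#' @param model a [metabolic_model()]
#' @return a `flux_solution` with fields `status`, `objective_value`,
#'   `fluxes` (named), `total_abs_flux`
#' @export
fba <- function(model) {
  S <- build_stoichiometric_matrix(model)
  b <- model_bounds(model)
  obj <- as.numeric(colnames(S) == model$objective_id)
  res <- solve_lp(S, b$lb, b$ub, objective = obj, maximize = TRUE)
  if (res$status != "optimal") return(flux_solution(res$status))
  flux_solution("optimal", res$value, res$v)
}

#' Parsimonious flux balance analysis
#'
#' Two-stage LP: first the ordinary FBA optimum is computed; then, with the
#' objective flux constrained to at least `optimum_fraction` times that
#' optimum (minus a small relative tolerance), the total absolute flux
#' `sum(|v|)` is minimized over the split `v = v+ - v-`. The reported
#' objective value is the realized objective flux of the parsimonious
#' solution.
#'
#' @param model a [metabolic_model()]
#' @param optimum_fraction fraction of the stage-1 optimum to enforce
#'   (default 1.0)
#' @param epsilon relative slack on the enforced optimum (default 1e-6)
#' @return a `flux_solution`
#' @export
pfba <- function(model, optimum_fraction = 1.0, epsilon = 1e-6) {
  stage1 <- fba(model)
  if (stage1$status != "optimal") return(stage1)
  opt <- stage1$objective_value

  S <- build_stoichiometric_matrix(model)
  b <- model_bounds(model)
  n <- ncol(S)
  obj <- as.numeric(colnames(S) == model$objective_id)
  floor_val <- optimum_fraction * opt - (abs(opt) * epsilon + 1e-9)
  extra <- list(A = matrix(obj, 1), dir = ">=", rhs = floor_val)
  res <- solve_lp(S, b$lb, b$ub, l1 = TRUE, maximize = FALSE, extra = extra)
  if (res$status != "optimal") return(flux_solution(res$status))
  flux_solution("optimal", unname(res$v[model$objective_id]), res$v)
}

#' Exact FBA optimum by exhaustive vertex enumeration
#'
#' Independent reference method for small networks: enumerates every vertex of
#' the flux polytope `{S v = 0, lb <= v <= ub}` (all choices of
#' `n - rank(S)` reactions pinned at a bound) and evaluates the objective at
#' each. Exponential in the number of reactions; intended for models with at
#' most ~10 reactions as an oracle against the LP path.
#'
#' @param model a [metabolic_model()]
#' @param tol feasibility tolerance for bound/balance checks
#' @return list with `status`, `objective_value`, `fluxes` (an optimal
#'   vertex), and `vertices` (matrix, one row per vertex)
#' @export
fba_enumerate <- function(model, tol = 1e-8) {
  S <- build_stoichiometric_matrix(model)
  b <- model_bounds(model)
  n <- ncol(S)
  qrS <- qr(S)
  r <- qrS$rank
  k <- n - r
  verts <- list()
  if (k == 0L) {
    sol <- qr.solve(S, rep(0, nrow(S)))
    if (all(sol >= b$lb - tol & sol <= b$ub + tol)) verts[[1]] <- sol
  } else {
    fixed_sets <- utils::combn(n, k, simplify = FALSE)
    for (fix in fixed_sets) {
      free <- setdiff(seq_len(n), fix)
      Sb <- S[, free, drop = FALSE]
      if (qr(Sb)$rank < r) next
      for (mask in seq_len(2^k) - 1L) {
        at_ub <- bitwAnd(rep(mask, k), 2^(seq_len(k) - 1L)) > 0
        vf <- ifelse(at_ub, b$ub[fix], b$lb[fix])
        if (any(!is.finite(vf))) next
        rhs <- -S[, fix, drop = FALSE] %*% vf
        vb <- tryCatch(qr.solve(Sb, rhs), error = function(e) NULL)
        if (is.null(vb)) next
        v <- numeric(n)
        v[fix] <- vf
        v[free] <- vb
        if (max(abs(S %*% v)) > 1e-6) next
        if (any(v < b$lb - tol | v > b$ub + tol)) next
        verts[[length(verts) + 1L]] <- v
      }
    }
  }
  if (!length(verts)) return(list(status = "infeasible", objective_value = NA_real_,
                                  fluxes = NULL, vertices = NULL))
  V <- unique(round(do.call(rbind, verts), 9))
  colnames(V) <- colnames(S)
  objv <- V[, model$objective_id]
  best <- which.max(objv)
  list(status = "optimal", objective_value = unname(objv[best]),
       fluxes = V[best, ], vertices = V)
}

#' Alternative optimum under a randomized objective
#'
#' Fixes the model objective at (near) a given optimal value and maximizes a
#' random linear objective instead, yielding an alternative optimal flux
#' vector. Used to probe the optimal face when checking that the parsimonious
#' solution has minimal total flux among alternative optima.
#'
#' @param model a [metabolic_model()]
#' @param opt_value objective value to enforce
#' @param weights numeric vector of length `n_reactions` (the random
#'   objective); drawn uniformly from [-1, 1] if `NULL`
#' @param epsilon relative slack on the enforced optimum
#' @return a `flux_solution` on the optimal face (or non-optimal status)
#' @export
alternative_optimum <- function(model, opt_value, weights = NULL, epsilon = 1e-6) {
  S <- build_stoichiometric_matrix(model)
  b <- model_bounds(model)
  n <- ncol(S)
  if (is.null(weights)) weights <- stats::runif(n, -1, 1)
  obj <- as.numeric(colnames(S) == model$objective_id)
  floor_val <- opt_value - (abs(opt_value) * epsilon + 1e-9)
  extra <- list(A = matrix(obj, 1), dir = ">=", rhs = floor_val)
  res <- solve_lp(S, b$lb, b$ub, objective = weights, maximize = TRUE, extra = extra)
  if (res$status != "optimal") return(flux_solution(res$status))
  flux_solution("optimal", unname(res$v[model$objective_id]), res$v)
}
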