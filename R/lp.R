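# Dense two-phase primal simplex with Bland's anti-cycling rule.
#
# Solves  min c'x  s.t.  A x {<=,>=,=} b,  x >= 0.
# Small and deterministic by construction: FBA-type problems are highly
# degenerate (many zero right-hand sides), which is exactly where naive
# pivoting rules stall or cycle, so entering/leaving choices follow Bland's
# smallest-index rule throughout. Intended for the small LPs this package
# builds (tens of variables); everything is dense base R.
#
# Returns list(status = "optimal"|"infeasible"|"unbounded", x, value).
simplex_core <- function(c_vec, A, b, dir, tol = 1e-9, max_iter = 20000L) {
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(b) == m, length(dir) == m, length(c_vec) == n)

  flip <- b < 0
  if (any(flip)) {
    A[flip, ] <- -A[flip, , drop = FALSE]
    b[flip] <- -b[flip]
    dir[flip] <- c("<=" = ">=", ">=" = "<=", "=" = "=")[dir[flip]]
  }

  slack_sign <- ifelse(dir == "<=", 1, ifelse(dir == ">=", -1, 0))
  n_slack <- sum(slack_sign != 0)
  ntot <- n + n_slack
  Aall <- cbind(A, matrix(0, m, n_slack))
  k <- n
  slack_of <- rep(NA_integer_, m)
  for (i in seq_len(m)) {
    if (slack_sign[i] != 0) {
      k <- k + 1L
      Aall[i, k] <- slack_sign[i]
      slack_of[i] <- k
    }
  }

  # initial basis: the +1 slack where available, otherwise an artificial
  basis <- integer(m)
  n_art <- 0L
  for (i in seq_len(m)) {
    if (!is.na(slack_of[i]) && slack_sign[i] == 1) {
      basis[i] <- slack_of[i]
    } else {
      n_art <- n_art + 1L
      col <- numeric(m); col[i] <- 1
      Aall <- cbind(Aall, col)
      basis[i] <- ntot + n_art
    }
  }
  ncols <- ntot + n_art
  tab <- cbind(Aall, b)   # rows already in basis form (identity basis columns)

  # one simplex run on the current tableau; candidates limits entering columns
  iterate <- function(tab, basis, cost, candidates) {
    it <- 0L
    repeat {
      d <- cost - as.numeric(cost[basis] %*% tab[, seq_len(ncols), drop = FALSE])
      enter <- candidates[which(d[candidates] < -tol)]
      if (!length(enter)) return(list(tab = tab, basis = basis, status = "optimal"))
      j <- min(enter)                       # Bland: smallest eligible index
      col <- tab[, j]
      pos <- which(col > tol)
      if (!length(pos)) return(list(tab = tab, basis = basis, status = "unbounded"))
      ratios <- tab[pos, ncols + 1L] / col[pos]
      best <- min(ratios)
      cand_rows <- pos[ratios <= best + tol]
      i <- cand_rows[which.min(basis[cand_rows])]  # Bland on ties
      piv <- tab[i, j]
      tab[i, ] <- tab[i, ] / piv
      other <- setdiff(seq_len(m), i)
      tab[other, ] <- tab[other, ] - outer(tab[other, j], tab[i, ])
      basis[i] <- j
      it <- it + 1L
      if (it > max_iter) return(list(tab = tab, basis = basis, status = "iteration-limit"))
    }
  }

  if (n_art > 0L) {
    cost1 <- c(rep(0, ntot), rep(1, n_art))
    ph1 <- iterate(tab, basis, cost1, candidates = seq_len(ncols))
    if (ph1$status != "optimal") return(list(status = "infeasible", x = NULL, value = NA_real_))
    tab <- ph1$tab; basis <- ph1$basis
    if (sum(tab[basis > ntot, ncols + 1L]) > 1e-7)
      return(list(status = "infeasible", x = NULL, value = NA_real_))
    # drive artificials still basic (at zero) out of the basis, or drop the row
    keep <- rep(TRUE, m)
    for (i in which(basis > ntot)) {
      j <- which(abs(tab[i, seq_len(ntot)]) > tol)
      j <- j[!j %in% basis]
      if (length(j)) {
        j <- j[1]
        piv <- tab[i, j]
        tab[i, ] <- tab[i, ] / piv
        other <- setdiff(seq_len(m), i)
        tab[other, ] <- tab[other, ] - outer(tab[other, j], tab[i, ])
        basis[i] <- j
      } else {
        keep[i] <- FALSE                    # redundant constraint row
      }
    }
    if (!all(keep)) {
      tab <- tab[keep, , drop = FALSE]
      basis <- basis[keep]
      m <- nrow(tab)
    }
  }

  # artificials are either out of the basis or their rows were dropped above,
  # and `candidates` keeps them from re-entering, so their phase-2 cost is moot
  cost2 <- c(c_vec, rep(0, n_slack), rep(0, max(ncols - ntot, 0)))
  ph2 <- iterate(tab, basis, cost2, candidates = seq_len(ntot))
  if (ph2$status == "unbounded") return(list(status = "unbounded", x = NULL, value = NA_real_))
  if (ph2$status != "optimal") return(list(status = "infeasible", x = NULL, value = NA_real_))
  x <- numeric(ntot)
  ok <- ph2$basis <= ntot
  x[ph2$basis[ok]] <- ph2$tab[ok, ncols + 1L]
  list(status = "optimal", x = x[seq_len(n)], value = sum(c_vec * x[seq_len(n)]))
}
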