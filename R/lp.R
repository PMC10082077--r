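# Flux linear programs solved as ridge-regularized quadratic programs.
#
# maximize c'v - eps * ||v||^2  subject to  A v = b, lb <= v <= ub
#
# The tiny strictly-convex ridge makes the solution unique: among alternate
# LP optima the minimum-norm (parsimonious) flux vector is returned, which
# keeps downstream statistics deterministic. At a nondegenerate vertex
# optimum the solution is exact for small eps (the active set is stable), so
# the reported objective matches the LP optimum to machine precision.
#
# A presolve pass first propagates variables that the equalities force to a
# constant (singleton rows; same-sign rows with zero right-hand side over
# nonnegative variables). This removes the degeneracies that the
# Goldfarb-Idnani active-set method cannot stomach, and detects most
# infeasibilities outright.

lp_bounded <- function(obj, A_eq, b_eq, lb, ub, eps = 1e-6) {
  n <- length(obj)
  stopifnot(ncol(A_eq) == n, length(b_eq) == nrow(A_eq),
            length(lb) == n, length(ub) == n)
  if (any(lb > ub + 1e-12)) {
    return(list(x = rep(NA_real_, n), objective = 0, status = "infeasible"))
  }
  tol <- 1e-9
  fixed_val <- rep(NA_real_, n)
  fixed_val[ub - lb <= 1e-12] <- lb[ub - lb <= 1e-12]

  # constraint propagation until a fixed point
  repeat {
    changed <- FALSE
    is_free <- is.na(fixed_val)
    resid <- b_eq - as.vector(A_eq %*% ifelse(is_free, 0, fixed_val))
    for (i in seq_len(nrow(A_eq))) {
      nz <- which(is_free & A_eq[i, ] != 0)
      if (length(nz) == 0) {
        if (abs(resid[i]) > 1e-8) {
          return(list(x = rep(NA_real_, n), objective = 0,
                      status = "infeasible"))
        }
      } else if (length(nz) == 1) {
        val <- resid[i] / A_eq[i, nz]
        if (val < lb[nz] - 1e-8 || val > ub[nz] + 1e-8) {
          return(list(x = rep(NA_real_, n), objective = 0,
                      status = "infeasible"))
        }
        fixed_val[nz] <- val
        changed <- TRUE
      } else if (abs(resid[i]) <= tol) {
        a <- A_eq[i, nz]
        # every term sign-constrained the same way => all must vanish
        nonneg <- all((a > 0 & lb[nz] >= -tol) | (a < 0 & ub[nz] <= tol))
        nonpos <- all((a < 0 & lb[nz] >= -tol) | (a > 0 & ub[nz] <= tol))
        if (nonneg || nonpos) {
          if (any(lb[nz] > tol | ub[nz] < -tol)) {
            return(list(x = rep(NA_real_, n), objective = 0,
                        status = "infeasible"))
          }
          fixed_val[nz] <- 0
          changed <- TRUE
        }
      }
      if (changed) break
    }
    if (!changed) break
  }

  free <- which(is.na(fixed_val))
  v <- ifelse(is.na(fixed_val), 0, fixed_val)
  b_adj <- b_eq - as.vector(A_eq %*% v)
  if (!length(free)) {
    if (max(abs(b_adj)) > 1e-8) {
      return(list(x = rep(NA_real_, n), objective = 0, status = "infeasible"))
    }
    return(list(x = v, objective = sum(obj * v), status = "optimal"))
  }
  A <- A_eq[, free, drop = FALSE]
  live <- rowSums(A != 0) > 0
  if (any(abs(b_adj[!live]) > 1e-8)) {
    return(list(x = rep(NA_real_, n), objective = 0, status = "infeasible"))
  }
  A <- A[live, , drop = FALSE]
  b_live <- b_adj[live]
  # drop linearly dependent equality rows (duplicates arise when reactions
  # are fixed), verifying that their right-hand sides stay consistent
  if (nrow(A) > 1) {
    qt <- qr(t(A))
    if (qt$rank < nrow(A)) {
      keep <- sort(qt$pivot[seq_len(qt$rank)])
      drop_r <- setdiff(seq_len(nrow(A)), keep)
      lam <- qr.solve(t(A[keep, , drop = FALSE]),
                      t(A[drop_r, , drop = FALSE]))
      b_implied <- drop(crossprod(lam, b_live[keep]))
      if (max(abs(b_implied - b_live[drop_r])) > 1e-8) {
        return(list(x = rep(NA_real_, n), objective = 0,
                    status = "infeasible"))
      }
      A <- A[keep, , drop = FALSE]
      b_live <- b_live[keep]
    }
  }
  m <- length(free)
  Amat <- cbind(if (nrow(A)) t(A) else NULL, diag(m), -diag(m))
  bvec <- c(b_live, lb[free], -ub[free])
  sol <- NULL
  for (e in c(eps, eps * 100)) {
    sol <- tryCatch(
      quadprog::solve.QP(Dmat = diag(2 * e, m), dvec = obj[free],
                         Amat = Amat, bvec = bvec, meq = nrow(A)),
      error = function(err) NULL
    )
    if (!is.null(sol)) break
  }
  if (!is.null(sol)) {
    v[free] <- sol$solution
    return(list(x = v, objective = sum(obj * v), status = "optimal"))
  }
  # degenerate geometries that defeat the active-set QP go to a
  # deterministic Bland's-rule simplex (vertex solution, no ridge)
  sx <- simplex_bland(obj[free], A, b_live, lb[free], ub[free])
  if (is.null(sx)) {
    return(list(x = rep(NA_real_, n), objective = 0, status = "infeasible"))
  }
  v[free] <- sx
  list(x = v, objective = sum(obj * v), status = "optimal")
}

# Dense two-phase simplex, maximizing c'v subject to A v = b, lb <= v <= ub.
# Bland's anti-cycling rule makes it terminate and fully deterministic.
# Upper bounds are handled as explicit slack rows; scale is tiny here
# (toy metabolic networks), so the dense tableau is fine.
simplex_bland <- function(c_obj, A, b, lb, ub) {
  n <- length(c_obj)
  # shift to x = v - lb >= 0, cap infinite widths
  width <- pmin(ub - lb, 1e6)
  b2 <- b - as.vector(A %*% lb)
  # standard form: [A 0; I I] [x; s] = [b2; width], x, s >= 0
  m_eq <- nrow(A)
  Afull <- rbind(cbind(A, matrix(0, m_eq, n)), cbind(diag(n), diag(n)))
  bfull <- c(b2, width)
  # make rhs nonnegative
  neg <- bfull < 0
  Afull[neg, ] <- -Afull[neg, , drop = FALSE]
  bfull <- abs(bfull)
  m_all <- nrow(Afull)
  n_all <- ncol(Afull)
  cfull <- c(c_obj, rep(0, n))

  tab <- cbind(Afull, diag(m_all), bfull)      # artificial basis
  basis <- n_all + seq_len(m_all)
  run_simplex <- function(tab, basis, cost) {
    repeat {
      cb <- cost[basis]
      z <- drop(crossprod(cb, tab[, seq_len(n_all + m_all), drop = FALSE]))
      red <- cost[seq_len(n_all + m_all)] - z
      enter <- which(red > 1e-9)
      if (!length(enter)) return(list(tab = tab, basis = basis))
      j <- min(enter)                          # Bland: lowest index enters
      col <- tab[, j]
      pos <- which(col > 1e-9)
      if (!length(pos)) return(NULL)           # unbounded
      ratio <- tab[pos, ncol(tab)] / col[pos]
      cand <- pos[ratio <= min(ratio) + 1e-9]
      i <- cand[which.min(basis[cand])]        # Bland: lowest basis leaves
      piv <- tab[i, j]
      tab[i, ] <- tab[i, ] / piv
      for (r in seq_len(nrow(tab))[-i]) {
        tab[r, ] <- tab[r, ] - tab[r, j] * tab[i, ]
      }
      basis[i] <- j
      tab_basis <- list(tab = tab, basis = basis)
      tab <- tab_basis$tab; basis <- tab_basis$basis
    }
  }
  # phase 1: drive artificials out
  cost1 <- c(rep(0, n_all), rep(-1, m_all))
  ph1 <- run_simplex(tab, basis, cost1)
  if (is.null(ph1)) return(NULL)
  infeas <- -sum(cost1[ph1$basis] * ph1$tab[, ncol(ph1$tab)])
  if (infeas > 1e-7) return(NULL)
  # phase 2 on the original objective (artificials barred by -Inf cost)
  cost2 <- c(cfull, rep(-1e12, m_all))
  ph2 <- run_simplex(ph1$tab, ph1$basis, cost2)
  if (is.null(ph2)) return(NULL)
  x <- numeric(n_all)
  in_x <- ph2$basis <= n_all
  x[ph2$basis[in_x]] <- ph2$tab[in_x, ncol(ph2$tab)]
  x[seq_len(n)] + lb
}
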