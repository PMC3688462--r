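# Independent brute-force oracle: exhaustive enumeration of the vertices of
# the flux polytope {A v (sense) rhs, lb <= v <= ub}. Linear (and
# linear-fractional) optima over a bounded polytope are attained at
# vertices, so the maximum over the enumerated vertex set is an
# LP-solver-free reference value. Only usable for small fixtures.

enumerate_vertices <- function(p, tol = 1e-7) {
  vars <- colnames(p$A)
  n <- length(vars)
  Eq <- p$A[p$sense == "=", , drop = FALSE]
  f <- p$rhs[p$sense == "="]
  G <- rbind(p$A[p$sense == "<=", , drop = FALSE],
             -p$A[p$sense == ">=", , drop = FALSE])
  h <- c(p$rhs[p$sense == "<="], -p$rhs[p$sense == ">="])
  lb <- p$lb[vars]; ub <- p$ub[vars]
  I <- diag(n)
  G <- rbind(G, I[is.finite(ub), , drop = FALSE],
             -I[is.finite(lb), , drop = FALSE])
  h <- c(h, ub[is.finite(ub)], -lb[is.finite(lb)])
  rk <- if (nrow(Eq)) qr(Eq)$rank else 0
  d <- n - rk
  feasible <- function(v) {
    all(is.finite(v)) &&
      (!nrow(Eq) || max(abs(Eq %*% v - f)) < tol) &&
      (!nrow(G) || all(G %*% v <= h + tol))
  }
  verts <- list()
  combs <- if (d == 0) list(integer(0)) else
    utils::combn(nrow(G), d, simplify = FALSE)
  for (cmb in combs) {
    M <- rbind(Eq, G[cmb, , drop = FALSE])
    b <- c(f, h[cmb])
    if (qr(M)$rank < n) next
    v <- tryCatch(qr.solve(qr(M, tol = 1e-10), b), error = function(e) NULL)
    if (is.null(v) || !feasible(v)) next
    verts[[length(verts) + 1L]] <- round(v, 9)
  }
  if (!length(verts)) return(matrix(numeric(0), 0, n,
                                    dimnames = list(NULL, vars)))
  V <- unique(do.call(rbind, verts))
  colnames(V) <- vars
  V
}

# oracle optimum of a linear objective: max/min over vertices
vertex_optimum <- function(p, objective, maximize = TRUE) {
  V <- enumerate_vertices(p)
  if (!nrow(V)) return(NULL)
  obj <- stats::setNames(numeric(ncol(V)), colnames(V))
  obj[names(objective)] <- objective
  vals <- drop(V %*% obj)
  i <- if (maximize) which.max(vals) else which.min(vals)
  list(objval = vals[i], vertex = V[i, ], all_values = vals, vertices = V)
}

# oracle optimum of a fractional objective f(v)/sum(|v|) over internal
# reactions. On each sign-orthant of the reversible reactions the objective
# is linear-fractional, hence vertex-attained; enumerate every orthant piece
# (vertices of the polytope cut by v_j >= 0 / v_j <= 0 per reversible j).
vertex_fractional_optimum <- function(p, f_rxn, over) {
  rev_ids <- over[p$lb[over] < 0]
  signsets <- expand.grid(rep(list(c(1, -1)), length(rev_ids)))
  best <- list(objval = -Inf)
  for (k in seq_len(max(1, nrow(signsets)))) {
    q <- p
    if (length(rev_ids)) {
      for (j in seq_along(rev_ids)) {
        s <- if (nrow(signsets)) signsets[k, j] else 1
        q <- add_constraint_row(q, stats::setNames(s, rev_ids[j]), ">=", 0,
                                paste0("orthant_", rev_ids[j]))
      }
    }
    V <- enumerate_vertices(q)
    if (!nrow(V)) next
    ratios <- apply(V, 1, function(v) {
      g <- sum(abs(v[over]))
      if (g < 1e-12) -Inf else v[[f_rxn]] / g
    })
    i <- which.max(ratios)
    if (ratios[i] > best$objval)
      best <- list(objval = ratios[i], vertex = V[i, ])
  }
  best
}
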