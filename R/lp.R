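#' Solve a linear program
#'
#' Dense two-phase primal simplex with Bland's anti-cycling rule, supporting
#' mixed equality/inequality rows and per-variable bounds (including infinite
#' and negative bounds). This is the numerical core behind every flux-balance
#' optimization in the package; problem sizes here are small (tens to a few
#' hundred variables), so a dense tableau with a termination-guaranteed pivot
#' rule is preferred over speed.
#'
#' @param obj numeric objective coefficients, length `n`.
#' @param A constraint matrix (`m x n`); may have zero rows.
#' @param sense character vector of `"<="`, `">="`, `"="`, length `m`.
#' @param rhs numeric right-hand sides, length `m`.
#' @param lb,ub variable bounds, length `n`; `-Inf`/`Inf` allowed.
#' @param maximize logical; maximize instead of minimize.
#' @param tol numeric feasibility/pivot tolerance.
#' @param max_iter simplex iteration cap per phase.
#'
#' @return A list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   `objval`, and `x` (solution in the original variable space; `NA` unless
#'   optimal).
#' @export
solve_lp <- function(obj, A, sense, rhs, lb = rep(0, length(obj)),
                     ub = rep(Inf, length(obj)), maximize = FALSE,
                     tol = 1e-9, max_iter = 20000L) {
  n <- length(obj)
  A <- matrix(as.numeric(A), nrow = length(rhs), ncol = n)
  stopifnot(length(sense) == length(rhs), length(lb) == n, length(ub) == n)
  if (any(lb > ub + tol)) {
    return(list(status = "infeasible", objval = NA_real_, x = rep(NA_real_, n)))
  }
  if (any(!sense %in% c("<=", ">=", "="))) stop("sense must be one of <=, >=, =")

  cc <- if (maximize) -obj else obj

  ## --- translate to standard form: min c'y, Ay {<=,>=,=} b, y >= 0 ---------
  ## Each original variable becomes one or two nonnegative columns plus,
  ## where both bounds are finite, an extra <= row for the upper bound.
  cols <- list()      # per-original-var: list(idx, sign, shift)
  std_c <- numeric(0)
  std_A <- matrix(0, nrow = nrow(A), ncol = 0)
  const <- 0
  extra_rows <- list()  # list(col, rhs) for upper-bound rows on shifted vars
  for (j in seq_len(n)) {
    aj <- A[, j, drop = FALSE]
    if (is.finite(lb[j])) {
      ## x = lb + y, y >= 0
      k <- ncol(std_A) + 1L
      std_A <- cbind(std_A, aj)
      std_c <- c(std_c, cc[j])
      const <- const + cc[j] * lb[j]
      rhs <- rhs - A[, j] * lb[j]
      cols[[j]] <- list(idx = k, sign = 1, shift = lb[j])
      if (is.finite(ub[j])) extra_rows[[length(extra_rows) + 1L]] <-
          list(col = k, rhs = ub[j] - lb[j])
    } else if (is.finite(ub[j])) {
      ## x = ub - y, y >= 0
      k <- ncol(std_A) + 1L
      std_A <- cbind(std_A, -aj)
      std_c <- c(std_c, -cc[j])
      const <- const + cc[j] * ub[j]
      rhs <- rhs - A[, j] * ub[j]
      cols[[j]] <- list(idx = k, sign = -1, shift = ub[j])
    } else {
      ## free: x = y+ - y-
      k <- ncol(std_A) + 1L
      std_A <- cbind(std_A, aj, -aj)
      std_c <- c(std_c, cc[j], -cc[j])
      cols[[j]] <- list(idx = c(k, k + 1L), sign = c(1, -1), shift = 0)
    }
  }
  m0 <- nrow(std_A)
  if (length(extra_rows)) {
    for (er in extra_rows) {
      row <- numeric(ncol(std_A)); row[er$col] <- 1
      std_A <- rbind(std_A, row)
      rhs <- c(rhs, er$rhs)
      sense <- c(sense, "<=")
    }
  }
  m <- nrow(std_A)

  ## slacks/surplus
  nstruct <- ncol(std_A)
  slack_cols <- integer(0)
  for (i in seq_len(m)) {
    if (sense[i] == "<=") {
      v <- numeric(m); v[i] <- 1
      std_A <- cbind(std_A, v); std_c <- c(std_c, 0)
      slack_cols <- c(slack_cols, ncol(std_A))
    } else if (sense[i] == ">=") {
      v <- numeric(m); v[i] <- -1
      std_A <- cbind(std_A, v); std_c <- c(std_c, 0)
      slack_cols <- c(slack_cols, ncol(std_A))
    }
  }
  ## normalize rhs >= 0
  neg <- rhs < 0
  if (any(neg)) {
    std_A[neg, ] <- -std_A[neg, , drop = FALSE]
    rhs[neg] <- -rhs[neg]
  }
  ntot <- ncol(std_A)

  ## Phase 1: artificial basis. Where a slack column forms a unit column with
  ## positive rhs sign we could reuse it, but artificials everywhere is simpler
  ## and the problems are small.
  art <- ntot + seq_len(m)
  T_A <- cbind(std_A, diag(m))
  basis <- art
  p1 <- .simplex_iterate(T_A, rhs, c(rep(0, ntot), rep(1, m)), basis, tol, max_iter)
  if (p1$status != "optimal") {
    return(list(status = "infeasible", objval = NA_real_, x = rep(NA_real_, n)))
  }
  if (p1$objval > 1e-7) {
    return(list(status = "infeasible", objval = NA_real_, x = rep(NA_real_, n)))
  }
  T_A <- p1$A; brhs <- p1$b; basis <- p1$basis
  ## drive remaining artificials out of the basis
  keep <- rep(TRUE, length(basis))
  for (i in seq_along(basis)) {
    if (basis[i] > ntot) {
      piv <- which(abs(T_A[i, seq_len(ntot)]) > 1e-8)
      piv <- setdiff(piv, basis)
      if (length(piv)) {
        j <- piv[1L]
        fac <- T_A[i, j]
        T_A[i, ] <- T_A[i, ] / fac; brhs[i] <- brhs[i] / fac
        for (r in seq_len(nrow(T_A))) if (r != i && abs(T_A[r, j]) > 0) {
          brhs[r] <- brhs[r] - T_A[r, j] * brhs[i]
          T_A[r, ] <- T_A[r, ] - T_A[r, j] * T_A[i, ]
        }
        basis[i] <- j
      } else {
        keep[i] <- FALSE  # redundant row
      }
    }
  }
  T_A <- T_A[keep, , drop = FALSE]; brhs <- brhs[keep]; basis <- basis[keep]

  ## Phase 2 on structural + slack columns only
  T_A2 <- T_A[, seq_len(ntot), drop = FALSE]
  p2 <- .simplex_iterate(T_A2, brhs, std_c, basis, tol, max_iter)
  if (p2$status == "unbounded") {
    return(list(status = "unbounded", objval = if (maximize) Inf else -Inf,
                x = rep(NA_real_, n)))
  }
  if (p2$status != "optimal") {
    return(list(status = "infeasible", objval = NA_real_, x = rep(NA_real_, n)))
  }
  y <- numeric(ntot)
  y[p2$basis] <- p2$b
  x <- numeric(n)
  for (j in seq_len(n)) {
    cj <- cols[[j]]
    x[j] <- sum(cj$sign * y[cj$idx]) + cj$shift
  }
  objval <- sum(obj * x)
  list(status = "optimal", objval = objval, x = x)
}

## One run of the primal simplex on tableau (A | b) with basis giving an
## identity submatrix and b >= 0. Bland's rule (least-index entering and
## leaving) guarantees termination on degenerate problems.
.simplex_iterate <- function(A, b, cost, basis, tol, max_iter) {
  m <- nrow(A)
  for (it in seq_len(max_iter)) {
    cb <- cost[basis]
    ## reduced costs
    r <- cost - as.vector(crossprod(A, cb))
    r[basis] <- 0
    enter_cand <- which(r < -tol)
    if (!length(enter_cand)) {
      return(list(status = "optimal", A = A, b = b, basis = basis,
                  objval = sum(cb * b)))
    }
    j <- min(enter_cand)  # Bland
    col <- A[, j]
    pos <- which(col > tol)
    if (!length(pos)) return(list(status = "unbounded"))
    ratio <- b[pos] / col[pos]
    rmin <- min(ratio)
    ties <- pos[ratio <= rmin + tol]
    i <- ties[which.min(basis[ties])]  # Bland on leaving variable
    ## pivot on (i, j)
    piv <- A[i, j]
    A[i, ] <- A[i, ] / piv; b[i] <- b[i] / piv
    other <- which(abs(A[, j]) > 0); other <- setdiff(other, i)
    if (length(other)) {
      fac <- A[other, j]
      b[other] <- b[other] - fac * b[i]
      A[other, ] <- A[other, , drop = FALSE] - outer(fac, A[i, ])
    }
    b[b < 0 & b > -1e-11] <- 0
    basis[i] <- j
  }
  list(status = "maxiter")
}
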