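#' Build the steady-state flux polytope of a model
#'
#' Returns the linear constraint system \{S_int v = 0, lb <= v <= ub\} (one
#' mass-balance row per internal metabolite) as a `flux_problem`. Ratio
#' constraints and criterion-fixing rows are appended to this object; the
#' base model is never mutated.
#'
#' @param m a `metabolic_model`.
#' @return a `flux_problem`: fields `A` (rows x reactions), `sense`, `rhs`,
#'   `lb`, `ub`, `row_ids`, and the originating `model`.
#' @export
as_flux_problem <- function(m) {
  if (inherits(m, "flux_problem")) return(m)
  stopifnot(inherits(m, "metabolic_model"))
  im <- internal_metabolites(m)
  A <- m$S[im, , drop = FALSE]
  structure(list(
    A = A,
    sense = rep("=", length(im)),
    rhs = rep(0, length(im)),
    row_ids = im,
    lb = m$lb, ub = m$ub,
    model = m
  ), class = "flux_problem")
}

#' Append a linear constraint row to a flux problem
#'
#' @param p a `flux_problem`.
#' @param coeffs named numeric: reaction id -> coefficient (missing = 0).
#' @param sense one of `"<="`, `">="`, `"="`.
#' @param rhs right-hand side.
#' @param id row label used in infeasibility reports.
#' @return the augmented `flux_problem`.
#' @export
add_constraint_row <- function(p, coeffs, sense, rhs, id = "row") {
  stopifnot(inherits(p, "flux_problem"))
  unknown <- setdiff(names(coeffs), colnames(p$A))
  if (length(unknown)) stop("unknown reactions in constraint '", id, "': ",
                            paste(unknown, collapse = ", "))
  row <- stats::setNames(numeric(ncol(p$A)), colnames(p$A))
  row[names(coeffs)] <- coeffs
  p$A <- rbind(p$A, row)
  rownames(p$A) <- NULL
  p$sense <- c(p$sense, sense)
  p$rhs <- c(p$rhs, rhs)
  p$row_ids <- c(p$row_ids, id)
  p
}

#' Optimize a linear objective over a flux problem
#'
#' @param p a `flux_problem`.
#' @param objective named numeric objective coefficients over reactions.
#' @param maximize logical.
#' @return list with `status`, `objval` and named flux vector `flux`.
#' @export
optimize_flux <- function(p, objective, maximize = TRUE) {
  stopifnot(inherits(p, "flux_problem"))
  obj <- stats::setNames(numeric(ncol(p$A)), colnames(p$A))
  obj[names(objective)] <- objective
  sol <- solve_lp(obj, p$A, p$sense, p$rhs, lb = p$lb[colnames(p$A)],
                  ub = p$ub[colnames(p$A)], maximize = maximize)
  flux <- if (sol$status == "optimal")
    stats::setNames(sol$x, colnames(p$A)) else
      stats::setNames(rep(NA_real_, ncol(p$A)), colnames(p$A))
  list(status = sol$status, objval = sol$objval, flux = flux)
}

## Split reversible reactions of the selected set into forward/backward
## nonnegative parts so that sum(|v|) over that set is linear. Returns the
## split problem plus bookkeeping to fold solutions back.
.split_for_abs <- function(p, over) {
  A <- p$A; lb <- p$lb[colnames(A)]; ub <- p$ub[colnames(A)]
  rev_ids <- over[lb[over] < 0]
  add_ids <- character(0)
  for (r in rev_ids) {
    nid <- paste0(r, "..rev")
    A <- cbind(A, -A[, r])
    colnames(A)[ncol(A)] <- nid
    lb[nid] <- 0; ub[nid] <- -p$lb[[r]]
    lb[r] <- 0
    add_ids <- c(add_ids, nid)
  }
  q <- p
  q$A <- A; q$lb <- lb; q$ub <- ub
  abs_cols <- c(over, add_ids)
  list(problem = q, abs_cols = abs_cols, rev_ids = rev_ids,
       fold = function(flux) {
         v <- flux[setdiff(names(flux), add_ids)]
         for (r in rev_ids) v[r] <- flux[r] - flux[paste0(r, "..rev")]
         v
       })
}

## reactions entering the sum-of-fluxes term
.sum_v_set <- function(m, include_exchanges = FALSE) {
  if (include_exchanges) m$reactions else m$reactions[!m$is_exchange]
}
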