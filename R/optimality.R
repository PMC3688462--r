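#' Optimality criteria
#'
#' The four criteria under test: biomass yield per substrate (`BM_per_S`),
#' ATP yield per substrate (`ATP_per_S`), and the per-flux efficiencies
#' `BM_per_flux` and `ATP_per_flux` (criterion value divided by the sum of
#' absolute fluxes). With substrate uptake fixed by the observed environment,
#' the per-substrate yields coincide with maximizing the biomass (resp.
#' maintenance-ATP) flux, so those two are plain LPs; the per-flux criteria
#' are linear-fractional programs solved by Dinkelbach iteration.
#' @export
optimality_criteria <- c("BM_per_S", "ATP_per_S", "BM_per_flux", "ATP_per_flux")

#' Maximize an optimality criterion over the (possibly ratio-constrained)
#' flux polytope
#'
#' @param x a `metabolic_model` with its environment applied, or a
#'   `flux_problem` already carrying ratio-constraint rows.
#' @param criterion one of [optimality_criteria].
#' @param biomass_floor lower bound on the biomass flux, required for the ATP
#'   criteria (representing the ancestral growth rate); ignored for the
#'   biomass criteria.
#' @param include_exchanges include exchange fluxes in the sum-of-fluxes term
#'   of the per-flux criteria (default `FALSE`: exchanges are excluded so the
#'   fixed uptake does not dominate the enzymatic-burden proxy).
#' @param tol Dinkelbach convergence tolerance on the ratio update.
#' @param max_iter Dinkelbach iteration cap.
#' @return list with `status`, `criterion`, `optimum` (criterion value),
#'   `flux` (one representative optimal flux vector, original reaction
#'   space), and for per-flux criteria `lambda` (= optimum) and `sum_v`.
#' @export
maximize_criterion <- function(x, criterion = optimality_criteria,
                               biomass_floor = NULL,
                               include_exchanges = FALSE,
                               tol = 1e-9, max_iter = 50L) {
  criterion <- match.arg(criterion)
  p <- as_flux_problem(x)
  m <- p$model
  bm <- m$biomass_reaction_id
  atpm <- m$atp_maintenance_reaction_id
  if (criterion %in% c("ATP_per_S", "ATP_per_flux")) {
    if (is.na(atpm)) stop("model has no ATP maintenance reaction; ",
                          "ATP criteria unavailable")
    if (is.null(biomass_floor))
      stop("ATP criteria require a biomass_floor (ancestral growth rate)")
    p <- add_constraint_row(p, stats::setNames(1, bm), ">=", biomass_floor,
                            "biomass_floor")
  }
  objective_rxn <- if (criterion %in% c("BM_per_S", "BM_per_flux")) bm else atpm

  if (criterion %in% c("BM_per_S", "ATP_per_S")) {
    sol <- optimize_flux(p, stats::setNames(1, objective_rxn), maximize = TRUE)
    if (sol$status != "optimal")
      return(.opt_failure(sol$status, criterion, p))
    return(list(status = "optimal", criterion = criterion,
                optimum = sol$objval, flux = sol$flux))
  }

  ## ---- linear-fractional: max f(v) / sum(|v|) via Dinkelbach ----------------
  over <- .sum_v_set(m, include_exchanges)
  sp <- .split_for_abs(p, over)
  q <- sp$problem
  f_obj <- stats::setNames(numeric(ncol(q$A)), colnames(q$A))
  f_obj[objective_rxn] <- 1
  g_obj <- stats::setNames(numeric(ncol(q$A)), colnames(q$A))
  g_obj[sp$abs_cols] <- 1

  sol0 <- optimize_flux(q, f_obj[f_obj != 0], maximize = TRUE)
  if (sol0$status != "optimal") return(.opt_failure(sol0$status, criterion, p))
  g0 <- sum(g_obj * sol0$flux)
  if (g0 < tol)
    stop("sum of fluxes is zero at the initial point; fractional criterion ",
         "undefined")
  lambda <- sol0$objval / g0
  flux <- sol0$flux
  for (it in seq_len(max_iter)) {
    obj <- f_obj - lambda * g_obj
    sol <- optimize_flux(q, obj[obj != 0], maximize = TRUE)
    if (sol$status != "optimal") return(.opt_failure(sol$status, criterion, p))
    h <- sol$objval
    fv <- sum(f_obj * sol$flux); gv <- sum(g_obj * sol$flux)
    if (abs(h) <= tol * max(1, abs(lambda) * gv)) {
      flux <- sol$flux
      break
    }
    if (gv < tol) stop("degenerate Dinkelbach step: zero flux sum")
    lambda <- fv / gv
    flux <- sol$flux
    if (it == max_iter) warning("Dinkelbach iteration cap reached; ",
                                "returning last iterate")
  }
  list(status = "optimal", criterion = criterion, optimum = lambda,
       lambda = lambda, sum_v = sum(g_obj * flux), flux = sp$fold(flux))
}

.opt_failure <- function(status, criterion, p) {
  extra <- p$row_ids[!p$row_ids %in% internal_metabolites(p$model)]
  msg <- if (status == "infeasible")
    paste0("constraint system infeasible; non-stoichiometric rows: ",
           paste(extra, collapse = ", "))
  else "problem unbounded: check exchange bounds"
  list(status = status, criterion = criterion, optimum = NA_real_,
       flux = NULL, message = msg)
}

#' Percent optimality of observed flux ratios under one criterion
#'
#' Compares the criterion's optimum when the model is constrained to the
#' observed flux ratios against the unconstrained optimum:
#' 100 * constrained / unconstrained.
#'
#' @param m a `metabolic_model` with its environment applied.
#' @param criterion one of [optimality_criteria].
#' @param defs named list of [flux_ratio_definition()]s.
#' @param observations named ratio values (or data.frame, see
#'   [embed_ratio_set()]) for one biological replicate.
#' @param style dataset style passed to [embed_ratio_set()].
#' @param biomass_floor see [maximize_criterion()].
#' @param include_exchanges see [maximize_criterion()].
#' @return an `optimality_result` list: `criterion`,
#'   `unconstrained_optimum`, `constrained_optimum`, `percent_optimality`,
#'   `flux` (constrained-optimal representative), `status`.
#' @export
percent_optimality <- function(m, criterion, defs, observations,
                               style = "ltee", biomass_floor = NULL,
                               include_exchanges = FALSE) {
  unc <- maximize_criterion(m, criterion, biomass_floor = biomass_floor,
                            include_exchanges = include_exchanges)
  if (unc$status != "optimal")
    return(structure(list(criterion = criterion, status = unc$status,
                          message = unc$message), class = "optimality_result"))
  if (abs(unc$optimum) < 1e-12)
    stop("unconstrained optimum is 0; percent optimality undefined")
  p <- embed_ratio_set(as_flux_problem(m), defs, observations, style)
  con <- maximize_criterion(p, criterion, biomass_floor = biomass_floor,
                            include_exchanges = include_exchanges)
  if (con$status != "optimal")
    return(structure(list(criterion = criterion, status = con$status,
                          unconstrained_optimum = unc$optimum,
                          message = con$message), class = "optimality_result"))
  structure(list(
    criterion = criterion, status = "optimal",
    unconstrained_optimum = unc$optimum,
    constrained_optimum = con$optimum,
    percent_optimality = 100 * con$optimum / unc$optimum,
    flux = con$flux, unconstrained_flux = unc$flux
  ), class = "optimality_result")
}

#' @export
print.optimality_result <- function(x, ...) {
  cat("<optimality_result> ", x$criterion, " [", x$status, "]\n", sep = "")
  if (x$status == "optimal")
    cat(sprintf("  unconstrained %.6g | constrained %.6g | %% optimality %.2f\n",
                x$unconstrained_optimum, x$constrained_optimum,
                x$percent_optimality))
  invisible(x)
}
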