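#' Closest criterion-optimal flux distribution to observed ratios
#'
#' Per-substrate criteria usually admit many equally optimal flux
#' distributions. This fixes the criterion at its unconstrained optimum,
#' absorbs each ratio residual num(v) - R_obs * den(v) into a pair of
#' nonnegative deviation columns (D+, D-), and minimizes their sum by LP
#' (an L1 selection). The reported distance is the Euclidean (L2) distance
#' between the predicted and observed ratios of the selected solution; an
#' optional exact quadratic minimization over the optimal face is available
#' for cross-checking via `method = "l2"` (requires \pkg{quadprog}).
#'
#' @param m a `metabolic_model` with environment applied.
#' @param criterion one of [optimality_criteria].
#' @param defs named list of [flux_ratio_definition()]s.
#' @param observed named numeric of observed ratios (every declared ratio).
#' @param biomass_floor see [maximize_criterion()].
#' @param include_exchanges see [maximize_criterion()].
#' @param method `"l1"` (the deviation-column LP) or `"l2"` (quadratic
#'   cross-check minimizing the sum of squared residuals).
#' @param fix_tol relative tolerance used when pinning the criterion to its
#'   optimum; reported if relaxation is needed.
#' @return a `closest_optimal` list: `criterion`, `flux`, `predicted_ratios`,
#'   `euclidean_distance`, `l1_deviation`, `optimum`, `deviations` (per-ratio
#'   D+ - D- in denominator-weighted flux units).
#' @export
closest_optimal_ratios <- function(m, criterion, defs, observed,
                                   biomass_floor = NULL,
                                   include_exchanges = FALSE,
                                   method = c("l1", "l2"),
                                   fix_tol = 1e-7) {
  method <- match.arg(method)
  missing <- setdiff(names(defs), names(observed))
  if (length(missing)) stop("observed must contain every declared ratio; ",
                            "missing: ", paste(missing, collapse = ", "))
  opt <- maximize_criterion(m, criterion, biomass_floor = biomass_floor,
                            include_exchanges = include_exchanges)
  if (opt$status != "optimal") stop("unconstrained optimization failed: ",
                                    opt$message)
  p <- as_flux_problem(m)
  mdl <- p$model
  bm <- mdl$biomass_reaction_id; atpm <- mdl$atp_maintenance_reaction_id
  if (criterion %in% c("ATP_per_S", "ATP_per_flux")) {
    p <- add_constraint_row(p, stats::setNames(1, bm), ">=", biomass_floor,
                            "biomass_floor")
  }
  slack <- fix_tol * max(1, abs(opt$optimum))
  if (criterion == "BM_per_S") {
    p <- add_constraint_row(p, stats::setNames(1, bm), ">=",
                            opt$optimum - slack, "fix_optimum")
    split_over <- character(0)
  } else if (criterion == "ATP_per_S") {
    p <- add_constraint_row(p, stats::setNames(1, atpm), ">=",
                            opt$optimum - slack, "fix_optimum")
    split_over <- character(0)
  } else {
    ## fractional optimum: f(v) - lambda* sum|v| >= -tol is linear on the
    ## split problem and pins v to the optimal face of the fractional program
    split_over <- .sum_v_set(mdl, include_exchanges)
  }
  sp <- .split_for_abs(p, split_over)
  q <- sp$problem
  if (criterion %in% c("BM_per_flux", "ATP_per_flux")) {
    orx <- if (criterion == "BM_per_flux") bm else atpm
    cf <- stats::setNames(rep(-opt$lambda, length(sp$abs_cols)), sp$abs_cols)
    cf[orx] <- (if (orx %in% names(cf)) cf[[orx]] else 0) + 1
    q <- add_constraint_row(q, cf, ">=", -slack * max(1, opt$sum_v),
                            "fix_optimum")
    ## the fractional objective is scale-invariant, so also pin the flux-sum
    ## scale; otherwise a scaled-down vector could hide inside the slack
    gf <- stats::setNames(rep(1, length(sp$abs_cols)), sp$abs_cols)
    q <- add_constraint_row(q, gf, "=", opt$sum_v, "fix_scale")
  }

  ## deviation columns: num(v) - R_obs*den(v) - Dp + Dn = 0, Dp, Dn >= 0
  nr <- names(defs)
  A <- q$A
  for (nm in nr) {
    d <- defs[[nm]]
    z <- matrix(0, nrow(A), 2)
    colnames(z) <- paste0(c("Dp_", "Dn_"), nm)
    A <- cbind(A, z)
  }
  dev_cols <- c(paste0("Dp_", nr), paste0("Dn_", nr))
  q$lb[dev_cols] <- 0; q$ub[dev_cols] <- Inf
  q$A <- A
  for (nm in nr) {
    d <- defs[[nm]]
    cf <- -unname(observed[[nm]]) * d$denominator
    for (k in names(d$numerator))
      cf[k] <- (if (k %in% names(cf)) cf[[k]] else 0) + d$numerator[[k]]
    cf[paste0("Dp_", nm)] <- -1
    cf[paste0("Dn_", nm)] <- 1
    q <- add_constraint_row(q, cf, "=", 0, paste0("dev:", nm))
  }
  if (method == "l1") {
    obj <- stats::setNames(rep(1, length(dev_cols)), dev_cols)
    sol <- optimize_flux(q, obj, maximize = FALSE)
    if (sol$status != "optimal")
      stop("deviation LP ", sol$status,
           " even after relaxing the optimum by ", format(slack))
    full <- sol$flux
  } else {
    full <- .closest_qp(q, nr)
  }
  v <- sp$fold(full[setdiff(names(full), dev_cols)])
  pred <- ratios_from_flux_vector(defs, v)
  ok <- !is.na(pred)
  if (any(!ok))
    warning("predicted ratio(s) undefined at the optimum: ",
            paste(names(pred)[!ok], collapse = ", "))
  obsv <- unlist(observed[names(defs)])
  d2 <- sqrt(sum((pred[ok] - obsv[ok])^2))
  structure(list(
    criterion = criterion, flux = v,
    predicted_ratios = pred,
    euclidean_distance = d2,
    l1_deviation = sum(full[dev_cols]),
    deviations = stats::setNames(full[paste0("Dp_", nr)] -
                                   full[paste0("Dn_", nr)], nr),
    optimum = opt$optimum
  ), class = "closest_optimal")
}

## exact quadratic cross-check: min sum_i (num_i - R_i den_i)^2 over the
## criterion-fixed polytope, using quadprog with a small ridge for positive
## definiteness. The deviation rows already define Dp - Dn = residual, so we
## minimize sum (Dp_i - Dn_i)^2.
.closest_qp <- function(q, nr) {
  if (!requireNamespace("quadprog", quietly = TRUE))
    stop("method 'l2' requires the quadprog package")
  vars <- colnames(q$A)
  nv <- length(vars)
  Dmat <- diag(1e-8, nv)
  for (nm in nr) {
    i <- match(paste0("Dp_", nm), vars); j <- match(paste0("Dn_", nm), vars)
    Dmat[i, i] <- Dmat[i, i] + 2; Dmat[j, j] <- Dmat[j, j] + 2
    Dmat[i, j] <- Dmat[i, j] - 2; Dmat[j, i] <- Dmat[j, i] - 2
  }
  ## constraints: equalities first, then >= forms of everything else
  Aeq <- q$A[q$sense == "=", , drop = FALSE]; beq <- q$rhs[q$sense == "="]
  Age <- rbind(q$A[q$sense == ">=", , drop = FALSE],
               -q$A[q$sense == "<=", , drop = FALSE])
  bge <- c(q$rhs[q$sense == ">="], -q$rhs[q$sense == "<="])
  lb <- q$lb[vars]; ub <- q$ub[vars]
  fin_l <- which(is.finite(lb)); fin_u <- which(is.finite(ub))
  Abnd <- rbind(diag(nv)[fin_l, , drop = FALSE],
                -diag(nv)[fin_u, , drop = FALSE])
  bbnd <- c(lb[fin_l], -ub[fin_u])
  Amat <- t(rbind(Aeq, Age, Abnd))
  bvec <- c(beq, bge, bbnd)
  sol <- quadprog::solve.QP(Dmat, rep(0, nv), Amat, bvec, meq = nrow(Aeq))
  stats::setNames(sol$solution, vars)
}

#' Relative distance-to-optimum metric for an evolved strain
#'
#' Summarizes whether an evolved strain's flux ratios moved nearer to
#' (positive) or farther from (negative) the closest criterion-optimal flux
#' distribution than its ancestor: log10(D_AO / D_EO) under the default sign
#' convention, with both distances floored at `eps`.
#'
#' @param D_EO evolved strain's distance to its closest optimum (>= 0).
#' @param D_AO ancestor's distance to its closest optimum (>= 0).
#' @param sign_convention `"AO_over_EO"` (default: positive = evolved moved
#'   nearer the optimum) or `"EO_over_AO"` (the mirrored convention used in
#'   some figure labellings).
#' @param eps floor applied to both distances before taking the log.
#' @return scalar metric; 0 (with attribute `"both_at_optimum"`) when both
#'   distances are below `eps`.
#' @export
distance_metric <- function(D_EO, D_AO,
                            sign_convention = c("AO_over_EO", "EO_over_AO"),
                            eps = 1e-6) {
  sign_convention <- match.arg(sign_convention)
  if (D_EO < 0 || D_AO < 0) stop("distances must be >= 0")
  if (D_EO < eps && D_AO < eps)
    return(structure(0, both_at_optimum = TRUE))
  val <- log10(max(D_AO, eps) / max(D_EO, eps))
  if (sign_convention == "EO_over_AO") val <- -val
  val
}

#' Build a Pareto surface over biomass, ATP and minimal total flux
#'
#' Nested grid search at fixed substrate uptake: an outer grid across the
#' feasible biomass range; at each biomass value an inner grid across the
#' feasible maintenance-ATP range; at each node the sum of absolute internal
#' fluxes is minimized by LP. Infeasible nodes are dropped.
#'
#' @param m a `metabolic_model` with environment applied; must have an ATP
#'   maintenance reaction.
#' @param n_bm,n_atp grid sizes (>= 2).
#' @param include_exchanges include exchanges in the sum-of-fluxes term.
#' @return a `pareto_surface`: data.frame `points` (biomass, atp, sum_v),
#'   `standardization` (bm_max, atp_max, sum_v_max), `uptake`.
#' @export
build_pareto_surface <- function(m, n_bm = 20, n_atp = 20,
                                 include_exchanges = FALSE) {
  stopifnot(n_bm >= 2, n_atp >= 2)
  if (is.na(m$atp_maintenance_reaction_id))
    stop("Pareto surface requires an ATP maintenance reaction")
  bm <- m$biomass_reaction_id; atpm <- m$atp_maintenance_reaction_id
  base <- as_flux_problem(m)
  bmx <- optimize_flux(base, stats::setNames(1, bm), maximize = TRUE)
  if (bmx$status != "optimal") stop("empty feasible region: ", bmx$status)
  atx <- optimize_flux(base, stats::setNames(1, atpm), maximize = TRUE)
  sp <- .split_for_abs(base, .sum_v_set(m, include_exchanges))
  g_obj <- stats::setNames(rep(1, length(sp$abs_cols)), sp$abs_cols)
  pts <- list()
  for (b in seq(0, bmx$objval, length.out = n_bm)) {
    pb <- add_constraint_row(base, stats::setNames(1, bm), "=", b, "bm_node")
    alo <- optimize_flux(pb, stats::setNames(1, atpm), maximize = FALSE)
    ahi <- optimize_flux(pb, stats::setNames(1, atpm), maximize = TRUE)
    if (alo$status != "optimal" || ahi$status != "optimal") next
    for (a in seq(alo$objval, ahi$objval, length.out = n_atp)) {
      qa <- add_constraint_row(sp$problem, stats::setNames(1, bm), "=", b,
                               "bm_node")
      qa <- add_constraint_row(qa, stats::setNames(1, atpm), "=", a,
                               "atp_node")
      sv <- optimize_flux(qa, g_obj, maximize = FALSE)
      if (sv$status != "optimal") next
      pts[[length(pts) + 1L]] <- c(biomass = b, atp = a, sum_v = sv$objval)
    }
  }
  if (!length(pts)) stop("empty Pareto surface: no feasible grid nodes")
  points <- unique(as.data.frame(do.call(rbind, pts)))
  ## keep only non-dominated grid nodes (the optimal trade-off surface)
  eps <- 1e-9
  n <- nrow(points)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    better <- points$biomass >= points$biomass[i] - eps &
      points$atp >= points$atp[i] - eps &
      points$sum_v <= points$sum_v[i] + eps
    strict <- points$biomass > points$biomass[i] + eps |
      points$atp > points$atp[i] + eps |
      points$sum_v < points$sum_v[i] - eps
    if (any(better & strict)) keep[i] <- FALSE
  }
  points <- points[keep, , drop = FALSE]
  rownames(points) <- NULL
  structure(list(
    points = points,
    standardization = c(bm_max = bmx$objval, atp_max = atx$objval,
                        sum_v_max = max(points$sum_v)),
    uptake = unname(abs(m$lb[m$substrate_exchange_id])),
    include_exchanges = include_exchanges
  ), class = "pareto_surface")
}

## standardized coordinates: all axes oriented so larger = better
.pareto_std <- function(bm, atp, sv, st) {
  c(bm / st[["bm_max"]], atp / st[["atp_max"]], 1 - sv / st[["sum_v_max"]])
}

#' Distance from a (ratio-constrained) strain to its Pareto surface
#'
#' For each surface grid point, an LP finds the achievable flux distribution
#' under the observed constraints whose standardized (biomass, ATP, sum-v)
#' triple is nearest in L1; the reported value is the minimum Euclidean
#' distance over grid points ("the closest possible position" — a
#' conservative estimate).
#'
#' @param surface a [build_pareto_surface()] result built at the strain's
#'   uptake.
#' @param x the strain's `flux_problem` (model + environment + observed
#'   ratio constraints) or `metabolic_model`.
#' @return scalar distance >= 0, with attribute `"closest_point"`.
#' @export
pareto_distance <- function(surface, x) {
  stopifnot(inherits(surface, "pareto_surface"))
  p <- as_flux_problem(x)
  m <- p$model
  if (!nrow(surface$points)) stop("empty Pareto surface")
  st <- surface$standardization
  bm <- m$biomass_reaction_id; atpm <- m$atp_maintenance_reaction_id
  sp <- .split_for_abs(p, .sum_v_set(m, surface$include_exchanges))
  q0 <- sp$problem
  nv0 <- ncol(q0$A)
  ## slack columns a1..a3 >= |coord_i(v) - target_i| in standardized units
  q0$A <- cbind(q0$A, matrix(0, nrow(q0$A), 3))
  colnames(q0$A)[nv0 + 1:3] <- c("a_bm", "a_atp", "a_sv")
  q0$lb[c("a_bm", "a_atp", "a_sv")] <- 0
  q0$ub[c("a_bm", "a_atp", "a_sv")] <- Inf
  coord_rows <- function(q, target) {
    ## bm coordinate: v_bm/bm_max - t1 in [-a1, a1]
    mk <- function(q, cf, aname, tval) {
      cf1 <- c(cf, stats::setNames(-1, aname))
      q <- add_constraint_row(q, cf1, "<=", tval, paste0(aname, "_hi"))
      cf2 <- c(cf, stats::setNames(1, aname))
      add_constraint_row(q, cf2, ">=", tval, paste0(aname, "_lo"))
    }
    q <- mk(q, stats::setNames(1 / st[["bm_max"]], bm), "a_bm", target[1])
    q <- mk(q, stats::setNames(1 / st[["atp_max"]], atpm), "a_atp", target[2])
    ## sum-v coordinate is 1 - sum/sum_v_max: |(1 - sum/svmax) - t3| =
    ## |sum/svmax - (1 - t3)|
    cf <- stats::setNames(rep(1 / st[["sum_v_max"]], length(sp$abs_cols)),
                          sp$abs_cols)
    mk(q, cf, "a_sv", 1 - target[3])
  }
  best <- Inf; best_pt <- NULL
  obj <- stats::setNames(rep(1, 3), c("a_bm", "a_atp", "a_sv"))
  for (i in seq_len(nrow(surface$points))) {
    pt <- surface$points[i, ]
    tgt <- .pareto_std(pt$biomass, pt$atp, pt$sum_v, st)
    q <- coord_rows(q0, tgt)
    sol <- optimize_flux(q, obj, maximize = FALSE)
    if (sol$status != "optimal") next
    v <- sol$flux
    got <- .pareto_std(v[[bm]], v[[atpm]], sum(v[sp$abs_cols]), st)
    d <- sqrt(sum((got - tgt)^2))
    if (d < best) { best <- d; best_pt <- pt }
  }
  if (!is.finite(best)) stop("no feasible solution against any surface point")
  structure(best, closest_point = best_pt)
}
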