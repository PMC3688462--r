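test_that("closest optimal solution never sacrifices optimality", {
  for (fx in list(fix_t1(), fix_two_branch(), fix_t1_dup())) {
    set.seed(17)
    obs <- stats::setNames(runif(length(fx$defs)), names(fx$defs))
    co <- closest_optimal_ratios(fx$model, "BM_per_S", fx$defs, obs)
    opt <- maximize_criterion(fx$model, "BM_per_S")$optimum
    got <- co$flux[[fx$model$biomass_reaction_id]]
    expect_gt(got, opt * (1 - 1e-6), label = fx$model$id)
  }
})

test_that("unique optimum: distance equals the observed-ratio gap", {
  fx <- fix_t1()
  co <- closest_optimal_ratios(fx$model, "BM_per_S", fx$defs,
                               c(waste = 0.4))
  ## the only optimal vertex routes everything through V1 (ratio 0)
  expect_equal(unname(co$predicted_ratios[["waste"]]), 0, tolerance = 1e-6)
  expect_equal(co$euclidean_distance, 0.4, tolerance = 1e-6)
  ## observed at the optimal vertex: zero distance, zero deviation columns
  co0 <- closest_optimal_ratios(fx$model, "BM_per_S", fx$defs,
                                c(waste = 0))
  expect_equal(co0$euclidean_distance, 0, tolerance = 1e-8)
  expect_equal(co0$l1_deviation, 0, tolerance = 1e-8)
})

test_that("alternate optima span the observed ratio (distance 0)", {
  fx <- fix_t1_dup()
  ## any V1/V3 split is optimal; the LP should pick the observed 0.7 split
  co <- closest_optimal_ratios(fx$model, "BM_per_S", fx$defs,
                               c(waste = 0, dup = 0.7))
  expect_equal(unname(co$predicted_ratios[["dup"]]), 0.7, tolerance = 1e-6)
  expect_equal(co$euclidean_distance, 0, tolerance = 1e-6)
})

test_that("L1-selected and exact quadratic solutions agree off degeneracy", {
  skip_if_not_installed("quadprog")
  fx <- fix_t1()
  for (R in c(0.15, 0.5, 0.9)) {
    l1 <- closest_optimal_ratios(fx$model, "BM_per_S", fx$defs,
                                 c(waste = R))
    l2 <- closest_optimal_ratios(fx$model, "BM_per_S", fx$defs,
                                 c(waste = R), method = "l2")
    expect_equal(l1$euclidean_distance, l2$euclidean_distance,
                 tolerance = 1e-5)
  }
})

test_that("closest-optimal distances hold for fractional criteria too", {
  fx <- fix_two_branch()
  co <- closest_optimal_ratios(fx$model, "BM_per_flux", fx$defs,
                               c(r_upper = 0.3, r_lower = 0.2))
  opt <- maximize_criterion(fx$model, "BM_per_flux")
  over <- evoflux:::.sum_v_set(fx$model)
  ratio_at <- co$flux[[fx$model$biomass_reaction_id]] /
    sum(abs(co$flux[over]))
  expect_gt(ratio_at, opt$optimum * (1 - 1e-5))
})

test_that("distance metric follows the verbal contract and is antisymmetric", {
  expect_equal(distance_metric(0.3, 0.3), 0)
  expect_equal(distance_metric(0.4, 0.2), -0.30103, tolerance = 1e-5)
  expect_equal(distance_metric(0.2, 0.4), 0.30103, tolerance = 1e-5)
  set.seed(2)
  for (i in 1:10) {
    a <- runif(1, 1e-4, 1); b <- runif(1, 1e-4, 1)
    expect_equal(distance_metric(a, b), -distance_metric(b, a))
  }
  ## both at the optimum: flagged zero
  z <- distance_metric(0, 0)
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "both_at_optimum"))
  ## mirrored figure-label convention
  expect_equal(distance_metric(0.4, 0.2, sign_convention = "EO_over_AO"),
               0.30103, tolerance = 1e-5)
  expect_error(distance_metric(-1, 1), ">= 0")
})

test_that("Pareto surface nodes match hand LP and drop conflicting nodes", {
  m <- fix_t1_atp()$model
  me <- apply_environment(m, environment_spec(10, maintenance_lower_bound = 0))
  surf <- build_pareto_surface(me, 5, 5)
  ## node at max biomass has ATP at the floor and min sum of fluxes 30
  top <- surf$points[abs(surf$points$biomass - 20) < 1e-8, ]
  expect_equal(nrow(top), 1)
  expect_equal(top$atp, 0, tolerance = 1e-8)
  expect_equal(top$sum_v, 30, tolerance = 1e-8)
  ## max biomass and max ATP conflict: no node carries both
  expect_false(any(abs(surf$points$biomass - 20) < 1e-8 &
                     abs(surf$points$atp - 20) < 1e-8))
  ## minimal grid
  s2 <- build_pareto_surface(me, 2, 2)
  expect_lte(nrow(s2$points), 4)
  expect_error(build_pareto_surface(me, 1, 2))
})

test_that("each surface node's flux minimum matches vertex enumeration", {
  m <- fix_t1_atp()$model
  me <- apply_environment(m, environment_spec(10, maintenance_lower_bound = 0))
  surf <- build_pareto_surface(me, 3, 2)
  p <- as_flux_problem(me)
  over <- evoflux:::.sum_v_set(me)
  for (i in seq_len(nrow(surf$points))) {
    pt <- surf$points[i, ]
    q <- add_constraint_row(p, stats::setNames(1, "Vbm"), "=", pt$biomass, "b")
    q <- add_constraint_row(q, stats::setNames(1, "Vatp"), "=", pt$atp, "a")
    V <- enumerate_vertices(q)
    ref <- min(apply(V, 1, function(v) sum(abs(v[over]))))
    expect_equal(pt$sum_v, ref, tolerance = 1e-6)
  }
})

test_that("no Pareto grid point is strictly dominated", {
  fx <- central_fixture()
  surf <- build_pareto_surface(fx$model, 8, 6)
  pts <- surf$points
  for (i in seq_len(nrow(pts))) {
    dominated <- any(
      pts$biomass >= pts$biomass[i] - 1e-9 &
        pts$atp >= pts$atp[i] - 1e-9 &
        pts$sum_v <= pts$sum_v[i] + 1e-9 &
        (pts$biomass > pts$biomass[i] + 1e-7 |
           pts$atp > pts$atp[i] + 1e-7 |
           pts$sum_v < pts$sum_v[i] - 1e-7))
    expect_false(dominated)
  }
})

test_that("Pareto distance is zero at the optimum, monotone under relaxation", {
  fx <- central_fixture()
  surf <- build_pareto_surface(fx$model, 8, 6)
  expect_equal(as.numeric(pareto_distance(surf, fx$model)), 0,
               tolerance = 1e-7)
  an <- evoflux:::.path_anchors(fx$model, fx$defs)
  dists <- sapply(c(0.5, 0.25, 0), function(t) {
    v <- (1 - t) * an$v_opt + t * an$v_far
    r <- pmin(pmax(ratios_from_flux_vector(fx$defs, v), 0), 1)
    pareto_distance(surf, embed_ratio_set(fx$model, fx$defs, r, "ltee"))
  })
  expect_gt(dists[1], dists[2])
  expect_gt(dists[2], dists[3] + 1e-6)
  expect_lt(dists[3], 1e-7)
})
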