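test_that("exact ratio rows pin the branch split", {
  fx <- fix_t1()
  p <- as_flux_problem(fx$model)
  d <- fx$defs$waste
  ## R = 0 forces the wasteful path off
  s0 <- optimize_flux(embed_ratio_constraint(p, d, 0), c(Vbm = 1))
  expect_equal(unname(s0$flux[["V2"]]), 0, tolerance = 1e-9)
  ## R = 0.4 splits 6:4 at uptake 10
  s4 <- optimize_flux(embed_ratio_constraint(p, d, 0.4), c(Vbm = 1))
  expect_equal(unname(s4$flux[["V1"]]), 6, tolerance = 1e-8)
  expect_equal(unname(s4$flux[["V2"]]), 4, tolerance = 1e-8)
  ## R = 1 is the mirrored case
  s1 <- optimize_flux(embed_ratio_constraint(p, d, 1), c(Vbm = 1))
  expect_equal(unname(s1$flux[["V1"]]), 0, tolerance = 1e-9)
  expect_error(embed_ratio_constraint(p, d, 1.2), "\\[0, 1\\]")
  expect_error(embed_ratio_constraint(p, d, -0.1), "\\[0, 1\\]")
})

test_that("ratio read-back is consistent with the embedded value", {
  set.seed(11)
  for (R in runif(6)) {
    fx <- fix_two_branch()
    p <- embed_ratio_constraint(as_flux_problem(fx$model),
                                fx$defs$r_upper, R)
    sol <- optimize_flux(p, c(Vbm = 1))
    expect_equal(sol$status, "optimal")
    got <- ratios_from_flux_vector(fx$defs, sol$flux)
    expect_equal(unname(got[["r_upper"]]), R, tolerance = 1e-6)
  }
})

test_that("embedding the optimum's own ratios leaves the optimum unchanged", {
  for (fx in list(fix_t1(), fix_two_branch(), fix_t1_dup())) {
    opt <- maximize_criterion(fx$model, "BM_per_S")
    r <- ratios_from_flux_vector(fx$defs, opt$flux)
    p <- as_flux_problem(fx$model)
    for (nm in names(fx$defs))
      p <- embed_ratio_constraint(p, fx$defs[[nm]], unname(r[[nm]]))
    con <- optimize_flux(p, stats::setNames(1, fx$model$biomass_reaction_id))
    expect_equal(con$objval, opt$optimum, tolerance = 1e-7,
                 label = fx$model$id)
  }
})

test_that("dataset styles produce the documented interval bounds", {
  fx <- fix_t1()
  ## lactate: value +/- 5% relative
  p <- embed_ratio_set(fx$model, fx$defs, c(waste = 0.40), "lactate")
  k <- length(p$rhs)
  lo_row <- p$A[k - 1, ]; hi_row <- p$A[k, ]
  ## num - lo*den >= 0 with lo = 0.38: V2 coef = 1 - 0.38
  expect_equal(unname(lo_row[["V2"]]), 1 - 0.38)
  expect_equal(unname(lo_row[["V1"]]), -0.38)
  expect_equal(unname(hi_row[["V2"]]), 1 - 0.42)
  ## ko: value +/- reported error
  obs <- data.frame(ratio = "waste", value = 0.30, se = 0.05)
  pk <- embed_ratio_set(fx$model, fx$defs, obs, "ko")
  k <- length(pk$rhs)
  expect_equal(unname(pk$A[k - 1, ][["V1"]]), -0.25)
  expect_equal(unname(pk$A[k, ][["V1"]]), -0.35)
  ## a feasible solution respects the interval
  sol <- optimize_flux(pk, c(Vbm = 1))
  rr <- ratios_from_flux_vector(fx$defs, sol$flux)[["waste"]]
  expect_gte(rr, 0.25 - 1e-8)
  expect_lte(rr, 0.35 + 1e-8)
  expect_error(embed_ratio_set(fx$model, fx$defs, c(other = 0.4), "ltee"),
               "missing observation")
})

test_that("all five central-metabolism ratios embed jointly and feasibly", {
  fx <- central_fixture()
  opt <- maximize_criterion(fx$model, "BM_per_S")
  r <- ratios_from_flux_vector(fx$defs, opt$flux)
  expect_length(attr(r, "undefined"), 0)
  ## a mildly perturbed feasible ratio vector stays feasible when embedded
  an <- evoflux:::.path_anchors(fx$model, fx$defs)
  v <- 0.7 * an$v_opt + 0.3 * an$v_far
  robs <- pmin(pmax(ratios_from_flux_vector(fx$defs, v), 0), 1)
  p <- embed_ratio_set(fx$model, fx$defs, robs, "ltee")
  sol <- optimize_flux(p, c(BIOMASS = 1))
  expect_equal(sol$status, "optimal")
  got <- ratios_from_flux_vector(fx$defs, sol$flux)
  ## exact-mode ratios are reproduced; the lower-bound-mode ratio is >=
  for (nm in c("ser_from_glycolysis", "pyr_from_ED", "oaa_from_pep",
               "pep_from_oaa"))
    expect_equal(unname(got[[nm]]), unname(robs[[nm]]), tolerance = 1e-6)
  expect_gte(got[["pyr_from_mal"]], robs[["pyr_from_mal"]] - 1e-8)
})

test_that("undefined denominators are flagged, not coerced to zero", {
  fx <- fix_t1()
  v <- c(Vup = 0, V1 = 0, V2 = 0, Vbm = 0)
  r <- ratios_from_flux_vector(fx$defs, v)
  expect_true(is.na(r[["waste"]]))
  expect_identical(attr(r, "undefined"), "waste")
  ## well-defined cases
  expect_equal(unname(ratios_from_flux_vector(
    fx$defs, c(Vup = 10, V1 = 10, V2 = 0, Vbm = 20))[["waste"]]), 0)
  expect_equal(unname(ratios_from_flux_vector(
    fx$defs, c(Vup = 10, V1 = 6, V2 = 4, Vbm = 16))[["waste"]]), 0.4)
})

test_that("replicate summary averages technical before biological replicates", {
  obs <- data.frame(
    strain = "s1",
    replicate = rep(c("b1", "b2"), each = 3),
    ratio = "r",
    value = c(0.1, 0.2, 0.3, 0.5, 0.5, 0.5))
  sm <- replicate_summary(obs)
  ## bio means 0.2 and 0.5 -> strain mean 0.35, SE = sd(c(.2,.5))/sqrt(2)
  expect_equal(sm$mean, 0.35)
  expect_equal(sm$se, stats::sd(c(0.2, 0.5)) / sqrt(2))
  expect_equal(sm$n_bio, 2)
})

test_that("cross-population CV matches hand-computed contributions", {
  roles <- c(anc = "ancestor", e1 = "evolved", e2 = "evolved")
  mk <- function(vals, ratio) data.frame(
    strain = names(vals), replicate = "b1", ratio = ratio,
    value = unname(vals))
  ## evolved {0.2, 0.4}: sd 0.1414 / mean 0.3 = 0.4714
  obs1 <- mk(c(anc = 0.3, e1 = 0.2, e2 = 0.4), "rA")
  expect_equal(cv_across_evolved(obs1, roles), 0.4714, tolerance = 1e-4)
  ## adding a zero-variance ratio averages in a zero contribution
  obs2 <- rbind(obs1, mk(c(anc = 0.5, e1 = 0.3, e2 = 0.3), "rB"))
  expect_equal(cv_across_evolved(obs2, roles), 0.2357, tolerance = 1e-4)
  ## identical evolved values contribute exactly zero
  obs3 <- mk(c(anc = 0.1, e1 = 0.3, e2 = 0.3), "rA")
  expect_equal(cv_across_evolved(obs3, roles), 0)
  ## zero-mean ratios are excluded with a warning
  obs4 <- rbind(obs1, mk(c(anc = 0.2, e1 = 0, e2 = 0), "rC"))
  expect_warning(cv <- cv_across_evolved(obs4, roles), "zero mean")
  expect_equal(cv, 0.4714, tolerance = 1e-4)
})

test_that("ratio definitions and observations round-trip through disk", {
  fx <- central_fixture()
  ypath <- withr::local_tempfile(fileext = ".yaml")
  write_ratio_definitions(fx$defs, ypath)
  back <- read_ratio_definitions(ypath)
  expect_identical(names(back), names(fx$defs))
  expect_equal(back$pyr_from_mal$mode, "lower_bound")
  expect_equal(back$ser_from_glycolysis$denominator,
               fx$defs$ser_from_glycolysis$denominator)
  obs <- data.frame(strain = "a", replicate = "b1",
                    ratio = names(fx$defs), value = 0.2, se = 0.01)
  tpath <- withr::local_tempfile(fileext = ".tsv")
  write_observations(obs, tpath)
  expect_equal(read_observations(tpath), obs)
})
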