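write_t1_tsv <- function(path, uptake = 10) {
  writeLines(c(
    "#! biomass Vbm",
    "#! substrate Vup",
    "#! exchange Vup",
    paste0("Vup\t-> S\t", uptake, "\t", uptake),
    "V1\tS -> 2 P\t0\t1000",
    "V2\tS -> P\t0\t1000",
    "Vbm\tP ->\t0\t1000"), path)
  path
}

test_that("TSV toy model loads with the expected structure", {
  path <- write_t1_tsv(withr::local_tempfile(fileext = ".tsv"))
  m <- load_model(path)
  expect_s3_class(m, "metabolic_model")
  expect_length(m$reactions, 4)
  expect_length(internal_metabolites(m), 2)
  expect_equal(m$biomass_reaction_id, "Vbm")
  expect_equal(unname(m$S["P", "V1"]), 2)
  expect_false(m$is_exchange[["Vbm"]])
  expect_true(m$is_exchange[["Vup"]])
})

test_that("malformed model files raise format errors naming the culprit", {
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#! biomass Vbm", "#! substrate Vup",
               "Vup\tno arrow here\t0\t10"), bad)
  expect_error(load_model(bad), "Vup")
  nob <- withr::local_tempfile(fileext = ".tsv")
  writeLines("V1\tS -> P\t0\t10", nob)
  expect_error(load_model(nob), "biomass")
  expect_error(load_model(withr::local_tempfile(fileext = ".json")),
               "not found")
})

test_that("models round-trip through all three dialects", {
  m <- make_toy_network("central_metabolism")
  for (fmt in c("tsv", "bigg_json", "sbml")) {
    ext <- switch(fmt, tsv = ".tsv", bigg_json = ".json", sbml = ".xml")
    path <- withr::local_tempfile(fileext = ext)
    write_model(m, path, fmt)
    m2 <- load_model(path, format = fmt,
                     substrate_exchange = m$substrate_exchange_id,
                     oxygen_exchange = m$oxygen_exchange_id)
    expect_identical(sort(m2$reactions), sort(m$reactions), label = fmt)
    expect_equal(m2$S[rownames(m$S), m$reactions], m$S, label = fmt)
    expect_equal(m2$lb[m$reactions], m$lb, label = fmt)
    expect_equal(m2$ub[m$reactions], m$ub, label = fmt)
    expect_identical(m2$biomass_reaction_id, m$biomass_reaction_id)
    expect_identical(m2$atp_maintenance_reaction_id,
                     m$atp_maintenance_reaction_id)
  }
})

test_that("apply_environment fixes observed rates and the maintenance floor", {
  fx <- fix_t1_atp()
  env <- environment_spec(10, maintenance_lower_bound = 3)
  me <- apply_environment(fx$model, env)
  sol <- optimize_flux(as_flux_problem(me), c(Vbm = 1))
  expect_equal(unname(sol$flux[["Vup"]]), 10, tolerance = 1e-9)
  expect_gte(sol$flux[["Vatp"]] + 1e-9, 3)
  ## uptake equality within +/- 1 SE when supplied
  me2 <- apply_environment(fx$model,
                           environment_spec(10, substrate_se = 0.5,
                                            maintenance_lower_bound = 0))
  expect_equal(unname(me2$lb[["Vup"]]), 9.5)
  expect_equal(unname(me2$ub[["Vup"]]), 10.5)
  expect_error(environment_spec(-1), "non-negative")
})

test_that("oxygen policy preserves the ancestral oxygen/substrate ratio", {
  expect_equal(apply_oxygen_policy(14.75, 10, 10, 1), 14.75)
  expect_equal(apply_oxygen_policy(14.75, 10, 11.8, 1), 17.405)
  expect_equal(apply_oxygen_policy(11.5, 10, 11.8, 1), 13.57)
  ## slope scales the evolutionary change, not the baseline
  expect_equal(apply_oxygen_policy(10, 10, 12, 0.5), 11)
  expect_error(apply_oxygen_policy(10, 0, 12, 1), "> 0")
})

test_that("knockouts zero the targeted reactions and nothing else", {
  fx <- fix_t1()
  ko <- apply_knockout(fx$model, "V1")
  expect_equal(unname(ko$ub[["V1"]]), 0)
  expect_equal(ko$ub[setdiff(names(ko$ub), "V1")],
               fx$model$ub[setdiff(names(ko$ub), "V1")])
  ## only the wasteful path remains: yield 1 x uptake 10
  expect_equal(maximize_criterion(ko, "BM_per_S")$optimum, 10)
  ## empty knockout is the identity
  expect_identical(apply_knockout(fx$model, character(0)), fx$model)
  ## knocking out biomass forces the optimum to zero
  kb <- apply_knockout(fx$model, "Vbm")
  expect_equal(maximize_criterion(kb, "BM_per_S")$optimum, 0)
  expect_error(apply_knockout(fx$model, "nope"), "unknown")
})

test_that("biomass composition scaling multiplies tagged coefficients", {
  m <- metabolic_model(
    list(Vup = c(S = 1), V1 = c(S = -1, P = 1, L = 0.5),
         Vbm = c(P = -1, L = -0.5)),
    lb = c(Vup = 10), ub = c(Vup = 10),
    biomass = "Vbm", substrate_exchange = "Vup",
    lipid_components = "L", id = "lipid_toy")
  expect_equal(scale_biomass_composition(m, "lipid", 1)$S, m$S)
  m2 <- scale_biomass_composition(m, "lipid", 1.2)
  expect_equal(unname(m2$S["L", "Vbm"]), -0.6)
  expect_equal(unname(m2$S["P", "Vbm"]), -1)
  expect_error(scale_biomass_composition(m, "lipid", 0), "factor")
  expect_error(scale_biomass_composition(fix_t1()$model, "lipid", 1.2),
               "tagged")
})

test_that("environment and knockout application commute", {
  m <- make_toy_network("central_metabolism")
  env <- environment_spec(8, oxygen_uptake = 12, maintenance_lower_bound = 5)
  a <- apply_knockout(apply_environment(m, env), "PPC")
  b <- apply_environment(apply_knockout(m, "PPC"), env)
  expect_equal(a$lb, b$lb)
  expect_equal(a$ub, b$ub)
})

test_that("feasible solutions satisfy steady-state mass balance", {
  for (fx in oracle_fixtures()) {
    p <- as_flux_problem(fx$model)
    sol <- optimize_flux(p, stats::setNames(1, fx$model$biomass_reaction_id))
    expect_equal(sol$status, "optimal", label = fx$model$id)
    S_int <- fx$model$S[internal_metabolites(fx$model), , drop = FALSE]
    expect_lt(max(abs(S_int %*% sol$flux)), 1e-8)
  }
})
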