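test_that("toy templates have the advertised structure and optima", {
  t1 <- make_toy_network("T1_two_path")
  expect_equal(maximize_criterion(t1, "BM_per_S")$optimum, 20)
  ## symmetric yields: both paths optimal
  sym <- make_toy_network("T1_two_path", parameters = list(yield2 = 2))
  expect_equal(maximize_criterion(sym, "BM_per_S")$optimum, 20)
  ## central: all five ratios evaluable at the biomass optimum
  fx <- central_fixture()
  r <- ratios_from_flux_vector(fx$defs,
                               maximize_criterion(fx$model, "BM_per_S")$flux)
  expect_length(attr(r, "undefined"), 0)
  expect_error(make_toy_network("nope"))
  expect_error(make_toy_network("T1_two_path",
                                parameters = list(yield1 = -1)), "> 0")
})

test_that("bisection places the ancestor at the target percent optimality", {
  net <- make_toy_network("T1_two_path")
  sim <- simulate_dataset(net, scenario_spec("ltee_like", n_populations = 2,
                                             noise_sd = 0, seed = 1))
  anc <- sim$truth$strains$ancestor
  expect_equal(anc$true_percent_optimality, 80, tolerance = 0.1)
  ## percent = 100 (2 - R) / 2 on this network, so R = 0.4 at 80%
  expect_equal(unname(anc$true_ratios[["waste"]]), 0.4, tolerance = 0.002)
  ## unreachable target reports the achievable range
  expect_error(simulate_dataset(net, scenario_spec(
    "ltee_like", ancestor_percent_optimality = 20, noise_sd = 0)),
    "achievable range")
})

test_that("noiseless observations equal the true ratios exactly", {
  net <- make_toy_network("central_metabolism")
  sim <- simulate_dataset(net, scenario_spec("ltee_like", n_populations = 3,
                                             noise_sd = 0, seed = 5))
  for (d in sim$datasets) {
    tr <- sim$truth$strains[[d$strain_id]]$true_ratios
    for (i in seq_len(nrow(d$observations)))
      expect_equal(d$observations$value[i],
                   unname(tr[[d$observations$ratio[i]]]))
  }
})

test_that("the generator is deterministic given a seed and perturbs per strain", {
  net <- make_toy_network("T1_two_path")
  sp <- scenario_spec("ltee_like", n_populations = 3, noise_sd = 0.03,
                      seed = 99)
  a <- simulate_dataset(net, sp)
  b <- simulate_dataset(net, sp)
  expect_identical(lapply(a$datasets, `[[`, "observations"),
                   lapply(b$datasets, `[[`, "observations"))
  ## adding a population leaves existing strains' draws untouched
  sp4 <- scenario_spec("ltee_like", n_populations = 4, noise_sd = 0.03,
                       seed = 99)
  c4 <- simulate_dataset(net, sp4)
  expect_identical(a$datasets[[2]]$observations,
                   c4$datasets[[2]]$observations)
  ## different seeds differ
  d2 <- simulate_dataset(net, scenario_spec("ltee_like", n_populations = 3,
                                            noise_sd = 0.03, seed = 100))
  expect_false(identical(a$datasets[[2]]$observations,
                         d2$datasets[[2]]$observations))
})

test_that("noisy observations are clipped to the unit interval", {
  net <- make_toy_network("T1_two_path")
  sim <- simulate_dataset(net, scenario_spec(
    "ltee_like", n_populations = 5, noise_sd = 0.5, seed = 12))
  vals <- unlist(lapply(sim$datasets, function(d) d$observations$value))
  expect_true(all(vals >= 0 & vals <= 1))
})

test_that("design-specific structure is honoured", {
  net <- make_toy_network("central_metabolism")
  ## lactate: single-valued ancestor
  lac <- simulate_dataset(net, scenario_spec("lactate_like", noise_sd = 0,
                                             n_populations = 3, seed = 2))
  anc_obs <- lac$datasets[[1]]$observations
  expect_equal(length(unique(anc_obs$replicate)), 1)
  ## ko: paired evolved per knockout ancestor, knockout applied
  ko <- simulate_dataset(net, scenario_spec("ko_like", noise_sd = 0,
                                            seed = 2))
  roles <- vapply(ko$datasets, `[[`, character(1), "role")
  expect_equal(sum(roles == "ancestor"), 3)
  expect_equal(sum(roles == "evolved"), 6)
  kos <- unique(unlist(lapply(ko$datasets, `[[`, "knockout")))
  expect_setequal(kos, c("EMP", "PYK", "PPC"))
  ## ko design needs knockout analogues
  expect_error(simulate_dataset(make_toy_network("T1_two_path"),
                                scenario_spec("ko_like", noise_sd = 0)),
               "knockout")
})

test_that("evolved uptake and oxygen follow the scenario's scaling", {
  net <- make_toy_network("central_metabolism")
  sim <- simulate_dataset(net, scenario_spec("ltee_like", n_populations = 2,
                                             noise_sd = 0, seed = 3))
  env_a <- sim$datasets[[1]]$environment
  env_e <- sim$datasets[[2]]$environment
  expect_equal(env_e$substrate_uptake, env_a$substrate_uptake * 1.18)
  expect_equal(env_e$oxygen_uptake,
               apply_oxygen_policy(env_a$oxygen_uptake,
                                   env_a$substrate_uptake,
                                   env_e$substrate_uptake))
})
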