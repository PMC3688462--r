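# Small fixture networks (<= 8 reactions) with hand-checkable optima, built
# in code at test time. Each returns an environment-applied model plus its
# ratio definitions.

fix_t1 <- function(uptake = 10) {
  list(model = make_toy_network("T1_two_path", uptake = uptake),
       defs = toy_ratio_definitions("T1_two_path"))
}

fix_t1_atp <- function(uptake = 10) {
  list(model = make_toy_network("T1_plus_atp", uptake = uptake),
       defs = toy_ratio_definitions("T1_plus_atp"))
}

# T1 with a duplicate efficient path V3 (alternate optima span the ratio)
fix_t1_dup <- function(uptake = 10) {
  m <- metabolic_model(
    list(Vup = c(S = 1), V1 = c(S = -1, P = 2), V2 = c(S = -1, P = 1),
         V3 = c(S = -1, P = 2), Vbm = c(P = -1)),
    ub = c(Vup = uptake),
    biomass = "Vbm", substrate_exchange = "Vup", id = "T1_dup")
  defs <- list(
    waste = flux_ratio_definition("waste", c(V2 = 1), c(V1 = 1, V2 = 1, V3 = 1)),
    dup = flux_ratio_definition("dup", c(V3 = 1), c(V1 = 1, V3 = 1)))
  list(model = m, defs = defs)
}

# symmetric yields: both paths optimal (alternate-optima fixture)
fix_t1_sym <- function(uptake = 10) {
  list(model = make_toy_network("T1_two_path", uptake = uptake,
                                parameters = list(yield1 = 2, yield2 = 2)),
       defs = toy_ratio_definitions("T1_two_path"))
}

# two branch points in series: S -> A via efficient/wasteful, A -> B likewise
fix_two_branch <- function(uptake = 10) {
  m <- metabolic_model(
    list(Vup = c(S = 1),
         V1 = c(S = -1, A = 2), V2 = c(S = -1, A = 1),
         V3 = c(A = -1, B = 1, ATP = 1), V4 = c(A = -1, B = 2),
         Vbm = c(B = -1), Vatp = c(ATP = -1)),
    ub = c(Vup = uptake),
    biomass = "Vbm", atpm = "Vatp",
    substrate_exchange = "Vup", id = "two_branch")
  defs <- list(
    r_upper = flux_ratio_definition("r_upper", c(V2 = 1), c(V1 = 1, V2 = 1)),
    r_lower = flux_ratio_definition("r_lower", c(V3 = 1), c(V3 = 1, V4 = 1)))
  list(model = m, defs = defs)
}

# a reversible internal shuttle, to exercise the forward/backward split
fix_reversible <- function(uptake = 10) {
  m <- metabolic_model(
    list(Vup = c(S = 1), V1 = c(S = -1, A = 1), V2 = c(S = -1, B = 2),
         Vshut = c(A = -1, B = 1), Vbm = c(B = -1)),
    lb = c(Vshut = -1000), ub = c(Vup = uptake),
    biomass = "Vbm", substrate_exchange = "Vup", id = "reversible_shuttle")
  defs <- list(
    direct = flux_ratio_definition("direct", c(V2 = 1), c(V1 = 1, V2 = 1)))
  list(model = m, defs = defs)
}

oracle_fixtures <- function() list(
  t1 = fix_t1(), t1_atp = fix_t1_atp(), t1_dup = fix_t1_dup(),
  t1_sym = fix_t1_sym(), two_branch = fix_two_branch(),
  reversible = fix_reversible())

central_fixture <- function(uptake = 10, o2 = 14.75, maint = 8.9) {
  m <- make_toy_network("central_metabolism", uptake = uptake)
  me <- apply_environment(m, environment_spec(
    uptake, oxygen_uptake = o2, maintenance_lower_bound = maint))
  list(model = me, raw = m, defs = toy_ratio_definitions("central_metabolism"))
}
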