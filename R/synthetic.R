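#' Build a toy metabolic network with analytically known optima
#'
#' Three templates:
#' \describe{
#'   \item{`T1_two_path`}{uptake of substrate S; an efficient path
#'     `V1: S -> yield1 P` and a wasteful path `V2: S -> yield2 P` feeding a
#'     biomass drain of P. One branch-point ratio `waste = V2/(V1+V2)`.}
#'   \item{`T1_plus_atp`}{as above, but the wasteful path also yields ATP
#'     (`V2: S -> P + atp_yield ATP`) drained by a maintenance reaction, so
#'     biomass and ATP trade off and a Pareto surface exists.}
#'   \item{`central_metabolism`}{a ~17-reaction carbon-lumped cartoon of
#'     E. coli central metabolism: upper glycolysis (EMP), the
#'     Entner-Doudoroff route (ED), an oxidative pentose-phosphate branch
#'     (PPP) feeding a pentose pool required by biomass with a lossy
#'     re-entry to PEP (PPE) — so the biomass optimum keeps the
#'     glycolysis/PPP split strictly interior, as observed — pyruvate kinase,
#'     PEP/OAA anaplerosis in both directions (PPC/PCK), pyruvate
#'     dehydrogenase, a lumped oxidative TCA pair (CS, MDH) consuming oxygen,
#'     malic enzyme (MAE), the glyoxylate shunt (GLX), acetate overflow and a
#'     biomass reaction with a lipid-tagged acetyl component. All five
#'     branch-point ratio analogues of the long-term evolution dataset have
#'     non-degenerate denominators at the biomass optimum.}
#' }
#'
#' @param template one of `"T1_two_path"`, `"T1_plus_atp"`,
#'   `"central_metabolism"`.
#' @param uptake substrate uptake capacity (mmol/gCDW/hr); analyses fix the
#'   uptake to the observed rate via [apply_environment()].
#' @param parameters named overrides: `yield1`, `yield2` (T1 path yields,
#'   default 2 and 1), `atp_yield` (T1_plus_atp, default 2).
#' @return a `metabolic_model`; attribute `"far_objective"` names the
#'   wasteful LP objective used by [simulate_dataset()] to anchor the
#'   inefficient end of the strain path, and `"ko_reactions"` the knockout
#'   analogues available to the `ko_like` design.
#' @export
make_toy_network <- function(template = c("T1_two_path", "T1_plus_atp",
                                          "central_metabolism"),
                             uptake = 10, parameters = list()) {
  template <- match.arg(template)
  y1 <- parameters$yield1 %||% 2
  y2 <- parameters$yield2 %||% 1
  if (y1 <= 0 || y2 <= 0) stop("path yields must be > 0")
  if (template == "T1_two_path") {
    m <- metabolic_model(
      list(Vup = c(S = 1), V1 = c(S = -1, P = y1), V2 = c(S = -1, P = y2),
           Vbm = c(P = -1)),
      ub = c(Vup = uptake),
      biomass = "Vbm", substrate_exchange = "Vup", id = "T1_two_path")
    attr(m, "far_objective") <- c(V2 = 1)
    return(m)
  }
  if (template == "T1_plus_atp") {
    ay <- parameters$atp_yield %||% 2
    m <- metabolic_model(
      list(Vup = c(S = 1), V1 = c(S = -1, P = y1),
           V2 = c(S = -1, P = y2, ATP = ay),
           Vbm = c(P = -1), Vatp = c(ATP = -1)),
      ub = c(Vup = uptake),
      biomass = "Vbm", atpm = "Vatp",
      substrate_exchange = "Vup", id = "T1_plus_atp")
    attr(m, "far_objective") <- c(V2 = 1)
    return(m)
  }
  ## central_metabolism
  m <- metabolic_model(
    list(
      GLC_up = c(G6P = 1),
      EX_o2 = c(O2 = 1),
      EX_ac = c(ACE = -1),
      EMP = c(G6P = -1, PEP = 2, ATP = 2),
      ED  = c(G6P = -1, PEP = 1, PYR = 1, ATP = 1),
      PPP = c(G6P = -1, P5P = 1, ATP = 0.5),
      PPE = c(P5P = -1, PEP = 1.4, ATP = 0.2),
      PYK = c(PEP = -1, PYR = 1, ATP = 1),
      PPC = c(PEP = -1, OAA = 1),
      PCK = c(OAA = -1, ATP = -1, PEP = 1),
      PDH = c(PYR = -1, ACA = 1),
      CS  = c(ACA = -1, OAA = -1, O2 = -1, MAL = 1, ATP = 2),
      MDH = c(MAL = -1, O2 = -0.5, OAA = 1, ATP = 1),
      MAE = c(MAL = -1, PYR = 1),
      GLX = c(ACA = -2, MAL = 1),
      ACK = c(ACA = -1, ACE = 1, ATP = 1),
      BIOMASS = c(PEP = -0.4, PYR = -0.4, OAA = -0.3, ACA = -0.3,
                  P5P = -0.2, ATP = -2),
      ATPM = c(ATP = -1)
    ),
    ub = c(GLC_up = uptake),
    biomass = "BIOMASS", atpm = "ATPM",
    substrate_exchange = "GLC_up", oxygen_exchange = "EX_o2",
    lipid_components = "ACA",
    id = "central_metabolism")
  ## wasteful anchor: carbon-lossy pentose-phosphate routing, the
  ## PEP->OAA->PEP futile cycle and malic-enzyme flux are all visible in the
  ## measured ratios and all cut the achievable biomass when embedded
  attr(m, "far_objective") <- c(PPP = 1, PCK = 1, MAE = 1)
  attr(m, "far_biomass_frac") <- 0.3
  attr(m, "ko_reactions") <- c(pgi_like = "EMP", tpi_like = "PYK",
                               ppc_like = "PPC")
  m
}

#' Branch-point ratio definitions for the toy networks
#'
#' @param template a [make_toy_network()] template name.
#' @return named list of [flux_ratio_definition()]s. For the T1 family a
#'   single exact ratio `waste` = V2/(V1+V2); for `central_metabolism` the
#'   five ratio analogues of the long-term evolution dataset (serine from
#'   glycolysis, pyruvate through Entner-Doudoroff, OAA from PEP, PEP from
#'   OAA, and pyruvate from malate as a lower bound).
#' @export
toy_ratio_definitions <- function(template = c("T1_two_path", "T1_plus_atp",
                                               "central_metabolism")) {
  template <- match.arg(template)
  if (template %in% c("T1_two_path", "T1_plus_atp")) {
    return(list(waste = flux_ratio_definition(
      "waste", c(V2 = 1), c(V1 = 1, V2 = 1), "exact")))
  }
  pep_prod <- c(EMP = 2, ED = 1, PPE = 1.4, PCK = 1)
  pyr_prod <- c(ED = 1, PYK = 1, MAE = 1)
  defs <- list(
    ser_from_glycolysis = flux_ratio_definition(
      "ser_from_glycolysis", c(EMP = 1), c(EMP = 1, PPP = 1), "exact"),
    pyr_from_ED = flux_ratio_definition(
      "pyr_from_ED", c(ED = 1), pyr_prod, "exact"),
    oaa_from_pep = flux_ratio_definition(
      "oaa_from_pep", c(PPC = 1), c(PPC = 1, MDH = 1), "exact"),
    pep_from_oaa = flux_ratio_definition(
      "pep_from_oaa", c(PCK = 1), pep_prod, "exact"),
    pyr_from_mal = flux_ratio_definition(
      "pyr_from_mal", c(MAE = 1), pyr_prod, "lower_bound")
  )
  defs
}

#' Scenario specification for synthetic evolution experiments
#'
#' @param design `"ltee_like"` (one ancestor with replicated observations,
#'   n_populations evolved lines, exact internal-ratio constraints),
#'   `"lactate_like"` (single-valued ancestor, interval constraints at
#'   +/- 5\%), or `"ko_like"` (paired evolved populations per knockout
#'   ancestor, interval constraints at +/- SE; requires the
#'   `central_metabolism` network).
#' @param n_populations evolved populations (per knockout ancestor for
#'   `ko_like`). Defaults: 10 / 7 / 2.
#' @param n_bio_reps,n_tech_reps replicate structure (defaults 3 and 3;
#'   `lactate_like` ancestors always carry a single value).
#' @param ancestor_percent_optimality target BM-per-substrate percent
#'   optimality of the ancestor, reached by bisection along a feasible path
#'   between the optimal and a wasteful flux distribution.
#' @param evolved_shift signed shift of the path coordinate for evolved
#'   strains: positive moves away from the optimum, negative toward it.
#' @param noise_sd Gaussian noise SD on each technical-replicate ratio
#'   observation (ratio units; observations clipped to \code{[0, 1]}).
#' @param uptake_gain evolved substrate uptake relative to ancestral
#'   (defaults 1.18 / 1.40 / 2.57 by design, the average gains of the three
#'   study systems).
#' @param seed integer seed; per-strain substreams are derived by hashing
#'   the strain id so adding a strain does not perturb the others.
#' @return a `scenario_spec` list.
#' @export
scenario_spec <- function(design = c("ltee_like", "lactate_like", "ko_like"),
                          n_populations = NULL, n_bio_reps = 3,
                          n_tech_reps = 3,
                          ancestor_percent_optimality = 80,
                          evolved_shift = 0.05, noise_sd = 0.02,
                          uptake_gain = NULL, seed = 1L) {
  design <- match.arg(design)
  n_populations <- n_populations %||%
    switch(design, ltee_like = 10L, lactate_like = 7L, ko_like = 2L)
  uptake_gain <- uptake_gain %||%
    switch(design, ltee_like = 1.18, lactate_like = 1.40, ko_like = 2.57)
  stopifnot(n_populations >= 1, n_bio_reps >= 1, n_tech_reps >= 1,
            ancestor_percent_optimality > 0,
            ancestor_percent_optimality <= 100, noise_sd >= 0,
            uptake_gain > 0)
  structure(list(design = design, n_populations = n_populations,
                 n_bio_reps = n_bio_reps, n_tech_reps = n_tech_reps,
                 ancestor_percent_optimality = ancestor_percent_optimality,
                 evolved_shift = evolved_shift, noise_sd = noise_sd,
                 uptake_gain = uptake_gain, seed = as.integer(seed)),
            class = "scenario_spec")
}

## deterministic 31-bit substream seed from the global seed and a strain id
.strain_seed <- function(seed, strain_id) {
  h <- 0
  for (k in utf8ToInt(strain_id)) h <- (h * 131 + k) %% 2147483399
  as.integer((seed * 2654435 + h) %% 2147483399 + 1)
}

## percent optimality of the exact ratios realized at path coordinate t;
## used for bisection toward the target ancestor percent
.path_percent <- function(m, defs, style, v_opt, v_far, t, criterion = "BM_per_S") {
  v <- (1 - t) * v_opt + t * v_far
  r <- ratios_from_flux_vector(defs, v)
  if (any(is.na(r))) return(list(percent = NA_real_, ratios = r))
  r <- pmin(pmax(r, 0), 1)
  res <- percent_optimality(m, criterion, defs, r, style = style)
  list(percent = if (res$status == "optimal") res$percent_optimality else NA_real_,
       ratios = r)
}

## anchor flux vectors for the optimal and wasteful ends of the strain path
.path_anchors <- function(m, defs) {
  p <- as_flux_problem(m)
  opt <- maximize_criterion(m, "BM_per_S")
  if (opt$status != "optimal") stop("network infeasible: ", opt$message)
  far_obj <- attr(m, "far_objective")
  if (is.null(far_obj)) stop("network lacks a 'far_objective' attribute")
  pf <- p
  frac <- attr(m, "far_biomass_frac")
  if (!is.null(frac))
    pf <- add_constraint_row(pf, stats::setNames(1, m$biomass_reaction_id),
                             ">=", frac * opt$optimum, "far_floor")
  far <- optimize_flux(pf, far_obj, maximize = TRUE)
  if (far$status != "optimal") stop("wasteful anchor infeasible")
  list(v_opt = opt$flux, v_far = far$flux)
}

## bisect the path coordinate so the embedded percent optimality hits target
.solve_path_t <- function(m, defs, style, target, tol = 0.005) {
  an <- .path_anchors(m, defs)
  pp <- function(t) .path_percent(m, defs, style, an$v_opt, an$v_far, t)$percent
  grid <- seq(0, 1, by = 0.125)
  pg <- vapply(grid, pp, numeric(1))
  ok <- which(!is.na(pg))
  if (!length(ok)) stop("no evaluable path points")
  rng <- range(pg[ok])
  if (target > rng[2] + 0.1 || target < rng[1] - 0.1)
    stop(sprintf("target percent %.1f unreachable; achievable range [%.1f, %.1f]",
                 target, rng[1], rng[2]))
  ## adjacent evaluable grid points bracketing the target
  br <- NULL
  for (k in seq_len(length(ok) - 1)) {
    a <- ok[k]; b <- ok[k + 1]
    if ((pg[a] - target) * (pg[b] - target) <= 0) { br <- c(a, b); break }
  }
  if (is.null(br)) {
    best <- ok[which.min(abs(pg[ok] - target))]
    return(list(t = grid[best], anchors = an))
  }
  lo <- grid[br[1]]; hi <- grid[br[2]]; plo <- pg[br[1]]
  for (it in 1:40) {
    mid <- (lo + hi) / 2
    pm <- pp(mid)
    if (is.na(pm)) { hi <- mid; next }
    if (abs(pm - target) < tol) return(list(t = mid, anchors = an))
    if ((plo - target) * (pm - target) <= 0) hi <- mid
    else { lo <- mid; plo <- pm }
  }
  list(t = (lo + hi) / 2, anchors = an)
}

#' Simulate replicate-structured strain datasets with known ground truth
#'
#' Generates an ancestor whose true flux ratios sit at a prescribed
#' percent optimality (by bisection along a feasible path between the
#' biomass-optimal flux distribution and a wasteful anchor), evolved
#' populations shifted along that path, and noisy replicate-structured
#' observations (technical replicates averaged into biological replicates).
#'
#' @param network a [make_toy_network()] model (uptake fixed).
#' @param spec a [scenario_spec()].
#' @param defs ratio definitions; default [toy_ratio_definitions()] for the
#'   network's template.
#' @return list with `datasets` (list of `strain_dataset`s: `strain_id`,
#'   `role`, `ancestor_id`, `environment`, `knockout`, `style`,
#'   `observations`) and `truth` (a `synthetic_truth`: per-strain true
#'   ratios, true percent optimality, true distances and metrics, the
#'   anchors, path coordinates and seed).
#' @export
simulate_dataset <- function(network, spec, defs = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  defs <- defs %||% toy_ratio_definitions(network$id)
  style <- switch(spec$design, ltee_like = "ltee", lactate_like = "lactate",
                  ko_like = "ko")
  has_atpm <- !is.na(network$atp_maintenance_reaction_id)
  maint <- if (has_atpm) 8.9 else 0
  anc_uptake <- unname(abs(network$ub[network$substrate_exchange_id]))
  anc_O2 <- if (!is.na(network$oxygen_exchange_id)) 14.75 else NA_real_
  mk_env <- function(uptake, o2) environment_spec(
    substrate_uptake = uptake, oxygen_uptake = o2,
    maintenance_lower_bound = maint)

  kos <- if (spec$design == "ko_like") {
    kr <- attr(network, "ko_reactions")
    if (is.null(kr)) stop("ko_like design requires a network with knockout ",
                          "analogues (central_metabolism)")
    kr
  } else stats::setNames(list(character(0)), "wt")

  datasets <- list(); truth_strains <- list()
  for (ki in seq_along(kos)) {
    ko_name <- names(kos)[ki]
    ko_rxns <- if (spec$design == "ko_like") unname(kos[ki]) else character(0)
    anc_id <- if (spec$design == "ko_like") paste0("anc_", ko_name) else "ancestor"
    m_anc <- apply_knockout(apply_environment(network, mk_env(anc_uptake, anc_O2)),
                            ko_rxns)
    sol <- .solve_path_t(m_anc, defs, style, spec$ancestor_percent_optimality)
    t_anc <- sol$t; an <- sol$anchors
    path_ratios <- function(t) {
      v <- (1 - t) * an$v_opt + t * an$v_far
      pmin(pmax(ratios_from_flux_vector(defs, v), 0), 1)
    }
    strains <- c(anc_id,
                 paste0(if (spec$design == "ko_like") paste0(ko_name, "_ev")
                        else "pop", seq_len(spec$n_populations)))
    roles <- c("ancestor", rep("evolved", spec$n_populations))
    for (si in seq_along(strains)) {
      sid <- strains[si]; role <- roles[si]
      t_s <- if (role == "ancestor") t_anc else
        min(max(t_anc + spec$evolved_shift, 0), 1)
      true_r <- path_ratios(t_s)
      uptake <- if (role == "ancestor") anc_uptake else
        anc_uptake * spec$uptake_gain
      o2 <- if (is.na(anc_O2)) NA_real_ else if (role == "ancestor") anc_O2
        else apply_oxygen_policy(anc_O2, anc_uptake, uptake, slope = 1)
      nb <- if (spec$design == "lactate_like" && role == "ancestor") 1L
        else spec$n_bio_reps
      nt <- if (spec$design == "lactate_like" && role == "ancestor") 1L
        else spec$n_tech_reps
      ## ratios whose numerator reactions are all deleted are structural
      ## zeros: reported as exactly 0, not as truncated noise around 0
      struct_zero <- vapply(defs, function(df)
        length(ko_rxns) > 0 && all(names(df$numerator) %in% ko_rxns),
        logical(1))
      set.seed(.strain_seed(spec$seed, sid))
      obs <- list()
      for (b in seq_len(nb)) {
        tech <- matrix(stats::rnorm(nt * length(defs), mean = rep(true_r, each = nt),
                                    sd = spec$noise_sd),
                       nrow = nt, ncol = length(defs))
        tech <- pmin(pmax(tech, 0), 1)
        tech[, struct_zero] <- 0
        obs[[b]] <- data.frame(
          strain = sid, replicate = paste0("b", b),
          ratio = names(defs), value = colMeans(tech),
          se = if (nt > 1) apply(tech, 2, stats::sd) / sqrt(nt) else 0)
      }
      obs <- do.call(rbind, obs)
      rownames(obs) <- NULL
      datasets[[sid]] <- structure(list(
        strain_id = sid, role = role,
        ancestor_id = if (role == "evolved") anc_id else NA_character_,
        environment = mk_env(uptake, o2), knockout = ko_rxns,
        style = style, observations = obs), class = "strain_dataset")
      truth_strains[[sid]] <- list(strain_id = sid, role = role,
                                   ancestor_id = datasets[[sid]]$ancestor_id,
                                   t = t_s, true_ratios = true_r,
                                   knockout = ko_rxns, uptake = uptake,
                                   oxygen = o2)
    }
  }
  truth <- .compute_truth(network, datasets, truth_strains, defs, maint)
  truth$seed <- spec$seed
  list(datasets = unname(datasets),
       truth = structure(truth, class = "synthetic_truth"))
}

## ground-truth percent optimality / distances on the noiseless ratios,
## computed with the same embedding the analysis applies (style-faithful)
.compute_truth <- function(network, datasets, truth_strains, defs, maint) {
  per <- list()
  for (ts in truth_strains) {
    d <- datasets[[ts$strain_id]]
    m_s <- apply_knockout(apply_environment(network, d$environment), ts$knockout)
    obs_se <- stats::setNames(rep(0, length(defs)), names(defs))
    ratios <- ts$true_ratios
    attr(ratios, "se") <- obs_se
    po <- percent_optimality(m_s, "BM_per_S", defs, ratios, style = d$style)
    co <- closest_optimal_ratios(m_s, "BM_per_S", defs, ratios)
    per[[ts$strain_id]] <- c(ts, list(
      true_percent_optimality = po$percent_optimality,
      true_distance = co$euclidean_distance))
  }
  ## per-evolved metric against its ancestor
  for (sid in names(per)) {
    if (per[[sid]]$role == "evolved") {
      anc <- per[[sid]]$ancestor_id
      per[[sid]]$true_metric <- distance_metric(
        per[[sid]]$true_distance, per[[anc]]$true_distance)
    }
  }
  list(strains = per)
}
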