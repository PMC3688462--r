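#' Run the full optimality analysis over a set of strains
#'
#' For every strain and criterion: per-biological-replicate percent
#' optimality and distance to the closest criterion-optimal flux
#' distribution, strain mean and SE, the log distance metric of each evolved
#' strain against its ancestor, optional Pareto-surface distances, the
#' ancestor-versus-evolved tests and the cross-population coefficient of
#' variation. Infeasible strains are recorded and the run continues.
#'
#' @param model a `metabolic_model` (environment applied per strain from the
#'   dataset's `environment`).
#' @param datasets list of `strain_dataset`s (see [simulate_dataset()] for
#'   the structure); exactly one ancestor per `ancestor_id` group.
#' @param defs named list of [flux_ratio_definition()]s.
#' @param criteria character subset of [optimality_criteria].
#' @param biomass_floor floor for the ATP criteria (the ancestral growth
#'   rate). Default: 90\% of each ancestor's ratio-constrained maximum
#'   biomass flux under its own environment — the measured growth rate a
#'   floor stands in for sits below the model optimum, and a floor at
#'   exactly the optimum is infeasible for noisy replicate ratio sets.
#' @param compute_distances also compute per-replicate distances to the
#'   closest criterion-optimal flux distribution (and the derived metric);
#'   disable for percent-optimality-only simulation studies.
#' @param pareto compute Pareto-surface distances (uses strain-mean ratios).
#' @param pareto_grid `c(n_bm, n_atp)` grid sizes.
#' @param include_exchanges see [maximize_criterion()].
#' @param sign_convention see [distance_metric()].
#' @param evolved_maintenance_factor,evolved_lipid_factor sensitivity knobs
#'   applied to evolved strains only (fraction of the default maintenance
#'   bound; biomass lipid-class scale factor).
#' @return an `evoflux_results` list: `strains` (tidy data.frame strain x
#'   criterion), `tests`, `cv`, `failures`, `flux_tests`, `notes`.
#' @export
run_analysis <- function(model, datasets, defs,
                         criteria = c("BM_per_S", "ATP_per_S"),
                         biomass_floor = NULL,
                         compute_distances = TRUE,
                         pareto = FALSE, pareto_grid = c(12, 12),
                         include_exchanges = FALSE,
                         sign_convention = "AO_over_EO",
                         evolved_maintenance_factor = 1,
                         evolved_lipid_factor = 1) {
  if (!length(criteria)) stop("criteria must be non-empty")
  criteria <- match.arg(criteria, optimality_criteria, several.ok = TRUE)
  names(datasets) <- vapply(datasets, `[[`, character(1), "strain_id")
  roles <- vapply(datasets, `[[`, character(1), "role")
  anc_ids <- names(datasets)[roles == "ancestor"]
  if (!length(anc_ids)) stop("datasets contain no ancestor")

  strain_model <- function(d) {
    env <- d$environment
    if (d$role == "evolved" && evolved_maintenance_factor != 1)
      env$maintenance_lower_bound <-
        env$maintenance_lower_bound * evolved_maintenance_factor
    m <- model
    if (d$role == "evolved" && evolved_lipid_factor != 1)
      m <- scale_biomass_composition(m, "lipid", evolved_lipid_factor)
    apply_knockout(apply_environment(m, env), d$knockout)
  }

  ## per-ancestor biomass floors (the "ancestral growth rate")
  floors <- list()
  needs_atp <- any(criteria %in% c("ATP_per_S", "ATP_per_flux"))
  if (needs_atp) {
    for (aid in anc_ids) {
      floors[[aid]] <- biomass_floor %||% tryCatch({
        d <- datasets[[aid]]
        m_a <- strain_model(d)
        smry <- replicate_summary(d$observations)
        rat <- stats::setNames(smry$mean, smry$ratio)[names(defs)]
        attr(rat, "se") <- stats::setNames(smry$se, smry$ratio)[names(defs)]
        con <- maximize_criterion(embed_ratio_set(m_a, defs, rat, d$style),
                                  "BM_per_S")
        if (con$status != "optimal") stop(con$message)
        0.9 * con$optimum
      }, error = function(e) NA_real_)
    }
  }

  rows <- list(); failures <- list()
  per_rep <- list()  # per strain x criterion: replicate-level percent values
  for (d in datasets) {
    sid <- d$strain_id
    aid <- if (d$role == "evolved") d$ancestor_id %||% anc_ids[1] else sid
    floor_s <- if (needs_atp) floors[[aid]] else NULL
    m_s <- tryCatch(strain_model(d), error = function(e) e)
    if (inherits(m_s, "error")) {
      failures[[sid]] <- conditionMessage(m_s)
      next
    }
    reps <- split(d$observations, d$observations$replicate)
    out <- list()
    for (cr in criteria) {
      res <- tryCatch({
        fl <- if (cr %in% c("ATP_per_S", "ATP_per_flux")) floor_s else NULL
        if (cr %in% c("ATP_per_S", "ATP_per_flux") &&
            (is.null(fl) || is.na(fl)))
          stop("no biomass floor available for ", cr)
        pcts <- c(); dists <- c()
        for (rp in reps) {
          rat <- stats::setNames(rp$value, rp$ratio)[names(defs)]
          attr(rat, "se") <- stats::setNames(rp$se, rp$ratio)[names(defs)]
          po <- percent_optimality(m_s, cr, defs, rat, style = d$style,
                                   biomass_floor = fl,
                                   include_exchanges = include_exchanges)
          if (po$status != "optimal") stop("replicate ", rp$replicate[1],
                                           ": ", po$message)
          pcts <- c(pcts, po$percent_optimality)
          if (compute_distances) {
            co <- closest_optimal_ratios(m_s, cr, defs,
                                         stats::setNames(rp$value, rp$ratio),
                                         biomass_floor = fl,
                                         include_exchanges = include_exchanges)
            dists <- c(dists, co$euclidean_distance)
          }
        }
        n <- length(pcts)
        per_rep[[paste(sid, cr, sep = "|")]] <- pcts
        data.frame(
          strain = sid, role = d$role, ancestor = aid, criterion = cr,
          n_reps = n,
          percent_mean = mean(pcts),
          percent_se = if (n > 1) stats::sd(pcts) / sqrt(n) else 0,
          D_mean = if (compute_distances) mean(dists) else NA_real_,
          D_se = if (compute_distances && n > 1)
            stats::sd(dists) / sqrt(n) else 0)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[[paste(sid, cr, sep = ":")]] <- conditionMessage(res)
      } else {
        out[[cr]] <- res
      }
    }
    if (length(out)) rows[[sid]] <- do.call(rbind, out)
  }
  if (!length(rows)) stop("every strain failed; first error: ",
                          failures[[1]])
  strains <- do.call(rbind, rows)
  rownames(strains) <- NULL

  ## distance metric vs the matching ancestor's mean distance
  strains$dist_metric <- NA_real_
  for (i in seq_len(nrow(strains))) {
    if (strains$role[i] != "evolved" || !compute_distances) next
    j <- strains$strain == strains$ancestor[i] &
      strains$criterion == strains$criterion[i]
    if (!any(j)) next
    strains$dist_metric[i] <- distance_metric(
      strains$D_mean[i], strains$D_mean[which(j)[1]],
      sign_convention = sign_convention)
  }

  ## Pareto distances on strain-mean ratios
  strains$pareto_distance <- NA_real_
  if (pareto && !is.na(model$atp_maintenance_reaction_id)) {
    for (d in datasets) {
      if (!d$strain_id %in% strains$strain) next
      pd <- tryCatch({
        m_s <- strain_model(d)
        surf <- build_pareto_surface(m_s, pareto_grid[1], pareto_grid[2],
                                     include_exchanges = include_exchanges)
        smry <- replicate_summary(d$observations)
        rat <- stats::setNames(smry$mean, smry$ratio)[names(defs)]
        attr(rat, "se") <- stats::setNames(smry$se, smry$ratio)[names(defs)]
        pr <- embed_ratio_set(m_s, defs, rat, d$style)
        as.numeric(pareto_distance(surf, pr))
      }, error = function(e) NA_real_)
      strains$pareto_distance[strains$strain == d$strain_id] <- pd
    }
  }

  ## ancestor-vs-evolved tests per criterion (two-sample for replicated
  ## ancestors, one-sample against the single ancestral value otherwise)
  tests <- list()
  single_anc <- length(anc_ids) == 1
  if (single_anc && sum(roles == "evolved") >= 2) {
    aid <- anc_ids[1]
    for (cr in criteria) {
      anc_vals <- per_rep[[paste(aid, cr, sep = "|")]]
      ev <- strains[strains$role == "evolved" & strains$criterion == cr, ]
      if (!length(anc_vals) || nrow(ev) < 2) next
      design <- if (length(anc_vals) > 1) "two_sample" else "one_sample"
      tests[[cr]] <- cbind(criterion = cr,
                           as.data.frame(compare_strains(
                             anc_vals, ev$percent_mean, design)))
    }
  }
  tests <- if (length(tests)) do.call(rbind, tests) else NULL

  ## cross-population CV and per-ratio tests need >= 2 evolved strains
  all_obs <- do.call(rbind, lapply(datasets[names(datasets) %in%
                                              strains$strain],
                                   `[[`, "observations"))
  notes <- character(0)
  cv <- withCallingHandlers(
    tryCatch(cv_across_evolved(all_obs, roles), error = function(e) NA_real_),
    warning = function(w) {
      notes <<- c(notes, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  flux_tests <- if (single_anc)
    tryCatch(flux_change_tests(all_obs, roles), error = function(e) NULL)
  else NULL

  structure(list(strains = strains, tests = tests, cv = cv,
                 flux_tests = flux_tests, failures = failures,
                 notes = notes, criteria = criteria),
            class = "evoflux_results")
}

#' @export
print.evoflux_results <- function(x, ...) {
  cat("<evoflux_results> ", length(unique(x$strains$strain)), " strains x ",
      length(x$criteria), " criteria\n", sep = "")
  print(utils::head(x$strains, 12))
  if (length(x$failures))
    cat("failed strains:", paste(names(x$failures), collapse = ", "), "\n")
  invisible(x)
}

#' Compare ancestor and evolved optimality values
#'
#' Normality of the residuals is checked with a Shapiro-Wilk test at alpha =
#' 0.05; if not rejected a two-sided t-test is used (pooled variance for the
#' two-sample design, one-sample against the ancestral value otherwise),
#' else the Mann-Whitney-Wilcoxon rank-sum (or signed-rank) test.
#' Zero-variance (degenerate) data fall back to the rank test.
#'
#' @param ancestor numeric: replicate values for the ancestor (two-sample) or
#'   a single ancestral value (one-sample).
#' @param evolved numeric values for the evolved strains (>= 2).
#' @param design `"two_sample"` or `"one_sample"`.
#' @return list: `test` (name), `statistic`, `p_value`,
#'   `shapiro_p`, `normal`, `degenerate`.
#' @export
compare_strains <- function(ancestor, evolved,
                            design = c("two_sample", "one_sample")) {
  design <- match.arg(design)
  if (length(evolved) < 2) stop("need >= 2 evolved values")
  if (design == "two_sample" && length(ancestor) < 2)
    stop("two_sample design needs >= 2 ancestor values")
  if (design == "one_sample" && length(ancestor) != 1)
    stop("one_sample design needs a single ancestral value")
  resid <- if (design == "two_sample")
    c(ancestor - mean(ancestor), evolved - mean(evolved))
  else evolved - mean(evolved)
  degen <- stats::sd(resid) < .Machine$double.eps^0.5
  if (degen && all(c(ancestor, evolved) == c(ancestor, evolved)[1])) {
    ## identical groups: no evidence of difference
    return(list(test = "wilcoxon", statistic = 0, p_value = 1,
                shapiro_p = NA_real_, normal = FALSE, degenerate = TRUE))
  }
  shap_p <- if (degen) 0 else
    tryCatch(stats::shapiro.test(resid)$p.value, error = function(e) 0)
  normal <- !degen && shap_p >= 0.05
  if (normal) {
    ht <- if (design == "two_sample")
      stats::t.test(evolved, ancestor, var.equal = TRUE)
    else stats::t.test(evolved, mu = ancestor)
    nm <- "t"
  } else {
    ht <- suppressWarnings(
      if (design == "two_sample") stats::wilcox.test(evolved, ancestor)
      else stats::wilcox.test(evolved, mu = ancestor))
    nm <- "wilcoxon"
  }
  pv <- ht$p.value
  if (is.na(pv)) pv <- 1
  list(test = nm, statistic = unname(ht$statistic), p_value = pv,
       shapiro_p = shap_p, normal = normal, degenerate = degen)
}

#' Per-ratio and multivariate tests of flux-ratio change across strains
#'
#' Per ratio: one-way ANOVA across strains on biological-replicate values,
#' Tukey HSD contrasts of each evolved strain against the ancestor, and
#' Benjamini-Hochberg FDR over the per-strain regression contrasts (ancestor
#' as the reference level). Multivariate: MANOVA with the ratios as
#' dependent variables and strain as the factor, reported as Pillai's trace.
#'
#' @param observations observations data.frame (biological-replicate level).
#' @param roles named character strain -> role; the ancestor is the
#'   reference level.
#' @return list: `anova` (ratio, F, p), `tukey` (ratio, contrast, diff,
#'   p_adj), `contrasts` (ratio, strain, estimate, p, p_fdr, significant),
#'   `manova` (pillai, approx_F, p) or `NULL` when < 2 ratios.
#' @export
flux_change_tests <- function(observations, roles) {
  anc <- names(roles)[roles == "ancestor"]
  if (length(anc) != 1) stop("flux_change_tests needs exactly one ancestor")
  obs <- observations
  obs$strain <- stats::relevel(factor(obs$strain), ref = anc)
  if (length(levels(obs$strain)) < 2) stop("need >= 2 strains")
  ratios <- unique(obs$ratio)
  an <- list(); tk <- list(); ct <- list()
  for (r in ratios) {
    d <- obs[obs$ratio == r, ]
    within_var <- sum(tapply(d$value, d$strain, function(x)
      sum((x - mean(x))^2)))
    if (min(table(d$strain)) < 2 || stats::var(d$value) == 0 ||
        within_var < 1e-20) {
      an[[r]] <- data.frame(ratio = r, F = NA_real_, p = NA_real_,
                            note = "unestimable")
      next
    }
    fit <- stats::aov(value ~ strain, data = d)
    s <- summary(fit)[[1]]
    an[[r]] <- data.frame(ratio = r, F = s$`F value`[1], p = s$`Pr(>F)`[1],
                          note = "")
    th <- stats::TukeyHSD(fit)$strain
    anc_rows <- grepl(paste0("-", anc, "$"), rownames(th)) |
      grepl(paste0("^", anc, "-"), rownames(th))
    th <- th[anc_rows, , drop = FALSE]
    tk[[r]] <- data.frame(ratio = r, contrast = rownames(th),
                          diff = th[, "diff"], p_adj = th[, "p adj"],
                          row.names = NULL)
    cf <- summary(stats::lm(value ~ strain, data = d))$coefficients
    cf <- cf[rownames(cf) != "(Intercept)", , drop = FALSE]
    ct[[r]] <- data.frame(ratio = r,
                          strain = sub("^strain", "", rownames(cf)),
                          estimate = cf[, "Estimate"],
                          p = cf[, "Pr(>|t|)"], row.names = NULL)
  }
  contrasts <- do.call(rbind, ct)
  if (!is.null(contrasts) && nrow(contrasts)) {
    contrasts$p_fdr <- stats::p.adjust(contrasts$p, method = "BH")
    contrasts$significant <- contrasts$p_fdr < 0.05
  }
  mv <- NULL
  if (length(ratios) >= 2) {
    wide <- stats::reshape(obs[, c("strain", "replicate", "ratio", "value")],
                           idvar = c("strain", "replicate"),
                           timevar = "ratio", direction = "wide")
    Y <- as.matrix(wide[, paste0("value.", ratios), drop = FALSE])
    keep <- stats::complete.cases(Y)
    Y <- Y[keep, , drop = FALSE]
    grp <- droplevels(wide$strain[keep])
    Y <- Y[, apply(Y, 2, stats::var) > 0, drop = FALSE]
    if (nlevels(grp) >= 2 && ncol(Y) >= 2 && nrow(Y) > nlevels(grp)) {
      fit <- stats::manova(Y ~ grp)
      s <- summary(fit, test = "Pillai")$stats
      mv <- list(pillai = s["grp", "Pillai"],
                 approx_F = s["grp", "approx F"],
                 p = s["grp", "Pr(>F)"])
    }
  }
  list(anova = do.call(rbind, an), tukey = do.call(rbind, tk),
       contrasts = contrasts, manova = mv)
}

#' Sensitivity scan over modelling assumptions
#'
#' Re-runs the full analysis across a range of values on one axis and
#' reports the mean evolved-minus-ancestor change in percent optimality per
#' criterion, with infeasible settings recorded rather than aborting.
#'
#' Axes: `"oxygen_uptake"` (ancestral oxygen uptake rate; evolved bounds
#' follow the oxygen policy at slope 1), `"oxygen_slope"` (slope of the
#' evolutionary oxygen/substrate scaling, scanned 0.5-1.5), `"maintenance"`
#' (evolved maintenance bound as a fraction of default, scanned 0.5-1.5) and
#' `"lipid"` (evolved biomass lipid-class scale factor, scanned 0.8-1.2).
#'
#' @param model,datasets,defs,criteria as in [run_analysis()].
#' @param axis scan axis.
#' @param values numeric values to scan.
#' @param ... further arguments passed to [run_analysis()].
#' @return data.frame: value x criterion with `delta_percent` (mean evolved -
#'   ancestor), `n_evolved`, `n_failed`.
#' @export
sensitivity_scan <- function(model, datasets, defs,
                             axis = c("oxygen_uptake", "oxygen_slope",
                                      "maintenance", "lipid"),
                             values, criteria = c("BM_per_S", "ATP_per_S"),
                             ...) {
  axis <- match.arg(axis)
  roles <- vapply(datasets, `[[`, character(1), "role")
  anc <- datasets[[which(roles == "ancestor")[1]]]
  anc_up <- anc$environment$substrate_uptake
  anc_o2 <- anc$environment$oxygen_uptake
  out <- list()
  for (val in values) {
    ds <- datasets
    extra <- list()
    if (axis == "oxygen_uptake" || axis == "oxygen_slope") {
      o2 <- if (axis == "oxygen_uptake") val else anc_o2
      slope <- if (axis == "oxygen_slope") val else 1
      if (is.na(o2)) stop("datasets carry no oxygen constraint to scan")
      ds <- lapply(ds, function(d) {
        d$environment$oxygen_uptake <- if (d$role == "ancestor") o2 else
          apply_oxygen_policy(o2, anc_up, d$environment$substrate_uptake,
                              slope = slope)
        d
      })
    } else if (axis == "maintenance") {
      extra$evolved_maintenance_factor <- val
    } else {
      extra$evolved_lipid_factor <- val
    }
    res <- tryCatch(
      do.call(run_analysis, c(list(model, ds, defs, criteria = criteria),
                              extra, list(...))),
      error = function(e) e)
    for (cr in criteria) {
      if (inherits(res, "error")) {
        out[[paste(val, cr)]] <- data.frame(
          value = val, criterion = cr, delta_percent = NA_real_,
          n_evolved = 0L, n_failed = length(datasets))
        next
      }
      st <- res$strains[res$strains$criterion == cr, ]
      ev <- st[st$role == "evolved", ]
      ap <- st$percent_mean[st$role == "ancestor"]
      out[[paste(val, cr)]] <- data.frame(
        value = val, criterion = cr,
        delta_percent = if (nrow(ev) && length(ap))
          mean(ev$percent_mean) - mean(ap) else NA_real_,
        n_evolved = nrow(ev), n_failed = length(res$failures))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
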