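#' Define a branch-point flux ratio
#'
#' A flux ratio is a linear-fractional function of the flux vector,
#' num(v)/den(v), where both terms are nonnegative linear combinations of
#' reaction fluxes (the fraction of a metabolite pool produced via one branch
#' of a branch point). Because embedding multiplies through by the
#' denominator, all denominator reactions must carry nonnegative flux; this
#' holds by construction for irreversible producer reactions and is asserted
#' when embedding.
#'
#' @param name unique ratio name (e.g. `"OAA_from_PEP"`).
#' @param numerator,denominator named numeric: reaction id -> coefficient;
#'   the denominator must be non-empty and typically contains the numerator
#'   terms.
#' @param mode how an observation of this ratio constrains the model:
#'   `"exact"` (equality), `"upper_bound"` (observed value is an upper bound
#'   on the ratio), `"lower_bound"`, or `"interval"`.
#' @return a `flux_ratio_definition`.
#' @export
flux_ratio_definition <- function(name, numerator, denominator,
                                  mode = c("exact", "upper_bound",
                                           "lower_bound", "interval")) {
  mode <- match.arg(mode)
  if (!length(denominator)) stop("denominator must be non-empty")
  if (!all(is.finite(unlist(c(numerator, denominator)))))
    stop("ratio coefficients must be finite")
  structure(list(name = name, numerator = unlist(numerator),
                 denominator = unlist(denominator), mode = mode),
            class = "flux_ratio_definition")
}

#' Read flux-ratio definitions from YAML
#'
#' Expected structure: a list of entries with fields `name`, `numerator`,
#' `denominator` (mappings reaction -> coefficient) and optional `mode`.
#' @param path YAML file.
#' @return named list of [flux_ratio_definition()]s.
#' @export
read_ratio_definitions <- function(path) {
  y <- yaml::read_yaml(path)
  defs <- lapply(y, function(e)
    flux_ratio_definition(e$name, unlist(e$numerator), unlist(e$denominator),
                          e$mode %||% "exact"))
  names(defs) <- vapply(defs, `[[`, character(1), "name")
  if (anyDuplicated(names(defs))) stop("ratio names must be unique")
  defs
}

#' Write flux-ratio definitions to YAML
#' @param defs named list of [flux_ratio_definition()]s.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ratio_definitions <- function(defs, path) {
  yaml::write_yaml(lapply(unname(defs), function(d)
    list(name = d$name, numerator = as.list(d$numerator),
         denominator = as.list(d$denominator), mode = d$mode)), path)
  invisible(path)
}

#' Embed one flux-ratio observation as a linear constraint
#'
#' Adds the homogeneous row num(v) - R * den(v) \{=, <=, >=\} 0 to the
#' constraint system, so any feasible solution with positive denominator has
#' its ratio pinned (or bounded) at R.
#'
#' @param p a `flux_problem` (or `metabolic_model`, coerced).
#' @param def a [flux_ratio_definition()].
#' @param R observed ratio in \code{[0, 1]}.
#' @param mode override of `def$mode`.
#' @param R_range length-2 numeric, required for `mode = "interval"`.
#' @return the augmented `flux_problem`.
#' @export
embed_ratio_constraint <- function(p, def, R, mode = NULL, R_range = NULL) {
  p <- as_flux_problem(p)
  stopifnot(inherits(def, "flux_ratio_definition"))
  mode <- mode %||% def$mode
  if (mode != "interval") {
    if (!is.finite(R) || R < 0 || R > 1)
      stop("ratio '", def$name, "': R must lie in [0, 1], got ", R)
  }
  if (any(p$lb[names(def$denominator)] < 0))
    stop("ratio '", def$name, "': denominator reactions must be irreversible ",
         "(or split) so den(v) >= 0 holds")
  row <- function(Rv) {
    cf <- -Rv * def$denominator
    for (nm in names(def$numerator))
      cf[nm] <- (if (nm %in% names(cf)) cf[[nm]] else 0) + def$numerator[[nm]]
    cf
  }
  switch(mode,
    exact = add_constraint_row(p, row(R), "=", 0, paste0("ratio:", def$name)),
    upper_bound = add_constraint_row(p, row(R), "<=", 0,
                                     paste0("ratio_ub:", def$name)),
    lower_bound = add_constraint_row(p, row(R), ">=", 0,
                                     paste0("ratio_lb:", def$name)),
    interval = {
      if (is.null(R_range) || length(R_range) != 2)
        stop("mode 'interval' requires R_range = c(lo, hi)")
      lo <- max(0, min(R_range)); hi <- min(1, max(R_range))
      p <- add_constraint_row(p, row(lo), ">=", 0,
                              paste0("ratio_lo:", def$name))
      add_constraint_row(p, row(hi), "<=", 0, paste0("ratio_hi:", def$name))
    })
}

#' Embed a full set of ratio observations for one replicate
#'
#' Dataset styles follow the three study designs: `"ltee"` embeds each ratio
#' with its definition's declared mode (internal-ratio rows; typically exact
#' with one lower-bound ratio); `"lactate"` embeds interval bounds at
#' value +/- 5\% relative; `"ko"` embeds interval bounds at value +/- its
#' reported standard error.
#'
#' @param p a `flux_problem` or `metabolic_model`.
#' @param defs named list of [flux_ratio_definition()]s.
#' @param observations named numeric vector of observed ratios (one per
#'   declared definition), or a data.frame with columns `ratio`, `value` and
#'   (for `"ko"`) `se`.
#' @param style `"ltee"`, `"lactate"` or `"ko"`.
#' @return the augmented `flux_problem`.
#' @export
embed_ratio_set <- function(p, defs, observations,
                            style = c("ltee", "lactate", "ko")) {
  style <- match.arg(style)
  p <- as_flux_problem(p)
  if (is.data.frame(observations)) {
    vals <- stats::setNames(observations$value, observations$ratio)
    ses <- if ("se" %in% names(observations))
      stats::setNames(observations$se, observations$ratio) else NULL
  } else {
    vals <- observations; ses <- attr(observations, "se")
  }
  missing <- setdiff(names(defs), names(vals))
  if (length(missing))
    stop("missing observation(s) for declared ratio(s): ",
         paste(missing, collapse = ", "))
  for (nm in names(defs)) {
    d <- defs[[nm]]; R <- unname(vals[[nm]])
    p <- switch(style,
      ltee = embed_ratio_constraint(p, d, R),
      lactate = embed_ratio_constraint(p, d, R, mode = "interval",
                                       R_range = R * c(0.95, 1.05)),
      ko = {
        se <- if (!is.null(ses) && nm %in% names(ses)) ses[[nm]] else 0
        embed_ratio_constraint(p, d, R, mode = "interval",
                               R_range = c(R - se, R + se))
      })
  }
  p
}

#' Evaluate ratio definitions on a flux vector
#'
#' @param defs named list of [flux_ratio_definition()]s.
#' @param v named flux vector.
#' @param tol denominators below `tol` flag the ratio as undefined (`NA`),
#'   never coerced to 0.
#' @return named numeric of ratios; undefined ratios are `NA` and listed in
#'   the `"undefined"` attribute.
#' @export
ratios_from_flux_vector <- function(defs, v, tol = 1e-9) {
  out <- stats::setNames(rep(NA_real_, length(defs)), names(defs))
  undef <- character(0)
  for (nm in names(defs)) {
    d <- defs[[nm]]
    den <- sum(d$denominator * v[names(d$denominator)])
    num <- sum(d$numerator * v[names(d$numerator)])
    if (!is.finite(den) || abs(den) < tol) undef <- c(undef, nm)
    else out[nm] <- num / den
  }
  attr(out, "undefined") <- undef
  out
}

#' Summarize replicate-structured ratio observations per strain
#'
#' Technical replicates (optional `tech` column) are averaged into biological
#' replicates first; the per-strain mean and standard error (sample SD /
#' sqrt(n)) are then computed across biological replicates.
#'
#' @param observations data.frame with columns `strain`, `replicate`,
#'   `ratio`, `value` and optionally `tech`.
#' @return data.frame with columns `strain`, `ratio`, `mean`, `se`, `n_bio`.
#' @export
replicate_summary <- function(observations) {
  req <- c("strain", "replicate", "ratio", "value")
  if (!all(req %in% names(observations)))
    stop("observations need columns: ", paste(req, collapse = ", "))
  bio <- stats::aggregate(value ~ strain + replicate + ratio, observations, mean)
  agg <- stats::aggregate(value ~ strain + ratio, bio, function(x)
    c(mean = mean(x), se = if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0,
      n = length(x)))
  out <- data.frame(strain = agg$strain, ratio = agg$ratio,
                    mean = agg$value[, "mean"], se = agg$value[, "se"],
                    n_bio = agg$value[, "n"])
  out[order(out$strain, out$ratio), , drop = FALSE]
}

#' Coefficient of variation of ratios across evolved strains
#'
#' Parallelism measure: for each ratio, the sample standard deviation of the
#' per-strain means across evolved strains divided by their mean, averaged
#' over ratios. Ratios with zero mean are excluded with a warning.
#'
#' @param observations observations data.frame (see [replicate_summary()]).
#' @param roles named character vector strain -> `"ancestor"`/`"evolved"`.
#' @return scalar CV.
#' @export
cv_across_evolved <- function(observations, roles) {
  smry <- replicate_summary(observations)
  ev <- smry[roles[as.character(smry$strain)] == "evolved", , drop = FALSE]
  if (length(unique(ev$strain)) < 2)
    stop("CV requires >= 2 evolved strains")
  contribs <- c()
  for (r in unique(ev$ratio)) {
    x <- ev$mean[ev$ratio == r]
    mu <- mean(x)
    if (abs(mu) < .Machine$double.eps^0.5) {
      warning("ratio '", r, "' has zero mean across evolved strains; ",
              "excluded from CV")
      next
    }
    contribs[r] <- stats::sd(x) / mu
  }
  mean(contribs)
}

#' Read/write ratio observations in the package TSV schema
#'
#' Columns: `strain`, `replicate`, `ratio`, `value`, `se` (biological-
#' replicate level; `se` is the SE over technical replicates).
#' @param path TSV file.
#' @return data.frame of observations.
#' @export
read_observations <- function(path) {
  obs <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("strain", "replicate", "ratio", "value")
  if (!all(req %in% names(obs)))
    stop("observation TSV needs columns: ", paste(req, collapse = ", "))
  if (any(obs$value < -1e-9 | obs$value > 1 + 1e-9))
    stop("ratio observations must lie in [0, 1]")
  obs
}

#' @rdname read_observations
#' @param observations data.frame of observations.
#' @export
write_observations <- function(observations, path) {
  utils::write.table(observations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
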