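#' Construct a stoichiometric metabolic model
#'
#' The central container: a stoichiometric matrix over metabolites and
#' reactions with flux bounds and designated reactions (biomass, ATP
#' maintenance, substrate and oxygen exchanges). Flux units are
#' mmol/gCDW/hr; the biomass flux is 1/hr.
#'
#' @param stoichiometry named list, one element per reaction: a named numeric
#'   vector of metabolite coefficients (negative = consumed).
#' @param lb,ub named numeric flux bounds per reaction (recycled defaults
#'   0/1000 for missing names).
#' @param is_exchange named logical; reactions exchanging matter with the
#'   environment. Defaults to reactions whose stoichiometry is one-sided,
#'   except the biomass reaction.
#' @param biomass,atpm,substrate_exchange,oxygen_exchange designated reaction
#'   ids (`atpm` and `oxygen_exchange` may be `NA` for minimal toy models).
#' @param boundary_metabolites character ids of boundary species excluded
#'   from the steady-state mass balance.
#' @param lipid_components metabolite ids whose biomass coefficients belong
#'   to the lipid class (used by [scale_biomass_composition()]).
#' @param id model name.
#' @return An object of class `metabolic_model`.
#' @export
metabolic_model <- function(stoichiometry, lb = NULL, ub = NULL,
                            is_exchange = NULL,
                            biomass, atpm = NA_character_,
                            substrate_exchange, oxygen_exchange = NA_character_,
                            boundary_metabolites = character(),
                            lipid_components = character(),
                            id = "model") {
  rxn_ids <- names(stoichiometry)
  if (is.null(rxn_ids) || anyDuplicated(rxn_ids))
    stop("reaction ids must be unique and named")
  met_ids <- sort(unique(unlist(lapply(stoichiometry, names))))
  if (anyNA(met_ids) || any(met_ids == ""))
    stop("every stoichiometric coefficient must name a metabolite")
  S <- matrix(0, length(met_ids), length(rxn_ids),
              dimnames = list(met_ids, rxn_ids))
  for (r in rxn_ids) {
    st <- stoichiometry[[r]]
    if (!length(st)) stop("reaction '", r, "' has empty stoichiometry")
    S[names(st), r] <- st
  }
  full <- function(x, default) {
    out <- rep(default, length(rxn_ids)); names(out) <- rxn_ids
    if (!is.null(x)) out[names(x)] <- x
    out
  }
  lb <- full(lb, 0); ub <- full(ub, 1000)
  if (any(lb > ub)) stop("lower_bound > upper_bound for: ",
                         paste(rxn_ids[lb > ub], collapse = ", "))
  if (is.null(is_exchange)) {
    one_sided <- vapply(stoichiometry, function(st) all(st > 0) || all(st < 0),
                        logical(1))
    is_exchange <- one_sided
    is_exchange[biomass] <- FALSE
    if (!is.na(atpm)) is_exchange[atpm] <- FALSE
  } else {
    is_exchange <- full(is_exchange, FALSE) > 0
  }
  m <- structure(list(
    id = id, S = S,
    reactions = rxn_ids, metabolites = met_ids,
    lb = lb, ub = ub, is_exchange = is_exchange,
    biomass_reaction_id = biomass,
    atp_maintenance_reaction_id = atpm,
    substrate_exchange_id = substrate_exchange,
    oxygen_exchange_id = oxygen_exchange,
    boundary_metabolites = boundary_metabolites,
    lipid_components = lipid_components
  ), class = "metabolic_model")
  validate_model(m)
}

#' Validate a metabolic model
#'
#' Checks id uniqueness, bound ordering, resolvable designated reactions and
#' a well-formed stoichiometric matrix. Called by all constructors/loaders.
#' @param m a `metabolic_model`.
#' @return `m`, invisibly returned unchanged, or an error.
#' @export
validate_model <- function(m) {
  stopifnot(inherits(m, "metabolic_model"))
  if (anyDuplicated(m$metabolites)) stop("metabolite ids are not unique")
  if (anyDuplicated(m$reactions)) stop("reaction ids are not unique")
  for (rid in c(m$biomass_reaction_id, m$substrate_exchange_id)) {
    if (!rid %in% m$reactions)
      stop("designated reaction '", rid, "' not present in model")
  }
  for (rid in c(m$atp_maintenance_reaction_id, m$oxygen_exchange_id)) {
    if (!is.na(rid) && !rid %in% m$reactions)
      stop("designated reaction '", rid, "' not present in model")
  }
  if (any(m$lb > m$ub)) stop("lower_bound exceeds upper_bound")
  bad <- setdiff(m$boundary_metabolites, m$metabolites)
  if (length(bad)) stop("unknown boundary metabolites: ", paste(bad, collapse = ", "))
  m
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, "\n",
      "  reactions:   ", length(x$reactions),
      " (", sum(x$is_exchange), " exchange)\n",
      "  metabolites: ", length(x$metabolites),
      " (", length(x$boundary_metabolites), " boundary)\n",
      "  biomass: ", x$biomass_reaction_id,
      "  atpm: ", x$atp_maintenance_reaction_id, "\n", sep = "")
  invisible(x)
}

#' Internal (balanced) metabolites of a model
#' @param m a `metabolic_model`.
#' @return character vector of metabolite ids subject to steady-state balance.
#' @export
internal_metabolites <- function(m) setdiff(m$metabolites, m$boundary_metabolites)

## ---------------------------------------------------------------------------
## File I/O

#' Load a metabolic model from disk
#'
#' Supported dialects: SBML Level 3 with the FBC extension (`"sbml"`),
#' BiGG-style JSON (`"bigg_json"`), and a plain TSV reaction table (`"tsv"`),
#' one reaction per line, `id<TAB>equation<TAB>lb<TAB>ub` with equations like
#' `A + 2 B -> C`. TSV files may carry directive lines
#' `#! biomass <id>`, `#! atpm <id>`, `#! substrate <id>`, `#! oxygen <id>`,
#' `#! exchange <id> ...`, `#! boundary <met> ...`, `#! lipid <met> ...`
#' naming the designated reactions and tagged metabolites.
#'
#' @param path file path.
#' @param format `"sbml"`, `"bigg_json"` or `"tsv"`; default guessed from the
#'   file extension.
#' @param biomass,atpm,substrate_exchange,oxygen_exchange designated reaction
#'   ids; defaults follow BiGG conventions (`BIOMASS*`/objective, `ATPM`,
#'   `EX_glc__D_e`, `EX_o2_e`) for SBML/JSON and `#!` directives for TSV.
#' @return a validated [metabolic_model()].
#' @export
load_model <- function(path, format = c("guess", "sbml", "bigg_json", "tsv"),
                       biomass = NULL, atpm = NULL,
                       substrate_exchange = NULL, oxygen_exchange = NULL) {
  format <- match.arg(format)
  if (format == "guess") {
    format <- switch(tolower(tools::file_ext(path)),
                     xml = , sbml = "sbml",
                     json = "bigg_json",
                     tsv = , txt = "tsv",
                     stop("cannot guess model format from extension of ", path))
  }
  if (!file.exists(path)) stop("model file not found: ", path)
  switch(format,
         tsv = .load_tsv_model(path, biomass, atpm, substrate_exchange, oxygen_exchange),
         bigg_json = .load_bigg_json(path, biomass, atpm, substrate_exchange, oxygen_exchange),
         sbml = .load_sbml(path, biomass, atpm, substrate_exchange, oxygen_exchange))
}

.parse_equation <- function(eq, rid) {
  arrow <- regmatches(eq, regexpr("<?->|<-", eq))
  if (!length(arrow)) stop("reaction '", rid, "': no arrow in equation '", eq, "'")
  parts <- strsplit(eq, "<?->|<-", perl = TRUE)[[1]]
  lhs <- if (length(parts) >= 1) trimws(parts[1]) else ""
  rhs <- if (length(parts) >= 2) trimws(parts[2]) else ""
  term <- function(side, sgn) {
    if (!nzchar(side)) return(numeric(0))
    toks <- trimws(strsplit(side, "\\+")[[1]])
    out <- numeric(0)
    for (tk in toks) {
      bits <- strsplit(tk, "\\s+")[[1]]
      if (length(bits) == 1) { coef <- 1; met <- bits }
      else if (length(bits) == 2) {
        coef <- suppressWarnings(as.numeric(bits[1]))
        if (is.na(coef)) stop("reaction '", rid, "': bad coefficient in '", tk, "'")
        met <- bits[2]
      } else stop("reaction '", rid, "': cannot parse term '", tk, "'")
      out[met] <- sgn * coef + if (met %in% names(out)) out[[met]] else 0
    }
    out
  }
  st <- c(term(lhs, -1), term(rhs, +1))
  st <- tapply(st, names(st), sum)
  st <- st[st != 0]
  if (!length(st)) stop("reaction '", rid, "': empty stoichiometry")
  stats::setNames(as.numeric(st), names(st))
}

.load_tsv_model <- function(path, biomass, atpm, substrate, oxygen) {
  lines <- readLines(path)
  direct <- lines[startsWith(lines, "#!")]
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  dget <- function(key) {
    hit <- grep(paste0("^#!\\s*", key, "\\b"), direct, value = TRUE)
    if (!length(hit)) return(NULL)
    strsplit(trimws(sub(paste0("^#!\\s*", key), "", hit[1])), "\\s+")[[1]]
  }
  stoich <- list(); lb <- c(); ub <- c()
  for (ln in lines) {
    f <- strsplit(ln, "\t")[[1]]
    if (length(f) != 4) stop("TSV model line must have 4 tab-separated fields: ", ln)
    rid <- trimws(f[1])
    stoich[[rid]] <- .parse_equation(trimws(f[2]), rid)
    lb[rid] <- as.numeric(f[3]); ub[rid] <- as.numeric(f[4])
  }
  biomass <- biomass %||% dget("biomass")
  if (is.null(biomass)) stop("TSV model lacks a '#! biomass' directive and none supplied")
  exch <- dget("exchange")
  is_exchange <- NULL
  if (!is.null(exch)) {
    is_exchange <- stats::setNames(names(stoich) %in% exch, names(stoich))
  }
  metabolic_model(
    stoich, lb = lb, ub = ub, is_exchange = is_exchange,
    biomass = biomass,
    atpm = (atpm %||% dget("atpm")) %||% NA_character_,
    substrate_exchange = substrate %||% dget("substrate") %||%
      stop("TSV model lacks a '#! substrate' directive and none supplied"),
    oxygen_exchange = (oxygen %||% dget("oxygen")) %||% NA_character_,
    boundary_metabolites = dget("boundary") %||% character(),
    lipid_components = dget("lipid") %||% character(),
    id = sub("\\.[^.]*$", "", basename(path)))
}

.load_bigg_json <- function(path, biomass, atpm, substrate, oxygen) {
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(j$reactions) || is.null(j$metabolites))
    stop("not a BiGG-style JSON model (missing 'reactions'/'metabolites'): ", path)
  mets <- vapply(j$metabolites, function(m) m$id, character(1))
  stoich <- list(); lb <- c(); ub <- c(); obj <- c()
  for (r in j$reactions) {
    st <- unlist(r$metabolites)
    if (is.null(st)) stop("reaction '", r$id, "' has no metabolites entry")
    stoich[[r$id]] <- st
    lb[r$id] <- r$lower_bound %||% -1000
    ub[r$id] <- r$upper_bound %||% 1000
    obj[r$id] <- r$objective_coefficient %||% 0
  }
  rids <- names(stoich)
  biomass <- biomass %||% {
    cand <- rids[obj != 0]
    if (!length(cand)) cand <- grep("^BIOMASS", rids, ignore.case = TRUE, value = TRUE)
    if (!length(cand)) stop("cannot identify a biomass reaction in ", path)
    cand[1]
  }
  is_exchange <- stats::setNames(
    startsWith(rids, "EX_") |
      vapply(stoich, function(s) length(s) == 1, logical(1)), rids)
  is_exchange[biomass] <- FALSE
  boundary <- mets[!mets %in% unlist(lapply(stoich, names))]
  metabolic_model(
    stoich, lb = lb, ub = ub, is_exchange = is_exchange,
    biomass = biomass,
    atpm = atpm %||% (if ("ATPM" %in% rids) "ATPM" else NA_character_),
    substrate_exchange = substrate %||%
      (if ("EX_glc__D_e" %in% rids) "EX_glc__D_e" else
        stop("cannot identify the substrate exchange; pass substrate_exchange=")),
    oxygen_exchange = oxygen %||% (if ("EX_o2_e" %in% rids) "EX_o2_e" else NA_character_),
    boundary_metabolites = boundary,
    id = j$id %||% basename(path))
}

.load_sbml <- function(path, biomass, atpm, substrate, oxygen) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  if (!length(sp)) stop("no species found; is this SBML? ", path)
  met_ids <- xml2::xml_attr(sp, "id")
  boundary <- met_ids[xml2::xml_attr(sp, "boundaryCondition") %in% "true"]
  params <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))
  rx <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  if (!length(rx)) stop("no reactions found in ", path)
  stoich <- list(); lb <- c(); ub <- c()
  for (r in rx) {
    rid <- xml2::xml_attr(r, "id")
    sref <- function(tag, sgn) {
      ss <- xml2::xml_find_all(r, paste0("./", tag, "/speciesReference"))
      stats::setNames(sgn * as.numeric(xml2::xml_attr(ss, "stoichiometry")),
                      xml2::xml_attr(ss, "species"))
    }
    st <- c(sref("listOfReactants", -1), sref("listOfProducts", +1))
    if (!length(st)) stop("reaction '", rid, "' has no reactants or products")
    st <- tapply(st, names(st), sum)
    stoich[[rid]] <- stats::setNames(as.numeric(st), names(st))
    lbp <- xml2::xml_attr(r, "lowerFluxBound"); ubp <- xml2::xml_attr(r, "upperFluxBound")
    rev <- xml2::xml_attr(r, "reversible") %in% "true"
    lb[rid] <- if (!is.na(lbp) && lbp %in% names(pval)) pval[[lbp]] else if (rev) -1000 else 0
    ub[rid] <- if (!is.na(ubp) && ubp %in% names(pval)) pval[[ubp]] else 1000
  }
  rids <- names(stoich)
  if (is.null(biomass)) {
    fo <- xml2::xml_find_first(doc, ".//listOfObjectives//fluxObjective")
    biomass <- if (!inherits(fo, "xml_missing")) xml2::xml_attr(fo, "reaction") else {
      cand <- grep("BIOMASS", rids, ignore.case = TRUE, value = TRUE)
      if (!length(cand)) stop("cannot identify a biomass reaction in ", path)
      cand[1]
    }
  }
  ## remove boundary species from stoichiometries but keep them listed
  metabolic_model(
    stoich, lb = lb, ub = ub,
    is_exchange = stats::setNames(
      startsWith(rids, "EX_") |
        vapply(stoich, function(s) all(names(s) %in% boundary) ||
                 length(setdiff(names(s), boundary)) == 1 && any(names(s) %in% boundary) ||
                 length(s) == 1, logical(1)) & rids != biomass, rids),
    biomass = biomass,
    atpm = atpm %||% (if ("ATPM" %in% rids) "ATPM" else NA_character_),
    substrate_exchange = substrate %||%
      (if ("EX_glc__D_e" %in% rids) "EX_glc__D_e" else
        stop("cannot identify the substrate exchange; pass substrate_exchange=")),
    oxygen_exchange = oxygen %||% (if ("EX_o2_e" %in% rids) "EX_o2_e" else NA_character_),
    boundary_metabolites = boundary,
    id = xml2::xml_attr(xml2::xml_find_first(doc, ".//model"), "id") %||% basename(path))
}

#' Write a metabolic model to disk
#'
#' Inverse of [load_model()] for the same three dialects; loading a written
#' file round-trips stoichiometry, bounds and designated reaction ids.
#' @param m a `metabolic_model`.
#' @param path output file.
#' @param format `"tsv"`, `"bigg_json"` or `"sbml"`.
#' @return `path`, invisibly.
#' @export
write_model <- function(m, path, format = c("tsv", "bigg_json", "sbml")) {
  format <- match.arg(format)
  switch(format,
         tsv = .write_tsv_model(m, path),
         bigg_json = .write_bigg_json(m, path),
         sbml = .write_sbml(m, path))
  invisible(path)
}

.fmt_num <- function(x) formatC(x, format = "g", digits = 15)

.write_tsv_model <- function(m, path) {
  eqn <- function(rid) {
    st <- m$S[, rid]; st <- st[st != 0]
    side <- function(v) paste(ifelse(v == 1, names(v),
                                     paste(.fmt_num(v), names(v))), collapse = " + ")
    paste(side(-st[st < 0]), "->", side(st[st > 0]))
  }
  hdr <- c(paste("#! biomass", m$biomass_reaction_id),
           paste("#! substrate", m$substrate_exchange_id),
           if (!is.na(m$atp_maintenance_reaction_id))
             paste("#! atpm", m$atp_maintenance_reaction_id),
           if (!is.na(m$oxygen_exchange_id))
             paste("#! oxygen", m$oxygen_exchange_id),
           paste(c("#! exchange", m$reactions[m$is_exchange]), collapse = " "),
           if (length(m$boundary_metabolites))
             paste(c("#! boundary", m$boundary_metabolites), collapse = " "),
           if (length(m$lipid_components))
             paste(c("#! lipid", m$lipid_components), collapse = " "))
  body <- vapply(m$reactions, function(r)
    paste(r, eqn(r), .fmt_num(m$lb[r]), .fmt_num(m$ub[r]), sep = "\t"), character(1))
  writeLines(c(hdr, body), path)
}

.write_bigg_json <- function(m, path) {
  rx <- lapply(m$reactions, function(r) {
    st <- m$S[, r]; st <- st[st != 0]
    list(id = r, metabolites = as.list(st),
         lower_bound = unname(m$lb[r]), upper_bound = unname(m$ub[r]),
         objective_coefficient = as.numeric(r == m$biomass_reaction_id))
  })
  mets <- lapply(m$metabolites, function(mm) list(id = mm))
  jsonlite::write_json(list(id = m$id, reactions = rx, metabolites = mets),
                       path, auto_unbox = TRUE, digits = NA)
}

.write_sbml <- function(m, path) {
  esc <- function(x) gsub("&", "&amp;", x)
  bnd_params <- unique(c(m$lb, m$ub))
  pid <- stats::setNames(paste0("par_", seq_along(bnd_params)), .fmt_num(bnd_params))
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
           'level="3" version="1" fbc:required="false">'),
    paste0('<model id="', esc(m$id), '" fbc:strict="true">'),
    '<listOfCompartments><compartment id="c" constant="true"/></listOfCompartments>',
    '<listOfSpecies>',
    vapply(m$metabolites, function(mm)
      paste0('<species id="', esc(mm), '" compartment="c" constant="false" ',
             'hasOnlySubstanceUnits="false" boundaryCondition="',
             tolower(mm %in% m$boundary_metabolites), '"/>'), character(1)),
    '</listOfSpecies>',
    '<listOfParameters>',
    vapply(seq_along(bnd_params), function(i)
      paste0('<parameter id="', pid[i], '" value="', .fmt_num(bnd_params[i]),
             '" constant="true"/>'), character(1)),
    '</listOfParameters>',
    '<listOfReactions>')
  for (r in m$reactions) {
    st <- m$S[, r]; st <- st[st != 0]
    sref <- function(v) paste0('<speciesReference species="', esc(names(v)),
                               '" stoichiometry="', .fmt_num(abs(unname(v))),
                               '" constant="true"/>', collapse = "")
    lines <- c(lines,
      paste0('<reaction id="', esc(r), '" reversible="', tolower(m$lb[r] < 0),
             '" fast="false" fbc:lowerFluxBound="', pid[.fmt_num(m$lb[r])],
             '" fbc:upperFluxBound="', pid[.fmt_num(m$ub[r])], '">'),
      if (any(st < 0)) paste0('<listOfReactants>', sref(st[st < 0]), '</listOfReactants>'),
      if (any(st > 0)) paste0('<listOfProducts>', sref(st[st > 0]), '</listOfProducts>'),
      '</reaction>')
  }
  lines <- c(lines, '</listOfReactions>',
    '<fbc:listOfObjectives fbc:activeObjective="obj">',
    paste0('<fbc:objective fbc:id="obj" fbc:type="maximize">',
           '<fbc:listOfFluxObjectives><fbc:fluxObjective fbc:reaction="',
           esc(m$biomass_reaction_id),
           '" fbc:coefficient="1"/></fbc:listOfFluxObjectives></fbc:objective>'),
    '</fbc:listOfObjectives>', '</model>', '</sbml>')
  writeLines(lines, path)
}

## ---------------------------------------------------------------------------
## Constraint application

#' Specify an observed growth environment
#'
#' @param substrate_uptake observed substrate uptake rate (positive magnitude,
#'   mmol/gCDW/hr).
#' @param substrate_se standard error of the uptake rate; uptake is fixed as
#'   an equality within +/- 1 SE (exact equality when `substrate_se = 0`).
#' @param oxygen_uptake cap on oxygen uptake magnitude, or `NA` to leave the
#'   model default.
#' @param excretions named list/vector: exchange reaction id -> observed
#'   excretion rate (positive magnitude), optionally a `c(rate, se)` pair.
#' @param maintenance_lower_bound lower bound on the ATP maintenance flux,
#'   default 8.9 mmol ATP/gCDW/hr.
#' @return an `environment_spec` list.
#' @export
environment_spec <- function(substrate_uptake, substrate_se = 0,
                             oxygen_uptake = NA_real_,
                             excretions = list(),
                             maintenance_lower_bound = 8.9) {
  if (!is.finite(substrate_uptake) || substrate_uptake < 0)
    stop("substrate_uptake must be a non-negative rate")
  if (substrate_se < 0) stop("substrate_se must be >= 0")
  if (!is.na(oxygen_uptake) && oxygen_uptake < 0)
    stop("oxygen_uptake must be non-negative")
  if (maintenance_lower_bound < 0)
    stop("maintenance_lower_bound must be >= 0")
  structure(list(substrate_uptake = substrate_uptake,
                 substrate_se = substrate_se,
                 oxygen_uptake = oxygen_uptake,
                 excretions = excretions,
                 maintenance_lower_bound = maintenance_lower_bound),
            class = "environment_spec")
}

## +1 if positive flux imports matter (one-sided equation producing the
## internal metabolite), -1 for the BiGG convention (reactant-only exchange,
## uptake = negative flux).
.exchange_orientation <- function(m, rid) {
  st <- m$S[, rid]; st <- st[st != 0]
  internal <- setdiff(names(st), m$boundary_metabolites)
  v <- if (length(internal)) st[internal] else st
  if (all(v > 0)) 1 else -1
}

#' Constrain a model to an observed environment
#'
#' Fixes substrate uptake (and any measured excretions) to the observed rate,
#' as an equality within one standard error when an SE is supplied; caps
#' oxygen uptake; sets the maintenance-energy lower bound. All other
#' exchanges keep the model's minimal-medium defaults.
#'
#' @param m a `metabolic_model`.
#' @param env an [environment_spec()].
#' @return the constrained model.
#' @export
apply_environment <- function(m, env) {
  stopifnot(inherits(m, "metabolic_model"), inherits(env, "environment_spec"))
  set_rate <- function(m, rid, rate, se, direction) {
    ## direction: "import" or "export"; rate is a magnitude
    orient <- .exchange_orientation(m, rid)
    sgn <- if (direction == "import") orient else -orient
    lo <- sgn * rate - abs(se); hi <- sgn * rate + abs(se)
    m$lb[rid] <- min(lo, hi); m$ub[rid] <- max(lo, hi)
    m
  }
  m <- set_rate(m, m$substrate_exchange_id, env$substrate_uptake,
                env$substrate_se, "import")
  if (!is.na(env$oxygen_uptake)) {
    if (is.na(m$oxygen_exchange_id))
      stop("model has no designated oxygen exchange")
    rid <- m$oxygen_exchange_id
    orient <- .exchange_orientation(m, rid)
    if (orient > 0) { m$lb[rid] <- 0; m$ub[rid] <- env$oxygen_uptake }
    else            { m$lb[rid] <- -env$oxygen_uptake; m$ub[rid] <- 0 }
  }
  for (rid in names(env$excretions)) {
    if (!rid %in% m$reactions) stop("excretion reaction '", rid, "' not in model")
    v <- env$excretions[[rid]]
    m <- set_rate(m, rid, v[1], if (length(v) > 1) v[2] else 0, "export")
  }
  if (!is.na(m$atp_maintenance_reaction_id)) {
    rid <- m$atp_maintenance_reaction_id
    m$lb[rid] <- env$maintenance_lower_bound
    m$ub[rid] <- max(m$ub[rid], env$maintenance_lower_bound)
  } else if (env$maintenance_lower_bound > 0) {
    stop("maintenance_lower_bound > 0 but model has no ATP maintenance reaction")
  }
  validate_model(m)
}

#' Oxygen bound for an evolved strain from the ancestral oxygen/substrate ratio
#'
#' Evolved oxygen uptake is assumed to scale with the evolved substrate uptake
#' so that the ancestral oxygen/substrate ratio is preserved (slope 1); the
#' slope parameter scales the evolutionary change in the ratio for
#' sensitivity analysis (0.5-1.5 is the scanned range).
#'
#' @param ancestor_O2 ancestral oxygen uptake rate (> 0).
#' @param ancestor_substrate,evolved_substrate substrate uptake rates (> 0).
#' @param slope scaling of the proportional change, default 1.
#' @return the evolved oxygen uptake bound.
#' @export
apply_oxygen_policy <- function(ancestor_O2, ancestor_substrate,
                                evolved_substrate, slope = 1) {
  if (any(c(ancestor_O2, ancestor_substrate, evolved_substrate) <= 0))
    stop("all rates must be > 0")
  ancestor_O2 * (1 + slope * (evolved_substrate / ancestor_substrate - 1))
}

#' Simulate reaction knockouts
#'
#' Constrains the listed reactions to zero flux, leaving every other bound
#' untouched.
#' @param m a `metabolic_model`.
#' @param reaction_ids reactions to disable (may be empty).
#' @return the constrained model.
#' @export
apply_knockout <- function(m, reaction_ids) {
  stopifnot(inherits(m, "metabolic_model"))
  unknown <- setdiff(reaction_ids, m$reactions)
  if (length(unknown)) stop("unknown knockout reactions: ",
                            paste(unknown, collapse = ", "))
  m$lb[reaction_ids] <- 0
  m$ub[reaction_ids] <- 0
  m
}

#' Rescale a biomass-composition component class
#'
#' Multiplies the biomass coefficients of the metabolites tagged as the named
#' component class (e.g. lipids) by `factor`, emulating an evolved change in
#' bulk biomass composition.
#' @param m a `metabolic_model` with tagged `lipid_components`.
#' @param component currently `"lipid"`.
#' @param factor positive scale factor (1 = unchanged; the scanned range is
#'   0.8-1.2).
#' @return the modified model.
#' @export
scale_biomass_composition <- function(m, component = "lipid", factor) {
  stopifnot(inherits(m, "metabolic_model"))
  component <- match.arg(component)
  if (!is.numeric(factor) || factor <= 0) stop("factor must be > 0")
  tags <- m$lipid_components
  tags <- intersect(tags, rownames(m$S))
  tags <- tags[m$S[tags, m$biomass_reaction_id] != 0]
  if (!length(tags))
    stop("no metabolites tagged as '", component,
         "' appear in the biomass reaction")
  m$S[tags, m$biomass_reaction_id] <- factor * m$S[tags, m$biomass_reaction_id]
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
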