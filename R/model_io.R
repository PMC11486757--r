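#' Stoichiometric metabolic models
#'
#' A lightweight container for constraint-based models: metabolites, reactions
#' with stoichiometries and flux bounds [mmol/gDW/h], one objective reaction,
#' and an optional non-growth-associated maintenance (NGAM) reaction id.
#' Negative stoichiometric coefficients mean consumption. Exchange reactions
#' are boundary reactions touching exactly one metabolite; flux through them
#' is negative for uptake and positive for secretion.
#'
#' @param id metabolite identifier
#' @param name display name
#' @param compartment compartment tag
#' @param formula optional elemental formula
#' @return a `metabolite` object
#' @export
metabolite <- function(id, name = id, compartment = "c", formula = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  structure(list(id = id, name = name, compartment = compartment,
                 formula = formula), class = "metabolite")
}

#' @rdname metabolite
#' @param stoich named numeric vector, metabolite id -> coefficient
#'   (negative = consumed)
#' @param lb,ub flux bounds [mmol/gDW/h], `lb <= ub`
#' @param subsystem optional pathway tag
#' @param is_exchange flag; defaults to "touches exactly one metabolite"
#' @export
reaction <- function(id, stoich, lb = 0, ub = 1000, subsystem = NULL,
                     is_exchange = length(stoich) == 1L) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!length(stoich) || is.null(names(stoich)) || any(!nzchar(names(stoich))))
    stop_chemoflux(sprintf("reaction '%s': stoichiometry must be a non-empty named vector", id),
                   "chemoflux_model_error")
  if (lb > ub)
    stop_chemoflux(sprintf("reaction '%s': lb > ub", id), "chemoflux_model_error")
  structure(list(id = id, stoich = stoich, lb = lb, ub = ub,
                 subsystem = subsystem, is_exchange = is_exchange),
            class = "reaction")
}

#' @rdname metabolite
#' @param metabolites list of [metabolite()]s
#' @param reactions list of [reaction()]s (declaration order is preserved and
#'   determines matrix column order)
#' @param objective_id id of the objective reaction (e.g. biomass production)
#' @param ngam_id optional id of the maintenance ATP-hydrolysis reaction
#' @param model_id model identifier
#' @export
metabolic_model <- function(metabolites, reactions, objective_id,
                            ngam_id = NULL, model_id = "model") {
  mets <- stats::setNames(metabolites, vapply(metabolites, `[[`, "", "id"))
  rxns <- stats::setNames(reactions, vapply(reactions, `[[`, "", "id"))
  m <- structure(list(id = model_id, metabolites = mets, reactions = rxns,
                      objective_id = objective_id, ngam_id = ngam_id),
                 class = "metabolic_model")
  issues <- validate_model(m)
  fatal <- issues[issues$severity == "error", , drop = FALSE]
  if (nrow(fatal))
    stop_chemoflux(paste0("invalid model: ", paste(fatal$message, collapse = "; ")),
                   "chemoflux_model_error")
  m
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model '%s': %d metabolites, %d reactions, objective '%s'>\n",
              x$id, length(x$metabolites), length(x$reactions), x$objective_id))
  invisible(x)
}

#' Validate a metabolic model
#'
#' Structural checks that never throw on readable input: duplicate ids, bound
#' sanity, orphan metabolites (never used by any reaction), unresolved
#' stoichiometry keys, missing objective, and exchange reactions touching more
#' than one metabolite.
#'
#' @param model a `metabolic_model` (or an unclassed list with the same shape)
#' @return tibble of issues with columns `kind`, `severity`, `message`;
#'   zero rows for a clean model
#' @export
validate_model <- function(model) {
  issues <- list()
  add <- function(kind, severity, message)
    issues[[length(issues) + 1L]] <<- tibble::tibble(
      kind = kind, severity = severity, message = message)

  met_ids <- vapply(model$metabolites, `[[`, "", "id")
  rxn_ids <- vapply(model$reactions, `[[`, "", "id")
  for (dup in unique(met_ids[duplicated(met_ids)]))
    add("duplicate-id", "error", sprintf("duplicated metabolite id '%s'", dup))
  for (dup in unique(rxn_ids[duplicated(rxn_ids)]))
    add("duplicate-id", "error", sprintf("duplicated reaction id '%s'", dup))

  used <- character()
  for (r in model$reactions) {
    if (!length(r$stoich))
      add("empty-stoichiometry", "error", sprintf("reaction '%s' has empty stoichiometry", r$id))
    unknown <- setdiff(names(r$stoich), met_ids)
    for (u in unknown)
      add("unresolved-metabolite", "error",
          sprintf("reaction '%s' references unknown metabolite '%s'", r$id, u))
    if (is.numeric(r$lb) && is.numeric(r$ub) && r$lb > r$ub)
      add("bad-bounds", "error", sprintf("reaction '%s' has lb > ub", r$id))
    if (isTRUE(r$is_exchange) && length(r$stoich) != 1L)
      add("bad-exchange", "error",
          sprintf("exchange reaction '%s' touches %d metabolites", r$id, length(r$stoich)))
    used <- union(used, names(r$stoich))
  }
  for (orphan in setdiff(met_ids, used))
    add("orphan-metabolite", "warning", sprintf("metabolite '%s' is unused", orphan))

  obj <- model$objective_id
  if (is.null(obj) || !length(obj) || !obj %in% rxn_ids)
    add("missing-objective", "error",
        sprintf("objective reaction '%s' not found", obj %||% "<none>"))
  if (!is.null(model$ngam_id) && !model$ngam_id %in% rxn_ids)
    add("missing-ngam", "warning",
        sprintf("NGAM reaction '%s' not found", model$ngam_id))

  if (length(issues)) do.call(rbind, issues)
  else tibble::tibble(kind = character(), severity = character(), message = character())
}

#' Native JSON model dialect
#'
#' Lossless, diffable on-disk form of a [metabolic_model()]: stable key order,
#' stoichiometries as sorted id->coefficient maps. `write_native()` followed by
#' `read_native()` reproduces the model; writing again is byte-identical.
#'
#' @param model a `metabolic_model`
#' @param path output/input file path
#' @return `read_native()`: the model; `write_native()`: `path`, invisibly
#' @export
write_native <- function(model, path) {
  obj <- list(
    id = model$id,
    objective_id = model$objective_id,
    ngam_id = model$ngam_id,
    metabolites = lapply(unname(model$metabolites), function(m)
      list(id = m$id, name = m$name, compartment = m$compartment,
           formula = m$formula)),
    reactions = lapply(unname(model$reactions), function(r) {
      st <- r$stoich[order(names(r$stoich))]
      list(id = r$id, stoichiometry = as.list(st), lb = r$lb, ub = r$ub,
           subsystem = r$subsystem, is_exchange = r$is_exchange)
    })
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE, digits = NA,
                           null = "null")
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_native
#' @export
read_native <- function(path) {
  if (!file.exists(path))
    stop_chemoflux(sprintf("file not found: %s", path), "chemoflux_io_error")
  obj <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop_chemoflux(
                    sprintf("malformed native model JSON (%s): %s", path, conditionMessage(e)),
                    "chemoflux_parse_error"))
  for (field in c("metabolites", "reactions", "objective_id"))
    if (is.null(obj[[field]]))
      stop_chemoflux(sprintf("native model at $.%s: field missing", field),
                     "chemoflux_parse_error")
  mets <- lapply(obj$metabolites, function(m)
    metabolite(m$id, m$name %||% m$id, m$compartment %||% "c", m$formula))
  rxns <- lapply(seq_along(obj$reactions), function(i) {
    r <- obj$reactions[[i]]
    if (is.null(r$id) || is.null(r$stoichiometry))
      stop_chemoflux(sprintf("native model at $.reactions[%d]: id/stoichiometry missing", i),
                     "chemoflux_parse_error")
    st <- unlist(r$stoichiometry)
    lb <- r$lb %||% 0
    ub <- r$ub %||% 1000
    if (lb > ub)
      stop_chemoflux(sprintf("native model at $.reactions[%d] ('%s'): lb > ub", i, r$id),
                     "chemoflux_parse_error")
    reaction(r$id, st, lb, ub, r$subsystem,
             is_exchange = r$is_exchange %||% (length(st) == 1L))
  })
  metabolic_model(mets, rxns, obj$objective_id, obj$ngam_id,
                  model_id = obj$id %||% "model")
}

sbml_ns <- function(doc) {
  ns <- xml2::xml_ns(doc)
  # map whatever prefixes the document uses onto stable ones
  uris <- unlist(ns)
  sb <- names(uris)[grepl("^http://www.sbml.org/sbml/level3", uris) &
                      !grepl("/fbc/", uris)][1]
  fbc <- names(uris)[grepl("/fbc/version", uris)][1]
  c(sb = sb, fbc = fbc)
}

#' Read an SBML Level 3 (core + fbc) model
#'
#' Minimal reader for the FBA-relevant subset of SBML: species, reactions with
#' stoichiometries, flux bounds given as fbc bound parameters, and the active
#' fbc objective. Kinetic laws and annotations are ignored. Reactions flagged
#' `boundaryCondition`-free whose stoichiometry touches one species, or whose
#' id starts with `exchange_prefix`, are marked as exchanges. Bounds default to
#' [-1000, 1000] for `reversible="true"` reactions and [0, 1000] otherwise.
#'
#' @param path SBML file
#' @param exchange_prefix reaction-id prefix marking exchanges (default "EX_",
#'   "R_EX_")
#' @return a [metabolic_model()]
#' @export
read_sbml <- function(path, exchange_prefix = c("EX_", "R_EX_")) {
  if (!file.exists(path))
    stop_chemoflux(sprintf("file not found: %s", path), "chemoflux_io_error")
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop_chemoflux(
                    sprintf("SBML parse error in %s: %s", path, conditionMessage(e)),
                    "chemoflux_parse_error"))
  ns <- xml2::xml_ns(doc)
  model_node <- xml2::xml_find_first(doc, "//*[local-name()='model']")
  if (inherits(model_node, "xml_missing"))
    stop_chemoflux("SBML parse error: no <model> element", "chemoflux_parse_error")

  if (length(xml2::xml_find_all(doc, "//*[local-name()='kineticLaw']")))
    warning("SBML kinetic laws present; ignored (only fbc bounds/objective are read)",
            call. = FALSE)

  # global parameters (fbc flux bounds live here)
  params <- xml2::xml_find_all(doc, "//*[local-name()='listOfParameters']/*[local-name()='parameter']")
  pvals <- stats::setNames(
    as.numeric(xml2::xml_attr(params, "value")),
    xml2::xml_attr(params, "id"))

  sp_nodes <- xml2::xml_find_all(doc, "//*[local-name()='listOfSpecies']/*[local-name()='species']")
  mets <- lapply(sp_nodes, function(s) metabolite(
    id = xml2::xml_attr(s, "id"),
    name = xml2::xml_attr(s, "name") %||% xml2::xml_attr(s, "id"),
    compartment = xml2::xml_attr(s, "compartment") %||% "c"))
  boundary <- xml2::xml_attr(sp_nodes, "boundaryCondition")
  boundary_ids <- xml2::xml_attr(sp_nodes, "id")[!is.na(boundary) & boundary == "true"]
  mets <- mets[!vapply(mets, function(m) m$id %in% boundary_ids, TRUE)]
  met_ids <- vapply(mets, `[[`, "", "id")

  rx_nodes <- xml2::xml_find_all(doc, "//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  if (!length(rx_nodes))
    stop_chemoflux("SBML parse error: model has no reactions", "chemoflux_parse_error")

  get_stoich <- function(rx, list_name, sign) {
    refs <- xml2::xml_find_all(
      rx, sprintf("./*[local-name()='%s']/*[local-name()='speciesReference']", list_name))
    if (!length(refs)) return(numeric())
    st <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
    st[is.na(st)] <- 1
    stats::setNames(sign * st, xml2::xml_attr(refs, "species"))
  }

  rxns <- lapply(rx_nodes, function(rx) {
    rid <- xml2::xml_attr(rx, "id")
    st <- c(get_stoich(rx, "listOfReactants", -1), get_stoich(rx, "listOfProducts", +1))
    # collapse duplicate species references, drop boundary species
    st <- tapply(st, names(st), sum)
    st <- stats::setNames(as.numeric(st), names(st))
    st <- st[names(st) %in% met_ids]
    if (!length(st))
      stop_chemoflux(sprintf("SBML reaction '%s' has no usable stoichiometry", rid),
                     "chemoflux_parse_error")
    rev <- identical(xml2::xml_attr(rx, "reversible"), "true")
    lb_ref <- xml2::xml_attr(rx, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(rx, "upperFluxBound")
    lb <- if (!is.na(lb_ref) && lb_ref %in% names(pvals)) pvals[[lb_ref]] else if (rev) -1000 else 0
    ub <- if (!is.na(ub_ref) && ub_ref %in% names(pvals)) pvals[[ub_ref]] else 1000
    reaction(rid, st, lb, ub,
             is_exchange = length(st) == 1L || any(startsWith(rid, exchange_prefix)))
  })

  obj_refs <- xml2::xml_find_all(
    doc, "//*[local-name()='listOfObjectives']//*[local-name()='fluxObjective']")
  if (!length(obj_refs))
    stop_chemoflux("SBML model has no fbc objective", "chemoflux_parse_error")
  objective_id <- xml2::xml_attr(obj_refs[[1]], "reaction")

  model <- metabolic_model(mets, rxns, objective_id,
                           model_id = xml2::xml_attr(model_node, "id") %||% "sbml_model")
  message(sprintf("read SBML model '%s': %d metabolites, %d reactions",
                  model$id, length(model$metabolites), length(model$reactions)))
  model
}

#' Export a model as COBRA-style JSON
#'
#' Writes the model in the JSON schema used by common constraint-based
#' analysis toolchains (metabolites/reactions/genes arrays with bounds and an
#' objective coefficient), enabling interoperability checks against other FBA
#' implementations.
#'
#' @param model a [metabolic_model()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_cobra_json <- function(model, path) {
  rx <- lapply(unname(model$reactions), function(r) list(
    id = r$id, name = r$id, metabolites = as.list(r$stoich),
    lower_bound = r$lb, upper_bound = r$ub, gene_reaction_rule = "",
    objective_coefficient = if (r$id == model$objective_id) 1 else 0))
  mets <- lapply(unname(model$metabolites), function(m) list(
    id = m$id, name = m$name, compartment = m$compartment))
  obj <- list(id = model$id, metabolites = mets, reactions = rx, genes = list(),
              compartments = list(c = "cytosol"), version = "1")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
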