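#' Pathway-grouped flux normalization schemes
#'
#' A normalization scheme names a group of reactions (a pathway block on a
#' flux map) and a rule producing the reference scalar by which their flux
#' magnitudes are divided:
#' * `"reaction"` — the absolute flux of one reference reaction (e.g. glucose
#'   uptake for the Entner-Doudoroff block, or the G3P-forming reaction for
#'   the glycogen/trehalose block);
#' * `"max_member"` — the maximal absolute flux among the member reactions
#'   (the TCA-cycle convention, so the largest member reads exactly 1);
#' * `"sum"` — the summed absolute flux of a set of reference reactions (the
#'   total glutamate incorporated into the TCA cycle via deamination plus
#'   transamination).
#'
#' Reaction membership is configuration, not code: model reaction ids differ
#' between reconstructions, so schemes are built per model (shipped defaults
#' target the toy networks).
#'
#' @param name scheme name (e.g. `"ed_glucose"`, `"tca_max"`,
#'   `"glutamate_incorporation"`, `"g3p_formation"`)
#' @param members character vector of member reaction ids (non-empty)
#' @param reference_type one of `"reaction"`, `"max_member"`, `"sum"`
#' @param reference_ids reaction id(s) defining the reference (ignored for
#'   `"max_member"`)
#' @return a `normalization_scheme`
#' @export
normalization_scheme <- function(name, members,
                                 reference_type = c("reaction", "max_member", "sum"),
                                 reference_ids = NULL) {
  reference_type <- match.arg(reference_type)
  if (!length(members))
    stop_chemoflux("scheme member list must be non-empty", "chemoflux_scheme_error")
  if (reference_type != "max_member" && !length(reference_ids))
    stop_chemoflux("reference_ids required for this reference type", "chemoflux_scheme_error")
  structure(list(name = name, members = members, reference_type = reference_type,
                 reference_ids = reference_ids), class = "normalization_scheme")
}

scheme_reference <- function(fluxes, scheme) {
  switch(scheme$reference_type,
         reaction = abs(fluxes[[scheme$reference_ids[1]]]),
         max_member = max(abs(fluxes[scheme$members])),
         sum = sum(abs(fluxes[scheme$reference_ids])))
}

#' Normalize fluxes under a scheme
#'
#' Divides the flux magnitudes of the member reactions by the scheme's
#' reference scalar. Signs are reported separately in a `direction` column
#' (+1 forward, -1 reverse, 0 inactive) because flux-map captions report
#' direction independently of the normalized magnitude.
#'
#' @param solution a `flux_solution` (or an `ensemble_result`, whose mean
#'   fluxes are used)
#' @param scheme a [normalization_scheme()]
#' @return tibble with `reaction`, `raw_flux`, `normalized` (magnitude),
#'   `direction`, `scheme`, `reference`
#' @export
normalize_fluxes <- function(solution, scheme) {
  fluxes <- if (inherits(solution, "ensemble_result")) solution$mean_fluxes
            else solution$fluxes
  missing <- setdiff(c(scheme$members,
                       if (scheme$reference_type != "max_member") scheme$reference_ids),
                     names(fluxes))
  if (length(missing))
    stop_chemoflux(paste0("scheme '", scheme$name, "' references reactions absent from the solution: ",
                          paste(missing, collapse = ", ")), "chemoflux_scheme_error")
  ref <- scheme_reference(fluxes, scheme)
  if (!is.finite(ref) || ref <= 0)
    stop_chemoflux(sprintf("normalization reference for scheme '%s' is zero: normalized fluxes undefined",
                           scheme$name), "chemoflux_scheme_error")
  raw <- fluxes[scheme$members]
  tibble::tibble(
    reaction = scheme$members,
    raw_flux = unname(raw),
    normalized = unname(abs(raw) / ref),
    direction = sign(unname(raw)),
    scheme = scheme$name,
    reference = ref
  )
}

#' Flag reactions running in different directions across conditions
#'
#' Given one flux solution per condition, reports the member reactions whose
#' flux sign differs between conditions; for these a single normalized value
#' cannot be put on a shared map arrow.
#'
#' @param solutions named list of `flux_solution`s (names = conditions)
#' @param reactions reaction ids to check (default: all shared reactions)
#' @param tol fluxes with `|v| <= tol` count as inactive, not directional
#' @return tibble with `reaction`, `directions` (comma-joined per condition),
#'   `conflict`
#' @export
flag_direction_conflicts <- function(solutions, reactions = NULL, tol = 1e-9) {
  stopifnot(length(solutions) >= 2L)
  flux_list <- lapply(solutions, function(s)
    if (inherits(s, "ensemble_result")) s$mean_fluxes else s$fluxes)
  shared <- Reduce(intersect, lapply(flux_list, names))
  reactions <- reactions %||% shared
  signs <- vapply(flux_list, function(f) {
    v <- f[reactions]
    ifelse(abs(v) <= tol, 0, sign(v))
  }, numeric(length(reactions)))
  signs <- matrix(signs, nrow = length(reactions),
                  dimnames = list(reactions, names(solutions)))
  conflict <- apply(signs, 1, function(s) {
    s <- s[s != 0]
    length(unique(s)) > 1L
  })
  tibble::tibble(
    reaction = reactions,
    directions = apply(signs, 1, paste, collapse = ","),
    conflict = unname(conflict)
  )
}

#' Export a flux-map overlay
#'
#' Writes the reaction-id to flux mapping as the flat JSON object that pathway
#' map viewers (e.g. Escher) accept as reaction data. When a layout file is
#' given, reaction ids in the solution that do not occur in the layout are
#' reported as a warning (and returned), not an error — the overlay is still
#' written in full.
#'
#' @param solution a `flux_solution` or `ensemble_result`
#' @param out_path output JSON path
#' @param layout_path optional pathway-map layout JSON (an Escher map or any
#'   JSON whose recursively-harvested `bigg_id`/`reaction` fields or top-level
#'   `reactions` array name the mapped reactions)
#' @return invisibly, character vector of unmapped reaction ids
#' @export
export_flux_map <- function(solution, out_path, layout_path = NULL) {
  fluxes <- if (inherits(solution, "ensemble_result")) solution$mean_fluxes
            else solution$fluxes
  fluxes <- fluxes %||% stats::setNames(numeric(), character())
  unmapped <- character()
  if (!is.null(layout_path)) {
    layout <- jsonlite::read_json(layout_path)
    harvest <- function(x) {
      if (is.list(x)) {
        ids <- character()
        if (!is.null(x$bigg_id) && is.character(x$bigg_id)) ids <- x$bigg_id
        if (!is.null(x$reaction) && is.character(x$reaction)) ids <- c(ids, x$reaction)
        c(ids, unlist(lapply(x, harvest), use.names = FALSE))
      } else if (is.character(x)) x else character()
    }
    layout_ids <- unique(harvest(layout))
    unmapped <- setdiff(names(fluxes), layout_ids)
    if (length(unmapped))
      warning(paste("reactions absent from layout:", paste(unmapped, collapse = ", ")),
              call. = FALSE)
  }
  json <- jsonlite::toJSON(as.list(fluxes), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(json, out_path)
  invisible(unmapped)
}

#' Built-in normalization schemes for the toy networks
#'
#' Scheme set for [make_toy_model()] topologies, mirroring the four map-block
#' conventions: glucose-uptake normalization of the Entner-Doudoroff block,
#' max-member normalization of the TCA block, glutamate-incorporation
#' normalization (deamination + transamination) and G3P-formation
#' normalization of the storage block.
#'
#' @param topology `"dual_substrate"` or `"branched_tca"`
#' @return named list of [normalization_scheme()]s
#' @export
toy_schemes <- function(topology = c("dual_substrate", "branched_tca")) {
  topology <- match.arg(topology)
  if (topology == "dual_substrate") {
    list(
      glutamate_incorporation = normalization_scheme(
        "glutamate_incorporation", members = c("GDH", "AAT", "OVF"),
        reference_type = "sum", reference_ids = c("GDH", "AAT")),
      ed_glucose = normalization_scheme(
        "ed_glucose", members = c("BIOMASS"),
        reference_type = "reaction", reference_ids = "EX_glc")
    )
  } else {
    list(
      ed_glucose = normalization_scheme(
        "ed_glucose", members = c("ED_NP", "ED_SP1", "ED_SP2"),
        reference_type = "reaction", reference_ids = "EX_s"),
      tca_max = normalization_scheme(
        "tca_max", members = c("TCA", "BIOMASS", "NGAM"),
        reference_type = "max_member"),
      g3p_formation = normalization_scheme(
        "g3p_formation", members = c("ED_SP1", "ED_SP2"),
        reference_type = "reaction", reference_ids = "ED_SP1")
    )
  }
}
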