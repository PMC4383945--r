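#' Construct a flux map
#'
#' A flux map is the universal input object of the package: a named set of
#' central-carbon reactions, each with a signed stoichiometry, an optional EC
#' class, a compartment label, and a net flux value. Flux values are expressed
#' relative to substrate uptake (see [normalize_fluxes()]); a missing flux is
#' `NA`, never 0 -- the two mean different things downstream (a zero flux is a
#' measured absence of net conversion, `NA` is an unmeasured reaction).
#'
#' Reaction identity is the id string compared case-insensitively. Three kinds
#' of reaction are recognised from the id: KEGG-style reaction numbers
#' (`R00658`), `transport...` pseudo-reactions (membrane transport), and
#' `unknown...` pseudo-reactions (lumped substrate feeds). Pseudo-reactions may
#' be one-sided (only consume or only produce); ordinary reactions must consume
#' at least one metabolite and produce at least one.
#'
#' @param id character vector of reaction ids, unique after case-folding.
#' @param stoich list of named numeric vectors, one per reaction: names are
#'   metabolite ids, values the signed stoichiometric coefficients (negative =
#'   consumed, positive = produced). Zero coefficients are dropped.
#' @param flux numeric vector of net flux values (`NA` = absent), one per
#'   reaction, signed relative to the written equation direction.
#' @param ec list of EC classes (anything [ec_class()] accepts, or `NULL`),
#'   one per reaction.
#' @param compartment character vector of compartment labels (may be `NA`).
#' @param reversible logical vector: was the equation written with `<=>`?
#'   Affects only serialization, not any score.
#' @param substrate_ids ids of the substrate-uptake reactions (used by
#'   [normalize_fluxes()]).
#' @param name case label.
#' @param metadata named list of study metadata (strain, culture medium,
#'   carbon source, growth rate, specific rates, description).
#' @return An object of class `flux_map`.
#' @seealso [parse_flux_table()], [build_stoich_matrix()], [normalize_fluxes()]
#' @examples
#' m <- flux_map(
#'   id = c("unknown_feed", "R00658"),
#'   stoich = list(c(pg2 = 1), c(pg2 = -1, pep = 1, h2o = 1)),
#'   flux = c(100, 85),
#'   ec = list(NULL, c(4, 2, 1, 11)),
#'   substrate_ids = "unknown_feed"
#' )
#' print(m)
#' @export
flux_map <- function(id, stoich, flux, ec = NULL, compartment = NULL,
                     reversible = NULL, substrate_ids = character(),
                     name = "flux_map", metadata = list()) {
  n <- length(id)
  id <- as.character(id)
  if (n == 0L) stop_fluxalign("no reactions")
  if (!is.list(stoich) || length(stoich) != n)
    stop_fluxalign("`stoich` must be a list of length ", n)
  flux <- as.numeric(flux)
  if (length(flux) != n)
    stop_fluxalign("`flux` must have one value per reaction (", n, ")")
  if (is.null(ec)) ec <- vector("list", n)
  if (length(ec) != n) stop_fluxalign("`ec` must have one entry per reaction")
  ec <- lapply(ec, function(e) if (is.null(e)) NULL else unclass(ec_class(e)))
  compartment <- if (is.null(compartment)) rep(NA_character_, n)
                 else as.character(rep_len(compartment, n))
  reversible <- if (is.null(reversible)) rep(FALSE, n)
                else as.logical(rep_len(reversible, n))

  map <- structure(
    list(id = id, stoich = stoich, flux = flux, ec = ec,
         compartment = compartment, reversible = reversible,
         substrate_ids = as.character(substrate_ids),
         name = as.character(name)[1], metadata = metadata),
    class = "flux_map")
  validate_flux_map(map)
}

#' Validate a flux map
#'
#' Checks the structural invariants of a [flux_map()]: unique non-empty
#' reaction ids, non-zero stoichiometric coefficients, two-sided stoichiometry
#' for ordinary (non-pseudo) reactions, finite-or-`NA` fluxes, and substrate
#' ids that exist in the map.
#'
#' @param map a `flux_map`.
#' @return `map`, invisibly unchanged, or an error describing the violation.
#' @export
validate_flux_map <- function(map) {
  stopifnot(inherits(map, "flux_map"))
  id <- map$id
  if (any(!nzchar(trimws(id))))
    stop_fluxalign("reaction ids must be nonempty")
  dup <- duplicated(id_key(id))
  if (any(dup))
    stop_fluxalign("duplicate reaction id: ", paste(unique(id[dup]), collapse = ", "))
  type <- reaction_type(id)
  for (i in seq_along(id)) {
    s <- map$stoich[[i]]
    if (length(s)) {
      if (is.null(names(s)) || any(!nzchar(names(s))))
        stop_fluxalign("reaction ", id[i], ": stoichiometry must be a named vector")
      if (any(!is.finite(s)) || any(s == 0))
        stop_fluxalign("reaction ", id[i], ": coefficients must be finite and nonzero")
      if (anyDuplicated(names(s)))
        stop_fluxalign("reaction ", id[i], ": duplicate metabolite in stoichiometry")
    }
    if (type[i] == "reaction" && (!any(s < 0) || !any(s > 0)))
      stop_fluxalign("reaction ", id[i],
                     ": must consume and produce at least one metabolite")
    if (type[i] != "reaction" && length(s) == 0L)
      stop_fluxalign("reaction ", id[i], ": empty stoichiometry")
  }
  if (any(is.infinite(map$flux) | is.nan(map$flux)))
    stop_fluxalign("flux values must be finite or NA")
  missing_sub <- setdiff(id_key(map$substrate_ids), id_key(id))
  if (length(missing_sub))
    stop_fluxalign("substrate id not in map: ", paste(missing_sub, collapse = ", "))
  invisible(map)
}

#' Reaction type from the reaction id
#'
#' Ids starting with `transport` or `unknown` (case-insensitive) denote
#' pseudo-reactions; everything else is an ordinary (enzymatic) reaction.
#'
#' @param id character vector of reaction ids.
#' @return character vector: `"reaction"`, `"transport"` or `"unknown"`.
#' @export
reaction_type <- function(id) {
  key <- id_key(id)
  ifelse(startsWith(key, "transport"), "transport",
         ifelse(startsWith(key, "unknown"), "unknown", "reaction"))
}

#' @export
print.flux_map <- function(x, ...) {
  cat("<flux_map> ", x$name, ": ", length(x$id), " reactions, ",
      length(metabolite_ids(x)), " metabolites\n", sep = "")
  na <- sum(is.na(x$flux))
  if (na) cat("  absent flux values:", na, "\n")
  if (length(x$substrate_ids))
    cat("  substrate uptake:", paste(x$substrate_ids, collapse = ", "), "\n")
  df <- as.data.frame(x)
  print(utils::head(df, 10), row.names = FALSE)
  if (nrow(df) > 10) cat("  ... and", nrow(df) - 10, "more reactions\n")
  invisible(x)
}

#' @export
summary.flux_map <- function(object, ...) {
  cat("Flux map:", object$name, "\n")
  cat("  reactions:  ", length(object$id),
      " (", sum(reaction_type(object$id) == "reaction"), " enzymatic)\n", sep = "")
  cat("  metabolites:", length(metabolite_ids(object)), "\n")
  fl <- object$flux[!is.na(object$flux)]
  if (length(fl))
    cat("  flux range: [", format(min(fl)), ", ", format(max(fl)), "]\n", sep = "")
  if (length(object$metadata))
    for (k in names(object$metadata))
      cat("  ", k, ": ", format(object$metadata[[k]]), "\n", sep = "")
  invisible(object)
}

#' @export
as.data.frame.flux_map <- function(x, ...) {
  data.frame(
    id = x$id,
    ec = vapply(x$ec, function(e) if (is.null(e)) "" else format_ec(e), ""),
    equation = vapply(seq_along(x$id), function(i)
      deparse_equation(x$stoich[[i]], x$reversible[i]), ""),
    flux = x$flux,
    compartment = x$compartment,
    stringsAsFactors = FALSE)
}

#' Metabolite index of a flux map
#'
#' @param map a `flux_map`.
#' @return sorted character vector of all metabolite ids appearing in the
#'   map's stoichiometries.
#' @export
metabolite_ids <- function(map) {
  stopifnot(inherits(map, "flux_map"))
  sort(unique(unlist(lapply(map$stoich, names), use.names = FALSE)))
}

#' Number of reactions in a flux map
#' @param map a `flux_map`.
#' @return integer count.
#' @export
n_reactions <- function(map) length(map$id)

#' Replace flux values or EC classes of a flux map
#'
#' Convenience mutators used when deriving fixtures: `with_fluxes()` swaps the
#' whole flux vector, `with_ec()` the EC class list; both revalidate.
#'
#' @param map a `flux_map`.
#' @param flux numeric vector of new flux values (`NA` allowed).
#' @param ec list of EC classes (or `NULL` entries), one per reaction.
#' @return the modified `flux_map`.
#' @export
with_fluxes <- function(map, flux) {
  stopifnot(inherits(map, "flux_map"))
  map$flux <- as.numeric(rep_len(flux, length(map$id)))
  validate_flux_map(map)
  map
}

#' @rdname with_fluxes
#' @export
with_ec <- function(map, ec) {
  stopifnot(inherits(map, "flux_map"), length(ec) == length(map$id))
  map$ec <- lapply(ec, function(e) if (is.null(e)) NULL else unclass(ec_class(e)))
  validate_flux_map(map)
  map
}

# index of a reaction id (case-folded); NA when absent
match_id <- function(map, ids) match(id_key(ids), id_key(map$id))
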