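#' Stoichiometric matrix of a flux map
#'
#' The l x n signed coefficient matrix S over the map's metabolite index
#' (rows, sorted by metabolite id) and reactions (columns, in map order):
#' `S[k, i]` is the coefficient of metabolite k in reaction i, 0 where the
#' metabolite does not take part. `S %*% v = 0` over internal metabolites
#' expresses steady-state mass balance.
#'
#' @param map a `flux_map`.
#' @param metabolites optional row frame: a character vector of metabolite
#'   ids (extra rows are zero-filled). Defaults to [metabolite_ids()] of the
#'   map.
#' @return numeric matrix with metabolite/reaction dimnames.
#' @export
build_stoich_matrix <- function(map, metabolites = NULL) {
  stopifnot(inherits(map, "flux_map"))
  mets <- metabolites %||% metabolite_ids(map)
  S <- matrix(0, nrow = length(mets), ncol = length(map$id),
              dimnames = list(mets, map$id))
  for (i in seq_along(map$id)) {
    s <- map$stoich[[i]]
    keep <- names(s) %in% mets
    S[names(s)[keep], i] <- s[keep]
  }
  S
}

#' Normalize fluxes to substrate uptake = 100
#'
#' Rescales every flux by one common factor so that the sum of the
#' substrate-uptake fluxes equals 100 -- the database convention that makes
#' flux values comparable across studies with different absolute uptake rates
#' (mmol per gram per hour). With multiple substrates, the *sum* of all uptake
#' rates is set to 100. Absent (`NA`) values stay absent. Idempotent.
#'
#' @param map a `flux_map` with at least one substrate-uptake reaction whose
#'   flux is present and the uptake total nonzero.
#' @return the rescaled `flux_map`.
#' @export
normalize_fluxes <- function(map) {
  stopifnot(inherits(map, "flux_map"))
  idx <- match_id(map, map$substrate_ids)
  if (length(idx) == 0L)
    stop_fluxalign("cannot normalize: no substrate uptake reactions designated")
  up <- map$flux[idx]
  if (all(is.na(up)))
    stop_fluxalign("cannot normalize: all substrate uptake fluxes absent")
  total <- sum(up, na.rm = TRUE)
  if (abs(total) < .Machine$double.eps * 100)
    stop_fluxalign("cannot normalize: total substrate uptake is zero")
  map$flux <- map$flux * (100 / total)
  map
}

#' Shared reaction set of two flux maps
#'
#' Reaction ids present in both maps (compared case-insensitively) with a
#' non-absent flux in both, in canonical (lexicographic) order. This is the
#' common frame on which the vector and stoichiometry similarities are
#' computed.
#'
#' @param a,b `flux_map` objects.
#' @return character vector of shared ids (as written in `a`), sorted.
#' @export
shared_reaction_set <- function(a, b) {
  stopifnot(inherits(a, "flux_map"), inherits(b, "flux_map"))
  ka <- id_key(a$id); kb <- id_key(b$id)
  common <- intersect(ka[!is.na(a$flux)], kb[!is.na(b$flux)])
  ids <- a$id[match(common, ka)]
  ids[order(id_key(ids), method = "radix")]
}
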