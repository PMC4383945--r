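#' Cofactor map for energetics
#'
#' Describes how reactions of a flux map contribute to NADPH and ATP
#' production: a rule table mapping reaction ids to a cofactor species and a
#' stoichiometric yield per unit flux, a wobble set of reactions whose
#' dehydrogenase may use either NAD or NADP, and the P/O ratios converting
#' reduced cofactor flux to ATP (2.5 ATP per NADH, 1.5 per FADH2).
#'
#' @param rules data frame with columns `id` (reaction id), `species` (one
#'   of `"NADPH"`, `"NADH"`, `"FADH2"`, `"ATP"`, `"wobble"`) and `yield`
#'   (cofactor produced per unit flux; negative = consumed, e.g. kinase ATP
#'   investment).
#' @param po_nadh,po_fadh2 P/O ratios (ATP per NADH / per FADH2); must be
#'   positive.
#' @return A `cofactor_map`.
#' @seealso [default_cofactor_map()], [production_range()]
#' @export
cofactor_map <- function(rules, po_nadh = 2.5, po_fadh2 = 1.5) {
  stopifnot(is.data.frame(rules),
            all(c("id", "species", "yield") %in% names(rules)))
  ok <- rules$species %in% c("NADPH", "NADH", "FADH2", "ATP", "wobble")
  if (!all(ok))
    stop_fluxalign("unknown cofactor species: ",
                   paste(unique(rules$species[!ok]), collapse = ", "))
  if (po_nadh <= 0 || po_fadh2 <= 0)
    stop_fluxalign("P/O ratios must be strictly positive")
  if (anyDuplicated(paste(id_key(rules$id), rules$species)))
    stop_fluxalign("duplicate (id, species) rule")
  structure(list(rules = rules, po_nadh = po_nadh, po_fadh2 = po_fadh2),
            class = "cofactor_map")
}

#' Default central-carbon cofactor map
#'
#' The standard-biochemistry assignment for the central carbon network,
#' fully overridable: the oxidative pentose phosphate dehydrogenases
#' (glucose-6-phosphate dehydrogenase R00835, 6-phosphogluconate
#' dehydrogenase R01528) produce NADPH; glyceraldehyde-3-phosphate
#' dehydrogenase R01061, pyruvate dehydrogenase R00209, alpha-ketoglutarate
#' dehydrogenase R08549 and malate dehydrogenase R00342 produce NADH;
#' succinate dehydrogenase R02164 produces FADH2; phosphoglycerate kinase
#' R01512, pyruvate kinase R00200 and succinyl-CoA synthetase R00405 yield
#' substrate-level ATP; hexokinase R00299 and phosphofructokinase R00756
#' invest ATP (negative yield, see `gross` in [production_range()]).
#' Isocitrate dehydrogenase R00267 and malic enzyme R00216 are the wobble
#' enzymes whose cofactor specificity may swing between NAD and NADP.
#'
#' @return A `cofactor_map`.
#' @export
default_cofactor_map <- function() {
  rules <- data.frame(
    id = c("R00835", "R01528",
           "R01061", "R00209", "R08549", "R00342",
           "R02164",
           "R01512", "R00200", "R00405",
           "R00299", "R00756",
           "R00267", "R00216"),
    species = c("NADPH", "NADPH",
                "NADH", "NADH", "NADH", "NADH",
                "FADH2",
                "ATP", "ATP", "ATP",
                "ATP", "ATP",
                "wobble", "wobble"),
    yield = c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1, -1, -1, 1, 1),
    stringsAsFactors = FALSE)
  cofactor_map(rules)
}

#' Read a cofactor map from a YAML or JSON config
#'
#' The config holds `rules` (list of `{id, species, yield}` records) and
#' optional `po_nadh` / `po_fadh2` overrides.
#'
#' @param path YAML (`.yaml`/`.yml`) or JSON file.
#' @return A `cofactor_map`.
#' @export
read_cofactor_map <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = FALSE)
  rules <- do.call(rbind, lapply(obj$rules, function(r)
    data.frame(id = r$id, species = r$species, yield = as.numeric(r$yield),
               stringsAsFactors = FALSE)))
  cofactor_map(rules, po_nadh = obj$po_nadh %||% 2.5,
               po_fadh2 = obj$po_fadh2 %||% 1.5)
}

#' @export
print.cofactor_map <- function(x, ...) {
  cat("<cofactor_map> ", nrow(x$rules), " rules (",
      sum(x$rules$species == "wobble"), " wobble), P/O NADH = ", x$po_nadh,
      ", FADH2 = ", x$po_fadh2, "\n", sep = "")
  invisible(x)
}

#' Flag quantities invalidated by absent fluxes
#'
#' A production rate that depends on a reaction whose flux is absent cannot
#' be computed and is reported N/A rather than silently dropped. ATP depends
#' on the substrate-level ATP, NADH, FADH2 and wobble rules present in the
#' map; NADPH on the NADPH and wobble rules. A wobble reaction with absent
#' flux therefore voids both.
#'
#' @param map a `flux_map`.
#' @param cofactors a `cofactor_map`.
#' @return list with logical `atp_na`, `nadph_na` and the offending
#'   `missing_ids`.
#' @export
na_propagation <- function(map, cofactors = default_cofactor_map()) {
  stopifnot(inherits(map, "flux_map"), inherits(cofactors, "cofactor_map"))
  rules <- cofactors$rules
  idx <- match_id(map, rules$id)
  present <- !is.na(idx)
  absent_flux <- present & is.na(map$flux[idx])
  dep_atp <- rules$species %in% c("ATP", "NADH", "FADH2", "wobble")
  dep_nadph <- rules$species %in% c("NADPH", "wobble")
  list(atp_na = any(absent_flux & dep_atp),
       nadph_na = any(absent_flux & dep_nadph),
       missing_ids = unique(rules$id[absent_flux]))
}

#' NADPH and ATP production ranges of a flux distribution
#'
#' Recalculates the NADPH and ATP production rates implied by a flux map,
#' in the same relative units as the fluxes. ATP production is the
#' substrate-level ATP yield plus the P/O-converted reduced cofactors
#' (2.5 ATP per NADH, 1.5 per FADH2); NADPH production sums the NADPH
#' producers. Because the wobble enzymes (isocitrate dehydrogenase, malic
#' enzyme) may operate with either NAD or NADP, a single production rate is
#' rarely defined: the minimum and maximum are obtained by assuming the
#' wobble enzymes operate exclusively with NADH (one extreme) or exclusively
#' with NADPH (the other). Any contributing reaction with an absent flux
#' makes the affected quantities N/A (see [na_propagation()]).
#'
#' @param map a `flux_map`.
#' @param cofactors a `cofactor_map` (default [default_cofactor_map()]).
#' @param gross report gross ATP production, ignoring negative-yield
#'   (ATP-investing kinase) rules; default `FALSE` nets them out.
#' @return An `energy_report`: `atp_min`, `atp_max`, `nadph_min`,
#'   `nadph_max` (`NA` = N/A), plus the per-reaction contribution table.
#' @export
production_range <- function(map, cofactors = default_cofactor_map(),
                             gross = FALSE) {
  stopifnot(inherits(map, "flux_map"), inherits(cofactors, "cofactor_map"))
  rules <- cofactors$rules
  idx <- match_id(map, rules$id)
  keep <- !is.na(idx)
  rules <- rules[keep, , drop = FALSE]
  idx <- idx[keep]
  flux <- map$flux[idx]
  if (gross) {
    drop <- rules$species == "ATP" & rules$yield < 0
    rules <- rules[!drop, , drop = FALSE]
    flux <- flux[!drop]
    idx <- idx[!drop]
  }
  contrib <- rules$yield * flux   # cofactor produced per unit time
  pool0 <- function(sp) {          # NA-tolerant (flagging handled separately)
    x <- contrib[rules$species == sp]
    sum(x[!is.na(x)])
  }
  nas <- na_propagation(map, cofactors)

  atp_base <- pool0("ATP") + cofactors$po_nadh * pool0("NADH") +
    cofactors$po_fadh2 * pool0("FADH2")
  wob <- pool0("wobble")
  # two extremes: all wobble flux to NADH vs all to NADPH
  atp_scen <- c(nadh = atp_base + cofactors$po_nadh * wob,
                nadph = atp_base)
  nadph_base <- pool0("NADPH")
  nadph_scen <- c(nadh = nadph_base, nadph = nadph_base + wob)

  res <- list(
    atp_min = if (nas$atp_na) NA_real_ else min(atp_scen),
    atp_max = if (nas$atp_na) NA_real_ else max(atp_scen),
    nadph_min = if (nas$nadph_na) NA_real_ else min(nadph_scen),
    nadph_max = if (nas$nadph_na) NA_real_ else max(nadph_scen),
    na_flags = nas,
    contributions = data.frame(id = map$id[idx], species = rules$species,
                               yield = rules$yield, flux = flux,
                               cofactor_rate = contrib,
                               stringsAsFactors = FALSE),
    po_nadh = cofactors$po_nadh, po_fadh2 = cofactors$po_fadh2,
    gross = gross, map = map$name)
  structure(res, class = "energy_report")
}

#' @export
print.energy_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "N/A" else format(v, digits = 6)
  cat("<energy_report> ", x$map, if (x$gross) " (gross ATP)" else "", "\n",
      "  ATP production:   [", fmt(x$atp_min), ", ", fmt(x$atp_max), "]\n",
      "  NADPH production: [", fmt(x$nadph_min), ", ", fmt(x$nadph_max),
      "]\n", sep = "")
  if (length(x$na_flags$missing_ids))
    cat("  N/A caused by absent flux:",
        paste(x$na_flags$missing_ids, collapse = ", "), "\n")
  invisible(x)
}
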