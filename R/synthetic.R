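#' Toy central-carbon networks for simulation and testing
#'
#' Curated reaction skeletons with KEGG-style ids and EC classes whose
#' stoichiometric matrix over internal metabolites has a nontrivial null
#' space, so steady-state flux distributions exist and can be sampled
#' ([sample_steady_state_fluxes()]).
#'
#' * `"core"`: a 22-reaction reduction of central carbon metabolism --
#'   glycolysis (hexokinase step lumped into the unknown substrate feed, as
#'   curated databases do for carbon entry), the oxidative pentose phosphate
#'   branch, a full TCA cycle, one transport drain and one unknown feed.
#'   CO2 is treated as external. Two independent flux modes (glycolytic and
#'   pentose-phosphate) span its null space.
#' * `"chain5"`: a 5-reaction linear chain (feed, three enzymatic steps with
#'   distinct EC classes, drain) with a single flux mode -- after
#'   normalization every flux is 100.
#'
#' @param name `"core"` or `"chain5"`.
#' @return A `toy_network`: list with `map` (a [flux_map()] template with
#'   absent fluxes), `internal` (metabolite ids balanced at steady state).
#' @export
toy_network <- function(name = c("core", "chain5")) {
  name <- match.arg(name)
  if (name == "chain5") {
    tab <- data.frame(
      id = c("unknown_feed", "R90001", "R90002", "R90003", "transport_D"),
      ec = c("", "1.1.1.1", "2.7.1.1", "4.2.1.11", ""),
      equation = c("=> A", "A => B", "B => C", "C => D", "D =>"),
      flux = NA_real_, compartment = "cytosol", stringsAsFactors = FALSE)
    internal <- c("A", "B", "C", "D")
  } else {
    tab <- data.frame(
      id = c("unknown_glc_feed",
             "R02740", "R00756", "R01068", "R01015", "R01061", "R01512",
             "R01518", "R00658", "R00200", "R00209",
             "R00351", "R01324", "R00267", "R08549", "R00405", "R02164",
             "R01082", "R00342",
             "R00835", "R01528", "transport_ru5p"),
      ec = c("",
             "5.3.1.9", "2.7.1.11", "4.1.2.13", "5.3.1.1", "1.2.1.12",
             "2.7.2.3", "5.4.2.11", "4.2.1.11", "2.7.1.40", "1.2.4.1",
             "2.3.3.1", "4.2.1.3", "1.1.1.42", "1.2.4.2", "6.2.1.5",
             "1.3.5.1", "4.2.1.2", "1.1.1.37",
             "1.1.1.49", "1.1.1.44", ""),
      equation = c("=> g6p",
                   "g6p <=> f6p", "f6p => fdp", "fdp <=> dhap + g3p",
                   "dhap <=> g3p", "g3p <=> bpg13", "bpg13 <=> pg3",
                   "pg3 <=> pg2", "pg2 <=> pep", "pep => pyr",
                   "pyr => accoa + co2",
                   "accoa + oaa => cit", "cit <=> icit",
                   "icit => akg + co2", "akg => succoa + co2",
                   "succoa <=> suc", "suc <=> fum", "fum <=> mal",
                   "mal <=> oaa",
                   "g6p => 6pg", "6pg => ru5p + co2", "ru5p =>"),
      flux = NA_real_, compartment = "cytosol", stringsAsFactors = FALSE)
    internal <- c("g6p", "f6p", "fdp", "dhap", "g3p", "bpg13", "pg3", "pg2",
                  "pep", "pyr", "accoa", "oaa", "cit", "icit", "akg",
                  "succoa", "suc", "fum", "mal", "6pg", "ru5p")
  }
  map <- parse_flux_table(tab, name = paste0("toy_", name))
  structure(list(map = map, internal = internal, name = name),
            class = "toy_network")
}

#' @export
print.toy_network <- function(x, ...) {
  cat("<toy_network> ", x$name, ": ", n_reactions(x$map), " reactions, ",
      length(x$internal), " internal metabolites\n", sep = "")
  invisible(x)
}

#' Sample a mass-balanced flux distribution on a toy network
#'
#' Draws a random flux vector from the null space of the network's
#' stoichiometric matrix over internal metabolites (so `S v = 0`: the map is
#' at steady state), orients it so total substrate uptake is positive,
#' rejects draws that push flux backwards through irreversible reactions,
#' and normalizes so the substrate uptake sums to 100. With a fixed seed the
#' sampled map is reproducible.
#'
#' @param net a [toy_network()].
#' @param seed RNG seed.
#' @param name case label for the sampled map.
#' @return A `flux_map` with complete, mass-balanced, normalized fluxes.
#' @export
sample_steady_state_fluxes <- function(net, seed = NULL, name = NULL) {
  stopifnot(inherits(net, "toy_network"))
  map <- net$map
  S <- build_stoich_matrix(map, metabolites = net$internal)
  sv <- svd(S, nu = 0, nv = ncol(S))
  rk <- sum(sv$d > max(dim(S)) * max(sv$d) * .Machine$double.eps)
  k <- ncol(S) - rk
  if (k < 1L)
    stop_fluxalign("degenerate network: stoichiometric null space is trivial")
  N <- sv$v[, seq(rk + 1L, ncol(S)), drop = FALSE]
  sub_idx <- match_id(map, map$substrate_ids)
  flux <- with_seed(seed, {
    out <- NULL
    for (try in seq_len(1000L)) {
      v <- as.numeric(N %*% stats::rnorm(k))
      up <- sum(v[sub_idx])
      if (abs(up) < 1e-8 * max(abs(v), 1e-12)) next
      if (up < 0) v <- -v
      # irreversible reactions must not run backwards
      if (any(v[!map$reversible] < -1e-9 * max(abs(v)))) next
      out <- v
      break
    }
    out
  })
  if (is.null(flux))
    stop_fluxalign("could not sample an admissible steady-state flux vector")
  map$flux <- flux
  map$name <- name %||% paste0(map$name, "_s", seed %||% "")
  normalize_fluxes(map)
}

#' Reverse every reaction of a flux map
#'
#' Produces the reversal fixture: each reaction's equation sides are swapped
#' (stoichiometry negated) and its flux sign flipped, so magnitudes are
#' preserved while every flow runs the opposite way. The reversed copy's
#' weighted adjacency matrix is the negation of the original's, which is why
#' a map evaluated against its reversal at the structure-preserving matching
#' scores -1 ([evaluate_alignment()]) and its flux vector is antipodal to
#' the original ([vector_similarity()] of -1). Applying `reverse_all()`
#' twice restores the original map.
#'
#' @param map a `flux_map`.
#' @return the reversed `flux_map`.
#' @export
reverse_all <- function(map) {
  stopifnot(inherits(map, "flux_map"))
  map$stoich <- lapply(map$stoich, function(s) -s)
  map$flux <- -map$flux
  map$name <- paste0(map$name, "_reversed")
  validate_flux_map(map)
  map
}

#' Perturb the fluxes of a map with multiplicative noise
#'
#' Multiplies every flux by an i.i.d. lognormal factor
#' `exp(N(0, noise_sd^2))` and renormalizes the substrate uptake to 100 --
#' graded-similarity inputs for the comparison methods: similarity to the
#' unperturbed map decreases in expectation as `noise_sd` grows, and
#' `noise_sd = 0` returns the (normalized) map unchanged. Absent fluxes stay
#' absent; flux signs are preserved.
#'
#' @param map a `flux_map` with designated substrate uptake.
#' @param noise_sd standard deviation of the log-factor (>= 0).
#' @param seed RNG seed.
#' @return the perturbed `flux_map`.
#' @export
perturb_fluxes <- function(map, noise_sd, seed = NULL) {
  stopifnot(inherits(map, "flux_map"), noise_sd >= 0)
  with_seed(seed, {
    fac <- exp(stats::rnorm(n_reactions(map), 0, noise_sd))
    map$flux <- map$flux * fac
    normalize_fluxes(map)
  })
}

#' Random small flux maps (alignment test instances)
#'
#' Generates an arbitrary (not mass-balanced) flux map of `n` reactions over
#' a small random metabolite pool, with random coefficients, random EC
#' classes drawn from a narrow hierarchy (so common upper classes of every
#' depth occur), and random fluxes -- the instance generator for the
#' solver-vs-oracle equivalence suites.
#'
#' @param n number of reactions.
#' @param seed RNG seed.
#' @param n_mets metabolite pool size (default `n + 2`).
#' @param p_negative probability a flux value is negative.
#' @return A `flux_map`.
#' @export
random_flux_map <- function(n, seed = NULL, n_mets = n + 2L,
                            p_negative = 0.2) {
  stopifnot(n >= 1L, n_mets >= 2L)
  with_seed(seed, {
    mets <- paste0("M", seq_len(n_mets))
    stoich <- vector("list", n)
    for (i in seq_len(n)) {
      ns <- sample(1:2, 1); np <- sample(1:2, 1)
      subs <- sample(mets, ns)
      prods <- sample(setdiff(mets, subs), np)
      s <- c(stats::setNames(-sample(1:2, ns, replace = TRUE), subs),
             stats::setNames(sample(1:2, np, replace = TRUE), prods))
      stoich[[i]] <- s
    }
    ec <- replicate(n, c(sample(1:3, 1), sample(1:2, 1), sample(1:2, 1),
                         sample(1:9, 1)), simplify = FALSE)
    flux <- stats::runif(n, 10, 100) *
      ifelse(stats::runif(n) < p_negative, -1, 1)
    flux_map(id = sprintf("R%05d", seq_len(n) + 70000L), stoich = stoich,
             flux = flux, ec = ec,
             name = paste0("random_", seed %||% "map"))
  })
}
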