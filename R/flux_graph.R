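#' Weighted directed reaction graph of a flux map
#'
#' Treats a flux distribution as a weighted directed graph G(N, E, W): nodes
#' are the reactions (carrying flux value and EC class) and a directed edge
#' (i, j) exists whenever some product of reaction i is a reactant of
#' reaction j, i.e. material can flow from i into j. The shared-compound
#' coefficient of the pair is
#' \deqn{m_{ij} = \sum_{k} (|s_{ki}| + |s_{kj}|) }
#' summed over compounds k produced by i and consumed by j (written-equation
#' direction), minus the same sum in the opposite direction, which makes m
#' antisymmetric (`m_ji = -m_ij`) and zero when the two reactions share no
#' compounds.
#'
#' The weighted adjacency matrix W combines flux and stoichiometry:
#' diagonal entries are the normalized fluxes `v_i / ||v||_2`, off-diagonal
#' entries the normalized shared-compound coefficients
#' `m_ij / ||m||_F` (Frobenius norm over all ordered pairs). The off-diagonal
#' part is antisymmetric by construction.
#'
#' @param map a `flux_map` with a complete (no `NA`) flux vector.
#' @return A `flux_graph`: list with `ids`, `flux`, `ec`, `edges` (data frame
#'   `from`, `to`, `m` for pairs with forward material flow), `m` (full
#'   antisymmetric coefficient matrix) and `W` (weighted adjacency matrix).
#' @seealso [weighted_adjacency()], [align_topology()]
#' @export
build_flux_graph <- function(map) {
  stopifnot(inherits(map, "flux_map"))
  if (anyNA(map$flux))
    stop_fluxalign("flux graph needs a complete flux vector (absent values: ",
                   paste(map$id[is.na(map$flux)], collapse = ", "), ")")
  n <- n_reactions(map)
  prods <- lapply(map$stoich, function(s) s[s > 0])
  reacs <- lapply(map$stoich, function(s) s[s < 0])
  fwd <- matrix(0, n, n)  # fwd[i,j]: products of i feeding reactants of j
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      shared <- intersect(names(prods[[i]]), names(reacs[[j]]))
      if (length(shared))
        fwd[i, j] <- sum(abs(prods[[i]][shared])) + sum(abs(reacs[[j]][shared]))
    }
  }
  m <- fwd - t(fwd)
  dimnames(m) <- list(map$id, map$id)
  ij <- which(fwd > 0, arr.ind = TRUE)
  edges <- data.frame(from = map$id[ij[, 1]], to = map$id[ij[, 2]],
                      m = m[ij], stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  g <- structure(list(ids = map$id, flux = map$flux, ec = map$ec,
                      type = reaction_type(map$id),
                      edges = edges, m = m, W = NULL),
                 class = "flux_graph")
  g$W <- weighted_adjacency(g)
  g
}

#' @export
print.flux_graph <- function(x, ...) {
  cat("<flux_graph> ", length(x$ids), " reaction nodes, ",
      nrow(x$edges), " directed edges\n", sep = "")
  invisible(x)
}

#' Weighted adjacency matrix of a flux graph
#'
#' @param g a `flux_graph` (see [build_flux_graph()]).
#' @return the n x n weighted adjacency matrix W described in
#'   [build_flux_graph()]: normalized fluxes on the diagonal, antisymmetric
#'   normalized shared-compound coefficients off it.
#' @export
weighted_adjacency <- function(g) {
  stopifnot(inherits(g, "flux_graph"))
  v <- g$flux
  nv <- vnorm(v)
  if (nv == 0)
    stop_fluxalign("all-zero flux vector: weighted adjacency undefined")
  nm <- vnorm(g$m)
  W <- if (nm > 0) g$m / nm else g$m
  diag(W) <- v / nv
  W
}
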