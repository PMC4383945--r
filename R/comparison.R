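new_similarity <- function(method, score, n_shared, details) {
  structure(list(method = method, score = score, n_shared = n_shared,
                 details = details),
            class = "flux_similarity")
}

#' @export
print.flux_similarity <- function(x, ...) {
  cat("<flux_similarity> method = ", x$method,
      ", score = ", format(x$score, digits = 6),
      " (", x$n_shared, " shared reactions)\n", sep = "")
  invisible(x)
}

#' Vector-based similarity of two flux distributions
#'
#' Represents each flux distribution as the vector of its reaction rates and
#' scores the pair by the angular cosine
#' \deqn{\mathrm{sim} = \frac{\sum_i A_i B_i}{\sqrt{\sum_i A_i^2}\sqrt{\sum_i B_i^2}}}
#' computed over the shared reaction set (reactions present with a measured
#' flux in both maps), in canonical order. The score lies in `[-1, 1]`, is
#' symmetric, and is invariant to rescaling either map -- so maps need not be
#' normalized first.
#'
#' @param a,b `flux_map` objects with a nonempty shared reaction set and
#'   nonzero restricted flux vectors.
#' @return A `flux_similarity` with per-reaction contributions in `$details`.
#' @seealso [stoichiometry_similarity()], [similarity_matrix()]
#' @export
vector_similarity <- function(a, b) {
  ids <- shared_reaction_set(a, b)
  if (length(ids) == 0L)
    stop_fluxalign("empty shared reaction set")
  A <- a$flux[match_id(a, ids)]
  B <- b$flux[match_id(b, ids)]
  na <- vnorm(A); nb <- vnorm(B)
  if (na == 0 || nb == 0)
    stop_fluxalign("undefined cosine: zero-norm flux vector on the shared set")
  contrib <- A * B / (na * nb)
  new_similarity("vector", sum(contrib), length(ids),
                 data.frame(id = ids, flux_a = A, flux_b = B,
                            contribution = contrib))
}

#' Flux matrix of a flux map
#'
#' The stoichiometry-weighted representation of a flux distribution: each
#' column of the stoichiometric matrix is scaled by its reaction's flux,
#' `F[k, i] = S[k, i] * v_i`. The resulting l x n matrix describes how much
#' of each metabolite every reaction turns over and is the object the
#' stoichiometry-based similarity compares.
#'
#' @param map a `flux_map`.
#' @param reactions reaction ids to include (default: all); every included
#'   reaction must have a measured flux.
#' @param metabolites optional metabolite row frame (see
#'   [build_stoich_matrix()]).
#' @return numeric l x n matrix.
#' @export
flux_matrix <- function(map, reactions = NULL, metabolites = NULL) {
  stopifnot(inherits(map, "flux_map"))
  ids <- reactions %||% map$id
  idx <- match_id(map, ids)
  if (anyNA(idx))
    stop_fluxalign("unknown reaction id: ",
                   paste(ids[is.na(idx)], collapse = ", "))
  v <- map$flux[idx]
  if (anyNA(v))
    stop_fluxalign("absent flux value in compared reaction: ",
                   paste(map$id[idx][is.na(v)], collapse = ", "))
  S <- build_stoich_matrix(map, metabolites = metabolites)[, idx, drop = FALSE]
  sweep(S, 2L, v, `*`)
}

#' Stoichiometry-based similarity of two flux distributions
#'
#' Builds each map's flux matrix (stoichiometric matrix with columns scaled
#' by flux, see [flux_matrix()]) on a common frame -- the shared reaction set
#' and the union of both maps' metabolites, zero-filling metabolites absent
#' from one map -- and scores the pair by the Frobenius-inner-product cosine
#' \deqn{\mathrm{sim} = \frac{\langle A, B\rangle_F}{\|A\|_F\,\|B\|_F}.}
#' Equivalently: the vector cosine of the two flattened matrices. Unlike the
#' plain vector score this weights every reaction by how many metabolites it
#' converts and by their coefficients.
#'
#' @param a,b `flux_map` objects.
#' @return A `flux_similarity`; `$details` holds per-reaction (column) inner
#'   products.
#' @export
stoichiometry_similarity <- function(a, b) {
  ids <- shared_reaction_set(a, b)
  if (length(ids) == 0L)
    stop_fluxalign("empty shared reaction set")
  mets <- sort(unique(c(metabolite_ids(a), metabolite_ids(b))))
  A <- flux_matrix(a, reactions = ids, metabolites = mets)
  B <- flux_matrix(b, reactions = ids, metabolites = mets)
  na <- vnorm(A); nb <- vnorm(B)
  if (na == 0 || nb == 0)
    stop_fluxalign("zero-norm flux matrix on the shared frame")
  contrib <- colSums(A * B) / (na * nb)
  new_similarity("stoichiometry", sum(contrib), length(ids),
                 data.frame(id = ids, contribution = as.numeric(contrib)))
}

#' All-vs-all similarity matrix
#'
#' Runs one of the four comparison methods on every pair of a list of flux
#' maps and assembles the symmetric score matrix -- the input for downstream
#' hierarchical clustering of flux distributions (clustering itself is left
#' to standard tools such as [stats::hclust()]). Pairs whose comparison fails
#' (e.g. no shared reactions) are left `NA` with a warning. The diagonal is 1
#' for the vector and stoichiometry methods; for the alignment methods it is
#' the computed self-alignment score.
#'
#' @param maps list of `flux_map` objects (>= 2).
#' @param method `"vector"`, `"stoichiometry"`, `"enzyme_topology"` or
#'   `"topology"`.
#' @param lam trade-off parameter for `method = "topology"` (see
#'   [align_topology()]).
#' @param ... further arguments passed to the alignment methods.
#' @return symmetric numeric matrix with map names as dimnames.
#' @export
similarity_matrix <- function(maps, method = c("vector", "stoichiometry",
                                               "enzyme_topology", "topology"),
                              lam = 0.5, ...) {
  method <- match.arg(method)
  stopifnot(is.list(maps), length(maps) >= 2L)
  nm <- vapply(maps, function(m) m$name, "")
  if (anyDuplicated(nm)) nm <- make.unique(nm)
  n <- length(maps)
  M <- matrix(NA_real_, n, n, dimnames = list(nm, nm))
  pair_score <- function(x, y) {
    switch(method,
      vector = vector_similarity(x, y)$score,
      stoichiometry = stoichiometry_similarity(x, y)$score,
      enzyme_topology = enzyme_topology_similarity(x, y, ...)$score,
      topology = align_topology(x, y, lam = lam, ...)$score)
  }
  for (i in seq_len(n)) {
    M[i, i] <- if (method %in% c("vector", "stoichiometry")) 1
               else tryCatch(pair_score(maps[[i]], maps[[i]]),
                             error = function(e) NA_real_)
    if (i == n) break
    for (j in seq(i + 1L, n)) {
      M[i, j] <- M[j, i] <- tryCatch(
        pair_score(maps[[i]], maps[[j]]),
        error = function(e) {
          warning("comparison of '", nm[i], "' and '", nm[j], "' failed: ",
                  conditionMessage(e), call. = FALSE)
          NA_real_
        })
    }
  }
  M
}
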