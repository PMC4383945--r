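# ---- scoring internals ----------------------------------------------------
#
# The alignment objective over a one-to-one partial matching X between the
# reaction nodes of two weighted graphs (adjacency Wa o x o, Wb p x p, node
# similarity S o x p) is
#
#   f = lambda * sum_(i,j) S_ij a_ii b_jj x_ij
#     + (1-lambda) * sum_(i,j),(k,l) a_ik b_jl y_ijkl
#
# with y ranging over edge quadruples (i != k, j != l, a_ik != 0, b_jl != 0)
# and the assignment constraints sum_j x_ij <= 1, sum_i x_ij <= 1,
# x_ij >= y_ijkl, x_kl >= y_ijkl, x and y binary. Restricting y to edge
# quadruples (not the diagonal i = k) is what makes the self-alignment score
# exactly 1: diagonal quadruples would re-count the node terms.
#
# Two y semantics are supported:
#   "optimal": y maximized under the printed constraints -- a maximizer keeps
#              only quadruples with positive coefficient a_ik * b_jl;
#   "product": y = x_ij * x_kl -- negative edge terms count too (the strict
#              linearization y >= x_ij + x_kl - 1). This is the semantics
#              under which a map evaluated against its fully reversed copy at
#              the structure-preserving matching scores -1.
#
# Because a_ik b_jl = a_ki b_lj (both off-diagonal parts are antisymmetric),
# the quadruples (i,j,k,l) and (k,l,i,j) contribute equally; each unordered
# pair of matched nodes contributes 2 * a_ik * b_jl.

# per-pair score pieces for a matching given as parallel index vectors
# (rows[m] in graph a matched to cols[m] in graph b)
score_matching_idx <- function(NP, Aoff, Boff, lam, rows, cols,
                               positive_y = TRUE) {
  k <- length(rows)
  contrib <- numeric(k)
  if (k == 0L) return(list(score = 0, contributions = contrib))
  contrib <- NP[cbind(rows, cols)]
  if (k >= 2L && lam < 1) {
    for (m in seq_len(k - 1L)) {
      for (mm in seq(m + 1L, k)) {
        q <- 2 * Aoff[rows[m], rows[mm]] * Boff[cols[m], cols[mm]]
        if (positive_y) q <- max(0, q)
        q <- (1 - lam) * q
        contrib[m] <- contrib[m] + q / 2
        contrib[mm] <- contrib[mm] + q / 2
      }
    }
  }
  list(score = sum(contrib), contributions = contrib)
}

align_problem <- function(a, b, lam) {
  stopifnot(inherits(a, "flux_map"), inherits(b, "flux_map"))
  if (lam < 0 || lam > 1) stop_fluxalign("`lam` must be in [0, 1]")
  ga <- build_flux_graph(a)
  gb <- build_flux_graph(b)
  S <- node_similarity_matrix(a, b)
  Aoff <- ga$W; diag(Aoff) <- 0
  Boff <- gb$W; diag(Boff) <- 0
  NP <- lam * S * outer(diag(ga$W), diag(gb$W))
  list(ga = ga, gb = gb, S = S, Aoff = Aoff, Boff = Boff, NP = NP, lam = lam)
}

# Global upper bound on the objective (Cauchy-Schwarz): the node part is at
# most ||diag Wa|| * ||diag Wb|| = 1 and the edge part at most
# ||Aoff||_F * ||Boff||_F (= 1 when both graphs have edges, 0 otherwise).
align_cap <- function(pr) {
  pr$lam * vnorm(diag(pr$ga$W)) * vnorm(diag(pr$gb$W)) +
    (1 - pr$lam) * vnorm(pr$Aoff) * vnorm(pr$Boff)
}

# ---- exact branch-and-bound solver ----------------------------------------
#
# Depth-first search over injective partial matchings, rows taken in a static
# heuristic order, candidate columns by decreasing incremental gain (ties by
# column index: deterministic). Pruning uses an admissible bound: for every
# unassigned row the best assignable column value, counting exact (positive-
# part) interactions with already-matched pairs plus a rearrangement bound on
# interactions with other unassigned rows (the sorted |a_ik| magnitudes paired
# with the sorted |b_jl| magnitudes -- admissible because matched columns are
# distinct), all clamped at the global Cauchy-Schwarz cap.
solve_alignment_bb <- function(pr, positive_y = TRUE, eps = 1e-12,
                               time_limit = Inf) {
  t_start <- proc.time()[[3]]
  node_count <- 0L
  NP <- pr$NP; Aoff <- pr$Aoff; Boff <- pr$Boff; lam <- pr$lam
  o <- nrow(NP); p <- ncol(NP)
  absA <- abs(Aoff)
  absB <- abs(Boff)
  # sortB[j, ] : |Boff[j, ]| sorted decreasing (future-pair pairing bound)
  sortB <- if (p > 0) t(apply(absB, 1L, sort, decreasing = TRUE))
           else matrix(0, 0, 0)
  cap <- align_cap(pr)
  ord <- order(-(apply(NP, 1L, max) + (1 - lam) * rowSums(absA)))

  best_score <- 0
  best_rows <- integer(0)
  best_cols <- integer(0)

  edge_gain <- function(i, js, mrows, mcols) {
    g <- numeric(length(js))
    for (m in seq_along(mrows)) {
      q <- 2 * Aoff[i, mrows[m]] * Boff[js, mcols[m]]
      if (positive_y) q <- pmax(0, q)
      g <- g + q
    }
    g
  }

  # Multi-restart greedy incumbent: optionally pin the heuristically first
  # row to each column in turn, then grow the matching by the globally best
  # positive incremental gain, updating the gain matrix incrementally. With
  # lam = 0 the root carries no gain signal at all, so a pinned seed pair
  # plus best-pair growth is what finds (for identical maps) the identity
  # matching -- which attains the global cap and lets it prune the search.
  greedy_once <- function(i0, j0) {
    R <- seq_len(o); C <- seq_len(p)
    mrows <- integer(0); mcols <- integer(0); score <- 0
    G <- NP
    repeat {
      if (!length(R) || !length(C)) break
      if (is.na(i0)) {
        sub <- G[R, C, drop = FALSE]
        k <- which.max(sub)
        g <- sub[k]
        if (g <= 0) break
        i <- R[(k - 1L) %% length(R) + 1L]
        j <- C[(k - 1L) %/% length(R) + 1L]
      } else {
        i <- i0; j <- j0; g <- G[i, j]
        i0 <- NA
      }
      score <- score + g
      mrows <- c(mrows, i); mcols <- c(mcols, j)
      R <- R[R != i]; C <- C[C != j]
      if (lam < 1 && length(R) && length(C)) {
        q <- 2 * outer(Aoff[R, i], Boff[C, j])
        if (positive_y) q <- pmax(0, q)
        G[R, C] <- G[R, C] + (1 - lam) * q
      }
    }
    if (score > best_score + eps) {
      best_score <<- score; best_rows <<- mrows; best_cols <<- mcols
    }
  }
  greedy_incumbent <- function() {
    greedy_once(NA, NA)
    for (j0 in seq_len(p)) greedy_once(ord[1L], j0)
  }

  bound_rest <- function(t, avail, mrows, mcols) {
    rem <- ord[seq(t, o)]
    if (length(avail) == 0L) return(0)
    U <- NP[rem, avail, drop = FALSE]
    if (lam < 1) {
      for (m in seq_along(mrows)) {
        U <- U + (1 - lam) *
          pmax(0, 2 * outer(Aoff[rem, mrows[m]], Boff[avail, mcols[m]]))
      }
      # pairs among still-unassigned rows: pair each row's sorted |a|
      # magnitudes (to other remaining rows) with each column's sorted |b|
      # magnitudes; distinct matched columns make this admissible
      r <- min(length(rem) - 1L, p)
      if (r > 0L) {
        sA <- apply(absA[rem, rem, drop = FALSE], 1L, function(x)
          sort(x, decreasing = TRUE)[seq_len(r)])
        sA <- matrix(sA, nrow = r)          # r x |rem|
        # each unordered future pair is counted once from each of its two
        # rows, so the per-row share of the 2*a*b term carries factor 1
        fut <- crossprod(sA, t(sortB[avail, seq_len(r), drop = FALSE]))
        U <- U + (1 - lam) * fut
      }
    }
    sum(pmax(0, apply(U, 1L, max)))
  }

  rec <- function(t, avail, mrows, mcols, score) {
    node_count <<- node_count + 1L
    if (node_count %% 512L == 0L &&
        proc.time()[[3]] - t_start > time_limit)
      stop_fluxalign("alignment solver timeout after ", time_limit,
                     " s: best score so far ", format(best_score),
                     ", upper bound ", format(cap))
    if (score > best_score + eps) {
      best_score <<- score
      best_rows <<- mrows
      best_cols <<- mcols
    }
    if (t > o) return(invisible())
    ub <- min(score + bound_rest(t, avail, mrows, mcols), cap)
    if (ub <= best_score + eps) return(invisible())
    i <- ord[t]
    if (length(avail)) {
      gains <- NP[i, avail] +
        (1 - lam) * edge_gain(i, avail, mrows, mcols)
      for (idx in order(-gains, avail)) {
        j <- avail[idx]
        rec(t + 1L, avail[avail != j], c(mrows, i), c(mcols, j),
            score + gains[idx])
      }
    }
    rec(t + 1L, avail, mrows, mcols, score)  # leave row i unmatched
    invisible()
  }
  if (o > 0 && p > 0) greedy_incumbent()
  rec(1L, seq_len(p), integer(0), integer(0), 0)
  list(score = best_score, rows = best_rows, cols = best_cols)
}

# ---- result object ---------------------------------------------------------

new_alignment <- function(method, a, b, pr, rows, cols, lam, positive_y) {
  sc <- score_matching_idx(pr$NP, pr$Aoff, pr$Boff, lam, rows, cols,
                           positive_y = positive_y)
  ordm <- order(rows)
  rows <- rows[ordm]; cols <- cols[ordm]
  matching <- data.frame(id_a = a$id[rows], id_b = b$id[cols],
                         contribution = sc$contributions[ordm],
                         stringsAsFactors = FALSE)
  res <- structure(
    list(method = method, score = sc$score, lam = lam,
         p_value = NA_real_, matching = matching,
         gaps = a$id[setdiff(seq_along(a$id), rows)],
         insertions = b$id[setdiff(seq_along(b$id), cols)],
         conserved_pathways = conserved_pathways(pr$ga, pr$gb, rows, cols),
         map_a = a$name, map_b = b$name,
         n_a = n_reactions(a), n_b = n_reactions(b)),
    class = "flux_alignment")
  res
}

# Conserved metabolic pathways: weakly connected components (size >= 2) of
# the matched subgraph, whose vertices are the matched pairs and whose edges
# join pairs connected in both maps.
conserved_pathways <- function(ga, gb, rows, cols) {
  k <- length(rows)
  if (k < 2L) return(list())
  el <- NULL
  for (m in seq_len(k - 1L)) {
    for (mm in seq(m + 1L, k)) {
      if (ga$m[rows[m], rows[mm]] != 0 && gb$m[cols[m], cols[mm]] != 0)
        el <- rbind(el, c(m, mm))
    }
  }
  if (is.null(el)) return(list())
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, k - igraph::vcount(g)))
  comp <- igraph::components(g)
  out <- list()
  for (cid in which(comp$csize >= 2L)) {
    mem <- which(comp$membership == cid)
    out[[length(out) + 1L]] <-
      data.frame(id_a = ga$ids[rows[mem]], id_b = gb$ids[cols[mem]],
                 stringsAsFactors = FALSE)
  }
  out
}

#' @export
print.flux_alignment <- function(x, ...) {
  cat("<flux_alignment> ", x$method, " (lambda = ", format(x$lam), ")\n",
      "  ", x$map_a, "  vs  ", x$map_b, "\n",
      "  score: ", format(x$score, digits = 6), sep = "")
  if (!is.na(x$p_value)) cat("   P-value:", format(x$p_value))
  cat("\n  matched: ", nrow(x$matching),
      "  conserved pathways: ", length(x$conserved_pathways),
      "  gaps: ", length(x$gaps),
      "  insertions: ", length(x$insertions), "\n", sep = "")
  invisible(x)
}

#' @export
summary.flux_alignment <- function(object, ...) {
  print(object)
  if (nrow(object$matching)) {
    cat("\nMatched reaction pairs:\n")
    print(object$matching, row.names = FALSE)
  }
  invisible(object)
}

# ---- user-facing operations ------------------------------------------------

#' Topology-based alignment of two flux maps
#'
#' Aligns the weighted directed reaction graphs of two flux distributions by
#' solving, exactly, the integer program that maximizes
#' \deqn{\lambda \sum_{ij} S_{ij} a_{ii} b_{jj} x_{ij} +
#'       (1-\lambda) \sum_{ijkl} a_{ik} b_{jl} y_{ijkl}}
#' over one-to-one partial node matchings `x` (binary, with row/column sums
#' at most 1) and edge-pair indicators `y` constrained by
#' `y_ijkl <= x_ij, y_ijkl <= x_kl`. The node term rewards matching reactions
#' with similar EC classes (see [node_similarity()]) and similar normalized
#' fluxes; the edge term rewards preserving weighted connectivity. `lam`
#' trades the two off; `lam = 1` is the enzyme-topology score, `lam = 0` pure
#' topology. Scores lie in `[-1, 1]`: an identical pair of maps scores 1.
#'
#' Under the printed constraints a maximizing solver drops `y` terms with
#' negative coefficient; `strict_y = TRUE` adds the linearization
#' `y >= x_ij + x_kl - 1`, forcing negative edge terms to count.
#'
#' The solver is an exact branch-and-bound over injective partial matchings
#' with an admissible interaction bound and a global Cauchy-Schwarz cap;
#' central-carbon maps (tens of reactions) solve in seconds.
#'
#' @param a,b `flux_map` objects with complete flux vectors.
#' @param lam trade-off in `[0, 1]` between node and edge score
#'   (default 0.5).
#' @param strict_y force negative edge terms into the objective (see above).
#' @param time_limit solver wall-clock limit in seconds; on timeout an error
#'   reports the incumbent score (lower bound) and the global upper bound.
#' @return A `flux_alignment`: optimal `score`, the `matching` with
#'   per-pair contributions (summing to the score), `gaps` (unmatched
#'   reactions of `a`), `insertions` (unmatched reactions of `b`) and
#'   `conserved_pathways` (connected matched subgraphs of 2+ reactions).
#' @seealso [enzyme_topology_similarity()], [evaluate_alignment()],
#'   [permutation_pvalue()], [alignment_report()]
#' @export
align_topology <- function(a, b, lam = 0.5, strict_y = FALSE,
                           time_limit = Inf) {
  pr <- align_problem(a, b, lam)
  sol <- solve_alignment_bb(pr, positive_y = !strict_y,
                            time_limit = time_limit)
  new_alignment("topology", a, b, pr, sol$rows, sol$cols, lam,
                positive_y = !strict_y)
}

#' Enzyme-topology similarity (lambda = 1 alignment)
#'
#' The special case of [align_topology()] with `lam = 1`: the edge terms
#' vanish and the program reduces to a linear assignment on the weights
#' `S_ij a_ii b_jj` (EC-hierarchy similarity scaled by normalized fluxes),
#' with negatively-weighted pairs never matched.
#'
#' @inheritParams align_topology
#' @return A `flux_alignment` with method `"enzyme_topology"`.
#' @export
enzyme_topology_similarity <- function(a, b, strict_y = FALSE,
                                       time_limit = Inf) {
  pr <- align_problem(a, b, 1)
  sol <- solve_alignment_bb(pr, positive_y = !strict_y,
                            time_limit = time_limit)
  new_alignment("enzyme_topology", a, b, pr, sol$rows, sol$cols, 1,
                positive_y = !strict_y)
}

#' Evaluate the alignment objective at a fixed matching
#'
#' Computes the alignment objective of [align_topology()] at a given
#' one-to-one matching instead of maximizing over matchings. By default the
#' edge indicators follow the product semantics `y = x_ij * x_kl`, so
#' negative edge terms count: this is the evaluation under which a flux map
#' scored against its fully reversed copy ([reverse_all()]) at the
#' structure-preserving matching yields exactly -1, at any `lam`.
#'
#' @inheritParams align_topology
#' @param matching the matching to evaluate: a two-column object (data frame
#'   or matrix) of reaction ids `id_a`, `id_b`, or a character vector of
#'   `b`-ids named by `a`-ids.
#' @param y `"product"` (default; `y = x * x`) or `"optimal"` (positive
#'   coefficients only, as a maximizing solver would set them).
#' @return A `flux_alignment` holding the evaluated (not maximized) score.
#' @export
evaluate_alignment <- function(a, b, matching, lam = 0.5,
                               y = c("product", "optimal")) {
  y <- match.arg(y)
  pr <- align_problem(a, b, lam)
  if (is.character(matching) && !is.null(names(matching)))
    matching <- cbind(names(matching), unname(matching))
  matching <- as.matrix(matching)
  if (ncol(matching) != 2L)
    stop_fluxalign("`matching` must have two columns (id_a, id_b)")
  rows <- match_id(a, matching[, 1])
  cols <- match_id(b, matching[, 2])
  if (anyNA(rows) || anyNA(cols))
    stop_fluxalign("matching refers to unknown reaction ids")
  if (anyDuplicated(rows) || anyDuplicated(cols))
    stop_fluxalign("matching must be one-to-one")
  res <- new_alignment("evaluated", a, b, pr, rows, cols, lam,
                       positive_y = (y == "optimal"))
  res
}

#' Brute-force alignment oracle
#'
#' Exhaustively enumerates every injective partial matching between the two
#' reaction sets and returns the one maximizing the alignment objective --
#' the independent reference implementation the branch-and-bound solver is
#' verified against. The edge indicators mirror the solver's relaxation
#' (positive-coefficient quadruples only, unless `strict_y`).
#'
#' @inheritParams align_topology
#' @param max_nodes size guard: error when either map exceeds this many
#'   reactions (the enumeration is factorial).
#' @return A `flux_alignment`.
#' @export
brute_force_alignment <- function(a, b, lam = 0.5, strict_y = FALSE,
                                  max_nodes = 7L) {
  pr <- align_problem(a, b, lam)
  o <- n_reactions(a); p <- n_reactions(b)
  if (o > max_nodes || p > max_nodes)
    stop_fluxalign("brute force guard exceeded (", o, "x", p,
                   " > ", max_nodes, "x", max_nodes, ")")
  positive_y <- !strict_y
  best_score <- 0; best_rows <- integer(0); best_cols <- integer(0)
  rec <- function(i, avail, mrows, mcols) {
    if (i > o) {
      sc <- score_matching_idx(pr$NP, pr$Aoff, pr$Boff, lam, mrows, mcols,
                               positive_y = positive_y)$score
      if (sc > best_score + 1e-15) {
        best_score <<- sc; best_rows <<- mrows; best_cols <<- mcols
      }
      return(invisible())
    }
    rec(i + 1L, avail, mrows, mcols)
    for (j in avail)
      rec(i + 1L, avail[avail != j], c(mrows, i), c(mcols, j))
    invisible()
  }
  rec(1L, seq_len(p), integer(0), integer(0))
  new_alignment("brute_force", a, b, pr, best_rows, best_cols, lam,
                positive_y = positive_y)
}
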