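#' Monte Carlo permutation P-value for an alignment score
#'
#' Assesses the significance of an alignment score by re-running the same
#' comparison against random-valued flux maps: the second map's flux values
#' are resampled i.i.d. uniform on `[0, max |flux|]` (its topology, EC labels
#' and stoichiometry kept), the alignment recomputed, and the P-value taken
#' as the fraction of the `n_perm` null maps whose alignment score strictly
#' exceeds the observed one. The default 100 null maps gives P-value
#' resolution 1/100.
#'
#' @inheritParams align_topology
#' @param n_perm number of random-valued null maps (default 100).
#' @param seed RNG seed for reproducible null sampling.
#' @param method `"topology"` or `"enzyme_topology"`.
#' @param observed optionally, a precomputed `flux_alignment` of `a` and `b`
#'   (saves one solve).
#' @return the P-value, a numeric in `[0, 1]` (a step multiple of
#'   `1/n_perm`), with attributes `observed` (observed score) and
#'   `null_scores` (the `n_perm` null alignment scores).
#' @export
permutation_pvalue <- function(a, b, lam = 0.5, n_perm = 100L, seed = NULL,
                               method = c("topology", "enzyme_topology"),
                               strict_y = FALSE, observed = NULL) {
  method <- match.arg(method)
  stopifnot(n_perm >= 1L)
  run <- function(x, y) {
    if (method == "topology") align_topology(x, y, lam = lam,
                                             strict_y = strict_y)
    else enzyme_topology_similarity(x, y, strict_y = strict_y)
  }
  if (is.null(observed)) observed <- run(a, b)
  stopifnot(inherits(observed, "flux_alignment"))
  fmax <- max(abs(b$flux), na.rm = TRUE)
  null_scores <- with_seed(seed, {
    vapply(seq_len(n_perm), function(t) {
      bt <- with_fluxes(b, stats::runif(n_reactions(b), 0, fmax))
      run(a, bt)$score
    }, numeric(1))
  })
  p <- mean(null_scores > observed$score)
  attr(p, "observed") <- observed$score
  attr(p, "null_scores") <- null_scores
  p
}

#' Align two flux maps and attach a permutation P-value
#'
#' Convenience wrapper: runs [align_topology()] (or the `lam = 1`
#' enzyme-topology case) and, when `n_perm > 0`, attaches the
#' [permutation_pvalue()].
#'
#' @inheritParams permutation_pvalue
#' @return A `flux_alignment` with `p_value` filled in when `n_perm > 0`.
#' @export
align_with_pvalue <- function(a, b, lam = 0.5, n_perm = 100L, seed = NULL,
                              method = c("topology", "enzyme_topology"),
                              strict_y = FALSE) {
  method <- match.arg(method)
  res <- if (method == "topology") align_topology(a, b, lam, strict_y)
         else enzyme_topology_similarity(a, b, strict_y)
  if (n_perm > 0) {
    p <- permutation_pvalue(a, b, lam = lam, n_perm = n_perm, seed = seed,
                            method = method, strict_y = strict_y,
                            observed = res)
    res$p_value <- as.numeric(p)
    res$null_scores <- attr(p, "null_scores")
  }
  res
}
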