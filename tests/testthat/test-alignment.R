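test_that("self-alignment scores 1 with the identity matching at any lambda", {
  maps <- list(chain_map(3), sample_steady_state_fluxes(toy_network("core"),
                                                        seed = 5))
  for (m in maps) {
    for (lam in c(0, 0.5, 1)) {
      r <- align_topology(m, m, lam = lam)
      expect_score_equal(r$score, 1, 1e-6)
      expect_equal(r$matching$id_a, r$matching$id_b)
      expect_length(r$gaps, 0)
      expect_length(r$insertions, 0)
    }
  }
})

test_that("maps with nothing in common align empty with score 0", {
  a <- one_reaction_map("R1", st(A = -1, B = 1), 10)
  a <- with_ec(a, list(c(1, 1, 1, 1)))
  b <- one_reaction_map("R2", st(C = -1, D = 1), 10)
  b <- with_ec(b, list(c(3, 2, 2, 1)))
  r <- align_topology(a, b, lam = 1)
  expect_equal(r$score, 0)
  expect_equal(nrow(r$matching), 0)
  expect_equal(r$gaps, "R1")
  expect_equal(r$insertions, "R2")
})

test_that("a map with no enzymatic overlap aligns to score 0 at lambda 1", {
  # pure transport map vs enzymatic map: pseudo ids differ, no EC on one side
  a <- flux_map(c("transport_A", "transport_B"),
                list(st(A = -1), st(B = -1)), c(5, 5))
  b <- chain_map(2, name = "enzymatic")
  r <- enzyme_topology_similarity(a, b)
  expect_equal(r$score, 0)
  expect_equal(nrow(r$matching), 0)
})

test_that("branch-and-bound equals exhaustive enumeration on small instances", {
  # randomized equivalence suite across sizes, lambdas and y semantics
  cases <- expand.grid(s = 1:6, lam = c(0, 0.5, 1))
  for (k in seq_len(nrow(cases))) {
    s <- cases$s[k]; lam <- cases$lam[k]
    a <- random_flux_map(4, seed = s)
    b <- random_flux_map(4, seed = s + 1000)
    ilp <- align_topology(a, b, lam = lam)
    bf <- brute_force_alignment(a, b, lam = lam)
    expect_score_equal(ilp$score, bf$score, 1e-9)
  }
  for (s in 1:5) {
    a <- random_flux_map(3, seed = s)
    b <- random_flux_map(5, seed = s + 2000)
    ilp <- align_topology(a, b, lam = 0.5, strict_y = TRUE)
    bf <- brute_force_alignment(a, b, lam = 0.5, strict_y = TRUE)
    expect_score_equal(ilp$score, bf$score, 1e-9)
  }
})

test_that("lambda = 1 alignment equals the Hungarian linear-assignment oracle", {
  for (s in 1:10) {
    a <- random_flux_map(5, seed = s)
    b <- random_flux_map(5, seed = s + 3000)
    res <- enzyme_topology_similarity(a, b)
    ga <- build_flux_graph(a); gb <- build_flux_graph(b)
    S <- fluxalign:::node_similarity_matrix(a, b)
    w <- S * outer(diag(ga$W), diag(gb$W))
    # pad with zero-weight dummy columns so pairs may stay unmatched;
    # negative-weight pairs then never enter the optimum
    wp <- cbind(w, matrix(0, nrow(w), nrow(w)))
    sol <- clue::solve_LSAP(max(wp) - wp)
    oracle <- sum(wp[cbind(seq_len(nrow(w)), as.integer(sol))])
    expect_score_equal(res$score, oracle, 1e-9)
  }
})

test_that("matchings are injective and reports partition both reaction sets", {
  for (s in 1:8) {
    a <- random_flux_map(5, seed = s)
    b <- random_flux_map(6, seed = s + 4000)
    r <- align_topology(a, b, lam = 0.5)
    expect_false(anyDuplicated(r$matching$id_a) > 0)
    expect_false(anyDuplicated(r$matching$id_b) > 0)
    expect_setequal(c(r$matching$id_a, r$gaps), a$id)
    expect_setequal(c(r$matching$id_b, r$insertions), b$id)
    expect_true(r$score >= -1 - 1e-9 && r$score <= 1 + 1e-9)
    expect_score_equal(sum(r$matching$contribution), r$score, 1e-9)
  }
})

test_that("the objective at the structural matching of a reversed map is -1", {
  for (nm in c("chain5", "core")) {
    m <- sample_steady_state_fluxes(toy_network(nm), seed = 8)
    rev <- reverse_all(m)
    for (lam in c(0, 0.5, 1)) {
      ev <- evaluate_alignment(m, rev, cbind(m$id, m$id), lam = lam)
      expect_score_equal(ev$score, -1, 1e-6)
    }
    # per-pair contributions are negative and sum to the score
    ev <- evaluate_alignment(m, rev, cbind(m$id, m$id), lam = 0.5)
    expect_true(all(ev$matching$contribution < 0))
    expect_score_equal(sum(ev$matching$contribution), ev$score, 1e-9)
  }
})

test_that("evaluate_alignment validates its matching argument", {
  m <- chain_map(2)
  expect_error(evaluate_alignment(m, m, cbind("R90001", "nope")),
               "unknown reaction")
  expect_error(
    evaluate_alignment(m, m,
                       rbind(c("R90001", "R90001"), c("R90002", "R90001"))),
    "one-to-one")
  # maximizer-style y on the identity matching of a map with itself gives 1
  ev <- evaluate_alignment(m, m, cbind(m$id, m$id), y = "optimal")
  expect_score_equal(ev$score, 1, 1e-9)
})

test_that("the brute-force oracle guards its instance size", {
  a <- random_flux_map(8, seed = 1)
  expect_error(brute_force_alignment(a, a), "guard")
})

test_that("the solver time limit raises an informative error", {
  a <- sample_steady_state_fluxes(toy_network("core"), seed = 1)
  b <- random_flux_map(22, seed = 5)
  expect_error(align_topology(a, b, lam = 0.5, time_limit = 0.2),
               "timeout.*upper bound")
})
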