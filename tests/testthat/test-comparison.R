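test_that("vector similarity reproduces the angular cosine", {
  p <- shared_flux_pair(c(100, 50, 50), c(100, 50, 0))
  r <- vector_similarity(p$a, p$b)
  expect_score_equal(r$score, 12500 / (sqrt(15000) * sqrt(12500)), 1e-12)
  expect_equal(r$n_shared, 3)
  expect_score_equal(sum(r$details$contribution), r$score, 1e-12)

  expect_score_equal(vector_similarity(p$a, p$a)$score, 1, 1e-12)
  neg <- with_fluxes(p$a, -p$a$flux)
  expect_score_equal(vector_similarity(p$a, neg)$score, -1, 1e-12)

  z <- with_fluxes(p$a, c(0, 0, 0))
  expect_error(vector_similarity(p$a, z), "undefined cosine")
})

test_that("flux matrix scales stoichiometric columns by flux", {
  m <- flux_map("R1", list(st(A = -1, B = 1)), 10)
  expect_equal(as.numeric(flux_matrix(m)), c(-10, 10))

  ch <- chain_map(2)                       # feed, 2 steps, drain
  z <- with_fluxes(ch, rep(0, 4))
  expect_true(all(flux_matrix(z) == 0))

  ch4 <- chain_map(3)
  ch4 <- with_fluxes(ch4, c(100, 100, 50, 50, 50))
  F <- flux_matrix(ch4)
  expect_equal(F, sweep(build_stoich_matrix(ch4), 2, ch4$flux, `*`))
  expect_equal(F["B", "R90002"], -50)

  m_na <- with_fluxes(m, NA_real_)
  expect_error(flux_matrix(m_na), "absent flux")
})

test_that("stoichiometry similarity equals the flatten-then-cosine oracle", {
  p <- shared_flux_pair(c(100, 50, 50), c(100, 50, 100))
  r <- stoichiometry_similarity(p$a, p$b)
  # independent route: flatten both flux matrices, apply the plain cosine
  ids <- shared_reaction_set(p$a, p$b)
  mets <- sort(union(metabolite_ids(p$a), metabolite_ids(p$b)))
  A <- as.numeric(flux_matrix(p$a, ids, mets))
  B <- as.numeric(flux_matrix(p$b, ids, mets))
  oracle <- sum(A * B) / (sqrt(sum(A^2)) * sqrt(sum(B^2)))
  expect_score_equal(r$score, oracle, 1e-12)

  expect_score_equal(stoichiometry_similarity(p$a, p$a)$score, 1, 1e-12)
  neg <- with_fluxes(p$a, -p$a$flux)
  expect_score_equal(stoichiometry_similarity(p$a, neg)$score, -1, 1e-12)
})

test_that("vector and stoichiometry scores are symmetric, scale-invariant and bounded", {
  for (s in 1:10) {
    a <- random_flux_map(6, seed = s)
    b <- random_flux_map(6, seed = s + 50)
    b$id <- a$id   # force a shared reaction set
    b <- validate_flux_map(b)
    for (f in list(vector_similarity, stoichiometry_similarity)) {
      ab <- f(a, b)$score
      ba <- f(b, a)$score
      expect_score_equal(ab, ba, 1e-12)
      expect_true(ab >= -1 - 1e-9 && ab <= 1 + 1e-9)
      scaled <- with_fluxes(a, a$flux * 7.3)
      expect_score_equal(f(scaled, b)$score, ab, 1e-9)
    }
  }
})

test_that("similarity matrices assemble pairwise scores symmetrically", {
  p <- shared_flux_pair()
  M <- similarity_matrix(list(p$a, p$a), method = "vector")
  expect_equal(unname(M), matrix(1, 2, 2))

  maps <- list(p$a, p$b, with_fluxes(p$a, c(10, 90, 30)))
  M3 <- similarity_matrix(maps, method = "vector")
  expect_equal(M3[1, 2], vector_similarity(p$a, p$b)$score)
  expect_equal(M3[2, 3], vector_similarity(p$b, maps[[3]])$score)
  expect_equal(M3, t(M3))
  expect_true(all(diag(M3) == 1))

  # a failing pair is masked NA with a warning
  q <- chain_map(2, name = "alien")
  q$id <- c("unknown_q", "R97001", "R97002", "transport_Q")
  q$substrate_ids <- "unknown_q"
  q <- validate_flux_map(q)
  expect_warning(Mna <- similarity_matrix(list(p$a, q), method = "vector"),
                 "failed")
  expect_true(is.na(Mna[1, 2]))
})

test_that("an 18-map similarity matrix feeds hierarchical clustering", {
  base <- sample_steady_state_fluxes(toy_network("core"), seed = 10)
  maps <- lapply(1:18, function(i) {
    m <- perturb_fluxes(base, noise_sd = 0.2 + 0.05 * (i %% 3), seed = 100 + i)
    m$name <- paste0("case_", i)
    m
  })
  M <- similarity_matrix(maps, method = "vector")
  expect_equal(dim(M), c(18, 18))
  expect_true(all(M >= -1 - 1e-9 & M <= 1 + 1e-9))
  hc <- stats::hclust(stats::as.dist(1 - M), method = "average")
  expect_s3_class(hc, "hclust")
  expect_length(hc$order, 18)
})
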