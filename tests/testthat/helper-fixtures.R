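# fixture builders shared across the suite (everything generated in code)

# simple named-stoichiometry helper
st <- function(...) {
  x <- c(...)
  stopifnot(!is.null(names(x)))
  x
}

# linear chain map: feed -> A -> B -> ... -> drain, n enzymatic steps,
# distinct EC classes, all fluxes equal `flux`
chain_map <- function(n_steps = 3, flux = 100, name = "chain") {
  mets <- LETTERS[seq_len(n_steps + 1)]
  ids <- c("unknown_feed",
           sprintf("R9%04d", seq_len(n_steps)),
           paste0("transport_", mets[n_steps + 1]))
  stoich <- c(list(st(setNames(1, mets[1]))),
              lapply(seq_len(n_steps), function(i)
                st(setNames(c(-1, 1), mets[c(i, i + 1)]))),
              list(st(setNames(-1, mets[n_steps + 1]))))
  ec <- c(list(NULL),
          lapply(seq_len(n_steps), function(i) c(i, 1, 1, i)),
          list(NULL))
  flux_map(id = ids, stoich = stoich, flux = rep(flux, n_steps + 2),
           ec = ec, substrate_ids = "unknown_feed", name = name)
}

# two-substrate fixture: raw uptake rates 3 and 2 mmol/g/h
two_substrate_map <- function() {
  flux_map(
    id = c("unknown_feed_a", "unknown_feed_b", "R91001", "transport_C"),
    stoich = list(st(A = 1), st(B = 1), st(A = -1, B = -1, C = 1),
                  st(C = -1)),
    flux = c(3, 2, 2, 2),
    ec = list(NULL, NULL, c(2, 2, 1, 1), NULL),
    substrate_ids = c("unknown_feed_a", "unknown_feed_b"),
    name = "two_substrates")
}

# two maps sharing three reactions with prescribed fluxes
shared_flux_pair <- function(fa = c(100, 50, 50), fb = c(100, 50, 0)) {
  stoich <- list(st(A = -1, B = 1), st(B = -1, C = 1), st(B = -1, D = 1))
  ids <- c("R95001", "R95002", "R95003")
  ec <- list(c(1, 1, 1, 1), c(2, 1, 1, 1), c(3, 1, 1, 1))
  list(a = flux_map(ids, stoich, fa, ec, name = "pair_a"),
       b = flux_map(ids, stoich, fb, ec, name = "pair_b"))
}

# single-reaction energetics fixture around a given reaction id
one_reaction_map <- function(id, stoich, flux, name = "one") {
  flux_map(id = id, stoich = list(stoich), flux = flux, name = name)
}

# a tiny TSV on disk, returning its path
write_fixture_tsv <- function(map, path = tempfile(fileext = ".tsv")) {
  write_flux_table(map, path)
  path
}

expect_score_equal <- function(x, y, tol = 1e-9) {
  expect_lt(abs(x - y), tol)
}
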