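test_that("equation parsing transcribes rows into signed stoichiometry", {
  pe <- parse_equation("2pg <=> pep + h2o")
  expect_equal(pe$stoich, c(`2pg` = -1, pep = 1, h2o = 1))
  expect_true(pe$reversible)

  pe <- parse_equation("2 A => B")
  expect_equal(pe$stoich, c(A = -2, B = 1))
  expect_false(pe$reversible)

  # one-sided pseudo-reactions and netting of both-side metabolites
  expect_equal(parse_equation("=> g6p")$stoich, c(g6p = 1))
  expect_equal(parse_equation("mal =>")$stoich, c(mal = -1))
  expect_equal(parse_equation("A + B => B + C")$stoich, c(A = -1, C = 1))

  expect_error(parse_equation("A - B"), "no arrow")
  expect_error(parse_equation("A => B => C"), "multiple arrows")
  expect_error(parse_equation("0 A => B"), "zero coefficient")
})

test_that("a flux table row becomes a validated reaction", {
  df <- data.frame(id = "R00658", ec = "4.2.1.11",
                   equation = "2pg <=> pep + h2o", flux = "85.0",
                   compartment = "cytosol")
  m <- parse_flux_table(df)
  expect_s3_class(m, "flux_map")
  expect_equal(m$id, "R00658")
  expect_equal(unclass(m$ec[[1]]), c(4L, 2L, 1L, 11L))
  expect_equal(m$stoich[[1]], c(`2pg` = -1, pep = 1, h2o = 1))
  expect_equal(m$flux, 85)
})

test_that("degenerate and malformed tables are rejected with row context", {
  expect_error(parse_flux_table(data.frame(id = character(),
                                           equation = character(),
                                           flux = character())),
               "no reactions")
  bad <- data.frame(id = c("R1", "R2"),
                    equation = c("A => B", "B + C"), flux = c("1", "2"))
  expect_error(parse_flux_table(bad), "row 2")
  dup <- data.frame(id = c("R1", "r1"), equation = c("A => B", "B => C"),
                    flux = c("1", "2"))
  expect_error(parse_flux_table(dup), "duplicate reaction id")
  badflux <- data.frame(id = "R1", equation = "A => B", flux = "fast")
  expect_error(parse_flux_table(badflux), "unparseable flux")
})

test_that("flux map invariants are enforced", {
  # ordinary reactions must be two-sided
  expect_error(flux_map("R1", list(st(A = -1)), 1),
               "consume and produce")
  # pseudo-reactions may be one-sided
  expect_silent(validate_flux_map(
    flux_map("transport_A", list(st(A = -1)), 1)))
  expect_error(flux_map(c("R1", "R1"),
                        list(st(A = -1, B = 1), st(B = -1, C = 1)),
                        c(1, 2)), "duplicate")
  expect_error(flux_map("R1", list(st(A = 0, B = 1)), 1), "nonzero")
  expect_error(flux_map("R1", list(st(A = -1, B = 1)), Inf), "finite")
  # absent flux is NA, explicitly allowed
  m <- flux_map("R1", list(st(A = -1, B = 1)), NA_real_)
  expect_true(is.na(m$flux))
})

test_that("round-trip parse -> write -> parse is the identity", {
  for (net in c("chain5", "core")) {
    m <- sample_steady_state_fluxes(toy_network(net), seed = 4)
    # include an absent value to exercise NA encoding
    m$flux[2] <- NA
    path <- write_fixture_tsv(m)
    m2 <- parse_flux_table(path, name = m$name)
    expect_equal(m2$id, m$id)
    expect_equal(m2$stoich, m$stoich)
    expect_equal(m2$flux, m$flux, tolerance = 1e-12)
    expect_equal(m2$ec, m$ec)
    expect_equal(m2$reversible, m$reversible)
    # and a second cycle is byte-identical
    path2 <- write_fixture_tsv(m2)
    expect_identical(readLines(path), readLines(path2))
  }
})

test_that("JSON serialization round-trips a flux map", {
  m <- sample_steady_state_fluxes(toy_network("chain5"), seed = 1)
  m$flux[3] <- NA
  m$metadata <- list(strain = "toy", carbon_source = "glucose")
  js <- flux_map_to_json(m)
  m2 <- flux_map_from_json(js)
  expect_equal(m2$id, m$id)
  expect_equal(m2$stoich, m$stoich)
  expect_equal(m2$flux, m$flux)
  expect_equal(m2$metadata$strain, "toy")
})

test_that("Excel workbooks are ingested through the same validation path", {
  py <- Sys.which("python")
  expect_true(nzchar(py))
  xl <- tempfile(fileext = ".xlsx")
  code <- paste0(
    "import openpyxl\n",
    "wb = openpyxl.Workbook(); ws = wb.active; ws.title = 'case1'\n",
    "rows = [['id','ec','equation','flux','compartment'],\n",
    " ['unknown_feed','','=> A','100',''],\n",
    " ['R90001','1.1.1.1','A => B','50','cytosol'],\n",
    " ['R90002','2.7.1.1','A => C','50',''],\n",
    " ['transport_B','','B =>','50',''],\n",
    " ['transport_C','','C =>','50','']]\n",
    "for r in rows: ws.append(r)\n",
    "for row in ws.iter_rows():\n",
    "    for c in row:\n",
    "        if isinstance(c.value, str) and c.value.startswith('='):\n",
    "            c.data_type = 's'\n",
    "wb.save('", xl, "')\n")
  writeLines(code, f <- tempfile(fileext = ".py"))
  expect_equal(system2(py, f, stdout = FALSE, stderr = FALSE), 0L)
  m <- parse_flux_table(xl, dialect = "xlsx")
  expect_equal(n_reactions(m), 5)
  expect_equal(m$substrate_ids, "unknown_feed")
  expect_equal(m$flux, c(100, 50, 50, 50, 50))
  expect_equal(unclass(m$ec[[2]]), c(1L, 1L, 1L, 1L))
})

test_that("stoichiometric matrix matches hand-built columns", {
  m1 <- flux_map("R1", list(st(A = -1, B = 1)), 1)
  expect_equal(build_stoich_matrix(m1),
               matrix(c(-1, 1), 2, 1, dimnames = list(c("A", "B"), "R1")))
  m2 <- flux_map("R2", list(st(A = -2, B = 1)), 1)
  expect_equal(as.numeric(build_stoich_matrix(m2)), c(-2, 1))

  # hand-built matrix for the 5-reaction chain fixture
  m <- toy_network("chain5")$map
  S <- build_stoich_matrix(m)
  H <- matrix(0, 4, 5, dimnames = list(c("A", "B", "C", "D"), m$id))
  H["A", 1] <- 1
  H["A", 2] <- -1; H["B", 2] <- 1
  H["B", 3] <- -1; H["C", 3] <- 1
  H["C", 4] <- -1; H["D", 4] <- 1
  H["D", 5] <- -1
  expect_equal(S, H)
})

test_that("stoichiometric matrix is invariant under metabolite-row frames", {
  m <- sample_steady_state_fluxes(toy_network("core"), seed = 2)
  S <- build_stoich_matrix(m)
  perm <- sample(rownames(S))
  S2 <- build_stoich_matrix(m, metabolites = perm)
  expect_equal(S2[rownames(S), ], S)
})

test_that("normalization sets total substrate uptake to 100", {
  m <- flux_map(c("unknown_feed", "R1", "transport_B"),
                list(st(A = 1), st(A = -1, B = 1), st(B = -1)),
                c(5, 2.5, 2.5), substrate_ids = "unknown_feed")
  n <- normalize_fluxes(m)
  expect_equal(n$flux, c(100, 50, 50))

  n2 <- normalize_fluxes(two_substrate_map())
  expect_equal(n2$flux[1:2], c(60, 40))
  expect_equal(sum(n2$flux[1:2]), 100)

  z <- with_fluxes(m, c(0, 0, 0))
  expect_error(normalize_fluxes(z), "cannot normalize")
})

test_that("normalization is idempotent and keeps absent values absent", {
  m <- two_substrate_map()
  m$flux[3] <- NA
  n1 <- normalize_fluxes(m)
  n2 <- normalize_fluxes(n1)
  expect_equal(n1$flux, n2$flux, tolerance = 1e-9)
  expect_true(is.na(n1$flux[3]))
})

test_that("shared reaction set is a sorted, flux-aware intersection", {
  p <- shared_flux_pair()
  expect_equal(shared_reaction_set(p$a, p$a), sort(p$a$id))

  # disjoint maps share nothing and the vector comparison refuses them
  q <- chain_map(2, name = "other")
  q$id <- c("unknown_other", "R97001", "R97002", "transport_X")
  q$substrate_ids <- "unknown_other"
  q <- validate_flux_map(q)
  expect_length(shared_reaction_set(p$a, q), 0)
  expect_error(vector_similarity(p$a, q), "shared")

  # absent flux removes a reaction from the shared set; ids case-fold
  b <- p$b
  b$id[2] <- tolower(b$id[2])
  b$flux[1] <- NA
  expect_equal(shared_reaction_set(p$a, b), c("R95002", "R95003"))
})
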