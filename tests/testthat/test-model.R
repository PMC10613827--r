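test_that("coefficient matrix matches hand assembly for one transfer", {
  m <- two_compartment_model(rate = 3, decay = 0)
  A <- assemble_matrix(m)$matrix
  expect_equal(unname(A), matrix(c(-3, 3, 0, 0), 2, 2))
  expect_equal(unname(colSums(A)), c(0, 0))
})

test_that("column sums equal minus the decay constant", {
  m <- two_compartment_model(rate = 3, decay = 0.1)
  A <- assemble_matrix(m)$matrix
  expect_equal(unname(A), matrix(c(-3.1, 3, 0, -0.1), 2, 2))
  expect_equal(unname(colSums(A)), c(-0.1, -0.1))

  # holds for any single-nuclide model that represents all sinks
  toy <- toy_respiratory_model(decay_constant = 0.05)
  At <- assemble_matrix(toy)$matrix
  expect_equal(unname(colSums(At)), rep(-0.05, ncol(At)))
})

test_that("two-member chain matches the brute-force assembly oracle", {
  m <- biokinetic_model(
    compartments = data.frame(id = c("a", "b")),
    transfers = data.frame(donor = c("a", "a"), receiver = c("b", "b"),
                           rate = c(2, 0.5), nuclide = c("par", "chi")),
    nuclides = data.frame(name = c("par", "chi"),
                          decay_constant = c(0.3, 0.07)),
    branchings = data.frame(parent = "par", child = "chi", fraction = 1),
    initial_state = data.frame(nuclide = "par", compartment = "a",
                               value = 1))
  for (mode in c("parent", "progeny")) {
    A <- assemble_matrix(m, ingrowth = mode)$matrix
    expect_equal(unname(A), brute_force_assembly(m, ingrowth = mode),
                 info = mode)
    # chain ordering makes cross-member coupling strictly below-diagonal
    expect_true(all(A[1:2, 3:4] == 0))
  }
})

test_that("off-diagonals are non-negative and eigenvalues dissipative", {
  for (seed in 1:5) {
    m <- generate_stiff_model(8, 6, seed = seed)
    A <- assemble_matrix(m)$matrix
    offdiag <- A - diag(diag(A))
    expect_true(all(offdiag >= 0))
    expect_true(all(Re(eigen(A, only.values = TRUE)$values) <=
                      1e-8 * max(abs(diag(A)))))
  }
})

test_that("assembly is permutation-equivariant in compartment order", {
  set.seed(11)
  for (rep in 1:5) {
    m <- generate_stiff_model(7, 4, seed = rep + 20)
    A <- assemble_matrix(m)$matrix
    perm <- sample(nrow(m$compartments))
    m2 <- m
    m2$compartments <- m$compartments[perm, ]
    A2 <- assemble_matrix(m2)$matrix
    expect_equal(unname(A2), unname(A[perm, perm]))
  }
})

test_that("duplicate transfer entries are summed with a warning", {
  m <- biokinetic_model(
    compartments = data.frame(id = c("a", "b")),
    transfers = data.frame(donor = c("a", "a"), receiver = c("b", "b"),
                           rate = c(1, 2)),
    nuclides = data.frame(name = "n", decay_constant = 0))
  expect_warning(A <- assemble_matrix(m)$matrix, "summed")
  expect_equal(A[2, 1], 3)
})

test_that("validate_model returns named violations, not errors", {
  m <- two_compartment_model()
  expect_identical(validate_model(m), character(0))

  m$transfers$rate <- -1
  v <- validate_model(m)
  expect_length(v, 1L)
  expect_match(v, "a -> b")
  expect_match(v, "non-negative")

  m <- two_compartment_model()
  m$transfers$receiver <- "X"
  v <- validate_model(m)
  expect_length(v, 1L)
  expect_match(v, "unknown receiver compartment 'X'")

  expect_identical(validate_model(toy_respiratory_model()), character(0))
})

test_that("non-topological chain order is a violation", {
  m <- serial_chain_model(c(0.2, 0.1))
  m$branchings <- data.frame(parent = "member2", child = "member1",
                             fraction = 1)
  expect_match(validate_model(m), "not topological", all = FALSE)
})

test_that("disjoint coupling gives a block-diagonal matrix", {
  a <- two_compartment_model(rate = 3)
  b <- two_compartment_model(rate = 7)
  m <- couple_models(list(p1 = a, p2 = b))
  expect_equal(nrow(m$compartments), 4L)
  A <- assemble_matrix(m)$matrix
  expect_equal(unname(A[1:2, 3:4]), matrix(0, 2, 2))
  expect_equal(unname(A[3:4, 1:2]), matrix(0, 2, 2))
  expect_equal(A[2, 1], 3)
  expect_equal(A[4, 3], 7)
})

test_that("a link transfer adds exactly one off-diagonal entry", {
  hrtm <- biokinetic_model(
    compartments = data.frame(id = c("AL", "Oes_S")),
    transfers = data.frame(donor = "AL", receiver = "Oes_S", rate = 2),
    nuclides = data.frame(name = "n", decay_constant = 0))
  alim <- biokinetic_model(
    compartments = data.frame(id = c("Stomach_contents", "Faeces"),
                              region = c("alimentary", "excreta")),
    transfers = data.frame(donor = "Stomach_contents", receiver = "Faeces",
                           rate = 1),
    nuclides = data.frame(name = "n", decay_constant = 0))
  base <- couple_models(list(rt = hrtm, at = alim))
  linked <- couple_models(
    list(rt = hrtm, at = alim),
    links = data.frame(donor = "rt.Oes_S", receiver = "at.Stomach_contents",
                       rate = 12.3, nuclide = "n"))
  A0 <- assemble_matrix(base)$matrix
  A1 <- assemble_matrix(linked)$matrix
  d <- A1 - A0
  offdiag_changes <- which(d != 0 & row(d) != col(d))
  expect_length(offdiag_changes, 1L)
  expect_equal(d[cbind(3, 2)], 12.3)   # Stomach_contents row, Oes_S column
  expect_equal(d[2, 2], -12.3)         # donor loses what the link carries
})

test_that("coupling with duplicate compartment ids errors", {
  a <- two_compartment_model()
  expect_error(couple_models(list(a, a)), "duplicate compartment id")
  expect_error(
    couple_models(list(p1 = a, p2 = a),
                  links = data.frame(donor = "p1.b", receiver = "p2.a",
                                     rate = -2)),
    "non-negative")
})
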