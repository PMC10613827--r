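test_that("Pade coefficients reduce to the scalar (1,1) form", {
  b <- 0.3
  p <- pade_rational(matrix(b), 1, 1)
  expect_equal(p$N[1, 1], 1 + b / 2)
  expect_equal(p$D[1, 1], 1 - b / 2)
  expect_equal(p$ratio[1, 1], (1 + b / 2) / (1 - b / 2))
})

test_that("Pade of the zero matrix is the identity", {
  for (deg in list(c(1, 1), c(3, 5), c(13, 13))) {
    p <- pade_rational(matrix(0, 3, 3), deg[1], deg[2])
    expect_equal(p$N, diag(3))
    expect_equal(p$D, diag(3))
    expect_equal(p$ratio, diag(3))
  }
})

test_that("diagonal Pade matches the truncated power series on small norms", {
  series_expm <- function(B, terms = 40) {
    # independent oracle: straight truncation of the defining power series
    acc <- diag(nrow(B))
    term <- diag(nrow(B))
    for (i in seq_len(terms)) {
      term <- term %*% B / i
      acc <- acc + term
    }
    acc
  }
  set.seed(4)
  for (rep in 1:10) {
    B <- random_metzler(4)
    B <- B * (0.5 / norm(B, "1"))
    R <- pade_rational(B, 6, 6)$ratio
    expect_lt(norm(R - series_expm(B), "1"), 1e-12)
    expect_lt(norm(expm_matrix(B) - series_expm(B), "1"), 1e-12)
  }
})

test_that("expm_matrix handles the exact special cases", {
  expect_equal(expm_matrix(matrix(0, 3, 3)), diag(3))
  expect_equal(expm_matrix(diag(c(-1, -2))), diag(c(exp(-1), exp(-2))))
  # nilpotent: the series terminates exactly
  N <- matrix(c(0, 0, 1, 0), 2, 2)
  expect_equal(expm_matrix(N), matrix(c(1, 0, 1, 1), 2, 2))
})

test_that("expm_matrix agrees with an independent implementation", {
  skip_if_not_installed("Matrix")
  set.seed(9)
  for (rep in 1:5) {
    A <- random_metzler(6, scale = 10^runif(1, -1, 2))
    E1 <- expm_matrix(A)
    E2 <- as.matrix(Matrix::expm(Matrix::Matrix(A)))
    expect_lt(norm(E1 - E2, "1") / norm(E2, "1"), 1e-12)
  }
})

test_that("expm_matrix rejects non-finite input", {
  expect_error(expm_matrix(matrix(c(1, NA, 0, 1), 2, 2)), "non-finite")
})

test_that("propagation is exact for scalar decay and constant for A = 0", {
  grid <- default_grid(n = 50)
  m0 <- biokinetic_model(
    compartments = data.frame(id = "a"), transfers = NULL,
    nuclides = data.frame(name = "n", decay_constant = 0),
    initial_state = data.frame(nuclide = "n", compartment = "a", value = 1))
  expect_equal(unname(propagate(m0, grid = grid)$values[, 1]),
               rep(1, length(grid)))

  m1 <- biokinetic_model(
    compartments = data.frame(id = "a"), transfers = NULL,
    nuclides = data.frame(name = "n", decay_constant = 0.1),
    initial_state = data.frame(nuclide = "n", compartment = "a", value = 1))
  sol <- propagate(m1, grid = grid)
  expect_lt(max_rel_err(sol$values[, 1], exp(-0.1 * grid)), 1e-12)
})

test_that("propagate agrees with a tight implicit integration oracle", {
  toy <- toy_respiratory_model()
  grid <- default_grid(n = 120)
  sol <- propagate(toy, grid = grid)
  # independent route: adaptive Radau IIA at tight tolerance
  cm <- assemble_matrix(toy)
  A <- cm$matrix
  out <- deSolve::radau(y = initial_state_vector(toy, cm), times = grid,
                        func = function(t, y, p) list(as.vector(A %*% y)),
                        parms = NULL, rtol = 1e-12, atol = 1e-18,
                        jacfunc = function(t, y, p) A, jactype = "fullusr")
  ref <- out[, -1, drop = FALSE]
  # the comparison floor sits where the adaptive oracle itself still holds
  # 1e-6 relative accuracy (its absolute-tolerance floor dominates below)
  keep <- ref > 1e-10
  expect_lt(max(abs(sol$values[keep] - ref[keep]) / ref[keep]), 1e-6)
})

test_that("the propagator satisfies the semigroup property", {
  set.seed(21)
  for (rep in 1:5) {
    A <- random_metzler(5, scale = 2)
    y0 <- runif(5)
    t1 <- runif(1, 0.1, 2)
    t2 <- runif(1, 0.1, 2)
    one_shot <- expm_matrix(A * (t1 + t2)) %*% y0
    two_step <- expm_matrix(A * t2) %*% (expm_matrix(A * t1) %*% y0)
    expect_lt(max(abs(one_shot - two_step)) / max(abs(one_shot)), 1e-10)
  }
})

test_that("total propagated activity decays exactly as exp(-lambda t)", {
  lam <- 3.6e-4
  toy <- toy_respiratory_model(decay_constant = lam)
  grid <- default_grid(n = 100)
  sol <- propagate(toy, grid = grid)
  total <- rowSums(sol$values)
  expect_lt(max_rel_err(total, exp(-lam * grid)), 1e-10)
})

test_that("Metzler propagation keeps states non-negative without clipping", {
  for (seed in 1:3) {
    m <- generate_stiff_model(9, 8, seed = seed)
    sol <- propagate(m, grid = default_grid(n = 80))
    expect_true(all(sol$values >= 0))
    expect_identical(sol$n_clipped, 0L)
  }
})

test_that("propagate validates its grid", {
  m <- two_compartment_model()
  expect_error(propagate(m, grid = c(0, 2, 1)), "strictly increasing")
  expect_error(propagate(m, grid = c(1, 2, 3)), "start at 0")
})
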