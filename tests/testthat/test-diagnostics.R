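test_that("stiffness ratio of a diagonal matrix is the magnitude spread", {
  sr <- stiffness_ratio(diag(c(-1e3, -1e-3)))
  expect_equal(sr$stiffness_ratio, 1e6)
  expect_equal(sr$diag_bound, 1e6)
  expect_equal(sr$n_discarded, 0L)
})

test_that("zero eigenvalues are discarded before forming the ratio", {
  # closed 2-compartment exchange: eigenvalues 0 and -(a+b)
  a <- 2; b <- 0.5
  A <- matrix(c(-a, a, b, -b), 2, 2)
  sr <- stiffness_ratio(A)
  expect_equal(sr$n_discarded, 1L)
  expect_equal(sr$stiffness_ratio, 1)
  expect_equal(sr$lambda_L, a + b)

  # all eigenvalues discarded -> diagnostic error
  expect_error(stiffness_ratio(matrix(0, 2, 2)), "all eigenvalues discarded")
})

test_that("diag_bound <= SR holds on generated fixtures (reported, not forced)", {
  for (seed in 1:5) {
    m <- generate_stiff_model(8, 6, seed = seed)
    sr <- stiffness_ratio(assemble_matrix(m))
    expect_gte(sr$stiffness_ratio, 1)
    expect_gte(sr$diag_bound, 1)
    # weakly-coupled log-spread fixtures: eigenvalues track the loss terms
    expect_gt(sr$stiffness_ratio, sr$diag_bound / 100)
  }
})

test_that("amplification factors follow the per-step ratio definition", {
  expect_equal(amplification_factor(c(1, 1, 1))$values, c(1, 1))
  g <- amplification_factor(2 * 0.5^(0:5))
  expect_equal(g$values, rep(0.5, 5))
  # numerically-zero denominators are masked
  masked <- amplification_factor(c(1, 0, 1e-45), floor = 1e-30)
  expect_false(masked$mask[1])
  expect_true(masked$mask[2])
  expect_true(is.na(masked$values[2]))
  expect_error(amplification_factor(1), "at least 2 points")
})

test_that("exact decay gives max G below 1 and grade None", {
  lam <- 0.05
  m <- biokinetic_model(
    compartments = data.frame(id = "a"), transfers = NULL,
    nuclides = data.frame(name = "n", decay_constant = lam),
    initial_state = data.frame(nuclide = "n", compartment = "a", value = 1))
  grid <- seq(0, 100, by = 2)
  sol <- propagate(m, grid = grid)
  ss <- stability_summary(sol)
  expect_equal(unname(ss$per_group_max_G["whole_body"]),
               exp(-lam * 2), tolerance = 1e-12)
  expect_equal(ss$divergence_grade, "None")
})

test_that("negativity and oscillatory divergence are graded as specified", {
  fake_sol <- function(q) new_retention_solution(
    seq_along(q) - 1, matrix(q, ncol = 1, dimnames = list(NULL, "wb")),
    data.frame(nuclide = "n", compartment = "wb", index = 1,
               in_body = TRUE))

  # mild negativity within 1e3*atol: Moderate
  ss <- stability_summary(fake_sol(c(1, 0.5, -2e-5, 1e-5, 5e-6)),
                          atol = 1e-6)
  expect_true(ss$flags$negative[1])
  expect_equal(ss$divergence_grade, "Moderate")

  # deep negativity: High
  ss2 <- stability_summary(fake_sol(c(1, 0.9, -0.01, 0.5)), atol = 1e-6)
  expect_equal(ss2$divergence_grade, "High")

  # sign-alternating growth: oscillatory + divergent, High
  q <- (-15)^(0:5)
  ss3 <- stability_summary(fake_sol(q), atol = 1e-6)
  expect_true(ss3$flags$oscillatory[1])
  expect_true(ss3$flags$divergent[1])
  expect_equal(ss3$divergence_grade, "High")
})

test_that("propagator output on Metzler fixtures always grades None", {
  for (seed in 1:4) {
    m <- generate_stiff_model(9, 8, seed = seed)
    sol <- propagate(m, grid = default_grid(n = 60))
    expect_equal(stability_summary(sol)$divergence_grade, "None",
                 info = paste("seed", seed))
  }
})

test_that("whole-body G of an exact dissipative solution never exceeds 1", {
  toy <- toy_respiratory_model(decay_constant = 1e-3)
  sol <- propagate(toy, grid = default_grid(n = 100))
  wb <- aggregate_retention(sol)$values[, "whole_body"]
  g <- amplification_factor(wb)
  expect_true(all(g$values[!g$mask] <= 1 + 1e-12))
})

test_that("relative differences follow the test-vs-reference convention", {
  expect_equal(relative_difference(1.1, 1.0)$values[1, 1], 10)
  x <- matrix(runif(12), 4, 3)
  expect_true(all(relative_difference(x, x)$values == 0))
  # masking below the reference floor
  rd <- relative_difference(1e-38, 1e-40, floor = 1e-30)
  expect_true(rd$mask[1, 1])
  expect_true(is.na(rd$values[1, 1]))
  # antisymmetric sign under swap of ordering
  a <- matrix(2); b <- matrix(1)
  expect_gt(relative_difference(a, b)$values[1, 1], 0)
  expect_lt(relative_difference(b, a)$values[1, 1], 0)
})

test_that("relative_difference requires matching grids", {
  m <- two_compartment_model()
  s1 <- propagate(m, grid = c(0, 1, 2))
  s2 <- propagate(m, grid = c(0, 1, 3))
  expect_error(relative_difference(s1, s2), "same time grid")
})

test_that("grouped retention respects conservation", {
  toy <- toy_respiratory_model()           # no decay: closed total
  grid <- default_grid(n = 80)
  sol <- propagate(toy, grid = grid)
  agg <- aggregate_retention(sol, groups = list(
    excreta = c("FAECES", "URINE")))
  total <- agg$values[, "whole_body"] + agg$values[, "excreta"]
  expect_lt(max(abs(total - 1)), 1e-10)

  lam <- 0.01
  toy_d <- toy_respiratory_model(decay_constant = lam)
  sol_d <- propagate(toy_d, grid = grid)
  agg_d <- aggregate_retention(sol_d, groups = list(
    excreta = c("FAECES", "URINE")))
  total_d <- agg_d$values[, "whole_body"] + agg_d$values[, "excreta"]
  expect_lt(max_rel_err(total_d, exp(-lam * grid)), 1e-10)

  # singleton group is the identity on that series
  agg_s <- aggregate_retention(sol, groups = list(blood = "BLOOD"))
  expect_equal(unname(agg_s$values[, "blood"]),
               unname(sol$values[, "toy_nuclide:BLOOD"]))
})

test_that("group configuration errors are caught", {
  sol <- propagate(two_compartment_model(), grid = c(0, 1, 2))
  expect_error(aggregate_retention(sol, groups = list(g = "nope")),
               "unknown compartment")
  expect_error(aggregate_retention(sol, groups = list(g = character())),
               "empty")
})
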