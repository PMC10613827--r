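#' (p, q) Pade approximant of the matrix exponential
#'
#' Evaluates the numerator and denominator matrix polynomials of the rational
#' approximation `R_pq(B) = N_pq(B) / D_pq(B)` to `exp(B)`,
#' \deqn{N_{pq}(B) = \sum_{j=0}^{p} \frac{(p+q-j)!\,p!}{(p+q)!\,j!\,(p-j)!} B^j,
#' \qquad
#' D_{pq}(B) = \sum_{j=0}^{q} \frac{(p+q-j)!\,q!}{(p+q)!\,j!\,(q-j)!} (-B)^j.}
#' Coefficients are generated by the exact ratio recurrence
#' `c_j / c_{j-1} = (p - j + 1) / ((p + q - j + 1) j)` so no large factorial
#' is ever formed.  The diagonal case (p = q) is the one used by
#' [expm_matrix()]; the general case is exposed for study.
#'
#' @param B square numeric matrix.
#' @param p,q non-negative integer degrees of numerator and denominator.
#' @return Object of class `pade_approximant`: list with `p`, `q`, `N` and
#'   `D` (the evaluated matrix polynomials) and `ratio` (`solve(D, N)`).
#' @export
pade_rational <- function(B, p, q) {
  B <- as.matrix(B)
  stopifnot(nrow(B) == ncol(B), p >= 0, q >= 0,
            p == as.integer(p), q == as.integer(q))
  if (!all(is.finite(B))) stop("input error: non-finite matrix entries",
                               call. = FALSE)
  n <- nrow(B)
  I <- diag(1, n)
  poly <- function(deg, other_deg, X) {
    # c_0 = 1; c_j = c_{j-1} * (deg - j + 1) / ((deg + other_deg - j + 1) j)
    acc <- I
    term <- I
    cj <- 1
    if (deg >= 1L) for (j in seq_len(deg)) {
      cj <- cj * (deg - j + 1) / ((deg + other_deg - j + 1) * j)
      term <- term %*% X
      acc <- acc + cj * term
    }
    acc
  }
  Npq <- poly(p, q, B)
  Dpq <- poly(q, p, -B)
  ratio <- tryCatch(solve(Dpq, Npq), error = function(e)
    stop("approximation error: singular Pade denominator; ",
         "the input needs more scaling", call. = FALSE))
  structure(list(p = as.integer(p), q = as.integer(q),
                 N = Npq, D = Dpq, ratio = ratio),
            class = "pade_approximant")
}

# 1-norm acceptance thresholds for the diagonal Pade orders used by the
# scaling-and-squaring ladder (standard double-precision values).
.pade_theta <- c(`3` = 1.495585217958292e-2,
                 `5` = 2.539398330063230e-1,
                 `7` = 9.504178996162932e-1,
                 `9` = 2.097847961257068,
                 `13` = 5.371920351148152)

#' Matrix exponential by Pade scaling and squaring
#'
#' Computes `exp(A)` with the classic scaling-and-squaring scheme: pick the
#' smallest diagonal Pade order in \{3, 5, 7, 9, 13\} whose 1-norm acceptance
#' threshold covers `norm(A, "1")`; if even order 13 does not, scale
#' `A / 2^s` until it does, apply the order-13 approximant, and square the
#' result `s` times.  The rational ratio is formed by LU solve of the
#' denominator, never by explicit inversion.  Eigen-decomposition is
#' deliberately not used: it degenerates for the near-defective,
#' non-symmetric matrices that compartmental models with similar consecutive
#' rates produce.
#'
#' @param A square numeric matrix with finite entries.
#' @param s_extra non-negative integer: extra scaling-and-squaring steps
#'   beyond the norm criterion, for tightened reference evaluations.
#' @return Matrix `exp(A)` of the same dimension.
#' @examples
#' expm_matrix(diag(c(-1, -2)))      # diag(exp(-1), exp(-2))
#' @export
expm_matrix <- function(A, s_extra = 0L) {
  A <- as.matrix(A)
  stopifnot(nrow(A) == ncol(A), s_extra >= 0)
  if (!all(is.finite(A))) stop("input error: non-finite matrix entries",
                               call. = FALSE)
  nrmA <- norm(A, "1")
  if (nrmA == 0) return(diag(1, nrow(A)))
  orders <- as.integer(names(.pade_theta))
  fit <- which(nrmA <= .pade_theta)
  if (length(fit) && s_extra == 0L) {
    m <- orders[fit[1L]]
    s <- 0L
  } else {
    m <- 13L
    s <- max(0, ceiling(log2(nrmA / .pade_theta[["13"]]))) + as.integer(s_extra)
  }
  B <- if (s > 0L) A / 2^s else A
  E <- pade_rational(B, m, m)$ratio
  if (s > 0L) for (k in seq_len(s)) E <- E %*% E
  E
}

#' Propagate a biokinetic model with the matrix exponential
#'
#' Advances the linear system over an output grid by the recurrence
#' `y_{n+1} = exp(A dt_n) y_n`, caching the step exponential for every
#' distinct step length so log-spaced and uniform grids alike cost one Pade
#' evaluation per distinct `dt`.  This is the semi-analytical route: exact to
#' rounding, independent of stiffness, and used as the reference surface for
#' all integrator comparisons.  Tiny negative entries (roundoff below
#' `clip_tol` in magnitude) are clipped to zero; the clip count is recorded.
#'
#' @param cm a `coefficient_matrix` from [assemble_matrix()], or a
#'   [biokinetic_model()] (assembled on the fly).
#' @param y0 initial state: named numeric vector in matrix ordering, or
#'   `NULL` to use the model's initial-state table (model input only).
#' @param grid numeric vector of output times in days, strictly increasing,
#'   starting at 0.
#' @param clip_tol magnitude below which negative entries are clipped to 0.
#' @param s_extra passed to [expm_matrix()] for tightened evaluations.
#' @return Object of class `retention_solution`: list with `times`, `values`
#'   (length(grid) x N matrix, columns `"nuclide:compartment"`), `index_map`,
#'   `n_clipped`, and `method = "expm"`.
#' @export
propagate <- function(cm, y0 = NULL, grid, clip_tol = 1e-12, s_extra = 0L) {
  if (inherits(cm, "biokinetic_model")) {
    model <- cm
    cm <- assemble_matrix(model)
    if (is.null(y0)) y0 <- initial_state_vector(model, cm)
  }
  stopifnot(inherits(cm, "coefficient_matrix"))
  if (is.null(y0)) stop("y0 is required when propagating a bare matrix",
                        call. = FALSE)
  check_grid(grid)
  A <- cm$matrix
  stopifnot(length(y0) == nrow(A))

  dts <- diff(grid)
  cache <- new.env(parent = emptyenv())
  values <- matrix(0, length(grid), length(y0),
                   dimnames = list(NULL, colnames(A)))
  values[1L, ] <- y0
  y <- y0
  n_clipped <- 0L
  for (n in seq_along(dts)) {
    key <- sprintf("%.17g", dts[n])
    E <- cache[[key]]
    if (is.null(E)) {
      E <- expm_matrix(A * dts[n], s_extra = s_extra)
      cache[[key]] <- E
    }
    y <- drop(E %*% y)
    neg <- y < 0
    if (any(neg)) {
      if (any(y < -clip_tol))
        warning("propagated state below -clip_tol (min ", min(y),
                "); clipping", call. = FALSE)
      n_clipped <- n_clipped + sum(neg)
      y[neg] <- 0
    }
    values[n + 1L, ] <- y
  }
  new_retention_solution(grid, values, cm$index_map, method = "expm",
                         n_clipped = n_clipped)
}

check_grid <- function(grid) {
  if (!is.numeric(grid) || length(grid) < 2L || any(!is.finite(grid)))
    stop("input error: grid must be a finite numeric vector of length >= 2",
         call. = FALSE)
  if (grid[1L] != 0)
    stop("input error: grid must start at 0", call. = FALSE)
  if (any(diff(grid) <= 0))
    stop("input error: grid must be strictly increasing", call. = FALSE)
  invisible(grid)
}

new_retention_solution <- function(times, values, index_map,
                                   method = "expm", n_clipped = 0L,
                                   grouped = FALSE) {
  structure(list(times = times, values = values, index_map = index_map,
                 method = method, n_clipped = n_clipped, grouped = grouped),
            class = "retention_solution")
}

#' @export
print.retention_solution <- function(x, ...) {
  cat("<retention_solution> ", length(x$times), " time points x ",
      ncol(x$values), if (x$grouped) " groups" else " states",
      " (method ", x$method, ")\n", sep = "")
  cat(sprintf("  t in [%g, %g] d\n", min(x$times), max(x$times)))
  if (x$n_clipped > 0)
    cat("  ", x$n_clipped, " tiny negative value(s) clipped to 0\n", sep = "")
  invisible(x)
}

#' Default log-spaced output grid
#'
#' t = 0 followed by `n` log-spaced points from `from` to `to` days.  The
#' default horizon is 50 years at 365.25 d/y; the default resolution
#' resolves both fast early clearance (hundredths of a day) and slow
#' late-phase retention.
#'
#' @param from,to first and last positive times (days).
#' @param n number of positive points.
#' @return Numeric grid of length `n + 1` starting at 0.
#' @export
default_grid <- function(from = 1e-2, to = 50 * 365.25, n = 600L) {
  c(0, exp(seq(log(from), log(to), length.out = n)))
}
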