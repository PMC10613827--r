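#' Solver configuration profile
#'
#' Bundles an adaptive-integrator method name with its error-control
#' settings.  Methods span the explicit Runge-Kutta pairs (RK45 =
#' Dormand-Prince 5(4), RK23 = Bogacki-Shampine 3(2), DOP853 = the
#' order-8(7) Dormand-Prince pair), the implicit stiff methods (Radau =
#' Radau IIA order 5, BDF = variable-order 1-5 backward differentiation),
#' and LSODA (automatic Adams/BDF switching).
#'
#' @param method one of `"RK45"`, `"RK23"`, `"DOP853"`, `"Radau"`, `"BDF"`,
#'   `"LSODA"`.
#' @param rtol,atol relative and absolute local error tolerances (> 0).
#' @param max_step maximum step size in days (`Inf` = unbounded).
#' @param label profile name carried into reports.
#' @return Object of class `solver_profile`.
#' @export
solver_profile <- function(method = c("RK45", "RK23", "DOP853",
                                      "Radau", "BDF", "LSODA"),
                           rtol = 1e-3, atol = 1e-6, max_step = Inf,
                           label = "default") {
  method <- match.arg(method)
  if (!is.numeric(rtol) || rtol <= 0 || !is.numeric(atol) || atol <= 0)
    stop("configuration error: rtol and atol must be positive",
         call. = FALSE)
  if (!is.numeric(max_step) || max_step <= 0)
    stop("configuration error: max_step must be positive (Inf = unbounded)",
         call. = FALSE)
  structure(list(method = method, rtol = rtol, atol = atol,
                 max_step = max_step, label = label),
            class = "solver_profile")
}

#' @export
print.solver_profile <- function(x, ...) {
  cat(sprintf("<solver_profile> %s-%s: rtol %g, atol %g, max_step %s\n",
              x$method, x$label, x$rtol, x$atol,
              if (is.finite(x$max_step)) format(x$max_step) else "unbounded"))
  invisible(x)
}

#' Standard tolerance/step protocols
#'
#' The three configuration protocols exercised throughout the package, for a
#' given method:
#' * `"default"` — the integrator's stock error control, rtol 1e-3 and
#'   atol 1e-6, steps chosen freely;
#' * `"customized"` — strict local error control, rtol 1e-12 and atol 1e-15;
#' * `"customized2"` — `customized` plus a maximum step size of 0.2 d, the
#'   last-resort bound needed by the stiffest fast-clearing scenarios.
#'
#' @param method method name applied to every profile (default `"RK45"`, the
#'   stock choice of general-purpose IVP front ends).
#' @return Named list of [solver_profile()]s with names `default`,
#'   `customized`, `customized2`.
#' @export
standard_profiles <- function(method = "RK45") {
  list(
    default = solver_profile(method, rtol = 1e-3, atol = 1e-6,
                             label = "default"),
    customized = solver_profile(method, rtol = 1e-12, atol = 1e-15,
                                label = "customized"),
    customized2 = solver_profile(method, rtol = 1e-12, atol = 1e-15,
                                 max_step = 0.2, label = "customized2")
  )
}

#' Look up a standard profile by label
#'
#' @param label one of `"default"`, `"customized"`, `"customized2"`.
#' @param method method name for the returned profile.
#' @return A [solver_profile()].
#' @export
lookup_profile <- function(label, method = "RK45") {
  p <- standard_profiles(method)
  if (!label %in% names(p))
    stop("configuration error: unknown profile label '", label,
         "' (expected default, customized, customized2)", call. = FALSE)
  p[[label]]
}

.desolve_rk <- c(RK45 = "rk45dp7", RK23 = "rk23bs", DOP853 = "rk78dp")

#' Integrate a biokinetic model with an adaptive ODE solver
#'
#' Runs one configured integrator over the requested output grid.  The
#' right-hand side is the assembled-coefficient-matrix product `A y`; for
#' the implicit methods the constant matrix is also supplied as the analytic
#' Jacobian unless `jacobian = "fd"` asks for the integrator's
#' finite-difference approximation.  Integrator failure (step-count cap
#' exceeded, non-finite states, truncated output) is reported through
#' `success = FALSE` and a partial solution, never as an exception, so that
#' divergence of explicit methods on stiff systems can itself be diagnosed.
#'
#' @param model a valid [biokinetic_model()].
#' @param grid output times (days), strictly increasing from 0.
#' @param profile a [solver_profile()].
#' @param jacobian `"analytic"` (the assembled matrix; exact for these
#'   linear systems) or `"fd"` (finite differences, the stock behaviour).
#' @param maxsteps step-count cap per output interval, so explicit methods
#'   on stiff systems terminate in bounded time instead of grinding.
#' @param cm optional pre-assembled `coefficient_matrix`.
#' @return Object of class `solver_run`: list with `solution` (a
#'   `retention_solution`, possibly truncated on failure), `success`,
#'   `n_accepted_steps` (NA when unavailable), `wall_time` (seconds,
#'   informational only), `profile`, `message`.
#' @export
integrate_model <- function(model, grid, profile,
                            jacobian = c("analytic", "fd"),
                            maxsteps = 10000L, cm = NULL) {
  jacobian <- match.arg(jacobian)
  stopifnot(inherits(profile, "solver_profile"))
  check_grid(grid)
  if (is.null(cm)) cm <- assemble_matrix(model)
  A <- cm$matrix
  y0 <- initial_state_vector(model, cm)

  rhs <- function(t, y, parms) list(as.vector(A %*% y))
  jac <- function(t, y, parms) A
  hmax <- if (is.finite(profile$max_step)) profile$max_step else NULL

  msgs <- character()
  out <- NULL
  wt <- system.time({
    res <- tryCatch(
      withCallingHandlers({
        if (profile$method %in% names(.desolve_rk)) {
          args <- list(y = y0, times = grid, func = rhs, parms = NULL,
                       method = deSolve::rkMethod(
                         .desolve_rk[[profile$method]]),
                       rtol = profile$rtol, atol = profile$atol,
                       maxsteps = maxsteps)
          if (!is.null(hmax)) args$hmax <- hmax
          do.call(deSolve::ode, args)
        } else if (profile$method == "Radau") {
          args <- list(y = y0, times = grid, func = rhs, parms = NULL,
                       rtol = profile$rtol, atol = profile$atol,
                       maxsteps = maxsteps)
          if (!is.null(hmax)) args$hmax <- hmax
          if (jacobian == "analytic") {
            args$jacfunc <- jac; args$jactype <- "fullusr"
          }
          do.call(deSolve::radau, args)
        } else {
          meth <- if (profile$method == "BDF") "bdf" else "lsoda"
          args <- list(y = y0, times = grid, func = rhs, parms = NULL,
                       method = meth,
                       rtol = profile$rtol, atol = profile$atol,
                       maxsteps = maxsteps)
          if (!is.null(hmax)) args$hmax <- hmax
          if (jacobian == "analytic") {
            args$jacfunc <- jac; args$jactype <- "fullusr"
          }
          do.call(deSolve::ode, args)
        }
      }, warning = function(w) {
        msgs <<- c(msgs, conditionMessage(w))
        invokeRestart("muffleWarning")
      }),
      error = function(e) {
        msgs <<- c(msgs, conditionMessage(e))
        NULL
      })
    out <- res
  })

  n_steps <- NA_integer_
  values <- NULL
  times <- numeric()
  if (!is.null(out)) {
    istate <- attr(out, "istate")
    if (!is.null(istate) && length(istate) >= 3L) n_steps <- istate[3L]
    times <- out[, 1L]
    values <- out[, -1L, drop = FALSE]
    colnames(values) <- colnames(A)
  }
  complete <- !is.null(values) && nrow(values) == length(grid) &&
    all(is.finite(values))
  success <- complete && length(msgs) == 0L

  solution <- NULL
  if (!is.null(values) && nrow(values) >= 2L)
    solution <- new_retention_solution(times, values, cm$index_map,
                                       method = paste0(profile$method, "-",
                                                       profile$label))
  structure(list(solution = solution, success = success,
                 n_accepted_steps = n_steps,
                 wall_time = unname(wt["elapsed"]),
                 profile = profile,
                 message = if (length(msgs))
                   paste(unique(msgs), collapse = "; ") else ""),
            class = "solver_run")
}

#' @export
print.solver_run <- function(x, ...) {
  cat(sprintf("<solver_run> %s-%s: %s (%.3g s%s)\n",
              x$profile$method, x$profile$label,
              if (x$success) "success" else "FAILED",
              x$wall_time,
              if (!is.na(x$n_accepted_steps))
                paste0(", ", x$n_accepted_steps, " steps") else ""))
  if (nzchar(x$message)) cat("  note: ", x$message, "\n", sep = "")
  invisible(x)
}
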