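#' Stiffness ratio of a coefficient matrix
#'
#' Stiffness of the linear system is measured by the spread of the retained
#' eigenvalue magnitudes of the coefficient matrix,
#' `SR = |lambda_L| / |lambda_S|`.  Compartmental matrices routinely carry
#' zero eigenvalues (closed systems, sink compartments), which would make
#' the ratio undefined; eigenvalues with `|lambda| < zero_tol * max|lambda|`
#' or with non-negative real part are therefore discarded and the ratio is
#' formed from the remaining (negative-real-part) spectrum.  The diagonal
#' bound `max_i |A_ii| / min_i |A_ii|` over the non-zero loss terms is
#' reported alongside: it is a cheap surrogate often quoted as a lower bound
#' for SR, but the inequality is not guaranteed for arbitrary compartmental
#' matrices, so the report carries both instead of enforcing it.
#'
#' @param cm a `coefficient_matrix` (or bare square matrix).
#' @param zero_tol relative magnitude threshold for discarding eigenvalues.
#' @return Object of class `stiffness_report`: `eigenvalues` (full complex
#'   spectrum), `lambda_L`, `lambda_S`, `stiffness_ratio`, `diag_bound`,
#'   `n_discarded`.
#' @export
stiffness_ratio <- function(cm, zero_tol = 1e-12) {
  A <- if (inherits(cm, "coefficient_matrix")) cm$matrix else as.matrix(cm)
  stopifnot(nrow(A) == ncol(A))
  ev <- eigen(A, only.values = TRUE)$values
  mags <- Mod(ev)
  keep <- mags >= zero_tol * max(mags) & Re(ev) < 0
  if (!any(keep))
    stop("diagnostic error: all eigenvalues discarded; ",
         "stiffness ratio undefined", call. = FALSE)
  lambda_L <- max(mags[keep])
  lambda_S <- min(mags[keep])
  d <- abs(diag(A))
  d <- d[d >= zero_tol * max(d)]
  diag_bound <- if (length(d)) max(d) / min(d) else NA_real_
  structure(list(eigenvalues = ev, lambda_L = lambda_L,
                 lambda_S = lambda_S,
                 stiffness_ratio = lambda_L / lambda_S,
                 diag_bound = diag_bound,
                 n_discarded = sum(!keep)),
            class = "stiffness_report")
}

#' @export
print.stiffness_report <- function(x, ...) {
  cat(sprintf(paste0("<stiffness_report> SR = %.4g (|lambda| in ",
                     "[%.4g, %.4g], %d discarded); diag bound = %.4g\n"),
              x$stiffness_ratio, x$lambda_S, x$lambda_L, x$n_discarded,
              x$diag_bound))
  invisible(x)
}

#' Numerical amplification factor series
#'
#' The per-step growth factor `G_n = |q_{n+1} / q_n|` of a retention series:
#' the stability criterion for a computed solution is `G <= 1` over time.
#' Steps whose previous value lies below `floor` in magnitude are masked —
#' ratios of values that are numerically zero (integrators emitting exactly
#' 0 next to ~1e-45) carry no stability information.
#'
#' @param q numeric retention series on an ordered grid (length >= 2).
#' @param floor magnitude below which the denominator masks the step.
#' @return Object of class `amplification_series`: `values` (G per step,
#'   NA where masked) and `mask` (logical, TRUE = masked).
#' @export
amplification_factor <- function(q, floor = 1e-30) {
  if (!is.numeric(q) || length(q) < 2L)
    stop("diagnostic error: series must have at least 2 points",
         call. = FALSE)
  prev <- q[-length(q)]
  nxt <- q[-1L]
  mask <- !is.finite(prev) | !is.finite(nxt) | abs(prev) < floor
  g <- rep(NA_real_, length(prev))
  g[!mask] <- abs(nxt[!mask] / prev[!mask])
  structure(list(values = g, mask = mask), class = "amplification_series")
}

#' Aggregate a retention solution over compartment groups
#'
#' Sums the per-state series into named group series (e.g. the region rows
#' of a stability report), always adding a `whole_body` group (sum over all
#' in-body compartments, every chain member) unless the caller supplies one.
#' Groups are given as compartment-id vectors; for multi-nuclide chains the
#' group series sums over all chain members in those compartments.
#'
#' @param sol a `retention_solution` (ungrouped).
#' @param groups named list of compartment-id character vectors; `NULL` for
#'   just `whole_body`.
#' @return A grouped `retention_solution` whose columns are the groups.
#' @export
aggregate_retention <- function(sol, groups = NULL) {
  stopifnot(inherits(sol, "retention_solution"), !isTRUE(sol$grouped))
  im <- sol$index_map
  if (is.null(groups)) groups <- list()
  if (!"whole_body" %in% names(groups))
    groups <- c(groups, list(whole_body = unique(im$compartment[im$in_body])))
  out <- matrix(0, nrow(sol$values), length(groups),
                dimnames = list(NULL, names(groups)))
  for (g in seq_along(groups)) {
    ids <- groups[[g]]
    if (length(ids) == 0L)
      stop("configuration error: group '", names(groups)[g], "' is empty",
           call. = FALSE)
    unknown <- setdiff(ids, im$compartment)
    if (length(unknown))
      stop("configuration error: group '", names(groups)[g],
           "' references unknown compartment(s) ",
           paste0("'", unknown, "'", collapse = ", "), call. = FALSE)
    cols <- im$index[im$compartment %in% ids]
    out[, g] <- rowSums(sol$values[, cols, drop = FALSE])
  }
  new_retention_solution(sol$times, out,
                         index_map = data.frame(
                           nuclide = "*", compartment = names(groups),
                           index = seq_along(groups),
                           in_body = NA, stringsAsFactors = FALSE),
                         method = sol$method, n_clipped = sol$n_clipped,
                         grouped = TRUE)
}

#' Stability classification of a computed solution
#'
#' Aggregates the solution over the requested compartment groups, computes
#' per-group amplification factors, and grades divergence.  Flags, per
#' group:
#' * `negative` — any value below `-max(atol, 100 * eps * scale)`, where
#'   `scale` is the run's initial total: values inside the solver's absolute
#'   error band or within rounding error of zero at the problem's scale are
#'   indistinguishable from zero and are not flagged;
#' * `oscillatory` — at least 3 sign changes of the discrete derivative with
#'   amplitude beyond `1e3 * atol`;
#' * `divergent` — `G > 10` on 2 or more consecutive unmasked steps, any
#'   non-finite value, or growth beyond `1e3 *` the run's initial total
#'   scale (a retention fraction cannot legitimately dwarf the intake).
#'
#' Grade: `"None"` if no group is flagged; `"Moderate"` for negativity only,
#' with all negative values within `1e3 * atol` in magnitude; `"High"` for
#' oscillation, divergence, or deeper negativity.
#'
#' @param sol a `retention_solution` (grouped or not; ungrouped input is
#'   aggregated first).
#' @param groups named list of compartment groups (see
#'   [aggregate_retention()]).
#' @param atol absolute-tolerance scale of the run being graded.
#' @param g_floor masking floor for the amplification factors.
#' @return Object of class `stability_summary`: `per_group_max_G`, `flags`
#'   (data.frame group/negative/oscillatory/divergent), `divergence_grade`.
#' @export
stability_summary <- function(sol, groups = NULL, atol = 1e-6,
                              g_floor = 1e-30) {
  stopifnot(inherits(sol, "retention_solution"))
  if (nrow(sol$values) < 2L)
    stop("diagnostic error: solution has fewer than 2 time points",
         call. = FALSE)
  grouped <- if (isTRUE(sol$grouped)) sol else aggregate_retention(sol, groups)
  gn <- colnames(grouped$values)
  max_g <- setNames(rep(NA_real_, length(gn)), gn)
  neg <- osc <- div <- setNames(logical(length(gn)), gn)
  deep_neg <- FALSE
  # physical scale of the run: a retention fraction can redistribute between
  # groups but cannot legitimately exceed the initial total by orders of
  # magnitude
  scale0 <- max(abs(grouped$values[1L, ]), atol)
  neg_floor <- max(atol, 100 * .Machine$double.eps * scale0)
  band <- 1e3 * neg_floor

  for (g in seq_along(gn)) {
    q <- grouped$values[, g]
    af <- amplification_factor(q, floor = g_floor)
    if (any(!af$mask)) max_g[g] <- max(af$values[!af$mask])
    neg[g] <- any(q < -neg_floor, na.rm = TRUE)
    if (any(q < -band, na.rm = TRUE)) deep_neg <- TRUE
    dq <- diff(q)
    sg <- sign(dq[abs(dq) > band])
    sg <- sg[sg != 0]
    osc[g] <- length(sg) > 1L && sum(diff(sg) != 0) >= 3L
    big_g <- !af$mask & af$values > 10
    run2 <- any(big_g[-1L] & big_g[-length(big_g)])
    blown <- any(!is.finite(q)) ||
      max(abs(q), na.rm = TRUE) > 1e3 * scale0
    div[g] <- run2 || blown
  }

  grade <- if (any(osc) || any(div) || deep_neg) "High"
    else if (any(neg)) "Moderate"
    else "None"
  structure(list(per_group_max_G = max_g,
                 flags = data.frame(group = gn, negative = neg,
                                    oscillatory = osc, divergent = div,
                                    row.names = NULL,
                                    stringsAsFactors = FALSE),
                 divergence_grade = grade),
            class = "stability_summary")
}

#' @export
print.stability_summary <- function(x, ...) {
  cat("<stability_summary> grade:", x$divergence_grade, "\n")
  for (g in names(x$per_group_max_G))
    cat(sprintf("  %-16s max G = %s%s\n", g,
                formatC(x$per_group_max_G[[g]], format = "g", digits = 3),
                {
                  f <- x$flags[x$flags$group == g, ]
                  tags <- c("negative", "oscillatory", "divergent")[
                    c(f$negative, f$oscillatory, f$divergent)]
                  if (length(tags)) paste0("  [", paste(tags, collapse = ","),
                                           "]") else ""
                }))
  invisible(x)
}

#' Percent relative difference between two solutions
#'
#' `RD% = (test - reference) / reference * 100` per grid point and series.
#' Points where the reference magnitude falls below `floor` are masked:
#' relative differences against numerically-zero references are dominated by
#' representation noise and carry no information.
#'
#' @param test,reference `retention_solution`s on the same grid with the
#'   same columns (or plain numeric vectors/matrices of equal shape).
#' @param floor reference magnitude below which points are masked.
#' @return Object of class `relative_difference_series`: `values` (RD% with
#'   NA where masked) and `mask`.
#' @export
relative_difference <- function(test, reference, floor = 1e-30) {
  tv <- if (inherits(test, "retention_solution")) test$values else test
  rv <- if (inherits(reference, "retention_solution")) reference$values
        else reference
  if (inherits(test, "retention_solution") &&
      inherits(reference, "retention_solution")) {
    if (length(test$times) != length(reference$times) ||
        any(test$times != reference$times))
      stop("input error: solutions are not on the same time grid",
           call. = FALSE)
  }
  tv <- as.matrix(tv); rv <- as.matrix(rv)
  if (!all(dim(tv) == dim(rv)))
    stop("input error: test and reference shapes differ", call. = FALSE)
  mask <- !is.finite(rv) | abs(rv) < floor
  rd <- matrix(NA_real_, nrow(tv), ncol(tv), dimnames = dimnames(tv))
  rd[!mask] <- (tv[!mask] - rv[!mask]) / rv[!mask] * 100
  structure(list(values = rd, mask = mask),
            class = "relative_difference_series")
}
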