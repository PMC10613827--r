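#' Read a biokinetic model from its JSON definition
#'
#' The model file is a JSON object with top-level keys `"nuclides"`,
#' `"compartments"`, `"transfers"` and `"initial_state"`; all rates are in
#' per-day units.  The file is schema-checked on load and violations are
#' reported with a JSON-pointer-style location (e.g. `/transfers/3/rate`).
#' Numeric fields given as strings (a common hand-editing slip) are coerced
#' with a warning by default; `strict = TRUE` turns the coercion into a
#' parse error.
#'
#' @param path path to the JSON model file.
#' @param strict logical; refuse string-typed numeric fields.
#' @return A validated [biokinetic_model()].
#' @seealso [write_model()]
#' @export
read_model <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  for (key in c("nuclides", "compartments", "transfers"))
    if (is.null(doc[[key]]))
      stop("parse error at /", key, ": required key is missing",
           call. = FALSE)

  coerce_num <- function(x, where) {
    if (is.numeric(x)) return(x)
    if (is.character(x)) {
      y <- suppressWarnings(as.numeric(x))
      if (anyNA(y) & !anyNA(x))
        stop("parse error at ", where, ": not a number", call. = FALSE)
      if (strict)
        stop("parse error at ", where,
             ": number given as string (strict mode)", call. = FALSE)
      warning("coerced string to number at ", where, call. = FALSE)
      return(y)
    }
    stop("parse error at ", where, ": expected a number", call. = FALSE)
  }

  nuc <- as.data.frame(doc$nuclides, stringsAsFactors = FALSE)
  if (is.null(nuc$name) || is.null(nuc$decay_constant))
    stop("parse error at /nuclides: need fields 'name', 'decay_constant'",
         call. = FALSE)
  nuc$decay_constant <- coerce_num(nuc$decay_constant,
                                   "/nuclides/decay_constant")
  branchings <- NULL
  if (!is.null(nuc$progeny)) {
    br <- list()
    for (i in seq_len(nrow(nuc))) {
      p <- nuc$progeny[[i]]
      if (!is.null(p) && NROW(p))
        br[[length(br) + 1L]] <- data.frame(
          parent = nuc$name[i], child = as.character(p$child),
          fraction = coerce_num(p$fraction,
                                paste0("/nuclides/", i, "/progeny/fraction")),
          stringsAsFactors = FALSE)
    }
    if (length(br)) branchings <- do.call(rbind, br)
    nuc$progeny <- NULL
  }

  comp <- as.data.frame(doc$compartments, stringsAsFactors = FALSE)
  if (is.null(comp$id))
    stop("parse error at /compartments: need field 'id'", call. = FALSE)

  tr <- as.data.frame(doc$transfers, stringsAsFactors = FALSE)
  if (nrow(tr)) {
    for (f in c("donor", "receiver", "rate"))
      if (is.null(tr[[f]]))
        stop("parse error at /transfers: need field '", f, "'",
             call. = FALSE)
    tr$rate <- coerce_num(tr$rate, "/transfers/rate")
  }

  ini <- NULL
  if (!is.null(doc$initial_state)) {
    ini <- as.data.frame(doc$initial_state, stringsAsFactors = FALSE)
    if (nrow(ini)) ini$value <- coerce_num(ini$value, "/initial_state/value")
  }

  model <- biokinetic_model(
    compartments = comp, transfers = tr, nuclides = nuc,
    branchings = branchings, initial_state = ini,
    name = if (!is.null(doc$name)) doc$name else
      tools::file_path_sans_ext(basename(path)))
  v <- validate_model(model)
  if (length(v))
    stop("parse error: model fails validation:\n  ",
         paste(v, collapse = "\n  "), call. = FALSE)
  model
}

#' Write a biokinetic model to JSON
#'
#' Lossless counterpart of [read_model()]: writing then reading reproduces
#' the model exactly.
#'
#' @param model a [biokinetic_model()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "biokinetic_model"))
  nuc <- model$nuclides
  nuc_list <- lapply(seq_len(nrow(nuc)), function(i) {
    entry <- list(name = nuc$name[i],
                  decay_constant = nuc$decay_constant[i])
    br <- model$branchings[model$branchings$parent == nuc$name[i], ,
                           drop = FALSE]
    if (nrow(br))
      entry$progeny <- data.frame(child = br$child, fraction = br$fraction)
    entry
  })
  doc <- list(name = model$name,
              nuclides = nuc_list,
              compartments = model$compartments,
              transfers = model$transfers,
              initial_state = model$initial_state)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a retention solution to CSV
#'
#' One time column (`time_d`, days) and one column per state or group.
#' Provenance (package version, solution method, grid definition) is
#' embedded as `#`-prefixed header comment lines.
#'
#' @param sol a `retention_solution`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_retention <- function(sol, path) {
  stopifnot(inherits(sol, "retention_solution"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# biokinet %s retention table (time in d)",
            as.character(utils::packageVersion("biokinet"))),
    sprintf("# method: %s", sol$method),
    sprintf("# grid: %d points in [%g, %g] d", length(sol$times),
            min(sol$times), max(sol$times))), con)
  # full double precision so write-then-read is lossless
  df <- data.frame(time_d = sprintf("%.17g", sol$times),
                   apply(sol$values, 2L, function(v) sprintf("%.17g", v)),
                   check.names = FALSE)
  names(df) <- c("time_d", colnames(sol$values))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an external reference retention table
#'
#' Accepts a generic time/value CSV (for example a user export of published
#' reference retention values): first column is time in days, remaining
#' columns one series each; `#` lines are comments.  Rows are aligned to a
#' target grid by nearest-time join within `tolerance`; unmatched rows are
#' reported in the result.
#'
#' @param path path to the CSV.
#' @param grid optional target grid to align against.
#' @param tolerance maximum |time difference| (days) for a join match.
#' @return Object of class `retention_table`: `times`, `values` (matrix),
#'   and when `grid` was given, `grid_index` (NA for unmatched rows) and
#'   `n_unmatched`.
#' @export
read_reference <- function(path, grid = NULL, tolerance = 1e-6) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.csv(path, comment.char = "#", check.names = FALSE),
    error = function(e) stop("parse error: ", conditionMessage(e),
                             call. = FALSE))
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("parse error: reference table needs a time column and at least ",
         "one series", call. = FALSE)
  times <- as.numeric(df[[1L]])
  if (anyNA(times) || any(diff(times) <= 0))
    stop("parse error: time column must be numeric and strictly increasing",
         call. = FALSE)
  values <- as.matrix(df[, -1L, drop = FALSE])
  out <- list(times = times, values = values)
  if (!is.null(grid)) {
    gi <- vapply(times, function(tt) {
      j <- which.min(abs(grid - tt))
      if (abs(grid[j] - tt) <= tolerance) j else NA_integer_
    }, integer(1L))
    out$grid_index <- gi
    out$n_unmatched <- sum(is.na(gi))
  }
  structure(out, class = "retention_table")
}

#' Run a multi-solver comparison against the matrix-exponential reference
#'
#' Runs every requested solver profile plus the matrix-exponential
#' propagator on the model, grades each run's stability, and reports each
#' run's whole-body percent relative difference against the propagator (and
#' against an external reference table when supplied).  Failed runs produce
#' report rows, not errors.
#'
#' @param model a valid [biokinetic_model()].
#' @param profiles list of [solver_profile()]s, or character labels of the
#'   form `"Method-label"` (e.g. `"Radau-customized"`).
#' @param grid output times (days); default [default_grid()].
#' @param reference optional `retention_table` from [read_reference()], or a
#'   path to one.
#' @param groups compartment groups for the stability summary.
#' @param maxsteps per-interval step cap passed to [integrate_model()].
#' @return Object of class `comparison_report`: `rows` (data.frame with one
#'   row per run: label, success, grade, max G, RD% range vs the
#'   propagator and optionally vs the reference), `runs` (the solver_run
#'   objects), `reference_solution` (the propagator output), `grid`.
#' @export
run_comparison <- function(model, profiles, grid = default_grid(),
                           reference = NULL, groups = NULL,
                           maxsteps = 10000L) {
  stop_if_invalid(model)
  if (length(profiles) == 0L)
    stop("input error: at least one profile is required", call. = FALSE)
  profiles <- lapply(profiles, function(p) {
    if (inherits(p, "solver_profile")) return(p)
    parts <- strsplit(p, "-", fixed = TRUE)[[1L]]
    if (length(parts) != 2L)
      stop("configuration error: profile label '", p,
           "' is not of the form Method-label", call. = FALSE)
    lookup_profile(parts[2L], method = parts[1L])
  })
  if (is.character(reference)) reference <- read_reference(reference, grid)

  cm <- assemble_matrix(model)
  ref <- propagate(cm, initial_state_vector(model, cm), grid)
  ref_wb <- aggregate_retention(ref, groups)

  rows <- list()
  runs <- list()
  for (p in profiles) {
    run <- integrate_model(model, grid, p, cm = cm, maxsteps = maxsteps)
    lab <- paste0(p$method, "-", p$label)
    runs[[lab]] <- run
    row <- data.frame(label = lab, success = run$success,
                      grade = NA_character_, max_G_whole_body = NA_real_,
                      rd_min = NA_real_, rd_max = NA_real_,
                      wall_time_s = run$wall_time,
                      stringsAsFactors = FALSE)
    if (!is.null(run$solution) && nrow(run$solution$values) >= 2L) {
      ss <- stability_summary(run$solution, groups, atol = p$atol)
      row$grade <- ss$divergence_grade
      row$max_G_whole_body <- unname(ss$per_group_max_G["whole_body"])
      if (run$success) {
        wb <- aggregate_retention(run$solution, groups)
        rd <- relative_difference(wb$values[, "whole_body"],
                                  ref_wb$values[, "whole_body"])
        if (any(!rd$mask)) {
          row$rd_min <- min(rd$values, na.rm = TRUE)
          row$rd_max <- max(rd$values, na.rm = TRUE)
        }
      }
    }
    rows[[lab]] <- row
  }
  # the propagator's own row (reference row: RD identically zero)
  rd_self <- relative_difference(ref_wb$values[, "whole_body"],
                                 ref_wb$values[, "whole_body"])
  ss_ref <- stability_summary(ref, groups, atol = 1e-15)
  rows[["expm"]] <- data.frame(
    label = "expm", success = TRUE, grade = ss_ref$divergence_grade,
    max_G_whole_body = unname(ss_ref$per_group_max_G["whole_body"]),
    rd_min = if (any(!rd_self$mask)) min(rd_self$values, na.rm = TRUE)
             else NA_real_,
    rd_max = if (any(!rd_self$mask)) max(rd_self$values, na.rm = TRUE)
             else NA_real_,
    wall_time_s = NA_real_, stringsAsFactors = FALSE)

  tbl <- do.call(rbind, rows)
  rownames(tbl) <- NULL

  if (!is.null(reference)) {
    stopifnot(inherits(reference, "retention_table"))
    gi <- reference$grid_index
    if (is.null(gi))
      stop("input error: reference table was read without grid alignment",
           call. = FALSE)
    ok <- !is.na(gi)
    tbl$rd_ref_min <- NA_real_
    tbl$rd_ref_max <- NA_real_
    ref_series <- reference$values[, 1L]
    for (r in seq_len(nrow(tbl))) {
      lab <- tbl$label[r]
      sol <- if (lab == "expm") ref else runs[[lab]]$solution
      if (is.null(sol) || !isTRUE(tbl$success[r])) next
      wb <- aggregate_retention(sol, groups)$values[, "whole_body"]
      rd <- relative_difference(wb[gi[ok]], ref_series[ok])
      if (any(!rd$mask)) {
        tbl$rd_ref_min[r] <- min(rd$values, na.rm = TRUE)
        tbl$rd_ref_max[r] <- max(rd$values, na.rm = TRUE)
      }
    }
  }

  structure(list(rows = tbl, runs = runs, reference_solution = ref,
                 grid = grid),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report> ", nrow(x$rows), " run(s) on ",
      length(x$grid), " grid points\n", sep = "")
  print(x$rows, digits = 4)
  invisible(x)
}

#' Write a comparison report to CSV
#'
#' @param report a `comparison_report`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "comparison_report"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# biokinet %s comparison report",
            as.character(utils::packageVersion("biokinet"))),
    sprintf("# grid: %d points in [%g, %g] d", length(report$grid),
            min(report$grid), max(report$grid))), con)
  utils::write.csv(report$rows, con, row.names = FALSE)
  invisible(path)
}
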