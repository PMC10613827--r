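#' Generate a seeded compartmental model with controlled stiffness
#'
#' Builds a reproducible Metzler-structured compartmental fixture whose
#' diagonal loss terms span a requested number of decades, emulating the
#' coexisting fast- and slow-clearing pathways (rapid mechanical transit,
#' slow particle dissolution) that make inhalation biokinetics stiff.  The
#' last `ceiling(excreta_fraction * n)` compartments are excreta sinks with
#' no outflow; every non-sink compartment gets a total outflow rate placed
#' log-uniformly so the loss-term magnitudes span exactly
#' `target_log10_SR` decades, split over one or two receivers drawn at
#' random (always including a route that eventually reaches a sink, so mass
#' is dissipative and all eigenvalues have non-positive real parts).
#'
#' All rates are invented fixture values — they are not ICRP transfer
#' coefficients.
#'
#' @param n_compartments total compartment count (>= 2).
#' @param target_log10_SR decades spanned by the loss-term magnitudes
#'   (>= 0); the assembled `diag_bound` equals `10^target_log10_SR` up to
#'   the random rate split.
#' @param decay_constant physical decay constant of the single nuclide
#'   (per day); the default 0 keeps sink diagonals exactly zero so the
#'   diagonal spread is set purely by the transfer structure.
#' @param seed integer seed; identical seeds give identical models.
#' @param excreta_fraction fraction of compartments designated sinks
#'   (at least one sink is always created).
#' @return A valid [biokinetic_model()] with unit initial activity in the
#'   first compartment.
#' @export
generate_stiff_model <- function(n_compartments, target_log10_SR,
                                 decay_constant = 0, seed = 1L,
                                 excreta_fraction = 0.2) {
  stopifnot(n_compartments >= 2L, target_log10_SR >= 0,
            decay_constant >= 0,
            excreta_fraction >= 0, excreta_fraction < 1)
  n_sink <- max(1L, as.integer(ceiling(excreta_fraction * n_compartments)))
  n_body <- n_compartments - n_sink
  if (n_body < 1L)
    stop("generation error: excreta_fraction leaves no in-body compartment",
         call. = FALSE)

  ids <- c(sprintf("C%02d", seq_len(n_body)),
           sprintf("SINK%02d", seq_len(n_sink)))
  region <- c(rep("other", n_body), rep("excreta", n_sink))

  tr <- local_seed(seed, {
    # total outflow magnitudes: log-equispaced over the target span, shuffled
    mags <- 10^(seq(0, target_log10_SR,
                    length.out = max(n_body, 2L))[seq_len(n_body)])
    mags <- sample(mags)
    rows <- list()
    for (i in seq_len(n_body)) {
      others <- setdiff(seq_len(n_compartments), i)
      # guarantee dissipation: odd-indexed donors route part of their
      # outflow to a sink; the rest goes to a random other compartment
      r1 <- sample(others, 1L)
      split <- runif(1L, 0.2, 0.8)
      sink_target <- n_body + 1L + (i %% n_sink)
      if (r1 == sink_target) {
        rows[[length(rows) + 1L]] <-
          data.frame(donor = ids[i], receiver = ids[r1], rate = mags[i])
      } else {
        rows[[length(rows) + 1L]] <-
          data.frame(donor = ids[i], receiver = ids[r1],
                     rate = mags[i] * split)
        rows[[length(rows) + 1L]] <-
          data.frame(donor = ids[i], receiver = ids[sink_target],
                     rate = mags[i] * (1 - split))
      }
    }
    do.call(rbind, rows)
  })
  tr$nuclide <- "synthetic_nuclide"

  biokinetic_model(
    compartments = data.frame(id = ids, region = region,
                              in_body = region != "excreta"),
    transfers = tr,
    nuclides = data.frame(name = "synthetic_nuclide",
                          decay_constant = decay_constant),
    initial_state = data.frame(nuclide = "synthetic_nuclide",
                               compartment = ids[1L], value = 1),
    name = sprintf("synthetic_sr%g_seed%d", target_log10_SR, seed))
}

# evaluate expr under a temporary RNG state seeded with `seed`
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Fixed stiff respiratory-tract-like toy model
#'
#' A fixed ~10-compartment fixture with the topology that makes inhalation
#' biokinetics hard: three deposition compartments (extrathoracic-,
#' bronchial- and alveolar-like) cleared both mechanically (ciliary
#' escalator to an oesophagus-like fast-transit compartment, then a
#' stomach-like compartment, then a faecal sink) and by particle dissolution
#' (fast and slow routes into a blood compartment), with blood feeding two
#' systemic compartments of very different turnover and a urinary sink.
#' Rates span more than six decades (1e-5 to 100 per day), so the assembled
#' system is genuinely stiff.
#'
#' Every rate value is an invented fixture constant chosen for its order of
#' magnitude only — none is an ICRP transfer coefficient.
#'
#' @param decay_constant physical decay constant (per day) of the single
#'   nuclide; default 0 (stable tracer) so conservation is exact.
#' @return A valid [biokinetic_model()] with the unit intake deposited
#'   45/25/30 percent in the extrathoracic/bronchial/alveolar compartments.
#' @export
toy_respiratory_model <- function(decay_constant = 0) {
  stopifnot(decay_constant >= 0)
  comp <- data.frame(
    id = c("ET", "BR", "AL", "OES", "ST", "BLOOD", "SYS_FAST", "SYS_SLOW",
           "FAECES", "URINE"),
    region = c("respiratory_tract", "respiratory_tract",
               "respiratory_tract", "oesophagus", "alimentary", "systemic",
               "systemic", "systemic", "excreta", "excreta"),
    in_body = c(rep(TRUE, 8L), FALSE, FALSE))
  tr <- data.frame(
    donor    = c("ET",  "ET",    "BR", "BR",    "AL",    "AL",
                 "OES", "ST", "BLOOD",    "BLOOD",    "BLOOD",
                 "SYS_FAST", "SYS_SLOW"),
    receiver = c("OES", "BLOOD", "ET", "BLOOD", "BR",    "BLOOD",
                 "ST",  "FAECES", "SYS_FAST", "SYS_SLOW", "URINE",
                 "BLOOD",    "BLOOD"),
    rate     = c(10,    100,     2,    3e-3,    2e-3,    3e-4,
                 50,    1,        5,          1.5,        12,
                 1e-2,       1e-5),
    nuclide = "toy_nuclide")
  biokinetic_model(
    compartments = comp, transfers = tr,
    nuclides = data.frame(name = "toy_nuclide",
                          decay_constant = decay_constant),
    initial_state = data.frame(nuclide = "toy_nuclide",
                               compartment = c("ET", "BR", "AL"),
                               value = c(0.45, 0.25, 0.30)),
    name = "toy_respiratory")
}

#' Tightened matrix-exponential reference solution
#'
#' Ground-truth surface for integrator tests: the matrix-exponential
#' propagation with two extra scaling-and-squaring steps beyond the norm
#' criterion, so the reference carries more headroom than the solution
#' under test.
#'
#' @param model a valid [biokinetic_model()].
#' @param grid output times (days), strictly increasing from 0.
#' @return A `retention_solution` (see [propagate()]).
#' @export
reference_solution <- function(model, grid) {
  propagate(model, grid = grid, s_extra = 2L)
}
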