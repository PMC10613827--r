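#' Assemble the constant coefficient matrix of a biokinetic model
#'
#' Builds the N x N rate matrix `A` of the linear system `dY/dt = A Y`,
#' where the state vector `Y` stacks the per-compartment activities of every
#' chain member, chain-member-major (all compartments of the first nuclide,
#' then all compartments of the second, ...).  Within a member's block the
#' matrix is Metzler (non-negative off-diagonals); decay ingrowth from parent
#' to progeny appears only in below-diagonal blocks, so the full matrix is
#' block lower triangular in the chain ordering.
#'
#' Entry conventions, for chain member *i* and compartments *j* (donor),
#' *k* (receiver):
#' * `A[(i,k), (i,j)] = lambda_{i,k,j}` for `j != k`;
#' * `A[(i,j), (i,j)] = -(sum_k lambda_{i,k,j} + lambda^D_i)`;
#' * ingrowth `A[(i,j), (p,j)] = beta_{p,i} * lambda^D`, where which decay
#'   constant multiplies the branching fraction depends on `ingrowth`.
#'
#' @section Ingrowth conventions:
#' With `ingrowth = "parent"` (default) the ingrowth term carries the
#' *parent's* decay constant: this is the atom-balance convention, under
#' which column sums of a no-transfer chain block vanish and total activity
#' of a closed single-nuclide model decays exactly as `exp(-lambda^D t)`.
#' With `ingrowth = "progeny"` the term carries the progeny's own decay
#' constant, which is the self-consistent convention when the state vector is
#' expressed in activity units (A = lambda N).  Both are exact solutions of
#' the same physics in different units; mixing conventions between model
#' definition and interpretation is the only error.
#'
#' @param model a valid [biokinetic_model()].
#' @param ingrowth `"parent"` or `"progeny"`; see Details.
#' @return An object of class `coefficient_matrix`: list with `matrix`
#'   (the N x N rate matrix, dimnames `"nuclide:compartment"`), `index_map`
#'   (data.frame `nuclide`, `compartment`, `index`, `in_body`), `ingrowth`,
#'   and `model_name`.
#' @export
assemble_matrix <- function(model, ingrowth = c("parent", "progeny")) {
  ingrowth <- match.arg(ingrowth)
  stop_if_invalid(model)

  comp <- model$compartments$id
  nuc <- model$nuclides$name
  M <- length(comp)
  n_nuc <- length(nuc)
  N <- M * n_nuc
  idx <- function(i_nuc, j_comp) (i_nuc - 1L) * M + j_comp

  A <- matrix(0, N, N)
  labels <- as.vector(t(outer(nuc, comp, paste, sep = ":")))
  dimnames(A) <- list(labels, labels)

  tr <- model$transfers
  if (nrow(tr)) {
    key <- paste(tr$nuclide, tr$donor, tr$receiver, sep = "\r")
    if (anyDuplicated(key)) {
      warning("duplicate transfer entries summed: ",
              paste(unique(sprintf("%s -> %s [%s]",
                                   tr$donor[duplicated(key)],
                                   tr$receiver[duplicated(key)],
                                   tr$nuclide[duplicated(key)])),
                    collapse = ", "), call. = FALSE)
      tr <- aggregate(rate ~ nuclide + donor + receiver, data = tr, FUN = sum)
    }
    for (r in seq_len(nrow(tr))) {
      i <- match(tr$nuclide[r], nuc)
      j <- match(tr$donor[r], comp)
      k <- match(tr$receiver[r], comp)
      A[idx(i, k), idx(i, j)] <- A[idx(i, k), idx(i, j)] + tr$rate[r]
      A[idx(i, j), idx(i, j)] <- A[idx(i, j), idx(i, j)] - tr$rate[r]
    }
  }
  # decay loss on every diagonal entry of member i's block
  for (i in seq_len(n_nuc)) {
    lam <- model$nuclides$decay_constant[i]
    if (lam > 0) {
      d <- idx(i, seq_len(M))
      A[cbind(d, d)] <- A[cbind(d, d)] - lam
    }
  }
  # ingrowth: parent p feeds member i in the same compartment
  br <- model$branchings
  if (nrow(br)) {
    for (r in seq_len(nrow(br))) {
      p <- match(br$parent[r], nuc)
      i <- match(br$child[r], nuc)
      lam <- if (ingrowth == "parent") model$nuclides$decay_constant[p]
             else model$nuclides$decay_constant[i]
      if (br$fraction[r] > 0 && lam > 0) {
        for (j in seq_len(M))
          A[idx(i, j), idx(p, j)] <- A[idx(i, j), idx(p, j)] +
            br$fraction[r] * lam
      }
    }
  }

  index_map <- data.frame(
    nuclide = rep(nuc, each = M),
    compartment = rep(comp, times = n_nuc),
    index = seq_len(N),
    in_body = rep(model$compartments$in_body, times = n_nuc),
    stringsAsFactors = FALSE)

  structure(list(matrix = A, index_map = index_map, ingrowth = ingrowth,
                 model_name = model$name),
            class = "coefficient_matrix")
}

#' @export
print.coefficient_matrix <- function(x, ...) {
  cat("<coefficient_matrix> ", nrow(x$matrix), " x ", ncol(x$matrix),
      " (model '", x$model_name, "', ingrowth = ", x$ingrowth, ")\n",
      sep = "")
  d <- abs(diag(x$matrix))
  d <- d[d > 0]
  if (length(d))
    cat(sprintf("  |diag| range: %.3g .. %.3g d^-1\n", min(d), max(d)))
  invisible(x)
}

#' Initial state vector in matrix ordering
#'
#' Expands a model's sparse initial-state table into the dense state vector
#' matching a [assemble_matrix()] index map; unspecified entries are zero.
#'
#' @param model a [biokinetic_model()].
#' @param cm the corresponding `coefficient_matrix` (assembled on demand when
#'   omitted).
#' @return Named numeric vector of length N.
#' @export
initial_state_vector <- function(model, cm = NULL) {
  if (is.null(cm)) cm <- assemble_matrix(model)
  y0 <- numeric(nrow(cm$index_map))
  names(y0) <- paste(cm$index_map$nuclide, cm$index_map$compartment,
                     sep = ":")
  s <- model$initial_state
  if (nrow(s)) {
    at <- match(paste(s$nuclide, s$compartment, sep = ":"), names(y0))
    if (anyNA(at)) stop("initial state references unknown (nuclide, ",
                        "compartment) pair", call. = FALSE)
    y0[at] <- y0[at] + s$value
  }
  y0
}
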