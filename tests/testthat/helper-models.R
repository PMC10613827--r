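# Shared fixture builders: tiny models constructed in code, no files.

two_compartment_model <- function(rate = 3, decay = 0) {
  biokinetic_model(
    compartments = data.frame(id = c("a", "b")),
    transfers = data.frame(donor = "a", receiver = "b", rate = rate),
    nuclides = data.frame(name = "nuc", decay_constant = decay),
    initial_state = data.frame(nuclide = "nuc", compartment = "a",
                               value = 1))
}

# random Metzler matrix with non-positive column sums (dissipative)
random_metzler <- function(n, scale = 1) {
  A <- matrix(runif(n * n, 0, scale), n, n)
  diag(A) <- 0
  diag(A) <- -colSums(A) - runif(n, 0, scale / 10)
  A
}

# direct entry-by-entry assembly by looping over the governing equation's
# terms: transfer inflow, transfer+decay loss, decay ingrowth.  Independent
# of assemble_matrix()'s vectorized path.
brute_force_assembly <- function(model, ingrowth = "parent") {
  comp <- model$compartments$id
  nuc <- model$nuclides$name
  M <- length(comp)
  N <- M * length(nuc)
  A <- matrix(0, N, N)
  idx <- function(i, j) (i - 1L) * M + j
  for (i in seq_along(nuc)) {
    for (j in seq_len(M)) {
      col <- idx(i, j)
      # outflow and decay loss on the diagonal
      loss <- model$nuclides$decay_constant[i]
      for (k in seq_len(M)) {
        if (k == j) next
        tr <- model$transfers
        sel <- tr$nuclide == nuc[i] & tr$donor == comp[j] &
          tr$receiver == comp[k]
        r <- sum(tr$rate[sel])
        A[idx(i, k), col] <- A[idx(i, k), col] + r
        loss <- loss + r
      }
      A[col, col] <- -loss
      # ingrowth from every parent of member i, same compartment
      br <- model$branchings
      sel <- br$child == nuc[i]
      if (any(sel)) for (r in which(sel)) {
        p <- match(br$parent[r], nuc)
        lam <- if (ingrowth == "parent") model$nuclides$decay_constant[p]
               else model$nuclides$decay_constant[i]
        A[col, idx(p, j)] <- A[col, idx(p, j)] + br$fraction[r] * lam
      }
    }
  }
  A
}

max_rel_err <- function(x, ref, floor = 0) {
  keep <- abs(ref) > floor
  if (!any(keep)) return(0)
  max(abs(x[keep] - ref[keep]) / abs(ref[keep]))
}
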