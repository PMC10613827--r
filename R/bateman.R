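#' Closed-form serial decay chain (Bateman) activities
#'
#' Analytic solution of a serial decay chain with a unit amount of the first
#' member at t = 0 and no other source: an independent oracle for the
#' matrix-exponential propagator on chain models.  Member n's solution is
#' written as a confluent divided difference of `exp(-x t)` over the nodes
#' `lambda_1..lambda_n`, which reduces to the classical Bateman
#' partial-fraction sum for distinct rates and remains exact in the
#' degenerate (equal-rate) limit, where the partial-fraction form blows up:
#' \deqn{y_n(t) = \Big(\prod_{i<n} \beta_i \lambda_i\Big)\,
#'   (-1)^{n-1}\, f[\lambda_1, \ldots, \lambda_n], \quad f(x) = e^{-xt}.}
#' A block of r equal nodes contributes the confluent limit
#' `t^{r-1} exp(-lambda t) / (r-1)!` through the divided-difference
#' recursion, never a 0/0.
#'
#' The convention matches [assemble_matrix()] with `ingrowth = "parent"`
#' (ingrowth carries the parent's decay constant).
#'
#' @param lambdas numeric vector of decay constants (per day), parent first.
#' @param branchings branching fractions; `branchings[i]` feeds member i+1
#'   from member i.  Default all 1.  Length `length(lambdas) - 1`.
#' @param t numeric vector of times (days).
#' @return Matrix `length(t) x length(lambdas)` of chain member states.
#' @examples
#' bateman_chain(0.2, t = 5)                  # exp(-1)
#' bateman_chain(c(0.2, 0.05), t = c(1, 10))  # parent + in-grown progeny
#' @export
bateman_chain <- function(lambdas, branchings = NULL, t) {
  stopifnot(is.numeric(lambdas), length(lambdas) >= 1L,
            all(is.finite(lambdas)), all(lambdas >= 0),
            is.numeric(t), all(is.finite(t)))
  n <- length(lambdas)
  if (is.null(branchings)) branchings <- rep(1, max(n - 1L, 0L))
  stopifnot(length(branchings) == n - 1L,
            all(branchings >= 0), all(branchings <= 1))

  out <- matrix(0, length(t), n)
  colnames(out) <- paste0("member", seq_len(n))
  for (m in seq_len(n)) {
    pref <- if (m == 1L) 1 else prod(branchings[seq_len(m - 1L)] *
                                       lambdas[seq_len(m - 1L)])
    if (pref == 0) next
    dd <- vapply(t, function(tt)
      exp_divided_difference(lambdas[seq_len(m)], tt), numeric(1L))
    out[, m] <- pref * (-1)^(m - 1L) * dd
  }
  out
}

# Confluent divided difference of f(x) = exp(-x t) over possibly repeated
# nodes.  Recursive Newton form; equal-node blocks use f^(k)(x)/k!.
# Chains are short, so the exponential-time recursion is irrelevant.
exp_divided_difference <- function(nodes, t) {
  nodes <- sort(nodes)
  rec <- function(x) {
    n <- length(x)
    if (x[n] - x[1L] == 0)
      return((-t)^(n - 1L) * exp(-x[1L] * t) / factorial(n - 1L))
    (rec(x[-1L]) - rec(x[-n])) / (x[n] - x[1L])
  }
  rec(nodes)
}

#' Build the 1-compartment-per-member chain model
#'
#' Convenience constructor for the serial-chain biokinetic model equivalent
#' to [bateman_chain()]: one compartment, no transfers, each member decaying
#' into the next with the given branching fraction.
#'
#' @inheritParams bateman_chain
#' @return A [biokinetic_model()] whose propagated states match
#'   `bateman_chain(lambdas, branchings, t)`.
#' @export
serial_chain_model <- function(lambdas, branchings = NULL) {
  n <- length(lambdas)
  if (is.null(branchings)) branchings <- rep(1, max(n - 1L, 0L))
  nm <- paste0("member", seq_len(n))
  br <- if (n > 1L)
    data.frame(parent = nm[-n], child = nm[-1L], fraction = branchings)
  else NULL
  biokinetic_model(
    compartments = data.frame(id = "pool", region = "other",
                              in_body = TRUE),
    transfers = NULL,
    nuclides = data.frame(name = nm, decay_constant = lambdas),
    branchings = br,
    initial_state = data.frame(nuclide = nm[1L], compartment = "pool",
                               value = 1),
    name = "serial_chain")
}
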