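#' Construct a biokinetic compartment model
#'
#' A biokinetic model is a set of first-order compartments exchanging an
#' incorporated radionuclide (and, optionally, its decay progeny) at constant
#' fractional transfer rates.  The governing system is
#' \deqn{dA_{i,j}/dt = \sum_{k \ne j} A_{i,k}\lambda_{i,j,k}
#'   - A_{i,j}\big(\sum_{k \ne j}\lambda_{i,k,j} + \lambda^D_i\big)
#'   + \sum_{k < i} A_{k,j}\,\beta_{k,i}\,\lambda^D}
#' where \eqn{\lambda_{i,k,j}} is the transfer rate of chain member *i* from
#' donor compartment *j* to receiver *k* (per day) and \eqn{\lambda^D} the
#' physical decay constant.  See [assemble_matrix()] for the two conventions
#' on which decay constant multiplies the ingrowth term.
#'
#' @param compartments data.frame with columns `id` (unique labels), `region`
#'   (one of `"respiratory_tract"`, `"oesophagus"`, `"alimentary"`,
#'   `"systemic"`, `"excreta"`, `"other"`) and `in_body` (logical; whether the
#'   compartment counts toward whole-body retention).  Missing `region`
#'   defaults to `"other"`, missing `in_body` to `TRUE` except for
#'   `region == "excreta"`.
#' @param transfers data.frame with columns `donor`, `receiver` (compartment
#'   ids), `rate` (per day, non-negative) and `nuclide` (chain member the rate
#'   applies to; defaults to the first nuclide).
#' @param nuclides data.frame with columns `name` and `decay_constant`
#'   (per day).  Order matters: parents must precede progeny.
#' @param branchings data.frame with columns `parent`, `child`, `fraction`
#'   (branching fraction of parent decays feeding the child), or `NULL`.
#' @param initial_state data.frame with columns `nuclide`, `compartment`,
#'   `value` (activity fraction at t = 0); unspecified entries are zero.
#' @param name optional model label carried through coupling and file output.
#' @return An object of class `biokinetic_model`.
#' @seealso [validate_model()], [assemble_matrix()], [couple_models()]
#' @examples
#' m <- biokinetic_model(
#'   compartments  = data.frame(id = c("a", "b")),
#'   transfers     = data.frame(donor = "a", receiver = "b", rate = 3),
#'   nuclides      = data.frame(name = "nuc", decay_constant = 0),
#'   initial_state = data.frame(nuclide = "nuc", compartment = "a", value = 1)
#' )
#' assemble_matrix(m)$matrix
#' @export
biokinetic_model <- function(compartments, transfers, nuclides,
                             branchings = NULL, initial_state = NULL,
                             name = "model") {
  compartments <- as.data.frame(compartments, stringsAsFactors = FALSE)
  stopifnot(nrow(compartments) >= 1L, "id" %in% names(compartments))
  compartments$id <- as.character(compartments$id)
  if (is.null(compartments$region)) compartments$region <- "other"
  compartments$region <- as.character(compartments$region)
  if (is.null(compartments$in_body))
    compartments$in_body <- compartments$region != "excreta"
  compartments$in_body <- as.logical(compartments$in_body)
  compartments <- compartments[, c("id", "region", "in_body")]

  nuclides <- as.data.frame(nuclides, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "decay_constant") %in% names(nuclides)))
  nuclides$name <- as.character(nuclides$name)
  nuclides$decay_constant <- as.numeric(nuclides$decay_constant)
  nuclides <- nuclides[, c("name", "decay_constant")]

  if (is.null(transfers) || NROW(transfers) == 0L) {
    transfers <- data.frame(donor = character(), receiver = character(),
                            rate = numeric(), nuclide = character(),
                            stringsAsFactors = FALSE)
  } else {
    transfers <- as.data.frame(transfers, stringsAsFactors = FALSE)
    stopifnot(all(c("donor", "receiver", "rate") %in% names(transfers)))
    if (is.null(transfers$nuclide)) transfers$nuclide <- nuclides$name[1L]
    transfers <- data.frame(donor = as.character(transfers$donor),
                            receiver = as.character(transfers$receiver),
                            rate = as.numeric(transfers$rate),
                            nuclide = as.character(transfers$nuclide),
                            stringsAsFactors = FALSE)
  }

  if (is.null(branchings) || NROW(branchings) == 0L) {
    branchings <- data.frame(parent = character(), child = character(),
                             fraction = numeric(), stringsAsFactors = FALSE)
  } else {
    branchings <- as.data.frame(branchings, stringsAsFactors = FALSE)
    stopifnot(all(c("parent", "child", "fraction") %in% names(branchings)))
    branchings <- data.frame(parent = as.character(branchings$parent),
                             child = as.character(branchings$child),
                             fraction = as.numeric(branchings$fraction),
                             stringsAsFactors = FALSE)
  }

  if (is.null(initial_state) || NROW(initial_state) == 0L) {
    initial_state <- data.frame(nuclide = character(),
                                compartment = character(),
                                value = numeric(), stringsAsFactors = FALSE)
  } else {
    initial_state <- as.data.frame(initial_state, stringsAsFactors = FALSE)
    stopifnot(all(c("nuclide", "compartment", "value") %in%
                    names(initial_state)))
    initial_state <- data.frame(
      nuclide = as.character(initial_state$nuclide),
      compartment = as.character(initial_state$compartment),
      value = as.numeric(initial_state$value), stringsAsFactors = FALSE)
  }

  structure(list(compartments = compartments, transfers = transfers,
                 nuclides = nuclides, branchings = branchings,
                 initial_state = initial_state, name = as.character(name)),
            class = "biokinetic_model")
}

#' @export
print.biokinetic_model <- function(x, ...) {
  cat("<biokinetic_model> '", x$name, "'\n", sep = "")
  cat("  compartments: ", nrow(x$compartments),
      " (", sum(x$compartments$in_body), " in-body)\n", sep = "")
  cat("  transfers:    ", nrow(x$transfers), "\n", sep = "")
  cat("  chain:        ", paste(x$nuclides$name, collapse = " -> "),
      "\n", sep = "")
  invisible(x)
}

#' Validate a biokinetic model
#'
#' Checks all structural invariants and returns the violations found rather
#' than raising: non-negative transfer rates and decay constants, unique
#' compartment ids, dangling compartment/nuclide references, branching
#' fractions in \[0, 1\] summing to at most 1 per parent, topological chain
#' order (parents precede progeny), excreta compartments flagged out-of-body,
#' and non-negative initial activities.
#'
#' @param model a [biokinetic_model()].
#' @return Character vector of human-readable violations; empty when the
#'   model is valid.  Each entry names the offending element.
#' @export
validate_model <- function(model) {
  v <- character()
  cm <- model$compartments
  dup <- unique(cm$id[duplicated(cm$id)])
  if (length(dup))
    v <- c(v, paste0("duplicate compartment id '", dup, "'"))
  bad_excreta <- cm$id[cm$region == "excreta" & cm$in_body]
  if (length(bad_excreta))
    v <- c(v, paste0("excreta compartment '", bad_excreta,
                     "' must have in_body = FALSE"))

  nuc <- model$nuclides
  if (anyDuplicated(nuc$name))
    v <- c(v, paste0("duplicate nuclide '",
                     unique(nuc$name[duplicated(nuc$name)]), "'"))
  bad_dc <- nuc$name[!is.finite(nuc$decay_constant) | nuc$decay_constant < 0]
  if (length(bad_dc))
    v <- c(v, paste0("nuclide '", bad_dc,
                     "' has negative or non-finite decay constant"))

  tr <- model$transfers
  if (nrow(tr)) {
    for (r in seq_len(nrow(tr))) {
      lab <- paste0("transfer ", tr$donor[r], " -> ", tr$receiver[r],
                    " [", tr$nuclide[r], "]")
      if (!is.finite(tr$rate[r]) || tr$rate[r] < 0)
        v <- c(v, paste0(lab, ": rate must be a non-negative finite number"))
      if (tr$donor[r] == tr$receiver[r])
        v <- c(v, paste0(lab, ": donor equals receiver"))
      if (!tr$donor[r] %in% cm$id)
        v <- c(v, paste0(lab, ": unknown donor compartment '",
                         tr$donor[r], "'"))
      if (!tr$receiver[r] %in% cm$id)
        v <- c(v, paste0(lab, ": unknown receiver compartment '",
                         tr$receiver[r], "'"))
      if (!tr$nuclide[r] %in% nuc$name)
        v <- c(v, paste0(lab, ": unknown nuclide '", tr$nuclide[r], "'"))
    }
  }

  br <- model$branchings
  if (nrow(br)) {
    for (r in seq_len(nrow(br))) {
      lab <- paste0("branching ", br$parent[r], " -> ", br$child[r])
      if (!br$parent[r] %in% nuc$name)
        v <- c(v, paste0(lab, ": unknown parent nuclide"))
      if (!br$child[r] %in% nuc$name)
        v <- c(v, paste0(lab, ": unknown child nuclide"))
      if (!is.finite(br$fraction[r]) || br$fraction[r] < 0 ||
          br$fraction[r] > 1)
        v <- c(v, paste0(lab, ": branching fraction outside [0, 1]"))
      ip <- match(br$parent[r], nuc$name)
      ic <- match(br$child[r], nuc$name)
      if (!is.na(ip) && !is.na(ic) && ip >= ic)
        v <- c(v, paste0(lab, ": chain order is not topological ",
                         "(parent must precede child)"))
    }
    sums <- tapply(br$fraction, br$parent, sum)
    over <- names(sums)[is.finite(sums) & sums > 1 + 1e-12]
    if (length(over))
      v <- c(v, paste0("nuclide '", over,
                       "': branching fractions sum to more than 1"))
  }

  is0 <- model$initial_state
  if (nrow(is0)) {
    for (r in seq_len(nrow(is0))) {
      lab <- paste0("initial state (", is0$nuclide[r], ", ",
                    is0$compartment[r], ")")
      if (!is0$compartment[r] %in% cm$id)
        v <- c(v, paste0(lab, ": unknown compartment"))
      if (!is0$nuclide[r] %in% nuc$name)
        v <- c(v, paste0(lab, ": unknown nuclide"))
      if (!is.finite(is0$value[r]) || is0$value[r] < 0)
        v <- c(v, paste0(lab, ": value must be non-negative"))
    }
  }
  v
}

stop_if_invalid <- function(model) {
  v <- validate_model(model)
  if (length(v))
    stop("invalid biokinetic model:\n  ", paste(v, collapse = "\n  "),
         call. = FALSE)
  invisible(model)
}

#' Couple sub-models into one biokinetic model
#'
#' Joins independently defined sub-models (for example a respiratory-tract
#' deposition/clearance block, an alimentary-tract transit block, and a
#' systemic block) into a single model, optionally adding link transfers such
#' as the slow-oesophagus-to-stomach pathway or dissolution-to-blood uptake.
#' When `parts` is a named list, compartment ids are namespaced as
#' `"<part>.<id>"`; link transfers must reference the namespaced ids.
#'
#' @param parts list of [biokinetic_model()] objects; names, when present,
#'   are used as namespacing prefixes.
#' @param links data.frame of link transfers (`donor`, `receiver`, `rate`,
#'   optional `nuclide`) across parts, or `NULL`.
#' @return The coupled [biokinetic_model()].  Nuclide chains are merged; a
#'   nuclide appearing in several parts must have the same decay constant.
#' @export
couple_models <- function(parts, links = NULL) {
  stopifnot(is.list(parts), length(parts) >= 1L)
  nm <- names(parts)
  prefixed <- function(i, ids) {
    if (!is.null(nm) && !is.na(nm[i]) && nzchar(nm[i]))
      paste0(nm[i], ".", ids) else ids
  }
  comp_l <- list(); tr_l <- list(); is_l <- list()
  nuc_all <- data.frame(name = character(), decay_constant = numeric(),
                        stringsAsFactors = FALSE)
  br_l <- list()
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    stopifnot(inherits(p, "biokinetic_model"))
    ci <- p$compartments; ci$id <- prefixed(i, ci$id)
    comp_l[[i]] <- ci
    ti <- p$transfers
    if (nrow(ti)) {
      ti$donor <- prefixed(i, ti$donor)
      ti$receiver <- prefixed(i, ti$receiver)
    }
    tr_l[[i]] <- ti
    si <- p$initial_state
    if (nrow(si)) si$compartment <- prefixed(i, si$compartment)
    is_l[[i]] <- si
    for (r in seq_len(nrow(p$nuclides))) {
      j <- match(p$nuclides$name[r], nuc_all$name)
      if (is.na(j)) {
        nuc_all <- rbind(nuc_all, p$nuclides[r, , drop = FALSE])
      } else if (nuc_all$decay_constant[j] != p$nuclides$decay_constant[r]) {
        stop("coupling error: nuclide '", p$nuclides$name[r],
             "' has conflicting decay constants across parts", call. = FALSE)
      }
    }
    br_l[[i]] <- p$branchings
  }
  comp <- do.call(rbind, comp_l)
  dup <- unique(comp$id[duplicated(comp$id)])
  if (length(dup))
    stop("coupling error: duplicate compartment id(s) ",
         paste0("'", dup, "'", collapse = ", "), call. = FALSE)
  tr <- do.call(rbind, tr_l)
  br <- unique(do.call(rbind, br_l))
  if (!is.null(links) && NROW(links)) {
    links <- as.data.frame(links, stringsAsFactors = FALSE)
    if (is.null(links$nuclide)) links$nuclide <- nuc_all$name[1L]
    if (any(!is.finite(links$rate) | links$rate < 0))
      stop("model error: link transfer rate must be non-negative",
           call. = FALSE)
    bad <- setdiff(unique(c(links$donor, links$receiver)), comp$id)
    if (length(bad))
      stop("coupling error: link references unknown compartment(s) ",
           paste0("'", bad, "'", collapse = ", "), call. = FALSE)
    tr <- rbind(tr, links[, c("donor", "receiver", "rate", "nuclide")])
  }
  biokinetic_model(compartments = comp, transfers = tr, nuclides = nuc_all,
                   branchings = br,
                   initial_state = do.call(rbind, is_l),
                   name = paste(vapply(parts, `[[`, "", "name"),
                                collapse = "+"))
}
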