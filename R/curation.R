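#' Parse a chemical formula string
#'
#' Parses formulas like `"C6H12O6"` into named element counts. Element
#' symbols are an upper-case letter optionally followed by lower-case
#' letters; a missing count means 1. Synthetic networks use single
#' pseudo-element formulas such as `"X"` or `"X2"`.
#'
#' @param formula formula string.
#' @return named numeric vector of element counts, or `NULL` if the
#'   formula is `NA` or cannot be parsed.
#' @export
parse_formula <- function(formula) {
  if (is.na(formula) || !nzchar(formula)) return(NULL)
  m <- gregexpr("[A-Z][a-z]*[0-9]*", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  if (!length(toks) || sum(attr(m, "match.length")) != nchar(formula)) return(NULL)
  el <- sub("[0-9]+$", "", toks)
  ct <- suppressWarnings(as.numeric(sub("^[A-Za-z]+", "", toks)))
  ct[is.na(ct)] <- 1
  out <- tapply(ct, factor(el, levels = unique(el)), sum)
  stats::setNames(as.numeric(out), names(out))
}

#' Elemental mass-balance check of a single reaction
#'
#' Sums stoichiometric coefficient times elemental composition over the
#' reaction's participants. Exchange, sink and biomass reactions cross the
#' system boundary by design and are reported as exempt rather than
#' checked.
#'
#' @param net a `metabolic_network`.
#' @param reaction_id reaction to check.
#' @return list with `status` (`"balanced"`, `"imbalanced"`, `"exempt"`,
#'   or `"uncheckable"` when a participant lacks a formula) and
#'   `imbalance`, a named vector of net element creation (positive =
#'   created from nothing).
#' @export
mass_balance_check <- function(net, reaction_id) {
  j <- match(reaction_id, net$reactions$id)
  if (is.na(j)) stop("unknown reaction id: ", reaction_id)
  if (net$reactions$kind[j] != "internal") {
    return(list(status = "exempt", imbalance = numeric(0)))
  }
  sv <- net$S[, j]
  sv <- sv[sv != 0]
  tot <- numeric(0)
  for (k in seq_along(sv)) {
    f <- net$metabolites$formula[match(names(sv)[k], net$metabolites$id)]
    counts <- parse_formula(f)
    if (is.null(counts)) {
      return(list(status = "uncheckable", imbalance = numeric(0)))
    }
    for (el in names(counts)) {
      tot[el] <- (if (el %in% names(tot)) tot[el] else 0) + sv[k] * counts[el]
    }
  }
  tot <- tot[abs(tot) > 1e-9]
  list(status = if (length(tot)) "imbalanced" else "balanced", imbalance = tot)
}

#' Scan a closed network for free-mass generation
#'
#' Detects thermodynamically infeasible mass creation by a sink-flux
#' maximization: one sink reaction (metabolite -> nothing, bounds
#' `[0, 1000]`) is added for every non-extracellular metabolite, every
#' exchange reaction is fixed to zero flux in both directions, and the sum
#' of sink fluxes is maximized subject to steady state. A strictly
#' positive optimum means some reactions create mass from nothing --
#' through a single imbalanced reaction or an amplifying loop -- and the
#' reactions carrying flux in the optimal solution are reported as
#' culprits. This catches mass-generating loops that per-reaction formula
#' balancing cannot, and needs no formula annotations at all.
#'
#' Alternate optima exist in general: the objective value is unique for a
#' fixed network, but the reported culprit support is one optimal solution
#' (the solver is deterministic, so it is reproducible). The scan reports;
#' removal via [remove_reactions()] is an explicit user action.
#'
#' @param net a `metabolic_network`.
#' @param sink_cap upper bound on each sink flux.
#' @param eps flux-activity tolerance for reporting active sinks and
#'   culprit reactions.
#' @return object of class `free_mass_report`: list with `objective`,
#'   `active_sinks` (data frame metabolite id / sink flux, decreasing),
#'   `culprit_reactions` (character vector of non-sink reactions with
#'   `|net flux| > eps`), and `fluxes` (net base-reaction fluxes).
#' @export
free_mass_scan <- function(net, sink_cap = 1000, eps = 1e-6) {
  validate_network(net)
  split <- split_reversible(net)
  comp <- split$components
  ## close all exchanges completely: 0 <= v_ex <= 0
  comp$ub[comp$base_id %in% net$reactions$id[net$reactions$kind == "exchange"]] <- 0
  sink_mets <- net$metabolites$id[net$metabolites$compartment != net$extracellular]
  n <- nrow(comp); ns <- length(sink_mets)
  sink_cols <- matrix(0, nrow(split$S), ns)
  sink_cols[cbind(match(sink_mets, rownames(split$S)), seq_len(ns))] <- -1
  A <- cbind(as.matrix(split$S), sink_cols)
  obj <- c(numeric(n), rep(1, ns))
  ub <- c(comp$ub, rep(sink_cap, ns))
  sol <- solve_lp(obj, A, lb = numeric(n + ns), ub = ub, sense = "max")
  if (sol$status != "optimal") stop("free-mass LP did not solve: ", sol$status)
  sink_flux <- stats::setNames(sol$x[n + seq_len(ns)], sink_mets)
  active <- sink_flux[sink_flux > eps]
  net_v <- net_fluxes(split, stats::setNames(sol$x[seq_len(n)], comp$id))
  culprits <- names(net_v)[abs(net_v) > eps]
  structure(list(
    objective = max(0, sol$objective),
    active_sinks = data.frame(
      metabolite_id = names(sort(active, decreasing = TRUE)),
      sink_flux = unname(sort(active, decreasing = TRUE)),
      stringsAsFactors = FALSE),
    culprit_reactions = culprits,
    fluxes = net_v), class = "free_mass_report")
}

#' @export
print.free_mass_report <- function(x, ...) {
  cat("free_mass_report: objective =", format(x$objective), "\n")
  if (x$objective <= 0 || !nrow(x$active_sinks)) {
    cat("  no free-mass generation detected\n")
  } else {
    cat("  active sinks:", nrow(x$active_sinks),
        " culprit reactions:", length(x$culprit_reactions), "\n")
  }
  invisible(x)
}

#' Write a free-mass curation report
#'
#' One row per mass-generating metabolite with its sink flux; the culprit
#' reaction set of the optimal solution is attached to every row.
#'
#' @param report a `free_mass_report`.
#' @param path output TSV path.
#' @export
write_free_mass_report <- function(report, path) {
  tb <- report$active_sinks
  if (nrow(tb)) {
    tb$culprit_reaction_ids <- paste(report$culprit_reactions, collapse = ",")
  } else {
    tb <- data.frame(metabolite_id = character(0), sink_flux = numeric(0),
                     culprit_reaction_ids = character(0))
  }
  utils::write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
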