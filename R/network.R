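#' Construct a universal metabolic network
#'
#' The central container of the package: a stoichiometric network over
#' typed reactions (internal, exchange, sink, biomass) with per-reaction
#' flux bounds, used both as the curated universal biochemical network and
#' as the organism-specific model derived from it.
#'
#' Conventions: an exchange reaction is written `1 metabolite <-> nothing`
#' with stoichiometric coefficient -1 on a single extracellular metabolite,
#' so negative flux is uptake and positive flux is secretion. Default
#' bounds are 0 and +/-1000 mmol/gDW/h.
#'
#' @param metabolites data frame with columns `id`, `formula` (chemical
#'   formula string, `NA` if unknown), `charge`, `compartment`.
#' @param reactions data frame with columns `id`, `lb`, `ub`, `kind`
#'   (one of `"internal"`, `"exchange"`, `"sink"`, `"biomass"`). If `kind`
#'   is missing it is inferred: single-metabolite reactions on the
#'   extracellular compartment are exchanges, other single-metabolite
#'   reactions are sinks, the biomass id is biomass, the rest internal.
#' @param stoichiometry either a sparse/dense matrix (metabolites x
#'   reactions, dimnames matching the ids) or a list of named numeric
#'   vectors (one per reaction, names = metabolite ids, negative =
#'   consumed).
#' @param biomass_id id of the designated biomass reaction.
#' @param extracellular compartment tag meaning "outside the cell".
#' @return an object of class `metabolic_network`.
#' @export
metabolic_network <- function(metabolites, reactions, stoichiometry,
                              biomass_id, extracellular = "e") {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  req_m <- c("id", "formula", "charge", "compartment")
  for (col in setdiff(req_m, names(metabolites))) {
    metabolites[[col]] <- if (col == "charge") 0L else NA_character_
  }
  metabolites <- metabolites[req_m]
  if (anyDuplicated(metabolites$id)) {
    stop("duplicate metabolite ids: ",
         paste(unique(metabolites$id[duplicated(metabolites$id)]), collapse = ", "))
  }
  if (anyDuplicated(reactions$id)) {
    stop("duplicate reaction ids: ",
         paste(unique(reactions$id[duplicated(reactions$id)]), collapse = ", "))
  }
  if (is.list(stoichiometry) && !is.data.frame(stoichiometry) &&
      !inherits(stoichiometry, "Matrix") && !is.matrix(stoichiometry)) {
    S <- stoich_list_to_matrix(stoichiometry, metabolites$id, reactions$id)
  } else {
    S <- Matrix::Matrix(stoichiometry, sparse = TRUE)
    if (is.null(dimnames(S)) || is.null(rownames(S))) {
      dimnames(S) <- list(metabolites$id, reactions$id)
    }
    S <- S[metabolites$id, reactions$id, drop = FALSE]
  }
  if (!"lb" %in% names(reactions)) reactions$lb <- -1000
  if (!"ub" %in% names(reactions)) reactions$ub <- 1000
  reactions$lb <- as.numeric(reactions$lb)
  reactions$ub <- as.numeric(reactions$ub)
  metabolites$charge <- as.integer(metabolites$charge)
  if (any(reactions$lb > reactions$ub)) {
    stop("reaction with lower bound above upper bound")
  }
  empty <- Matrix::colSums(abs(S)) == 0
  if (any(empty)) {
    stop("reaction(s) with empty stoichiometry: ",
         paste(reactions$id[empty], collapse = ", "))
  }
  if (!"kind" %in% names(reactions) || anyNA(reactions$kind)) {
    kind <- infer_reaction_kinds(S, metabolites, reactions$id, biomass_id,
                                 extracellular)
    if (!"kind" %in% names(reactions)) reactions$kind <- kind
    else reactions$kind[is.na(reactions$kind)] <- kind[is.na(reactions$kind)]
  }
  if (!biomass_id %in% reactions$id) {
    stop("biomass reaction '", biomass_id, "' not found in the network")
  }
  reactions$kind[reactions$id == biomass_id] <- "biomass"
  bad_kind <- setdiff(reactions$kind, c("internal", "exchange", "sink", "biomass"))
  if (length(bad_kind)) stop("unknown reaction kind: ", paste(bad_kind, collapse = ", "))
  net <- structure(
    list(metabolites = metabolites, reactions = reactions, S = S,
         biomass_id = biomass_id, extracellular = extracellular),
    class = "metabolic_network")
  validate_network(net)
  net
}

stoich_list_to_matrix <- function(stoich, met_ids, rxn_ids) {
  if (length(stoich) != length(rxn_ids)) {
    stop("stoichiometry list length does not match number of reactions")
  }
  i <- integer(0); j <- integer(0); x <- numeric(0)
  for (col in seq_along(stoich)) {
    sv <- stoich[[col]]
    if (!length(sv)) stop("reaction '", rxn_ids[col], "' has empty stoichiometry")
    rows <- match(names(sv), met_ids)
    if (anyNA(rows)) {
      stop("reaction '", rxn_ids[col], "' references undeclared metabolite(s): ",
           paste(names(sv)[is.na(rows)], collapse = ", "))
    }
    i <- c(i, rows); j <- c(j, rep(col, length(sv))); x <- c(x, unname(sv))
  }
  Matrix::sparseMatrix(i = i, j = j, x = x,
                       dims = c(length(met_ids), length(rxn_ids)),
                       dimnames = list(met_ids, rxn_ids))
}

infer_reaction_kinds <- function(S, metabolites, rxn_ids, biomass_id,
                                 extracellular) {
  comp <- metabolites$compartment[match(rownames(S), metabolites$id)]
  vapply(seq_along(rxn_ids), function(j) {
    if (rxn_ids[j] == biomass_id) return("biomass")
    rows <- which(S[, j] != 0)
    if (length(rows) == 1) {
      if (identical(comp[rows], extracellular)) "exchange" else "sink"
    } else "internal"
  }, character(1))
}

validate_network <- function(net) {
  stopifnot(inherits(net, "metabolic_network"))
  used <- rownames(net$S)[Matrix::rowSums(abs(net$S)) > 0]
  missing <- setdiff(used, net$metabolites$id)
  if (length(missing)) {
    stop("dangling metabolite reference(s): ", paste(missing, collapse = ", "))
  }
  ex <- which(net$reactions$kind == "exchange")
  comp <- net$metabolites$compartment[match(rownames(net$S), net$metabolites$id)]
  for (j in ex) {
    rows <- which(net$S[, j] != 0)
    if (length(rows) != 1 || !identical(comp[rows], net$extracellular)) {
      stop("exchange reaction '", net$reactions$id[j],
           "' must touch exactly one extracellular metabolite")
    }
  }
  invisible(net)
}

#' @export
print.metabolic_network <- function(x, ...) {
  kinds <- table(x$reactions$kind)
  cat("metabolic_network:", nrow(x$metabolites), "metabolites,",
      nrow(x$reactions), "reactions\n")
  cat("  kinds:", paste(names(kinds), kinds, sep = "=", collapse = ", "), "\n")
  cat("  biomass:", x$biomass_id,
      " extracellular compartment:", x$extracellular, "\n")
  invisible(x)
}

#' Reversibility of each reaction
#'
#' A reaction is reversible when its lower bound is negative and its upper
#' bound positive.
#' @param net a `metabolic_network`.
#' @return named logical vector over reaction ids.
#' @export
is_reversible <- function(net) {
  stats::setNames(net$reactions$lb < 0 & net$reactions$ub > 0,
                  net$reactions$id)
}

#' Remove reactions from a network
#'
#' Returns a copy of the network without the listed reactions. Metabolites
#' that become orphaned are retained: in a universal network they may still
#' matter in another organism's context.
#'
#' @param net a `metabolic_network`.
#' @param ids character vector of reaction ids to drop.
#' @return the reduced `metabolic_network`.
#' @export
remove_reactions <- function(net, ids) {
  if (!length(ids)) return(net)
  unknown <- setdiff(ids, net$reactions$id)
  if (length(unknown)) {
    stop("unknown reaction id(s): ", paste(unknown, collapse = ", "))
  }
  if (net$biomass_id %in% ids) stop("cannot remove the biomass reaction")
  keep <- !(net$reactions$id %in% ids)
  net$reactions <- net$reactions[keep, , drop = FALSE]
  rownames(net$reactions) <- NULL
  net$S <- net$S[, keep, drop = FALSE]
  net
}

#' Define a growth-media condition
#'
#' A media condition lists, per exchange reaction, the maximum uptake
#' magnitude allowed; every exchange not listed is closed to uptake.
#' Secretion is never constrained by a media condition.
#'
#' @param id condition label.
#' @param uptake named numeric vector: exchange reaction id -> maximum
#'   uptake magnitude (>= 0), in mmol/gDW/h.
#' @return an object of class `media_condition`.
#' @export
media_condition <- function(id, uptake) {
  uptake <- unlist(uptake)
  if (length(uptake) && (is.null(names(uptake)) || any(!nzchar(names(uptake))))) {
    stop("uptake must be a named vector of exchange reaction ids")
  }
  if (any(uptake < 0)) stop("uptake magnitudes must be >= 0")
  structure(list(id = as.character(id), uptake = uptake),
            class = "media_condition")
}

#' @export
print.media_condition <- function(x, ...) {
  cat("media_condition '", x$id, "': ", length(x$uptake),
      " open uptake(s)\n", sep = "")
  if (length(x$uptake)) {
    cat(" ", paste(names(x$uptake), x$uptake, sep = "<=", collapse = ", "), "\n")
  }
  invisible(x)
}
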