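#' Split reversible reactions into forward and reverse components
#'
#' Every reversible reaction is represented as two opposing irreversible
#' components so that all flux variables are non-negative; the net flux of
#' a base reaction is forward minus reverse component flux. dgFBA, pFBA and
#' the free-mass scan are all formulated on this split network.
#'
#' Component bounds: the forward component gets `[0, ub]` of the base
#' reaction (0 if `ub < 0`), the reverse component `[0, -lb]` (0 if
#' `lb > 0`). Irreversible reactions keep a single component in their
#' feasible direction.
#'
#' @param net a `metabolic_network`.
#' @return an object of class `split_network`: the base network plus a
#'   component table (`id`, `base_id`, `direction`, `ub`) and the split
#'   stoichiometric matrix.
#' @export
split_reversible <- function(net) {
  stopifnot(inherits(net, "metabolic_network"))
  rx <- net$reactions
  comp <- do.call(rbind, lapply(seq_len(nrow(rx)), function(j) {
    out <- NULL
    if (rx$ub[j] > 0) {
      out <- rbind(out, data.frame(base_id = rx$id[j], direction = "forward",
                                   ub = rx$ub[j], sign = 1,
                                   stringsAsFactors = FALSE))
    }
    if (rx$lb[j] < 0) {
      out <- rbind(out, data.frame(base_id = rx$id[j], direction = "reverse",
                                   ub = -rx$lb[j], sign = -1,
                                   stringsAsFactors = FALSE))
    }
    if (is.null(out)) {  # fixed-zero reaction: keep a closed forward slot
      out <- data.frame(base_id = rx$id[j], direction = "forward", ub = 0,
                        sign = 1, stringsAsFactors = FALSE)
    }
    out
  }))
  comp$id <- ifelse(comp$direction == "forward",
                    paste0(comp$base_id, "__fwd"),
                    paste0(comp$base_id, "__rev"))
  S <- net$S[, match(comp$base_id, rx$id), drop = FALSE]
  S <- S %*% Matrix::Diagonal(x = comp$sign)
  dimnames(S) <- list(rownames(net$S), comp$id)
  structure(list(base = net,
                 components = comp[c("id", "base_id", "direction", "ub")],
                 S = S),
            class = "split_network")
}

#' @export
print.split_network <- function(x, ...) {
  cat("split_network:", nrow(x$components), "components over",
      nrow(x$base$reactions), "base reactions\n")
  invisible(x)
}

#' Apply a media condition to a split network
#'
#' Closes the uptake component of every exchange reaction that the media
#' does not list, and caps the listed ones at the stated uptake magnitude.
#' Under the exchange convention (`1 metabolite <-> nothing`, negative flux
#' = uptake) the uptake direction is the reverse component. Secretion
#' components and internal-reaction bounds are never altered.
#'
#' @param split a `split_network`.
#' @param media a `media_condition`.
#' @return the `split_network` with adjusted uptake bounds.
#' @export
apply_media <- function(split, media) {
  stopifnot(inherits(split, "split_network"), inherits(media, "media_condition"))
  rx <- split$base$reactions
  ex_ids <- rx$id[rx$kind == "exchange"]
  bad <- setdiff(names(media$uptake), ex_ids)
  if (length(bad)) {
    stop("media '", media$id, "' references non-exchange reaction(s): ",
         paste(bad, collapse = ", "))
  }
  comp <- split$components
  is_uptake <- comp$base_id %in% ex_ids & comp$direction == "reverse"
  comp$ub[is_uptake] <- 0
  listed <- is_uptake & comp$base_id %in% names(media$uptake)
  comp$ub[listed] <- unname(media$uptake[comp$base_id[listed]])
  split$components <- comp
  split
}

#' Recombine split-component fluxes into net base-reaction fluxes
#'
#' @param split a `split_network`.
#' @param flux named numeric vector over component ids.
#' @return named numeric vector of net fluxes over base reaction ids
#'   (forward minus reverse).
#' @export
net_fluxes <- function(split, flux) {
  comp <- split$components
  v <- flux[comp$id]
  v[is.na(v)] <- 0
  signed <- ifelse(comp$direction == "forward", v, -v)
  out <- tapply(signed, factor(comp$base_id, levels = unique(comp$base_id)), sum)
  stats::setNames(as.numeric(out), names(out))[split$base$reactions$id]
}
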