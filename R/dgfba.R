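#' Build the data-guided FBA linear program
#'
#' dgFBA maximizes the sum of weighted flux over all split components
#' subject to steady state, component bounds and a required minimum
#' biomass flux. Reactions with positive weight (substantial genetic
#' evidence) are maximized and reactions with negative weight (low or no
#' evidence) are minimized, each proportionally to the weight; both split
#' components of a reversible reaction inherit the base reaction's weight.
#' Reactions absent from `weights` default to -1 (no evidence). The
#' problem is a plain LP, not a MILP.
#'
#' @param split a `split_network`, typically after [apply_media()].
#' @param weights named numeric vector of reaction weights in `[-1, 1]`
#'   (see [reaction_weights()]); missing reactions default to -1.
#' @param biomass_min minimum required biomass flux (default 0.1, aligned
#'   with the growth-call threshold).
#' @return an object of class `lp_spec`: objective, constraint matrix,
#'   bounds and the component table.
#' @export
build_dgfba <- function(split, weights = numeric(0), biomass_min = 0.1) {
  stopifnot(inherits(split, "split_network"))
  comp <- split$components
  if (!split$base$biomass_id %in% comp$base_id) stop("biomass reaction missing")
  w <- weights[comp$base_id]
  w[is.na(w)] <- -1
  if (any(w < -1 | w > 1)) stop("weights must lie in [-1, 1]")
  lb <- numeric(nrow(comp))
  bio_fwd <- comp$base_id == split$base$biomass_id & comp$direction == "forward"
  lb[bio_fwd] <- biomass_min
  structure(list(objective = unname(w), A = split$S, lb = lb, ub = comp$ub,
                 components = comp, split = split, sense = "max"),
            class = "lp_spec")
}

#' Solve an LP spec into a flux solution
#'
#' @param spec an `lp_spec` from [build_dgfba()].
#' @return object of class `flux_solution`: `status` (`"optimal"` or
#'   `"infeasible"`), `fluxes` (named vector over split components, `NULL`
#'   unless optimal) and `objective`.
#' @export
solve_flux <- function(spec) {
  stopifnot(inherits(spec, "lp_spec"))
  sol <- solve_lp(spec$objective, spec$A, lb = spec$lb, ub = spec$ub,
                  sense = spec$sense)
  if (sol$status == "unbounded") stop("unbounded dgFBA objective: check bounds")
  structure(list(
    status = if (sol$status == "optimal") "optimal" else "infeasible",
    fluxes = if (sol$status == "optimal")
      stats::setNames(sol$x, spec$components$id) else NULL,
    objective = sol$objective,
    components = spec$components, split = spec$split),
    class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("flux_solution:", x$status)
  if (x$status == "optimal") cat(", objective =", format(x$objective))
  cat("\n")
  invisible(x)
}

#' Extract the flux-carrying reactions from a dgFBA solution
#'
#' Per base reaction the net flux is forward minus reverse component flux;
#' reactions with `|net flux| > eps` carry flux, tagged with the direction
#' of the net flux. A reaction whose two components cancel exactly (a
#' bound-capped pumping pair) has net flux 0 and is excluded, so a
#' reaction contributes at most one direction per solution.
#'
#' @param sol an optimal `flux_solution`.
#' @param eps net-flux activity tolerance.
#' @return object of class `fcr_set`: data frame with columns
#'   `reaction_id`, `direction` (`"forward"`/`"reverse"`), `net_flux`.
#' @export
extract_fcrs <- function(sol, eps = 1e-6) {
  stopifnot(inherits(sol, "flux_solution"))
  if (sol$status != "optimal") {
    stop("cannot extract flux-carrying reactions from an infeasible solution")
  }
  nv <- net_fluxes(sol$split, sol$fluxes)
  keep <- abs(nv) > eps
  structure(data.frame(
    reaction_id = names(nv)[keep],
    direction = ifelse(nv[keep] > 0, "forward", "reverse"),
    net_flux = unname(nv[keep]),
    stringsAsFactors = FALSE, row.names = NULL), class = c("fcr_set", "data.frame"))
}

#' Data-guided FBA for one media condition
#'
#' Convenience wrapper: applies the media, builds and solves the dgFBA LP
#' and extracts flux-carrying reactions. With `weights = NULL` every
#' reaction defaults to weight -1 and the problem reduces to parsimonious
#' FBA (minimize total flux subject to the biomass requirement), which is
#' how the pFBA comparison runs are produced.
#'
#' Because alternate optima exist, the flux-carrying set at the optimum
#' can depend on the pivot path. The default single solve is
#' deterministic (fixed pivot rule); `canonical = TRUE` additionally
#' re-solves with the weighted objective pinned at its optimum while
#' minimizing total unweighted flux, selecting a canonical minimal-flux
#' representative among the optima. Off by default to match the plain
#' single-solve training description.
#'
#' @param net a `metabolic_network` or pre-built `split_network`.
#' @param media a [media_condition()].
#' @param weights named weight vector, or `NULL` for pFBA.
#' @param biomass_min required biomass flux.
#' @param eps net-flux tolerance for FCR extraction.
#' @param canonical apply the secondary total-flux minimization.
#' @return list with `solution` (a `flux_solution`) and `fcrs` (an
#'   `fcr_set`, empty when infeasible).
#' @export
dgfba <- function(net, media, weights = numeric(0), biomass_min = 0.1,
                  eps = 1e-6, canonical = FALSE) {
  split <- if (inherits(net, "split_network")) net else split_reversible(net)
  split <- apply_media(split, media)
  if (is.null(weights)) weights <- numeric(0)
  spec <- build_dgfba(split, weights, biomass_min = biomass_min)
  sol <- solve_flux(spec)
  if (canonical && sol$status == "optimal") {
    A2 <- rbind(as.matrix(spec$A), spec$objective)
    b2 <- c(numeric(nrow(spec$A)), sol$objective)
    sec <- solve_lp(rep(1, length(spec$objective)), A2, b = b2,
                    lb = spec$lb, ub = spec$ub, sense = "min")
    if (sec$status == "optimal") {
      sol$fluxes <- stats::setNames(sec$x, spec$components$id)
    }
  }
  fcrs <- if (sol$status == "optimal") extract_fcrs(sol, eps = eps) else
    structure(data.frame(reaction_id = character(0), direction = character(0),
                         net_flux = numeric(0), stringsAsFactors = FALSE),
              class = c("fcr_set", "data.frame"))
  list(solution = sol, fcrs = fcrs)
}

#' Plain FBA growth simulation
#'
#' Maximizes biomass flux under a media condition. Returns the optimal
#' biomass flux, 0 when the problem is infeasible.
#'
#' @param net a `metabolic_network` or `split_network`.
#' @param media a [media_condition()].
#' @return optimal biomass flux (numeric scalar).
#' @export
fba_growth <- function(net, media) {
  split <- if (inherits(net, "split_network")) net else split_reversible(net)
  split <- apply_media(split, media)
  comp <- split$components
  obj <- as.numeric(comp$base_id == split$base$biomass_id &
                      comp$direction == "forward")
  sol <- solve_lp(obj, split$S, lb = numeric(nrow(comp)), ub = comp$ub,
                  sense = "max")
  if (sol$status != "optimal") 0 else max(0, sol$objective)
}

#' Binary growth call from a biomass flux
#'
#' A condition has simulated growth when the FBA biomass flux is strictly
#' greater than the threshold (default 0.1).
#'
#' @param flux biomass flux value(s).
#' @param threshold growth-call threshold.
#' @return character vector, `"growth"` or `"no_growth"`.
#' @export
growth_call <- function(flux, threshold = 0.1) {
  ifelse(flux > threshold, "growth", "no_growth")
}

#' Report flux-pumping cycles at their bounds
#'
#' Positive-weight reversible reactions (and positive-weight internal
#' loops) are objective-improving up to their flux caps, so a dgFBA
#' optimum routinely drives such component pairs to a bound with zero net
#' flux. They never enter the flux-carrying set (the net-flux rule removes
#' them), but this report lists base reactions with a component at its
#' upper bound and `|net flux| <= eps` so inflated solutions can be
#' inspected.
#'
#' @param sol an optimal `flux_solution`.
#' @param eps net-flux tolerance.
#' @return data frame with columns `reaction_id`, `forward`, `reverse`.
#' @export
loop_report <- function(sol, eps = 1e-6) {
  stopifnot(inherits(sol, "flux_solution"), sol$status == "optimal")
  comp <- sol$components
  at_cap <- sol$fluxes >= comp$ub - 1e-7 & comp$ub > 0
  nv <- net_fluxes(sol$split, sol$fluxes)
  cand <- unique(comp$base_id[at_cap])
  cand <- cand[abs(nv[cand]) <= eps]
  if (!length(cand)) {
    return(data.frame(reaction_id = character(0), forward = numeric(0),
                      reverse = numeric(0), stringsAsFactors = FALSE))
  }
  fwd <- sol$fluxes[paste0(cand, "__fwd")]
  rev <- sol$fluxes[paste0(cand, "__rev")]
  data.frame(reaction_id = cand,
             forward = unname(ifelse(is.na(fwd), 0, fwd)),
             reverse = unname(ifelse(is.na(rev), 0, rev)),
             stringsAsFactors = FALSE)
}
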