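#' Compute direction-specific reaction certainty values
#'
#' The certainty value (CV) of a reaction in a given direction is the
#' ratio of the number of training growth conditions in which the reaction
#' carries net flux in that direction to the total number of training
#' growth conditions. Because each per-condition solution assigns a
#' reaction at most one net-flux direction, the forward and reverse CVs of
#' a reaction always sum to at most 1.
#'
#' The denominator counts every experimentally growth-positive condition
#' used for training, including conditions whose dgFBA solve was
#' infeasible (those contribute no flux-carrying reactions but remain part
#' of the evidence base).
#'
#' @param fcr_sets named list of `fcr_set` objects, one per training
#'   growth condition (empty data frames allowed for infeasible solves).
#' @param n_conditions denominator; defaults to `length(fcr_sets)`.
#' @return object of class `certainty_table`: data frame with columns
#'   `reaction_id`, `direction`, `cv` (only rows with `cv > 0`), ordered
#'   by decreasing cv; attribute `n_conditions`.
#' @export
compute_cvs <- function(fcr_sets, n_conditions = length(fcr_sets)) {
  if (!length(fcr_sets)) stop("no training conditions: cannot compute certainty values")
  if (n_conditions < length(fcr_sets)) {
    stop("n_conditions cannot be smaller than the number of FCR sets")
  }
  all_fcr <- do.call(rbind, lapply(fcr_sets, function(f)
    as.data.frame(f)[c("reaction_id", "direction")]))
  if (is.null(all_fcr) || !nrow(all_fcr)) {
    tb <- data.frame(reaction_id = character(0), direction = character(0),
                     cv = numeric(0), stringsAsFactors = FALSE)
  } else {
    counts <- stats::aggregate(list(n = rep(1L, nrow(all_fcr))),
                               all_fcr[c("reaction_id", "direction")], sum)
    tb <- data.frame(reaction_id = counts$reaction_id,
                     direction = counts$direction,
                     cv = counts$n / n_conditions, stringsAsFactors = FALSE)
    tb <- tb[order(-tb$cv, tb$reaction_id, tb$direction), , drop = FALSE]
    rownames(tb) <- NULL
  }
  structure(tb, class = c("certainty_table", "data.frame"),
            n_conditions = n_conditions)
}

#' Assemble an organism-specific model from certainty values
#'
#' Includes exactly the reactions with CV > 0 in at least one direction,
#' with directionality restricted to the directions that received a CV: a
#' reversible reaction certain in only one direction is made irreversible
#' in that direction; one certain in both directions stays reversible.
#' Reactions with genetic evidence but CV = 0 are excluded. Exchange
#' reactions and the biomass reaction are structural necessities and are
#' always retained with their original bounds.
#'
#' @param universal the universal `metabolic_network` used for training.
#' @param certainty a `certainty_table` from [compute_cvs()].
#' @param evidence optional evidence data frame (`reaction_id`,
#'   `bitscore`) carried along for ranking and discovery analysis.
#' @param fcr_sets optional per-condition FCR provenance, stored as-is.
#' @return object of class `canyuns_model`: list with `network` (the
#'   restricted `metabolic_network`), `certainty`, `evidence`, and
#'   `provenance`.
#' @export
assemble_model <- function(universal, certainty, evidence = NULL,
                           fcr_sets = NULL) {
  stopifnot(inherits(universal, "metabolic_network"))
  unknown <- setdiff(certainty$reaction_id, universal$reactions$id)
  if (length(unknown)) {
    stop("certainty table references unknown reaction(s): ",
         paste(unknown, collapse = ", "))
  }
  rx <- universal$reactions
  structural <- rx$kind %in% c("exchange", "biomass")
  has_fwd <- rx$id %in% certainty$reaction_id[certainty$direction == "forward"]
  has_rev <- rx$id %in% certainty$reaction_id[certainty$direction == "reverse"]
  keep <- structural | has_fwd | has_rev
  rx <- rx[keep, , drop = FALSE]
  fwd <- has_fwd[keep]; rev <- has_rev[keep]; strc <- structural[keep]
  ## direction restriction for non-structural reactions with one-sided CVs
  restrict <- !strc
  rx$lb[restrict & fwd & !rev] <- pmax(rx$lb[restrict & fwd & !rev], 0)
  rx$ub[restrict & !fwd & rev] <- pmin(rx$ub[restrict & !fwd & rev], 0)
  net <- metabolic_network(universal$metabolites, rx,
                           universal$S[, keep, drop = FALSE],
                           biomass_id = universal$biomass_id,
                           extracellular = universal$extracellular)
  structure(list(network = net, certainty = certainty, evidence = evidence,
                 provenance = fcr_sets),
            class = "canyuns_model")
}

#' @export
print.canyuns_model <- function(x, ...) {
  rx <- x$network$reactions
  cv_rxns <- unique(x$certainty$reaction_id)
  cat("canyuns_model:", nrow(rx), "reactions (",
      sum(rx$id %in% cv_rxns), "with CV > 0 ) over",
      attr(x$certainty, "n_conditions"), "training conditions\n")
  cat("  forward CVs:", sum(x$certainty$direction == "forward"),
      " reverse CVs:", sum(x$certainty$direction == "reverse"),
      " both:", sum(table(x$certainty$reaction_id) == 2), "\n")
  invisible(x)
}

#' Simulate growth phenotypes across media conditions
#'
#' Runs plain FBA (maximize biomass) for each condition and calls growth
#' when the optimal biomass flux is strictly greater than the threshold.
#'
#' @param model a `canyuns_model` or bare `metabolic_network`.
#' @param media named list of [media_condition()] objects.
#' @param threshold growth-call threshold (default 0.1).
#' @return data frame with columns `condition_id`, `biomass_flux`, `call`.
#' @export
simulate_phenotypes <- function(model, media, threshold = 0.1) {
  net <- if (inherits(model, "canyuns_model")) model$network else model
  split <- split_reversible(net)
  flux <- vapply(media, function(m) fba_growth(split, m), numeric(1))
  data.frame(condition_id = vapply(media, `[[`, character(1), "id"),
             biomass_flux = unname(flux),
             call = growth_call(unname(flux), threshold),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Confusion matrix of growth predictions against observed phenotypes
#'
#' Growth observed and predicted is a true positive; no-growth observed
#' and predicted a true negative. Accuracy is `(TP+TN)/total`; the
#' Matthews correlation coefficient uses the standard formula and is
#' reported as 0 (flagged `mcc_degenerate`) when any marginal factor of
#' its denominator is zero.
#'
#' @param predictions data frame from [simulate_phenotypes()].
#' @param observed data frame with columns `condition_id`, `call`.
#' @return object of class `canyuns_confusion`: list with `tp`, `fp`,
#'   `tn`, `fn`, `accuracy`, `mcc`, `mcc_degenerate` and `per_condition`.
#' @export
evaluate_predictions <- function(predictions, observed) {
  m <- merge(predictions[c("condition_id", "call")],
             observed[c("condition_id", "call")],
             by = "condition_id", suffixes = c("_pred", "_obs"))
  if (!nrow(m)) stop("no overlapping conditions between predictions and phenotypes")
  tp <- sum(m$call_pred == "growth" & m$call_obs == "growth")
  fp <- sum(m$call_pred == "growth" & m$call_obs == "no_growth")
  tn <- sum(m$call_pred == "no_growth" & m$call_obs == "no_growth")
  fn <- sum(m$call_pred == "no_growth" & m$call_obs == "growth")
  denom <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  degenerate <- denom == 0
  mcc <- if (degenerate) 0 else
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(denom)
  m$quadrant <- ifelse(m$call_obs == "growth",
                       ifelse(m$call_pred == "growth", "TP", "FN"),
                       ifelse(m$call_pred == "growth", "FP", "TN"))
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 accuracy = (tp + tn) / nrow(m), mcc = mcc,
                 mcc_degenerate = degenerate, per_condition = m),
            class = "canyuns_confusion")
}

#' @export
print.canyuns_confusion <- function(x, ...) {
  cat(sprintf("confusion: TP=%d FP=%d TN=%d FN=%d | accuracy=%.3f MCC=%.3f%s\n",
              x$tp, x$fp, x$tn, x$fn, x$accuracy, x$mcc,
              if (x$mcc_degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Conditionally essential reactions per predicted-growth condition
#'
#' A reaction is conditionally essential in a condition when closing it
#' (both directions to zero) drops the FBA biomass optimum to at or below
#' the growth threshold. Only conditions predicted to grow (true and
#' false positives alike) are screened; exchange reactions and the
#' biomass reaction are structural and excluded from the screen.
#'
#' @param model a `canyuns_model` or `metabolic_network`.
#' @param media named list of media conditions.
#' @param predictions data frame from [simulate_phenotypes()]; recomputed
#'   when `NULL`.
#' @param threshold growth-call threshold.
#' @return data frame with columns `condition_id`, `reaction_id`, one row
#'   per (condition, essential reaction) pair.
#' @export
conditional_essentiality <- function(model, media, predictions = NULL,
                                     threshold = 0.1) {
  net <- if (inherits(model, "canyuns_model")) model$network else model
  if (is.null(predictions)) predictions <- simulate_phenotypes(net, media, threshold)
  grow <- predictions$condition_id[predictions$call == "growth"]
  rx <- net$reactions
  screen <- rx$id[!(rx$kind %in% c("exchange", "biomass"))]
  split <- split_reversible(net)
  out <- list()
  for (cid in grow) {
    sp <- apply_media(split, media[[cid]])
    comp <- sp$components
    obj <- as.numeric(comp$base_id == net$biomass_id & comp$direction == "forward")
    ess <- character(0)
    for (r in screen) {
      ub <- comp$ub
      ub[comp$base_id == r] <- 0
      sol <- solve_lp(obj, sp$S, lb = numeric(nrow(comp)), ub = ub, sense = "max")
      flux <- if (sol$status == "optimal") sol$objective else 0
      if (flux <= threshold) ess <- c(ess, r)
    }
    if (length(ess)) {
      out[[cid]] <- data.frame(condition_id = cid, reaction_id = ess,
                               stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(condition_id = character(0), reaction_id = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Rank reactions by net benefit of removal
#'
#' For each reaction that is conditionally essential somewhere,
#' `fp_corrected` counts the false-positive conditions in which it is
#' essential (removing it corrects those), `tp_lost` the true-positive
#' conditions (removing it loses those); the net benefit is their
#' difference. Records are ranked by net benefit decreasing, ties broken
#' by annotation evidence increasing, so the top record is the reaction
#' with the most leverage to improve accuracy and the least genetic
#' support.
#'
#' @param essentiality data frame from [conditional_essentiality()].
#' @param predictions data frame from [simulate_phenotypes()].
#' @param observed phenotype data frame (`condition_id`, `call`).
#' @param evidence optional evidence data frame for the tie-break
#'   bitscores (absent reactions score 0).
#' @return data frame with columns `reaction_id`, `fp_corrected`,
#'   `tp_lost`, `net_benefit`, `bitscore`, ordered best-first.
#' @export
net_benefit_ranking <- function(essentiality, predictions, observed,
                                evidence = NULL) {
  ev <- evaluate_predictions(predictions, observed)$per_condition
  quad <- stats::setNames(ev$quadrant, ev$condition_id)
  essentiality$quadrant <- quad[essentiality$condition_id]
  rids <- unique(essentiality$reaction_id)
  fp <- vapply(rids, function(r) sum(essentiality$reaction_id == r &
                                       essentiality$quadrant == "FP"), integer(1))
  tp <- vapply(rids, function(r) sum(essentiality$reaction_id == r &
                                       essentiality$quadrant == "TP"), integer(1))
  b <- if (is.null(evidence)) rep(0, length(rids)) else
    evidence_bitscore(evidence, rids)
  out <- data.frame(reaction_id = rids, fp_corrected = fp, tp_lost = tp,
                    net_benefit = fp - tp, bitscore = b,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$net_benefit, out$bitscore, out$reaction_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove reactions from an assembled model
#'
#' Pruning is an explicit user action on the ranked net-benefit records
#' (removal of the single worst offender, or the top-N for unattended
#' runs); the certainty table keeps the pruned reactions' history, only
#' the simulatable network changes.
#'
#' @param model a `canyuns_model`.
#' @param ids reaction ids to remove.
#' @return the pruned `canyuns_model`.
#' @export
prune_model <- function(model, ids) {
  stopifnot(inherits(model, "canyuns_model"))
  model$network <- remove_reactions(model$network, ids)
  model$pruned <- c(model$pruned, ids)
  model
}

#' Rarefaction of unique flux-carrying reactions
#'
#' For each subset size k = 1..N, samples `n_samples` subsets of k
#' distinct conditions (subsets drawn independently, i.e. with
#' replacement across samples) and records the number of unique reactions
#' in the union of their flux-carrying sets. Deterministic for a fixed
#' seed.
#'
#' @param fcr_sets named list of `fcr_set` objects.
#' @param n_samples subsets drawn per k (default 10000).
#' @param seed RNG seed.
#' @return data frame with columns `k`, `min`, `mean`, `max`.
#' @export
rarefaction <- function(fcr_sets, n_samples = 10000, seed = 1) {
  N <- length(fcr_sets)
  if (!N) stop("no FCR sets")
  all_ids <- unique(unlist(lapply(fcr_sets, function(f) f$reaction_id)))
  idx <- lapply(fcr_sets, function(f) match(unique(f$reaction_id), all_ids))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  out <- lapply(seq_len(N), function(k) {
    counts <- vapply(seq_len(n_samples), function(s) {
      pick <- sample.int(N, k)
      length(unique(unlist(idx[pick])))
    }, numeric(1))
    data.frame(k = k, min = min(counts), mean = mean(counts), max = max(counts))
  })
  do.call(rbind, out)
}

#' Reaction discovery categories against a reference reconstruction
#'
#' Partitions the model's flux-carrying reactions by genetic evidence
#' (bitscore at or above `bitscore_threshold`?) and presence in a trusted
#' reference reaction set: confirmed (evidence, in reference), true
#' discovered (no evidence, in reference), likely additions (evidence,
#' not in reference), false discovered (no evidence, not in reference).
#' Discovery accuracy is `true_discovered / (true_discovered +
#' false_discovered)` -- among reactions the method included without
#' sufficient annotation evidence, the fraction vindicated by the
#' reference -- and is `NA` when no such reactions exist. Exchange, sink
#' and biomass reactions are outside the comparison.
#'
#' Also returns the CV-stratified reference overlap: for each certainty
#' bin, the fraction of model reactions at or above that CV that are in
#' the reference.
#'
#' @param model a `canyuns_model`.
#' @param reference character vector of reference reaction ids.
#' @param evidence evidence data frame (`reaction_id`, `bitscore`).
#' @param bitscore_threshold evidence threshold (default 500).
#' @param cv_breaks breakpoints for the CV stratification.
#' @return object of class `discovery_metrics`: list with `categories`
#'   (named counts), `reactions` (per-reaction table), `discovery_accuracy`,
#'   `overlap` (fraction of compared reactions in the reference), and
#'   `cv_overlap` (per-bin table).
#' @export
discovery_metrics <- function(model, reference, evidence,
                              bitscore_threshold = 500,
                              cv_breaks = seq(0, 1, 0.25)) {
  stopifnot(inherits(model, "canyuns_model"))
  rx <- model$network$reactions
  ids <- rx$id[rx$kind == "internal"]
  b <- evidence_bitscore(evidence, ids)
  cv_tab <- model$certainty
  cv_tot <- vapply(ids, function(r)
    sum(cv_tab$cv[cv_tab$reaction_id == r]), numeric(1))
  has_ev <- b >= bitscore_threshold
  in_ref <- ids %in% reference
  cat4 <- ifelse(has_ev, ifelse(in_ref, "confirmed", "likely_addition"),
                 ifelse(in_ref, "true_discovered", "false_discovered"))
  counts <- vapply(c("confirmed", "true_discovered", "likely_addition",
                     "false_discovered"), function(k) sum(cat4 == k), integer(1))
  td <- counts[["true_discovered"]]; fd <- counts[["false_discovered"]]
  disc <- if (td + fd == 0) NA_real_ else td / (td + fd)
  bins <- cut(cv_tot, breaks = cv_breaks, include.lowest = TRUE)
  cv_overlap <- do.call(rbind, lapply(levels(bins), function(lv) {
    sel <- bins == lv
    data.frame(cv_bin = lv, n = sum(sel),
               overlap = if (any(sel)) mean(in_ref[sel]) else NA_real_,
               discovery_accuracy = if (any(sel & !has_ev))
                 mean(in_ref[sel & !has_ev]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  structure(list(
    categories = counts,
    reactions = data.frame(reaction_id = ids, bitscore = b, cv = cv_tot,
                           in_reference = in_ref, category = cat4,
                           stringsAsFactors = FALSE),
    discovery_accuracy = disc,
    overlap = if (length(ids)) mean(in_ref) else NA_real_,
    cv_overlap = cv_overlap), class = "discovery_metrics")
}

#' @export
print.discovery_metrics <- function(x, ...) {
  cat("discovery_metrics:",
      paste(names(x$categories), x$categories, sep = "=", collapse = ", "), "\n")
  cat(sprintf("  reference overlap %.1f%%; discovery accuracy %s\n",
              100 * x$overlap,
              if (is.na(x$discovery_accuracy)) "n/a (no unevidenced reactions)"
              else sprintf("%.1f%%", 100 * x$discovery_accuracy)))
  invisible(x)
}

#' Run the full model-building pipeline
#'
#' For every experimentally growth-positive condition a dgFBA solution on
#' the universal network records the direction-tagged flux-carrying
#' reactions; certainty values are their per-direction frequencies; the
#' model is assembled from the CV > 0 reactions and evaluated by FBA
#' growth simulation against all observed phenotypes.
#'
#' @param universal the curated universal `metabolic_network`.
#' @param evidence evidence data frame (`reaction_id`, `bitscore`); use
#'   `NULL` to run the pFBA variant (no genetic data).
#' @param media named list of [media_condition()] objects.
#' @param phenotypes observed phenotype data frame (`condition_id`,
#'   `call`).
#' @param config a [weight_config()].
#' @param biomass_min required biomass flux during dgFBA training solves.
#' @param growth_threshold growth-call threshold for evaluation.
#' @param eps net-flux tolerance.
#' @param verbose print per-stage progress.
#' @return a `canyuns_model` with the training `evaluation`
#'   (`canyuns_confusion`) and `predictions` attached.
#' @export
canyuns_build <- function(universal, evidence, media, phenotypes,
                          config = weight_config(), biomass_min = 0.1,
                          growth_threshold = 0.1, eps = 1e-6,
                          verbose = FALSE) {
  stopifnot(inherits(universal, "metabolic_network"))
  missing_media <- setdiff(phenotypes$condition_id, names(media))
  if (length(missing_media)) {
    stop("phenotype condition(s) without media definition: ",
         paste(missing_media, collapse = ", "))
  }
  weights <- if (is.null(evidence)) NULL else reaction_weights(evidence, config)
  train <- phenotypes$condition_id[phenotypes$call == "growth"]
  if (verbose) {
    message("training on ", length(train), " growth condition(s); ",
            "biomass_min=", biomass_min, ", growth_threshold=", growth_threshold,
            ", b_zero=", config$b_zero, ", b_sat=", config$b_sat, ", eps=", eps)
  }
  split <- split_reversible(universal)
  fcr_sets <- lapply(train, function(cid) {
    res <- dgfba(split, media[[cid]], weights, biomass_min = biomass_min,
                 eps = eps)
    if (verbose && res$solution$status != "optimal") {
      message("  dgFBA infeasible for growth condition '", cid, "'")
    }
    res$fcrs
  })
  names(fcr_sets) <- train
  certainty <- compute_cvs(fcr_sets, n_conditions = length(train))
  model <- assemble_model(universal, certainty, evidence = evidence,
                          fcr_sets = fcr_sets)
  model$predictions <- simulate_phenotypes(model, media[phenotypes$condition_id],
                                           threshold = growth_threshold)
  model$evaluation <- evaluate_predictions(model$predictions, phenotypes)
  model$config <- list(b_zero = config$b_zero, b_sat = config$b_sat,
                       biomass_min = biomass_min,
                       growth_threshold = growth_threshold, eps = eps,
                       mode = if (is.null(evidence)) "pfba" else "dgfba")
  model
}

#' Write an assembled model with certainty annotations
#'
#' Serializes the model's network in the JSON dialect with per-reaction
#' `cv_forward`, `cv_reverse` and `bitscore` entries in the reaction
#' notes, so the cumulative evidence travels with the network file.
#'
#' @param model a `canyuns_model`.
#' @param path output path (`.json`).
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "canyuns_model"))
  net <- model$network
  cv <- model$certainty
  notes <- lapply(net$reactions$id, function(r) {
    list(cv_forward = sum(cv$cv[cv$reaction_id == r & cv$direction == "forward"]),
         cv_reverse = sum(cv$cv[cv$reaction_id == r & cv$direction == "reverse"]),
         bitscore = if (is.null(model$evidence)) 0 else
           evidence_bitscore(model$evidence, r))
  })
  names(notes) <- net$reactions$id
  net$rxn_notes <- notes
  write_network(net, path, format = "json")
}

#' Write the certainty table (with bitscores) to TSV
#' @param model a `canyuns_model`.
#' @param path output TSV path.
#' @export
write_certainty <- function(model, path) {
  tb <- as.data.frame(model$certainty)
  tb$bitscore <- if (is.null(model$evidence)) 0 else
    evidence_bitscore(model$evidence, tb$reaction_id)
  utils::write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
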