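#' Generate a toy universal network with planted ground truth
#'
#' Builds an abstract metabolic network in the shape the method consumes:
#' `n_pathways` linear catabolic pathways, each from its own extracellular
#' carbon source through a transporter and `pathway_length` conversion
#' steps into a shared biomass precursor, plus decoy reactions that are
#' not part of the planted organism -- parsimonious shortcuts straight to
#' the precursor and dead-end drains -- and optionally `n_orphans` carbon
#' sources whose transporter and precursor feeder exist only in the
#' universal network, not in the planted truth. Every metabolite carries
#' the single pseudo-element formula `"X"`, so all internal reactions are
#' elementally balanced by construction and the free-mass scan of an
#' un-injected network is exactly zero.
#'
#' The planted truth (the simulated organism) consists of the pathway
#' transporters and chain reactions plus all exchange reactions and the
#' biomass reaction; decoys and orphan machinery belong only to the
#' universal network.
#'
#' @param n_pathways number of true catabolic pathways.
#' @param pathway_length conversion steps per pathway (>= 1).
#' @param n_decoys number of shortcut/dead-end decoy reactions.
#' @param reversible_fraction fraction of internal conversion reactions
#'   made reversible (bounds -1000..1000).
#' @param n_orphans carbon sources with universal-only catabolism.
#' @param seed RNG seed; identical seeds give identical networks.
#' @return a `metabolic_network` with extra fields `truth_ids` and
#'   `decoy_ids`.
#' @export
generate_network <- function(n_pathways = 3, pathway_length = 3,
                             n_decoys = 2, reversible_fraction = 0,
                             n_orphans = 0, seed = 1) {
  stopifnot(n_pathways >= 1, pathway_length >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  mets <- data.frame(id = "bm_c", formula = "X", charge = 0L,
                     compartment = "c", stringsAsFactors = FALSE)
  add_met <- function(id, comp) {
    if (!id %in% mets$id) {
      mets <<- rbind(mets, data.frame(id = id, formula = "X", charge = 0L,
                                      compartment = comp, stringsAsFactors = FALSE))
    }
  }
  stoich <- list(); lb <- numeric(0); ub <- numeric(0); kind <- character(0)
  add_rxn <- function(id, sv, l, u, k) {
    stoich[[id]] <<- sv; lb[id] <<- l; ub[id] <<- u; kind[id] <<- k
  }
  chain_mets <- character(0)  # candidates for dead-end taps
  truth <- character(0); decoy <- character(0)
  for (p in seq_len(n_pathways)) {
    se <- sprintf("s%d_e", p); sc <- sprintf("s%d_c", p)
    add_met(se, "e"); add_met(sc, "c")
    ex <- sprintf("EX_s%d", p); tr <- sprintf("TR_s%d", p)
    add_rxn(ex, stats::setNames(-1, se), -1000, 1000, "exchange")
    add_rxn(tr, stats::setNames(c(-1, 1), c(se, sc)), 0, 1000, "internal")
    truth <- c(truth, ex, tr)
    prev <- sc
    for (k in seq_len(pathway_length)) {
      nxt <- if (k == pathway_length) "bm_c" else sprintf("m%d_%d", p, k)
      add_met(nxt, "c")
      rid <- sprintf("PW%d_%d", p, k)
      rev <- stats::runif(1) < reversible_fraction
      add_rxn(rid, stats::setNames(c(-1, 1), c(prev, nxt)),
              if (rev) -1000 else 0, 1000, "internal")
      truth <- c(truth, rid)
      chain_mets <- c(chain_mets, prev)
      prev <- nxt
    }
  }
  for (j in seq_len(max(0, n_orphans))) {
    oe <- sprintf("o%d_e", j); oc <- sprintf("o%d_c", j)
    add_met(oe, "e"); add_met(oc, "c")
    ex <- sprintf("EX_o%d", j)
    add_rxn(ex, stats::setNames(-1, oe), -1000, 1000, "exchange")
    truth <- c(truth, ex)  # exchanges are structural, organism-independent
    tr <- sprintf("TR_o%d", j); fd <- sprintf("FEED_o%d", j)
    add_rxn(tr, stats::setNames(c(-1, 1), c(oe, oc)), 0, 1000, "internal")
    add_rxn(fd, stats::setNames(c(-1, 1), c(oc, "bm_c")), 0, 1000, "internal")
    decoy <- c(decoy, tr, fd)
  }
  for (k in seq_len(max(0, n_decoys))) {
    if (stats::runif(1) < 0.5) {  # parsimonious shortcut to the precursor
      p <- ((k - 1) %% n_pathways) + 1
      rid <- sprintf("SC_%d", k)
      add_rxn(rid, stats::setNames(c(-1, 1), c(sprintf("s%d_c", p), "bm_c")),
              0, 1000, "internal")
    } else {                      # dead-end drain off a chain metabolite
      src <- chain_mets[sample.int(length(chain_mets), 1)]
      dd <- sprintf("d%d_c", k)
      add_met(dd, "c")
      rid <- sprintf("DE_%d", k)
      add_rxn(rid, stats::setNames(c(-1, 1), c(src, dd)), 0, 1000, "internal")
    }
    decoy <- c(decoy, rid)
  }
  add_rxn("BIOMASS", stats::setNames(-1, "bm_c"), 0, 1000, "biomass")
  truth <- c(truth, "BIOMASS")
  rxns <- data.frame(id = names(stoich), lb = unname(lb), ub = unname(ub),
                     kind = unname(kind), stringsAsFactors = FALSE)
  net <- metabolic_network(mets, rxns, stoich, biomass_id = "BIOMASS",
                           extracellular = "e")
  net$truth_ids <- truth
  net$decoy_ids <- decoy
  net
}

#' Inject a free-mass defect into a network
#'
#' Adds either a single mass-imbalanced internal reaction (a metabolite
#' created from nothing, the net form of `A -> A + B`) or a two-reaction
#' stoichiometrically amplifying loop (`a -> 2 b`, `b -> a`). The injected
#' metabolite carries no formula, so per-reaction formula balancing cannot
#' certify it, but the free-mass scan flags it regardless: its objective
#' becomes strictly positive and the injected reactions carry flux in the
#' optimal solution.
#'
#' @param net a `metabolic_network`.
#' @param seed RNG seed (choice of type and attachment point).
#' @param type `"imbalanced"`, `"loop"`, or `"auto"` (seeded choice).
#' @return list with `network` (the modified network) and `injected`
#'   (character vector of injected reaction ids).
#' @export
inject_mass_loop <- function(net, seed = 1, type = c("auto", "imbalanced", "loop")) {
  type <- match.arg(type)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  if (type == "auto") type <- c("imbalanced", "loop")[sample.int(2, 1)]
  mets <- rbind(net$metabolites,
                data.frame(id = "mg_c", formula = NA_character_, charge = 0L,
                           compartment = "c", stringsAsFactors = FALSE))
  stoich <- lapply(seq_len(nrow(net$reactions)), function(j) {
    sv <- net$S[, j]; sv[sv != 0]
  })
  names(stoich) <- net$reactions$id
  rxns <- net$reactions
  if (type == "imbalanced") {
    stoich[["MG_imb"]] <- c(mg_c = 1)
    rxns <- rbind(rxns, data.frame(id = "MG_imb", lb = 0, ub = 1000,
                                   kind = "internal", stringsAsFactors = FALSE))
    injected <- "MG_imb"
  } else {
    cands <- net$metabolites$id[net$metabolites$compartment != net$extracellular]
    a <- cands[sample.int(length(cands), 1)]
    stoich[["MG_amp"]] <- stats::setNames(c(-1, 2), c(a, "mg_c"))
    stoich[["MG_ret"]] <- stats::setNames(c(-1, 1), c("mg_c", a))
    rxns <- rbind(rxns,
                  data.frame(id = c("MG_amp", "MG_ret"), lb = 0, ub = 1000,
                             kind = "internal", stringsAsFactors = FALSE))
    injected <- c("MG_amp", "MG_ret")
  }
  out <- metabolic_network(mets, rxns, stoich, biomass_id = net$biomass_id,
                           extracellular = net$extracellular)
  out$truth_ids <- net$truth_ids
  out$decoy_ids <- net$decoy_ids
  list(network = out, injected = injected)
}

#' Generate a complete synthetic training scenario
#'
#' Wraps [generate_network()] with evidence, media and phenotype
#' generation so the whole pipeline can be exercised against known ground
#' truth. Evidence: reactions of the planted truth draw bitscores from a
#' high class (normal around `b_truth_mean`, truncated above the
#' annotation threshold of 500), decoys from a low class (truncated below
#' 500); with probability `noise_fraction` a reaction draws from the
#' other class instead, which creates discovered / false-discovered
#' reactions in miniature. Exchanges and biomass carry no gene, hence no
#' evidence. Media: single-source conditions for every pathway and orphan
#' source, then two-source (pathway + orphan) conditions, each source
#' opened at `uptake`. Phenotypes are FBA growth calls of the planted
#' truth subnetwork at the 0.1 threshold, so they are exactly
#' reproducible from (truth, media, threshold).
#'
#' @param n_pathways,pathway_length,n_decoys,reversible_fraction,n_orphans
#'   passed to [generate_network()].
#' @param n_conditions number of media conditions (default: all singleton
#'   conditions plus up to two mixed ones, capped at 12); must be >= 1.
#' @param b_truth_mean,b_decoy_mean bitscore class centers.
#' @param noise_fraction probability of drawing from the wrong class.
#' @param uptake per-source maximum uptake magnitude (mmol/gDW/h).
#' @param seed RNG seed.
#' @return object of class `canyuns_scenario`: list with `network`,
#'   `truth` (reaction ids), `decoys`, `evidence`, `media`, `phenotypes`,
#'   `seed`, `params`.
#' @export
generate_scenario <- function(n_pathways = 3, pathway_length = 3,
                              n_decoys = 3, reversible_fraction = 0,
                              n_orphans = 2, n_conditions = NULL,
                              b_truth_mean = 750, b_decoy_mean = 250,
                              noise_fraction = 0, uptake = 10, seed = 1) {
  net <- generate_network(n_pathways, pathway_length, n_decoys,
                          reversible_fraction, n_orphans, seed = seed)
  ## candidate conditions: singletons first, then pathway+orphan pairs
  conds <- list()
  for (p in seq_len(n_pathways)) {
    conds[[sprintf("c_s%d", p)]] <- stats::setNames(uptake, sprintf("EX_s%d", p))
  }
  for (j in seq_len(max(0, n_orphans))) {
    conds[[sprintf("c_o%d", j)]] <- stats::setNames(uptake, sprintf("EX_o%d", j))
  }
  if (n_orphans >= 1) {
    for (p in seq_len(n_pathways)) {
      j <- ((p - 1) %% n_orphans) + 1
      conds[[sprintf("c_s%d_o%d", p, j)]] <-
        stats::setNames(c(uptake, uptake), c(sprintf("EX_s%d", p), sprintf("EX_o%d", j)))
    }
  }
  if (is.null(n_conditions)) {
    n_conditions <- min(length(conds), 12L)
  }
  if (n_conditions < 1) stop("need at least one media condition")
  if (n_conditions > length(conds)) {
    stop("at most ", length(conds), " conditions available for this geometry")
  }
  conds <- conds[seq_len(n_conditions)]
  media <- lapply(names(conds), function(id) media_condition(id, conds[[id]]))
  names(media) <- names(conds)
  ## evidence with seeded class noise
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed + 104729L)  # decouple evidence draws from network topology
  gene_rxns <- net$reactions$id[net$reactions$kind == "internal"]
  is_truth <- gene_rxns %in% net$truth_ids
  draw_high <- function(n) pmin(2500, pmax(501, stats::rnorm(n, b_truth_mean, b_truth_mean / 8)))
  draw_low <- function(n) pmin(499, pmax(0, stats::rnorm(n, b_decoy_mean, max(1, b_decoy_mean / 8))))
  flip <- stats::runif(length(gene_rxns)) < noise_fraction
  high <- xor(is_truth, flip)
  b <- numeric(length(gene_rxns))
  b[high] <- draw_high(sum(high))
  b[!high] <- draw_low(sum(!high))
  evidence <- data.frame(reaction_id = gene_rxns, bitscore = b,
                         stringsAsFactors = FALSE)
  ## phenotypes: FBA on the planted truth subnetwork
  truth_net <- remove_reactions(net, setdiff(net$reactions$id, net$truth_ids))
  phen <- simulate_phenotypes(truth_net, media, threshold = 0.1)
  structure(list(network = net, truth = net$truth_ids, decoys = net$decoy_ids,
                 evidence = evidence, media = media,
                 phenotypes = phen[c("condition_id", "call")], seed = seed,
                 params = list(n_pathways = n_pathways,
                               pathway_length = pathway_length,
                               n_decoys = n_decoys,
                               reversible_fraction = reversible_fraction,
                               n_orphans = n_orphans,
                               n_conditions = n_conditions,
                               b_truth_mean = b_truth_mean,
                               b_decoy_mean = b_decoy_mean,
                               noise_fraction = noise_fraction,
                               uptake = uptake)),
            class = "canyuns_scenario")
}

#' @export
print.canyuns_scenario <- function(x, ...) {
  cat("canyuns_scenario (seed ", x$seed, "): ",
      nrow(x$network$reactions), " reactions (",
      length(setdiff(x$truth, x$network$reactions$id[x$network$reactions$kind != "internal"])),
      " truth internal, ", length(x$decoys), " decoy), ",
      length(x$media), " conditions (",
      sum(x$phenotypes$call == "growth"), " growth)\n", sep = "")
  invisible(x)
}

#' Serialize a scenario to the pipeline's file formats
#'
#' Writes `network.json`, `network.xml`, `evidence.tsv`, `media.tsv`,
#' `phenotypes.tsv` and `truth_reactions.txt` into `dir`.
#'
#' @param scenario a `canyuns_scenario`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_network(scenario$network, file.path(dir, "network.json"))
  write_network(scenario$network, file.path(dir, "network.xml"))
  write_evidence(scenario$evidence, file.path(dir, "evidence.tsv"))
  write_media(scenario$media, file.path(dir, "media.tsv"))
  write_phenotypes(scenario$phenotypes, file.path(dir, "phenotypes.tsv"))
  writeLines(scenario$truth, file.path(dir, "truth_reactions.txt"))
  invisible(dir)
}
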