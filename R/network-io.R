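#' Read a metabolic network from SBML or JSON
#'
#' Two dialects are supported: SBML Level 3 with FBC-style flux bounds and
#' a flat JSON dialect compatible with the COBRA JSON schema (reactions
#' carry a `metabolites` map, `lower_bound`/`upper_bound`, and optionally
#' `objective_coefficient`; reaction kind is stored under `notes`).
#'
#' The biomass reaction is located, in order of precedence, from the
#' explicit `biomass_id` argument, the file's declared flux objective
#' (SBML `fbc:listOfObjectives` / JSON `objective_coefficient`), or an id
#' matching `biomass_pattern`.
#'
#' @param path file path.
#' @param format `"sbml"`, `"json"`, or `"auto"` (by file extension).
#' @param biomass_id optional explicit biomass reaction id.
#' @param biomass_pattern fallback regular expression (case-insensitive)
#'   used to locate the biomass reaction.
#' @param extracellular compartment tag meaning extracellular.
#' @return a `metabolic_network`.
#' @export
read_network <- function(path, format = c("auto", "sbml", "json"),
                         biomass_id = NULL, biomass_pattern = "biomass",
                         extracellular = "e") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) %in% c("xml", "sbml")) "sbml" else "json"
  }
  if (!file.exists(path)) stop("no such file: ", path)
  parts <- switch(format,
                  sbml = parse_sbml(path),
                  json = parse_network_json(path))
  if (is.null(biomass_id)) biomass_id <- parts$biomass_id
  if (is.null(biomass_id)) {
    hit <- grep(biomass_pattern, parts$reactions$id, ignore.case = TRUE, value = TRUE)
    if (length(hit) != 1) {
      stop("cannot identify a unique biomass reaction; pass biomass_id explicitly")
    }
    biomass_id <- hit
  }
  if (!is.null(parts$extracellular)) extracellular <- parts$extracellular
  metabolic_network(parts$metabolites, parts$reactions, parts$stoichiometry,
                    biomass_id = biomass_id, extracellular = extracellular)
}

#' Write a metabolic network to SBML or JSON
#'
#' `read_network(write_network(net, path), ...)` reproduces ids,
#' stoichiometry and bounds exactly in both formats.
#'
#' @param net a `metabolic_network`.
#' @param path output file path.
#' @param format `"sbml"`, `"json"`, or `"auto"` (by extension).
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("auto", "sbml", "json")) {
  validate_network(net)
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) %in% c("xml", "sbml")) "sbml" else "json"
  }
  switch(format,
         sbml = write_sbml(net, path),
         json = write_network_json(net, path))
  invisible(path)
}

## ---- JSON dialect (COBRA-schema compatible) --------------------------------

parse_network_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  mets <- do.call(rbind, lapply(doc$metabolites, function(m) {
    data.frame(id = m$id,
               formula = if (is.null(m$formula)) NA_character_ else m$formula,
               charge = if (is.null(m$charge)) 0L else as.integer(m$charge),
               compartment = if (is.null(m$compartment)) NA_character_ else m$compartment,
               stringsAsFactors = FALSE)
  }))
  rxns <- do.call(rbind, lapply(doc$reactions, function(r) {
    data.frame(id = r$id,
               lb = if (is.null(r$lower_bound)) -1000 else r$lower_bound,
               ub = if (is.null(r$upper_bound)) 1000 else r$upper_bound,
               kind = if (!is.null(r$notes$kind)) r$notes$kind else NA_character_,
               stringsAsFactors = FALSE)
  }))
  stoich <- lapply(doc$reactions, function(r) unlist(r$metabolites))
  biomass_id <- doc$biomass_id
  if (is.null(biomass_id)) {
    oc <- vapply(doc$reactions, function(r)
      if (is.null(r$objective_coefficient)) 0 else r$objective_coefficient, numeric(1))
    if (sum(oc != 0) == 1) biomass_id <- rxns$id[oc != 0]
  }
  list(metabolites = mets, reactions = rxns, stoichiometry = stoich,
       biomass_id = biomass_id, extracellular = doc$extracellular)
}

write_network_json <- function(net, path) {
  mets <- lapply(seq_len(nrow(net$metabolites)), function(i) {
    m <- net$metabolites[i, ]
    out <- list(id = m$id, name = m$id, compartment = m$compartment,
                charge = as.integer(m$charge))
    if (!is.na(m$formula)) out$formula <- m$formula
    out
  })
  rxns <- lapply(seq_len(nrow(net$reactions)), function(j) {
    r <- net$reactions[j, ]
    sv <- net$S[, j]
    sv <- sv[sv != 0]
    notes <- list(kind = r$kind)
    if (!is.null(net$rxn_notes[[r$id]])) notes <- c(notes, net$rxn_notes[[r$id]])
    list(id = r$id, name = r$id,
         metabolites = as.list(sv),
         lower_bound = r$lb, upper_bound = r$ub,
         gene_reaction_rule = "",
         objective_coefficient = if (r$id == net$biomass_id) 1 else 0,
         notes = notes)
  })
  doc <- list(id = "canyuns_network",
              metabolites = mets, reactions = rxns, genes = list(),
              compartments = as.list(stats::setNames(
                unique(net$metabolites$compartment),
                unique(net$metabolites$compartment))),
              version = "1",
              biomass_id = net$biomass_id,
              extracellular = net$extracellular)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

## ---- SBML L3 + FBC ---------------------------------------------------------

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

write_sbml <- function(net, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  num <- function(x) format(x, scientific = FALSE, trim = TRUE, digits = 15)
  L <- character(0)
  add <- function(...) L[[length(L) + 1]] <<- paste0(...)
  add('<?xml version="1.0" encoding="UTF-8"?>')
  add('<sbml xmlns="', SBML_NS, '" xmlns:fbc="', FBC_NS,
      '" level="3" version="1" fbc:required="false">')
  add('  <model id="canyuns_network" fbc:strict="true">')
  add('    <listOfCompartments>')
  for (cmp in unique(net$metabolites$compartment)) {
    add('      <compartment id="', esc(cmp), '" constant="true"/>')
  }
  add('    </listOfCompartments>')
  add('    <listOfSpecies>')
  for (i in seq_len(nrow(net$metabolites))) {
    m <- net$metabolites[i, ]
    frm <- if (is.na(m$formula)) "" else
      paste0(' fbc:chemicalFormula="', esc(m$formula), '"')
    add('      <species id="', esc(m$id), '" compartment="', esc(m$compartment),
        '" hasOnlySubstanceUnits="false" boundaryCondition="false" ',
        'constant="false" fbc:charge="', m$charge, '"', frm, '/>')
  }
  add('    </listOfSpecies>')
  add('    <listOfParameters>')
  bounds <- sort(unique(c(net$reactions$lb, net$reactions$ub)))
  bnd_id <- function(v) paste0("bnd_", gsub("[^0-9A-Za-z]", "_", num(v)))
  for (v in bounds) {
    add('      <parameter id="', bnd_id(v), '" value="', num(v),
        '" constant="true"/>')
  }
  add('    </listOfParameters>')
  add('    <listOfReactions>')
  for (j in seq_len(nrow(net$reactions))) {
    r <- net$reactions[j, ]
    sv <- net$S[, j]
    sv <- sv[sv != 0]
    add('      <reaction id="', esc(r$id), '" reversible="',
        tolower(r$lb < 0), '" fast="false" fbc:lowerFluxBound="',
        bnd_id(r$lb), '" fbc:upperFluxBound="', bnd_id(r$ub), '">')
    reac <- sv[sv < 0]; prod <- sv[sv > 0]
    if (length(reac)) {
      add('        <listOfReactants>')
      for (k in seq_along(reac)) {
        add('          <speciesReference species="', esc(names(reac)[k]),
            '" stoichiometry="', num(-reac[k]), '" constant="true"/>')
      }
      add('        </listOfReactants>')
    }
    if (length(prod)) {
      add('        <listOfProducts>')
      for (k in seq_along(prod)) {
        add('          <speciesReference species="', esc(names(prod)[k]),
            '" stoichiometry="', num(prod[k]), '" constant="true"/>')
      }
      add('        </listOfProducts>')
    }
    add('      </reaction>')
  }
  add('    </listOfReactions>')
  add('    <fbc:listOfObjectives fbc:activeObjective="obj">')
  add('      <fbc:objective fbc:id="obj" fbc:type="maximize">')
  add('        <fbc:listOfFluxObjectives>')
  add('          <fbc:fluxObjective fbc:reaction="', esc(net$biomass_id),
      '" fbc:coefficient="1"/>')
  add('        </fbc:listOfFluxObjectives>')
  add('      </fbc:objective>')
  add('    </fbc:listOfObjectives>')
  add('  </model>')
  add('</sbml>')
  writeLines(unlist(L), path)
}

parse_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  find <- function(node, what) {
    xml2::xml_find_all(node, paste0(".//*[local-name()='", what, "']"))
  }
  attr1 <- function(node, name) {
    a <- xml2::xml_attrs(node)
    out <- a[name]
    if (is.na(names(out))) NA_character_ else unname(out)
  }
  sp <- find(doc, "species")
  mets <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    formula = vapply(sp, attr1, character(1), name = "chemicalFormula"),
    charge = suppressWarnings(as.integer(
      vapply(sp, attr1, character(1), name = "charge"))),
    compartment = xml2::xml_attr(sp, "compartment"),
    stringsAsFactors = FALSE)
  mets$charge[is.na(mets$charge)] <- 0L
  pars <- find(doc, "parameter")
  pval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                          xml2::xml_attr(pars, "id"))
  rx_nodes <- xml2::xml_find_all(
    doc, ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  rxns <- data.frame(
    id = xml2::xml_attr(rx_nodes, "id"),
    lb = unname(pval[vapply(rx_nodes, attr1, character(1),
                            name = "lowerFluxBound")]),
    ub = unname(pval[vapply(rx_nodes, attr1, character(1),
                            name = "upperFluxBound")]),
    stringsAsFactors = FALSE)
  if (anyNA(rxns$lb) || anyNA(rxns$ub)) stop("SBML reaction without flux bounds")
  stoich <- lapply(rx_nodes, function(nd) {
    out <- numeric(0)
    for (ref in xml2::xml_find_all(
      nd, "./*[local-name()='listOfReactants']/*[local-name()='speciesReference']")) {
      out[xml2::xml_attr(ref, "species")] <-
        -as.numeric(xml2::xml_attr(ref, "stoichiometry"))
    }
    for (ref in xml2::xml_find_all(
      nd, "./*[local-name()='listOfProducts']/*[local-name()='speciesReference']")) {
      id <- xml2::xml_attr(ref, "species")
      out[id] <- (if (id %in% names(out)) out[id] else 0) +
        as.numeric(xml2::xml_attr(ref, "stoichiometry"))
    }
    unknown <- setdiff(names(out), mets$id)
    if (length(unknown)) {
      stop("reaction '", xml2::xml_attr(nd, "id"),
           "' references undeclared metabolite(s): ",
           paste(unknown, collapse = ", "))
    }
    out
  })
  fo <- find(doc, "fluxObjective")
  biomass_id <- NULL
  if (length(fo) == 1) biomass_id <- attr1(fo[[1]], "reaction")
  list(metabolites = mets, reactions = rxns, stoichiometry = stoich,
       biomass_id = biomass_id, extracellular = NULL)
}

## ---- tabular inputs --------------------------------------------------------

#' Read a media-condition table
#'
#' Expects tab-separated columns `condition_id`, `exchange_id`,
#' `max_uptake`; one row per open uptake.
#'
#' @param path TSV file path.
#' @return named list of [media_condition()] objects.
#' @export
read_media <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("condition_id", "exchange_id", "max_uptake")
  if (!all(need %in% names(tb))) {
    stop("media table must have columns: ", paste(need, collapse = ", "))
  }
  conds <- lapply(split(tb, tb$condition_id), function(d) {
    media_condition(d$condition_id[1],
                    stats::setNames(d$max_uptake, d$exchange_id))
  })
  conds[unique(tb$condition_id)]
}

#' Write a media-condition table
#' @param media list of [media_condition()] objects.
#' @param path output TSV path.
#' @export
write_media <- function(media, path) {
  rows <- do.call(rbind, lapply(media, function(m) {
    if (!length(m$uptake)) return(NULL)
    data.frame(condition_id = m$id, exchange_id = names(m$uptake),
               max_uptake = unname(m$uptake), stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a binary phenotype table
#'
#' Expects tab-separated columns `condition_id`, `call` with calls in
#' `growth` / `no_growth`; `inconclusive` is accepted and mapped to
#' `no_growth` (conservative handling of ambiguous plate reads).
#'
#' @param path TSV file path.
#' @return data frame with columns `condition_id`, `call`.
#' @export
read_phenotypes <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("condition_id", "call") %in% names(tb))) {
    stop("phenotype table must have columns: condition_id, call")
  }
  bad <- !tb$call %in% c("growth", "no_growth", "inconclusive")
  if (any(bad)) {
    stop("unknown phenotype call '", tb$call[bad][1], "' on line ",
         which(bad)[1] + 1L, " of ", path)
  }
  n_inc <- sum(tb$call == "inconclusive")
  if (n_inc) {
    message(n_inc, " inconclusive call(s) treated as no_growth")
    tb$call[tb$call == "inconclusive"] <- "no_growth"
  }
  if (anyDuplicated(tb$condition_id)) stop("duplicate condition_id in phenotype table")
  tb[c("condition_id", "call")]
}

#' Write a binary phenotype table
#' @param phenotypes data frame with columns `condition_id`, `call`.
#' @param path output TSV path.
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.table(phenotypes[c("condition_id", "call")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
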