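#' Configuration of the bitscore-to-weight transform
#'
#' Two knots define the step-wise linear transform: `b_zero`, the bitscore
#' that maps to weight 0 (the functional-annotation threshold; model
#' accuracy is insensitive to choices between 200 and 500, and 500 is the
#' default), and `b_sat`, the bitscore at and above which the weight
#' saturates at 1. A bitscore of 0 (no genetic evidence) always maps to
#' weight -1.
#'
#' @param b_zero bitscore mapping to weight 0 (default 500).
#' @param b_sat saturation bitscore mapping to weight 1 (default 1000).
#' @return an object of class `weight_config`.
#' @export
weight_config <- function(b_zero = 500, b_sat = 1000) {
  if (!(b_zero > 0 && b_sat > b_zero)) stop("need 0 < b_zero < b_sat")
  structure(list(b_zero = b_zero, b_sat = b_sat), class = "weight_config")
}

#' @export
print.weight_config <- function(x, ...) {
  cat("weight_config: b_zero =", x$b_zero, "(weight 0), b_sat =", x$b_sat,
      "(weight 1); bitscore 0 -> weight -1\n")
  invisible(x)
}

#' Step-wise linear bitscore-to-weight transform
#'
#' Maps reaction bitscores to dgFBA weights in `[-1, 1]`:
#' \deqn{w(b) = b/b_0 - 1} for `0 <= b <= b_zero`,
#' \deqn{w(b) = (b - b_0)/(b_{sat} - b_0)} for `b_zero <= b <= b_sat`, and
#' `w = 1` beyond `b_sat`. The transform is continuous and nondecreasing;
#' `w(0) = -1`, `w(b_zero) = 0`, `w(b_sat) = 1`. Bitscores below the
#' annotation threshold still carry information -- scores just short of the
#' threshold get weights just below zero, scores far short approach -1.
#'
#' @param b numeric vector of bitscores (>= 0).
#' @param config a [weight_config()].
#' @return numeric vector of weights in `[-1, 1]`.
#' @export
weight_transform <- function(b, config = weight_config()) {
  if (any(b < 0)) stop("bitscores must be >= 0")
  w <- ifelse(b <= config$b_zero,
              b / config$b_zero - 1,
              (b - config$b_zero) / (config$b_sat - config$b_zero))
  pmin(w, 1)
}

#' Aggregate gene-level alignment bitscores into reaction bitscores
#'
#' For each reference sequence, the best (maximum) bitscore over all query
#' genes hitting it is taken; a reaction's bitscore is then the maximum of
#' the best hits over its reference sequences (`aggregate = "max"`, the
#' conservative order-preserving choice) or their mean
#' (`aggregate = "mean"`). Bitscores are not normalized. Reactions with no
#' resolvable hits get bitscore 0 (no evidence). Alignment records whose
#' reference id is absent from the mapping are reported and skipped.
#'
#' @param alignments data frame with columns `query_id`, `reference_id`,
#'   `bitscore` (a tabular BLAST/DIAMOND outfmt-6 column subset).
#' @param mapping data frame with columns `reference_id`, `reaction_id`.
#' @param aggregate `"max"` or `"mean"`.
#' @return data frame with columns `reaction_id`, `bitscore`, one row per
#'   reaction in `mapping`.
#' @export
reaction_bitscores <- function(alignments, mapping,
                               aggregate = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  stopifnot(all(c("query_id", "reference_id", "bitscore") %in% names(alignments)),
            all(c("reference_id", "reaction_id") %in% names(mapping)))
  if (any(alignments$bitscore < 0)) stop("bitscores must be >= 0")
  unresolved <- setdiff(alignments$reference_id, mapping$reference_id)
  if (length(unresolved)) {
    message(length(unresolved),
            " alignment reference id(s) not in the sequence-to-reaction map; skipped")
    alignments <- alignments[alignments$reference_id %in% mapping$reference_id, ,
                             drop = FALSE]
  }
  best <- if (nrow(alignments)) {
    tapply(alignments$bitscore, alignments$reference_id, max)
  } else numeric(0)
  rxn_ids <- unique(mapping$reaction_id)
  scores <- vapply(rxn_ids, function(r) {
    refs <- mapping$reference_id[mapping$reaction_id == r]
    hits <- best[names(best) %in% refs]
    if (!length(hits)) 0 else if (aggregate == "max") max(hits) else mean(hits)
  }, numeric(1))
  data.frame(reaction_id = rxn_ids, bitscore = unname(scores),
             stringsAsFactors = FALSE)
}

#' Convert a reaction-evidence table into dgFBA weights
#'
#' @param evidence data frame with columns `reaction_id`, `bitscore`.
#' @param config a [weight_config()].
#' @return named numeric vector of weights by reaction id. Reactions
#'   absent from the table are handled downstream as weight -1 (no
#'   evidence).
#' @export
reaction_weights <- function(evidence, config = weight_config()) {
  stopifnot(all(c("reaction_id", "bitscore") %in% names(evidence)))
  stats::setNames(weight_transform(evidence$bitscore, config),
                  evidence$reaction_id)
}

#' Look up a reaction's evidence bitscore, with absent meaning zero
#' @param evidence data frame with columns `reaction_id`, `bitscore`.
#' @param ids reaction ids.
#' @return numeric vector of bitscores (0 where absent).
#' @export
evidence_bitscore <- function(evidence, ids) {
  b <- evidence$bitscore[match(ids, evidence$reaction_id)]
  b[is.na(b)] <- 0
  b
}

#' Read / write evidence tables
#'
#' `read_evidence` expects tab-separated columns `reaction_id`,
#' `bitscore`; `read_alignments` expects `query_id`, `reference_id`,
#' `bitscore`; `read_seq_to_reaction` expects `reference_id`,
#' `reaction_id`.
#'
#' @param path TSV file path.
#' @return data frame.
#' @export
read_evidence <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("reaction_id", "bitscore") %in% names(tb))) {
    stop("evidence table must have columns: reaction_id, bitscore")
  }
  if (any(tb$bitscore < 0)) stop("bitscores must be >= 0")
  tb[c("reaction_id", "bitscore")]
}

#' @rdname read_evidence
#' @param evidence data frame with columns `reaction_id`, `bitscore`.
#' @export
write_evidence <- function(evidence, path) {
  utils::write.table(evidence[c("reaction_id", "bitscore")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_evidence
#' @export
read_alignments <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("query_id", "reference_id", "bitscore") %in% names(tb))) {
    stop("alignment table must have columns: query_id, reference_id, bitscore")
  }
  tb
}

#' @rdname read_evidence
#' @export
read_seq_to_reaction <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("reference_id", "reaction_id") %in% names(tb))) {
    stop("mapping table must have columns: reference_id, reaction_id")
  }
  tb
}
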