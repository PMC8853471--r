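# Shared fixtures and independent oracles used across test files.

# Linear toy: one carbon source, a two-step evidence-backed chain to the
# biomass precursor and a one-step low-evidence shortcut.
#   EX_A (A_e <-> nothing), T (A_e -> A_c), C1 (A_c -> B), C2 (B -> P),
#   SHORT (A_c -> P), BIO (P -> nothing)
toy_linear_network <- function(short_lb = 0) {
  mets <- data.frame(id = c("A_e", "A_c", "B", "P"),
                     formula = c("X", "X", "X", "X"), charge = 0L,
                     compartment = c("e", "c", "c", "c"),
                     stringsAsFactors = FALSE)
  stoich <- list(EX_A = c(A_e = -1), T = c(A_e = -1, A_c = 1),
                 C1 = c(A_c = -1, B = 1), C2 = c(B = -1, P = 1),
                 SHORT = c(A_c = -1, P = 1), BIO = c(P = -1))
  rxns <- data.frame(id = names(stoich),
                     lb = c(-1000, 0, 0, short_lb, 0, 0), ub = 1000,
                     stringsAsFactors = FALSE)
  metabolic_network(mets, rxns, stoich, biomass_id = "BIO")
}

toy_weights <- c(T = 0.8, C1 = 0.7, C2 = 0.6, SHORT = -0.9)

# Brute-force LP oracle: enumerates every basic feasible point (vertex) of
# {A x = b, lb <= x <= ub} by choosing rank(A) basic columns and pinning
# the others at a bound. Exact and exhaustive; only viable for tiny
# problems (n - rank <= ~7).
lp_vertex_oracle <- function(obj, A, b = NULL, lb = NULL, ub = NULL,
                             sense = "max", tol = 1e-7) {
  A <- as.matrix(A)
  n <- ncol(A)
  if (is.null(b)) b <- numeric(nrow(A))
  if (is.null(lb)) lb <- numeric(n)
  if (is.null(ub)) ub <- rep(1000, n)
  qa <- qr(t(A))
  r <- qa$rank
  keep <- sort(qa$pivot[seq_len(r)])
  A <- A[keep, , drop = FALSE]; b <- b[keep]
  best <- NULL
  consider <- function(x) {
    if (all(x >= lb - tol) && all(x <= ub + tol)) {
      val <- sum(obj * x)
      if (is.null(best) || (sense == "max" && val > best) ||
          (sense == "min" && val < best)) best <<- val
    }
  }
  if (r == 0) {
    x <- ifelse((sense == "max") == (obj > 0), ub, lb)
    x[obj == 0] <- lb[obj == 0]
    consider(x)
    return(best)
  }
  combos <- utils::combn(n, r)
  for (ci in seq_len(ncol(combos))) {
    B <- combos[, ci]
    AB <- A[, B, drop = FALSE]
    if (abs(det(AB)) < 1e-10) next
    N <- setdiff(seq_len(n), B)
    for (mask in seq_len(2^length(N)) - 1L) {
      xN <- lb[N]
      if (length(N)) {
        at_ub <- bitwAnd(mask, 2^(seq_along(N) - 1L)) > 0
        xN[at_ub] <- ub[N][at_ub]
      }
      rhs <- b - (if (length(N)) A[, N, drop = FALSE] %*% xN else 0)
      xB <- tryCatch(solve(AB, rhs), error = function(e) NULL)
      if (is.null(xB)) next
      x <- numeric(n); x[B] <- xB; x[N] <- xN
      consider(x)
      if (!length(N)) break
    }
  }
  best
}

# Reference LP solve through scipy's HiGHS (independent implementation,
# called through the system python). Returns list(status, objective).
scipy_lp_oracle <- function(obj, A, lb, ub, sense = "max") {
  fin <- tempfile(fileext = ".json"); fout <- tempfile(fileext = ".json")
  jsonlite::write_json(list(obj = obj, A = as.matrix(A), lb = lb, ub = ub,
                            sense = sense),
                       fin, digits = NA, auto_unbox = TRUE)
  script <- sprintf("
import json, numpy as np
from scipy.optimize import linprog
d = json.load(open(%s))
sgn = -1.0 if d['sense'] == 'max' else 1.0
A = np.array(d['A'])
res = linprog(sgn*np.array(d['obj']), A_eq=A, b_eq=np.zeros(A.shape[0]),
              bounds=list(zip(d['lb'], d['ub'])), method='highs')
out = {'status': 'optimal' if res.status == 0 else
       ('infeasible' if res.status == 2 else 'other'),
       'objective': sgn*res.fun if res.status == 0 else None}
json.dump(out, open(%s, 'w'))
", deparse(fin), deparse(fout))
  rc <- system2("python", c("-c", shQuote(script)), stdout = FALSE, stderr = FALSE)
  if (rc != 0) stop("scipy oracle failed to run")
  jsonlite::fromJSON(fout)
}

# Exhaustive single-knockout essentiality by explicit reaction removal and
# a fresh FBA per knockout.
knockout_oracle <- function(net, media, threshold = 0.1) {
  screen <- net$reactions$id[!(net$reactions$kind %in% c("exchange", "biomass"))]
  ess <- character(0)
  for (r in screen) {
    f <- fba_growth(remove_reactions(net, r), media)
    if (f <= threshold) ess <- c(ess, r)
  }
  ess
}

# A feasible flux sample of a split network under media: solves with a
# random objective so different seeds explore different vertices.
random_feasible_flux <- function(split, media, seed) {
  sp <- apply_media(split, media)
  set.seed(seed)
  obj <- stats::runif(nrow(sp$components), -1, 1)
  sol <- solve_lp(obj, sp$S, lb = numeric(nrow(sp$components)),
                  ub = sp$components$ub, sense = "max")
  if (sol$status != "optimal") return(NULL)
  stats::setNames(sol$x, sp$components$id)
}

empty_fcr_set <- function() {
  structure(data.frame(reaction_id = character(0), direction = character(0),
                       net_flux = numeric(0), stringsAsFactors = FALSE),
            class = c("fcr_set", "data.frame"))
}

make_fcrs <- function(ids, dirs) {
  structure(data.frame(reaction_id = ids, direction = dirs,
                       net_flux = rep(1, length(ids)),
                       stringsAsFactors = FALSE),
            class = c("fcr_set", "data.frame"))
}
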