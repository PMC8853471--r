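#' Solve a bounded linear program
#'
#' Solves `max/min  c'x  subject to  A x = b,  lb <= x <= ub` with a dense
#' two-phase primal simplex using Bland's rule, which makes the pivot
#' sequence (and hence the returned vertex) fully deterministic. All linear
#' programs in this package -- plain FBA, dgFBA, pFBA and the free-mass scan
#' -- are instances of this form on the split (non-negative-flux) network.
#'
#' @param obj numeric objective coefficients, length n.
#' @param A constraint matrix (m x n); dense or any `Matrix` class.
#' @param b right-hand side, length m (defaults to all zero: steady state).
#' @param lb,ub variable bounds, length n; `ub` may contain `Inf`.
#' @param sense `"max"` or `"min"`.
#' @param tol numerical tolerance for pivoting and feasibility.
#' @return list with `status` (`"optimal"`, `"infeasible"` or
#'   `"unbounded"`), `x` (solution, `NULL` unless optimal) and `objective`.
#' @keywords internal
solve_lp <- function(obj, A, b = NULL, lb = NULL, ub = NULL,
                     sense = c("max", "min"), tol = 1e-9) {
  sense <- match.arg(sense)
  A <- as.matrix(A)
  n <- ncol(A)
  m <- nrow(A)
  stopifnot(length(obj) == n)
  if (is.null(b)) b <- numeric(m)
  if (is.null(lb)) lb <- numeric(n)
  if (is.null(ub)) ub <- rep(Inf, n)
  if (any(lb > ub + tol)) {
    return(list(status = "infeasible", x = NULL, objective = NA_real_))
  }

  ## shift to y = x - lb >= 0; add slack rows y_i + s_i = ub_i - lb_i
  bshift <- as.numeric(b - A %*% lb)
  ubs <- ub - lb
  bounded <- which(is.finite(ubs))
  k <- length(bounded)

  ncols <- n + k            # real vars + bound slacks
  nart <- m                 # one artificial per equality row
  Tb <- matrix(0, m + k, ncols + nart + 1)
  Tb[seq_len(m), seq_len(n)] <- A
  Tb[seq_len(m), ncols + nart + 1] <- bshift
  neg <- which(bshift < 0)
  if (length(neg)) Tb[neg, ] <- -Tb[neg, ]
  for (i in seq_len(m)) Tb[i, ncols + i] <- 1
  if (k) {
    for (j in seq_len(k)) {
      Tb[m + j, bounded[j]] <- 1
      Tb[m + j, n + j] <- 1
      Tb[m + j, ncols + nart + 1] <- ubs[bounded[j]]
    }
  }
  basis <- c(ncols + seq_len(m), n + seq_len(k))

  ## phase 1: drive artificials to zero
  c1 <- c(numeric(ncols), rep(1, nart))
  ph1 <- simplex_iterate(Tb, basis, c1, allowed = seq_len(ncols + nart), tol = tol)
  Tb <- ph1$T; basis <- ph1$basis
  p1obj <- sum(c1[basis] * Tb[, ncol(Tb)])
  if (p1obj > 1e-7) {
    return(list(status = "infeasible", x = NULL, objective = NA_real_))
  }
  ## pivot remaining artificials out of the basis, or drop redundant rows
  drop_rows <- integer(0)
  for (i in seq_along(basis)) {
    if (basis[i] > ncols) {
      piv <- which(abs(Tb[i, seq_len(ncols)]) > tol)
      if (length(piv)) {
        Tb <- pivot_tableau(Tb, i, piv[1])
        basis[i] <- piv[1]
      } else {
        drop_rows <- c(drop_rows, i)
      }
    }
  }
  if (length(drop_rows)) {
    Tb <- Tb[-drop_rows, , drop = FALSE]
    basis <- basis[-drop_rows]
  }

  ## phase 2 on real columns only
  c2 <- c(if (sense == "max") -obj else obj, numeric(k), rep(0, nart))
  ph2 <- simplex_iterate(Tb, basis, c2, allowed = seq_len(ncols), tol = tol)
  if (ph2$status == "unbounded") {
    return(list(status = "unbounded", x = NULL, objective = NA_real_))
  }
  Tb <- ph2$T; basis <- ph2$basis
  y <- numeric(ncols)
  y[basis] <- Tb[, ncol(Tb)]
  x <- y[seq_len(n)] + lb
  list(status = "optimal", x = x, objective = sum(obj * x))
}

## One simplex run (minimization) on an explicit tableau.
## `allowed` restricts entering columns (used to lock out artificials).
## Bland's rule: smallest entering index; leaving ties broken by smallest
## basic-variable index. Deterministic and cycle-free.
simplex_iterate <- function(Tb, basis, cost, allowed, tol = 1e-9,
                            max_iter = 100000L) {
  rhs_col <- ncol(Tb)
  for (it in seq_len(max_iter)) {
    cb <- cost[basis]
    rc <- cost[seq_len(rhs_col - 1)] -
      as.numeric(crossprod(Tb[, seq_len(rhs_col - 1), drop = FALSE], cb))
    cand <- allowed[rc[allowed] < -tol]
    if (!length(cand)) {
      return(list(T = Tb, basis = basis, status = "optimal"))
    }
    j <- min(cand)
    col <- Tb[, j]
    rows <- which(col > tol)
    if (!length(rows)) {
      return(list(T = Tb, basis = basis, status = "unbounded"))
    }
    ratios <- Tb[rows, rhs_col] / col[rows]
    best <- min(ratios)
    tie <- rows[ratios <= best + tol]
    r <- tie[which.min(basis[tie])]
    Tb <- pivot_tableau(Tb, r, j)
    basis[r] <- j
  }
  stop("simplex iteration limit exceeded")
}

pivot_tableau <- function(Tb, r, j) {
  Tb[r, ] <- Tb[r, ] / Tb[r, j]
  other <- setdiff(seq_len(nrow(Tb)), r)
  if (length(other)) {
    Tb[other, ] <- Tb[other, , drop = FALSE] - outer(Tb[other, j], Tb[r, ])
  }
  Tb
}
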