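# Dense two-phase primal simplex for the small linear programs arising in
# flux balance analysis:  max/min  obj'v  s.t.  A v = b,  lb <= v <= ub.
# No LP backend is assumed; problems here are small (tens of reactions), so a
# tableau method with Bland's-rule anti-cycling is robust and fast enough.

#' Solve a bounded linear program
#'
#' Solves `max (or min) obj'v` subject to `A v = b` and `lb <= v <= ub` with a
#' two-phase primal simplex. Intended for the small LPs of constraint-based
#' metabolic modeling; not a general sparse large-scale solver.
#'
#' @param obj numeric objective coefficient vector (length n).
#' @param A constraint matrix (m x n); dense or a `Matrix` sparse matrix.
#' @param b right-hand side vector (length m).
#' @param lb,ub lower/upper variable bounds; `lb` must be finite, `ub` may be
#'   `Inf`.
#' @param maximize logical; maximize (default) or minimize.
#' @param tol feasibility/optimality tolerance.
#' @param max_iter pivot iteration cap.
#'
#' @return list with `status` ("optimal", "infeasible", "unbounded",
#'   "iteration_limit"), `x` (solution vector, `NA` unless optimal),
#'   `objective`, and for unbounded problems `ray_var` (index of a variable on
#'   an unbounded ray).
#' @keywords internal
lp_solve <- function(obj, A, b, lb, ub, maximize = TRUE, tol = 1e-9,
                     max_iter = 10000L) {
  A <- as.matrix(A)
  n <- length(obj)
  m <- nrow(A)
  stopifnot(ncol(A) == n, length(b) == m, length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb))) {
    stop("lp_solve requires finite lower bounds (substitute a large negative bound)")
  }
  if (any(lb > ub + tol)) {
    return(list(status = "infeasible", x = rep(NA_real_, n), objective = NA_real_))
  }
  sense <- if (maximize) 1 else -1
  cvec <- sense * obj

  # shift x = v - lb >= 0
  ubx <- ub - lb
  rhs_eq <- b - as.numeric(A %*% lb)

  bounded <- which(is.finite(ubx))
  n_u <- length(bounded)

  # columns: x (n) | slack (n_u) | artificial (m); rows: bound rows then eq rows
  ncols <- n + n_u + m
  nrows <- n_u + m
  Tm <- matrix(0, nrows, ncols)
  rhs <- numeric(nrows)
  basis <- integer(nrows)
  if (n_u > 0L) {
    for (k in seq_len(n_u)) {
      Tm[k, bounded[k]] <- 1
      Tm[k, n + k] <- 1
      rhs[k] <- ubx[bounded[k]]
      basis[k] <- n + k
    }
  }
  for (i in seq_len(m)) {
    row <- A[i, ]
    r <- rhs_eq[i]
    if (r < 0) { row <- -row; r <- -r }
    Tm[n_u + i, seq_len(n)] <- row
    Tm[n_u + i, n + n_u + i] <- 1
    rhs[n_u + i] <- r
    basis[n_u + i] <- n + n_u + i
  }

  pivot <- function(Tm, rhs, pr, pc) {
    piv <- Tm[pr, pc]
    Tm[pr, ] <- Tm[pr, ] / piv
    rhs[pr] <- rhs[pr] / piv
    other <- setdiff(seq_len(nrow(Tm)), pr)
    fac <- Tm[other, pc]
    nz <- which(abs(fac) > 0)
    if (length(nz)) {
      rows <- other[nz]
      Tm[rows, ] <- Tm[rows, ] - outer(fac[nz], Tm[pr, ])
      rhs[rows] <- rhs[rows] - fac[nz] * rhs[pr]
      Tm[rows, pc] <- 0
    }
    list(Tm = Tm, rhs = rhs)
  }

  # maximize cost'x over current tableau; returns status and updated state
  run_phase <- function(Tm, rhs, basis, cost, allowed, bland_after = 200L) {
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > max_iter) return(list(status = "iteration_limit", Tm = Tm, rhs = rhs, basis = basis))
      cb <- cost[basis]
      red <- cost - as.numeric(cb %*% Tm)
      red[!allowed] <- -Inf
      red[basis] <- -Inf
      if (it <= bland_after) {
        pc <- which.max(red)
        if (red[pc] <= tol) return(list(status = "optimal", Tm = Tm, rhs = rhs, basis = basis))
      } else {
        cand <- which(red > tol)
        if (!length(cand)) return(list(status = "optimal", Tm = Tm, rhs = rhs, basis = basis))
        pc <- cand[1L]
      }
      col <- Tm[, pc]
      pos <- which(col > tol)
      if (!length(pos)) {
        return(list(status = "unbounded", Tm = Tm, rhs = rhs, basis = basis, ray = pc))
      }
      ratios <- rhs[pos] / col[pos]
      best <- min(ratios)
      ties <- pos[ratios <= best + tol * (1 + abs(best))]
      pr <- ties[which.min(basis[ties])]  # Bland-style tie break
      res <- pivot(Tm, rhs, pr, pc)
      Tm <- res$Tm; rhs <- res$rhs
      basis[pr] <- pc
    }
  }

  # phase 1: drive artificials to zero
  art_cols <- n + n_u + seq_len(m)
  cost1 <- numeric(ncols)
  cost1[art_cols] <- -1
  allowed1 <- rep(TRUE, ncols)
  ph1 <- run_phase(Tm, rhs, basis, cost1, allowed1)
  if (ph1$status == "iteration_limit") {
    return(list(status = "iteration_limit", x = rep(NA_real_, n), objective = NA_real_))
  }
  Tm <- ph1$Tm; rhs <- ph1$rhs; basis <- ph1$basis
  art_val <- sum(rhs[basis %in% art_cols])
  if (art_val > 1e-7 * (1 + max(abs(rhs_eq)))) {
    return(list(status = "infeasible", x = rep(NA_real_, n), objective = NA_real_))
  }
  # pivot out any artificial still basic (at zero); drop redundant rows
  for (r in which(basis %in% art_cols)) {
    cand <- which(abs(Tm[r, seq_len(n + n_u)]) > tol)
    if (length(cand)) {
      res <- pivot(Tm, rhs, r, cand[1L])
      Tm <- res$Tm; rhs <- res$rhs
      basis[r] <- cand[1L]
    }
  }

  # phase 2: real objective, artificials barred
  cost2 <- numeric(ncols)
  cost2[seq_len(n)] <- cvec
  allowed2 <- rep(TRUE, ncols)
  allowed2[art_cols] <- FALSE
  keep <- !(basis %in% art_cols)
  if (!all(keep)) {  # redundant rows: artificial basic at zero with no pivot
    Tm <- Tm[keep, , drop = FALSE]
    rhs <- rhs[keep]
    basis <- basis[keep]
  }
  ph2 <- run_phase(Tm, rhs, basis, cost2, allowed2)
  if (ph2$status == "iteration_limit") {
    return(list(status = "iteration_limit", x = rep(NA_real_, n), objective = NA_real_))
  }
  if (ph2$status == "unbounded") {
    rv <- ph2$ray
    return(list(status = "unbounded", x = rep(NA_real_, n), objective = NA_real_,
                ray_var = if (rv <= n) rv else NA_integer_))
  }
  x <- numeric(ncols)
  x[ph2$basis] <- ph2$rhs
  v <- x[seq_len(n)] + lb
  list(status = "optimal", x = v, objective = sum(obj * v))
}
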