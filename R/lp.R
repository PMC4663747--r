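## Bounded-variable linear programming by the two-phase simplex method.
##
## Flux balance analysis needs the LP
##     maximize  c'v   subject to  S v = 0,  lb <= v <= ub
## with box bounds handled natively (turning every bound into a slack row
## would square the tableau for nothing). Variables are kept at one of their
## bounds while nonbasic; Bland's smallest-index rule is used for both the
## entering and the leaving choice, which guarantees termination under
## degeneracy. Basis systems are re-solved densely each iteration -- the
## models handled here have at most a few hundred reactions, where two dense
## m-by-m solves per pivot are cheap and free of update drift.

#' Solve a bounded-variable linear program
#'
#' Maximizes (or minimizes) `obj %*% x` subject to `A %*% x == rhs` and
#' `lb <= x <= ub`. All bounds must be finite; this is always the case for
#' metabolic models after default bounds are applied.
#'
#' @param obj numeric objective coefficients, length `ncol(A)`.
#' @param A dense constraint matrix (equality rows only).
#' @param rhs right-hand side, length `nrow(A)`.
#' @param lb,ub finite lower/upper variable bounds.
#' @param maximize sense of optimization.
#' @param tol reduced-cost optimality tolerance.
#' @return list with `status` (`"optimal"`, `"infeasible"` or `"unbounded"`),
#'   `objective`, and the primal solution `x` (named after `colnames(A)`).
#' @export
lp_bounded <- function(obj, A, rhs, lb, ub, maximize = TRUE, tol = 1e-9) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(rhs) == m, length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop_runtime("lp_bounded requires finite variable bounds")
  if (any(lb > ub + 1e-12))
    stop_validation("lp_bounded: lower bound exceeds upper bound")
  cc <- if (maximize) as.numeric(obj) else -as.numeric(obj)

  if (m == 0L) { # pure box problem
    x <- ifelse(cc > 0, ub, lb)
    names(x) <- colnames(A)
    return(list(status = "optimal", objective = sum(obj * x), x = x))
  }

  ## start every structural variable at its bound nearest zero
  at_ub <- abs(ub) < abs(lb)
  x0 <- ifelse(at_ub, ub, lb)
  resid <- rhs - drop(A %*% x0)

  ## artificial columns give an immediate feasible basis for phase 1
  sg <- ifelse(resid >= 0, 1, -1)
  Afull <- cbind(A, diag(sg, nrow = m))
  lbf <- c(lb, rep(0, m))
  ubf <- c(ub, rep(Inf, m))
  basis <- n + seq_len(m)
  at_ub_full <- c(at_ub, rep(FALSE, m))

  phase1 <- c(rep(0, n), rep(-1, m))
  r1 <- simplex_core(Afull, rhs, lbf, ubf, phase1, basis, at_ub_full, tol)
  if (r1$status == "iteration_limit")
    stop_runtime("lp_bounded: iteration limit reached in phase 1")
  if (r1$objective < -1e-7)
    return(list(status = "infeasible", objective = NA_real_, x = NULL))

  ## pin artificials to zero and optimize the true objective
  ubf2 <- ubf; ubf2[n + seq_len(m)] <- 0
  r2 <- simplex_core(Afull, rhs, lbf, ubf2, c(cc, rep(0, m)),
                     r1$basis, r1$at_ub, tol)
  if (r2$status == "iteration_limit")
    stop_runtime("lp_bounded: iteration limit reached in phase 2")
  if (r2$status == "unbounded")
    return(list(status = "unbounded", objective = if (maximize) Inf else -Inf,
                x = NULL))
  x <- r2$x[seq_len(n)]
  names(x) <- colnames(A)
  list(status = "optimal", objective = sum(obj * x), x = x)
}

## Core bounded simplex iteration (maximization). Returns status, the final
## basis/bound-status (for phase hand-over), solution and objective.
simplex_core <- function(A, b, lb, ub, cc, basis, at_ub, tol,
                         max_iter = NULL) {
  m <- nrow(A); N <- ncol(A)
  if (is.null(max_iter)) max_iter <- 2000L + 60L * N
  piv_tol <- 1e-11
  in_basis <- rep(FALSE, N); in_basis[basis] <- TRUE

  for (iter in seq_len(max_iter)) {
    nb <- which(!in_basis)
    xN <- ifelse(at_ub[nb], ub[nb], lb[nb])
    B <- A[, basis, drop = FALSE]
    xB <- drop(solve(B, b - A[, nb, drop = FALSE] %*% xN))
    y <- drop(solve(t(B), cc[basis]))
    d <- cc[nb] - drop(crossprod(A[, nb, drop = FALSE], y))

    up <- !at_ub[nb] & d > tol     # at lower bound, wants to increase
    dn <- at_ub[nb] & d < -tol     # at upper bound, wants to decrease
    elig <- nb[up | dn]
    if (length(elig) == 0L) {
      x <- numeric(N)
      x[nb] <- xN; x[basis] <- xB
      return(list(status = "optimal", objective = sum(cc * x), x = x,
                  basis = basis, at_ub = at_ub))
    }
    j <- min(elig)                               # Bland: smallest index
    s <- if (at_ub[j]) -1 else 1                 # direction of movement
    w <- drop(solve(B, A[, j]))

    ## ratio test: entering variable's own span plus basic variables
    ## hitting either of their bounds while xB moves by -s*t*w
    cand_t <- ub[j] - lb[j]
    cand_i <- j
    sw <- s * w
    for (i in seq_len(m)) {
      bi <- basis[i]
      if (sw[i] > piv_tol) {
        ti <- (xB[i] - lb[bi]) / sw[i]
      } else if (sw[i] < -piv_tol) {
        ti <- (ub[bi] - xB[i]) / (-sw[i])
      } else next
      ti <- max(ti, 0)
      if (ti < cand_t - piv_tol ||
          (ti < cand_t + piv_tol && bi < cand_i)) {
        cand_t <- ti; cand_i <- bi
      }
    }
    if (!is.finite(cand_t))
      return(list(status = "unbounded", objective = Inf, x = NULL,
                  basis = basis, at_ub = at_ub))

    if (cand_i == j) {
      at_ub[j] <- !at_ub[j]                      # bound flip, basis unchanged
    } else {
      r <- match(cand_i, basis)
      leav <- basis[r]
      ## which bound did the leaving variable hit?
      at_ub[leav] <- sw[r] < 0
      basis[r] <- j
      in_basis[leav] <- FALSE
      in_basis[j] <- TRUE
    }
  }
  list(status = "iteration_limit", objective = NA_real_, x = NULL,
       basis = basis, at_ub = at_ub)
}
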