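# Internal linear-programming layer.
#
# All constraint-based computations in the package reduce to LPs of the form
#   optimise  c'v   s.t.  A v = b,  lb <= v <= ub
# with finite bounds (models use +/-1000 mmol/gCDW/h as "unconstrained").
# FBA instances are heavily degenerate, so the solver is a dense
# bounded-variable primal simplex with Bland's anti-cycling rule: two
# phases, phase 1 minimising artificial-variable mass, the basis factorised
# afresh each pivot (problems here are far too small for that to matter).
# Deterministic by construction: no randomised tie-breaking.

#' @keywords internal
#' @noRd
.simplex_bounded <- function(cost, A, b, lb, ub, tol = 1e-9, max_iter = NULL) {
  m <- nrow(A)
  n <- ncol(A)
  if (is.null(max_iter)) max_iter <- 2000L + 200L * (n + m)

  run_phase <- function(cost, A, lb, ub, basis, at_upper, b) {
    n <- ncol(A)
    m <- nrow(A)
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > max_iter)
        stop("simplex iteration limit reached", call. = FALSE)
      B <- A[, basis, drop = FALSE]
      nonbasic <- setdiff(seq_len(n), basis)
      xN <- ifelse(at_upper[nonbasic], ub[nonbasic], lb[nonbasic])
      xB <- tryCatch(
        as.numeric(solve(B, b - A[, nonbasic, drop = FALSE] %*% xN)),
        error = function(e) stop("singular basis", call. = FALSE))
      y <- solve(t(B), cost[basis])
      d <- cost - as.numeric(crossprod(A, y))
      movable <- ub[nonbasic] > lb[nonbasic]
      eligible <- nonbasic[movable &
                             ((!at_upper[nonbasic] & d[nonbasic] < -tol) |
                              (at_upper[nonbasic] & d[nonbasic] > tol))]
      if (length(eligible) == 0) {
        x <- numeric(n)
        x[nonbasic] <- xN
        x[basis] <- xB
        return(list(x = x, basis = basis, at_upper = at_upper,
                    value = sum(cost * x)))
      }
      j <- min(eligible)                 # Bland: smallest entering index
      up <- !at_upper[j]                 # entering variable moves up or down
      w <- as.numeric(solve(B, A[, j]))  # basic response per unit increase
      delta <- if (up) -w else w         # xB change per unit step
      t_own <- ub[j] - lb[j]
      t_basic <- rep(Inf, m)
      dn <- delta < -tol
      upk <- delta > tol
      t_basic[dn] <- (lb[basis[dn]] - xB[dn]) / delta[dn]
      t_basic[upk] <- (ub[basis[upk]] - xB[upk]) / delta[upk]
      t_basic[t_basic < 0] <- 0          # degenerate: already at the bound
      t_max <- min(t_own, t_basic)
      if (!is.finite(t_max))
        stop("LP unbounded (impossible with finite bounds)", call. = FALSE)
      if (t_own <= min(t_basic)) {
        # entering variable swings to its other bound; basis unchanged
        at_upper[j] <- up
        next
      }
      hits <- which(t_basic <= t_max + 1e-12)
      i_leave <- hits[which.min(basis[hits])]  # Bland on leaving index
      leave <- basis[i_leave]
      at_upper[leave] <- delta[i_leave] > 0
      basis[i_leave] <- j
      at_upper[j] <- FALSE
    }
  }

  # phase 1: artificial columns patch the residual of an all-lower-bound start
  x0 <- lb
  r <- b - as.numeric(A %*% x0)
  Aa <- cbind(A, diag(ifelse(r >= 0, 1, -1), m))
  lb1 <- c(lb, rep(0, m))
  ub1 <- c(ub, abs(r))
  basis <- n + seq_len(m)
  at_upper <- rep(FALSE, n + m)
  cost1 <- c(rep(0, n), rep(1, m))
  p1 <- run_phase(cost1, Aa, lb1, ub1, basis, at_upper, b)
  if (p1$value > 1e-7)
    return(list(status = "infeasible", x = NULL, objval = NA_real_))
  # pin artificials to zero and run phase 2 on the original costs; a basic
  # artificial stuck at zero is harmless (degenerate)
  lb1[n + seq_len(m)] <- 0
  ub1[n + seq_len(m)] <- 0
  cost2 <- c(cost, rep(0, m))
  p2 <- run_phase(cost2, Aa, lb1, ub1, p1$basis, p1$at_upper, b)
  list(status = "optimal", x = p2$x[seq_len(n)],
       objval = sum(cost * p2$x[seq_len(n)]))
}

#' @keywords internal
#' @noRd
lp_solve <- function(obj, A, b, lb, ub, sense = c("max", "min"), tol = 1e-9) {
  sense <- match.arg(sense)
  n <- length(obj)
  A <- as.matrix(A)
  stopifnot(length(lb) == n, length(ub) == n, ncol(A) == n,
            nrow(A) == length(b))
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("lp_solve requires finite variable bounds", call. = FALSE)
  if (any(lb > ub + 1e-12))
    return(list(status = "infeasible", x = NULL, objval = NA_real_))
  cost <- if (sense == "max") -obj else obj
  out <- .simplex_bounded(cost, A, b, lb, ub, tol = tol)
  if (!identical(out$status, "optimal")) return(out)
  list(status = "optimal", x = out$x, objval = sum(obj * out$x))
}
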