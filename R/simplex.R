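# Bounded-variable two-phase primal simplex.
#
# Solves   max/min  c'x   s.t.  A x = b,  lb <= x <= ub
# with possibly infinite bounds. Dense linear algebra: flux-balance problems
# at the core-model scale have a few dozen rows, for which factorising the
# basis at every iteration is cheap and numerically transparent. Bland's
# smallest-index rule throughout guarantees termination under degeneracy.

.SIMPLEX_PIVTOL <- 1e-10   # smallest pivot magnitude accepted
.SIMPLEX_DJTOL <- 1e-9     # reduced-cost optimality tolerance
.SIMPLEX_FEASTOL <- 1e-7   # phase-1 residual accepted as feasible

#' Solve a bounded linear program
#'
#' Internal solver behind [solveFBA()]. Maximises (or minimises) \code{obj'x}
#' subject to \code{A x = b} and \code{lb <= x <= ub}.
#'
#' @param obj numeric objective vector.
#' @param A constraint matrix (dense).
#' @param b right-hand side (defaults to zeros).
#' @param lb,ub bound vectors; \code{-Inf}/\code{Inf} allowed.
#' @param maximize logical.
#' @return list with \code{status} ("optimal", "infeasible", "unbounded"),
#'   \code{objective} and \code{x}.
#' @keywords internal
simplexSolve <- function(obj, A, b = NULL, lb, ub, maximize = TRUE) {
  A <- as.matrix(A)
  m <- nrow(A)
  n <- ncol(A)
  if (is.null(b)) b <- numeric(m)
  stopifnot(length(obj) == n, length(lb) == n, length(ub) == n,
            length(b) == m)
  if (any(lb > ub + 1e-12)) {
    return(list(status = "infeasible", objective = NA_real_, x = NULL))
  }
  # squeeze numerically-equal bounds to exact equality
  eq <- is.finite(lb) & is.finite(ub) & (ub - lb) < 1e-12
  ub[eq] <- lb[eq]

  if (m == 0L) {
    # no balance rows: optimum at the bounds
    x <- ifelse((obj > 0) == maximize & obj != 0, ub, lb)
    x[obj == 0] <- ifelse(is.finite(lb[obj == 0]), lb[obj == 0],
                          pmin(ub[obj == 0], 0))
    if (any(!is.finite(x[obj != 0]))) {
      return(list(status = "unbounded", objective = NA_real_, x = NULL))
    }
    x[!is.finite(x)] <- 0
    return(list(status = "optimal", objective = sum(obj * x), x = x))
  }

  # initial nonbasic placement of structural variables
  x <- numeric(n)
  at <- integer(n)                   # -1 at lb, +1 at ub, 2 free-at-zero
  for (j in seq_len(n)) {
    if (is.finite(lb[j])) { x[j] <- lb[j]; at[j] <- -1L }
    else if (is.finite(ub[j])) { x[j] <- ub[j]; at[j] <- 1L }
    else { x[j] <- 0; at[j] <- 2L }
  }
  r <- b - drop(A %*% x)
  sgn <- ifelse(r >= 0, 1, -1)
  Afull <- cbind(A, diag(sgn, nrow = m))
  nt <- n + m
  lbf <- c(lb, numeric(m))
  ubf <- c(ub, rep(Inf, m))
  xf <- c(x, abs(r))
  atf <- c(at, integer(m))           # artificials basic
  basis <- (n + 1L):nt
  inbasis <- logical(nt); inbasis[basis] <- TRUE

  runPhase <- function(cost, phase) {
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > 20000L) stop("simplex iteration limit exceeded")
      B <- Afull[, basis, drop = FALSE]
      cB <- cost[basis]
      y <- tryCatch(solve(t(B), cB), error = function(e) NULL)
      if (is.null(y)) stop("singular basis in simplex")
      d <- cost - drop(y %*% Afull)
      d[basis] <- 0
      # entering candidates (maximisation form)
      incr <- (!inbasis) & ((atf == -1L & d > .SIMPLEX_DJTOL) |
                            (atf == 2L & d > .SIMPLEX_DJTOL))
      decr <- (!inbasis) & ((atf == 1L & d < -.SIMPLEX_DJTOL) |
                            (atf == 2L & d < -.SIMPLEX_DJTOL))
      cand <- which(incr | decr)
      if (phase == 1L) cand <- cand[cand <= n]  # artificials never re-enter
      if (!length(cand)) return(TRUE)           # optimal for this phase
      t_ <- min(cand)                           # Bland
      delta <- if (incr[t_]) 1 else -1
      w <- solve(B, Afull[, t_])                # basic direction
      # ratio test
      step <- if (delta > 0) ubf[t_] - xf[t_] else xf[t_] - lbf[t_]
      leave <- 0L
      for (i in seq_len(m)) {
        wi <- delta * w[i]
        if (abs(wi) < .SIMPLEX_PIVTOL) next
        bi <- basis[i]
        room <- if (wi > 0) xf[bi] - lbf[bi] else ubf[bi] - xf[bi]
        s_i <- room / abs(wi)
        if (s_i < step - 1e-12 || (s_i < step + 1e-12 &&
            (leave == 0L || bi < basis[leave]))) {
          step <- s_i
          leave <- i
        }
      }
      if (!is.finite(step)) {
        return(FALSE)                           # unbounded direction
      }
      step <- max(step, 0)
      # apply the move
      xf[t_] <<- xf[t_] + delta * step
      if (step > 0) xf[basis] <<- xf[basis] - delta * step * w
      if (leave == 0L) {
        # entering variable hit its own opposite bound: bound flip
        atf[t_] <<- if (delta > 0) 1L else -1L
      } else {
        lv <- basis[leave]
        wi <- delta * w[leave]
        atf[lv] <<- if (wi > 0) -1L else 1L
        xf[lv] <<- if (wi > 0) lbf[lv] else ubf[lv]
        inbasis[lv] <<- FALSE
        basis[leave] <<- t_
        inbasis[t_] <<- TRUE
        atf[t_] <<- 0L
      }
    }
  }

  # Phase 1: drive artificials to zero
  c1 <- c(numeric(n), rep(-1, m))
  ok <- runPhase(c1, 1L)
  if (!ok) stop("internal: phase-1 unbounded")
  if (sum(xf[(n + 1L):nt]) > .SIMPLEX_FEASTOL) {
    return(list(status = "infeasible", objective = NA_real_, x = NULL))
  }
  # pin any residual (degenerate) basic artificials at zero
  ubf[(n + 1L):nt] <- 0
  xf[(n + 1L):nt] <- 0

  # Phase 2
  c2 <- c(if (maximize) obj else -obj, numeric(m))
  ok <- runPhase(c2, 2L)
  if (!ok) {
    return(list(status = "unbounded", objective = NA_real_, x = NULL))
  }
  xs <- xf[seq_len(n)]
  objval <- sum(obj * xs)
  list(status = "optimal", objective = objval, x = xs)
}
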