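# Dense bounded-variable primal simplex (two phases, Bland's anti-cycling
# rule). Written for the small, often degenerate LPs that flux balance
# analysis generates; correctness over speed. Problems are expected to be
# pre-scaled by the caller (solve_lp does column/row equilibration).
#
#   minimize c'x  subject to  A x = b,  l <= x <= u   (u may be Inf)

.bounded_simplex <- function(c_, A, b, l, u, tol = 1e-9, max_iter = 20000) {
  m <- nrow(A); n <- ncol(A)
  if (m == 0L) {
    # pure bound problem
    x <- ifelse(c_ > 0, l, ifelse(c_ < 0, u, l))
    if (any(!is.finite(x))) return(list(status = "unbounded"))
    return(list(status = "optimal", x = x, objective = sum(c_ * x)))
  }
  # phase 1: artificials with identity columns signed to match the residual
  start_at <- ifelse(is.finite(l), l, pmin(u, 0))
  x <- start_at
  r <- b - as.vector(A %*% x)
  sgn <- ifelse(r >= 0, 1, -1)
  Aext <- cbind(A, diag(sgn, m))
  lext <- c(l, rep(0, m))
  uext <- c(u, rep(Inf, m))
  xext <- c(x, abs(r))
  basis <- n + seq_len(m)
  at_upper <- rep(FALSE, n + m)   # status of nonbasic variables

  run_phase <- function(cost, basis, xext, at_upper, phase) {
    nm <- length(cost)
    for (it in seq_len(max_iter)) {
      Bmat <- Aext[, basis, drop = FALSE]
      Binv <- tryCatch(solve(Bmat), error = function(e) NULL)
      if (is.null(Binv)) return(list(status = "singular"))
      xB <- as.vector(Binv %*% (b - Aext[, -basis, drop = FALSE] %*%
                                  xext[-basis]))
      xext[basis] <- xB
      y <- as.vector(crossprod(Binv, cost[basis]))
      nonbasic <- setdiff(seq_len(nm), basis)
      dvec <- cost[nonbasic] - as.vector(crossprod(Aext[, nonbasic,
                                                        drop = FALSE], y))
      enter_lower <- nonbasic[dvec < -tol & !at_upper[nonbasic] &
                                is.finite(lext[nonbasic])]
      enter_upper <- nonbasic[dvec > tol & at_upper[nonbasic]]
      cand <- sort(c(enter_lower, enter_upper))
      if (!length(cand)) {
        return(list(status = "optimal", basis = basis, xext = xext,
                    at_upper = at_upper))
      }
      j <- cand[1]                       # Bland's rule: smallest index
      sigma <- if (at_upper[j]) -1 else 1
      w <- as.vector(Binv %*% Aext[, j]) * (-sigma)
      # ratio test; ties broken by smallest variable index (Bland)
      t_max <- uext[j] - lext[j]          # bound-to-bound flip distance
      leave <- 0L; leave_to <- NA
      eps_t <- 1e-12
      for (k in seq_len(m)) {
        bi <- basis[k]
        room <- if (w[k] > tol) (uext[bi] - xext[bi]) / w[k]
                else if (w[k] < -tol) (xext[bi] - lext[bi]) / (-w[k])
                else next
        dirn <- if (w[k] > tol) "upper" else "lower"
        if (room < t_max - eps_t) {
          t_max <- room; leave <- k; leave_to <- dirn
        } else if (room <= t_max + eps_t &&
                   (leave == 0L || bi < basis[leave])) {
          t_max <- min(t_max, room); leave <- k; leave_to <- dirn
        }
      }
      if (!is.finite(t_max)) return(list(status = "unbounded"))
      t_max <- max(t_max, 0)
      # apply the step
      xext[j] <- xext[j] + sigma * t_max
      xext[basis] <- xext[basis] + w * t_max
      if (leave == 0L) {
        at_upper[j] <- !at_upper[j]      # bound-to-bound flip
      } else {
        bi <- basis[leave]
        at_upper[bi] <- identical(leave_to, "upper")
        xext[bi] <- if (at_upper[bi]) uext[bi] else lext[bi]
        basis[leave] <- j
      }
    }
    list(status = "maxiter")
  }

  cost1 <- c(rep(0, n), rep(1, m))
  ph1 <- run_phase(cost1, basis, xext, at_upper, 1L)
  if (!identical(ph1$status, "optimal")) {
    return(list(status = if (identical(ph1$status, "maxiter")) "maxiter"
                else "infeasible"))
  }
  obj1 <- sum(cost1 * ph1$xext)
  if (obj1 > 1e-7) return(list(status = "infeasible"))
  # freeze artificials at zero for phase 2
  uext[n + seq_len(m)] <- 0
  xext <- ph1$xext
  xext[n + seq_len(m)] <- pmin(xext[n + seq_len(m)], 0)
  cost2 <- c(c_, rep(0, m))
  ph2 <- run_phase(cost2, ph1$basis, xext, ph1$at_upper, 2L)
  if (!identical(ph2$status, "optimal")) {
    return(list(status = ph2$status))
  }
  x <- ph2$xext[seq_len(n)]
  list(status = "optimal", x = x, objective = sum(c_ * x))
}
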