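#' @keywords internal
"_PACKAGE"

# Solver tolerances, stated once and used everywhere. EVA ranges and FCC
# difference quotients are tolerance-sensitive, so these are not per-call
# arguments.
.boolec_tol <- list(
  feasibility = 1e-9,  # constraint satisfaction required of a solution
  zero_flux   = 1e-6   # below this a flux counts as zero (mmol/gDW/h)
)

#' Solver tolerances used by all linear-programming routines
#'
#' @return Named list with elements `feasibility` and `zero_flux`.
#' @export
lp_tolerances <- function() .boolec_tol

#' Solve a bounded linear program
#'
#' Minimizes or maximizes `obj %*% x` subject to `Aeq %*% x == beq` and
#' `lb <= x <= ub`. This is the single entry point through which every
#' flux-balance computation in the package runs.
#'
#' The default backend is the package's dense bounded-variable primal
#' simplex (two phases, Bland's anti-cycling rule), written for the small
#' but degenerate and badly scaled problems that enzyme-constrained FBA
#' generates; the problem is column/row equilibrated before solving. The
#' `"boot"` (\code{boot::simplex}) and `"pracma"` (\code{pracma::linprog})
#' backends are retained as independent implementations for cross-checking
#' on the problems they handle.
#'
#' @param obj numeric objective coefficients.
#' @param Aeq equality constraint matrix (may have zero rows).
#' @param beq equality right-hand sides.
#' @param lb,ub variable bounds; `ub` may be `Inf`, `lb` must be finite.
#' @param sense `"min"` or `"max"`.
#' @param solver `"internal"` (default), `"boot"` or `"pracma"`.
#' @param inf_bound finite stand-in for infinite upper bounds (external
#'   backends only).
#' @return List with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`
#'   or `"maxiter"`), `objective`, and solution vector `x` (named like
#'   `obj` if it has names).
#' @export
solve_lp <- function(obj, Aeq, beq, lb, ub, sense = c("min", "max"),
                     solver = c("internal", "boot", "pracma"),
                     inf_bound = 1e6) {
  sense <- match.arg(sense)
  solver <- match.arg(solver)
  n <- length(obj)
  stopifnot(ncol(Aeq) == n, length(beq) == nrow(Aeq),
            length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb))) stop("solve_lp: lower bounds must be finite")
  fail <- function(status) {
    list(status = status, objective = NA_real_,
         x = stats::setNames(rep(NA_real_, n), names(obj)),
         provenance = list(solver = solver, tolerances = .boolec_tol))
  }
  if (any(lb > ub + .boolec_tol$feasibility)) return(fail("infeasible"))

  # column scaling: x = d * z with d ~ the variable's magnitude, so the
  # simplex works on O(1) quantities (enzyme usages are ~1e-5 while fluxes
  # are ~10, which defeats pivoting tolerances otherwise)
  ub_fin <- pmin(ub, inf_bound)
  d <- pmax(abs(ub_fin), abs(lb))
  d[d < 1e-12 | !is.finite(d)] <- 1
  Aeq_s <- sweep(Aeq, 2, d, `*`)
  sgn <- if (sense == "max") -1 else 1
  obj_s <- sgn * obj * d
  lb_s <- lb / d
  ub_s <- ub / d   # Inf stays Inf for the internal backend
  # row equilibration (solution unchanged)
  if (nrow(Aeq_s)) {
    rmax <- apply(abs(Aeq_s), 1, max)
    rmax[rmax < 1e-12] <- 1
    Aeq_s <- Aeq_s / rmax
    beq_s <- beq / rmax
  } else beq_s <- beq
  # drop linearly dependent equality rows (conserved-moiety balances make S
  # rank-deficient); the dropped rows are verified on the solution below
  dropped <- integer()
  if (nrow(Aeq_s) > 1) {
    qrt <- qr(t(Aeq_s))
    if (qrt$rank < nrow(Aeq_s)) {
      keep <- sort(qrt$pivot[seq_len(qrt$rank)])
      dropped <- setdiff(seq_len(nrow(Aeq_s)), keep)
      Aeq_all <- Aeq_s; beq_all <- beq_s
      Aeq_s <- Aeq_s[keep, , drop = FALSE]
      beq_s <- beq_s[keep]
    }
  }

  if (solver == "internal") {
    res <- .bounded_simplex(obj_s, Aeq_s, beq_s, lb_s, ub_s)
    if (res$status != "optimal") return(fail(res$status))
    x <- res$x * d
  } else {
    ub_s2 <- pmin(ub_s, inf_bound)
    width <- ub_s2 - lb_s
    beq_sh <- beq_s - as.vector(Aeq_s %*% lb_s)
    if (solver == "boot") {
      neg <- beq_sh < 0
      A3 <- Aeq_s
      if (any(neg)) {
        A3[neg, ] <- -A3[neg, , drop = FALSE]
        beq_sh[neg] <- -beq_sh[neg]
      }
      res <- tryCatch(
        boot::simplex(a = obj_s, A1 = diag(n), b1 = width, A3 = A3,
                      b3 = beq_sh, maxi = FALSE,
                      n.iter = 50 * (n + nrow(A3)), eps = 1e-10),
        error = function(e) NULL)
      if (is.null(res)) return(fail("solver_error"))
      status <- switch(as.character(res$solved),
                       "1" = "optimal", "0" = "maxiter", "-1" = "infeasible",
                       "unknown")
      if (status != "optimal") return(fail(status))
      x <- (as.numeric(res$soln) + lb_s) * d
    } else {
      if (!requireNamespace("pracma", quietly = TRUE)) {
        stop("solver 'pracma' requested but package pracma is not available")
      }
      res <- tryCatch(
        pracma::linprog(cc = obj_s, A = diag(n), b = width, Aeq = Aeq_s,
                        beq = beq_sh, maximize = FALSE, maxiter = 10000),
        error = function(e) NULL)
      if (is.null(res) || is.null(res$x)) return(fail("infeasible"))
      x <- (as.numeric(res$x) + lb_s) * d
    }
  }
  x <- pmin(pmax(x, lb), pmin(ub, Inf))
  names(x) <- names(obj)
  if (length(dropped)) {
    resid <- max(abs(Aeq_all[dropped, , drop = FALSE] %*% (x / d) -
                       beq_all[dropped]))
    if (resid > 1e-6) return(fail("infeasible"))
  }
  list(status = "optimal", objective = sum(obj * x), x = x,
       provenance = list(solver = solver, tolerances = .boolec_tol))
}
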