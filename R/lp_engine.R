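# Linear-programming computations over (enzyme-constrained) models:
# FBA, glucose minimization at fixed growth, parsimonious enzyme usage,
# and enzyme-usage variability analysis.

#' Build the FBA matrices of a model
#' @param model a `stoich_model` or `ec_model`.
#' @return List with `S` (metabolites x reactions), `lb`, `ub`, and the id
#'   vectors `mets`, `rxns`.
#' @export
fba_matrices <- function(model) {
  mets <- model$metabolites$id
  rxns <- model$reactions$id
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  for (j in seq_along(rxns)) {
    st <- model$stoich[[rxns[j]]]
    S[names(st), j] <- st
  }
  lb <- stats::setNames(model$reactions$lb, rxns)
  ub <- stats::setNames(model$reactions$ub, rxns)
  if (inherits(model, "ec_model")) {
    # an enzyme usage can never exceed pool capacity / Mw; substituting this
    # implied cap for the infinite bound keeps the LP well-scaled
    cap <- pool_capacity(model)
    for (k in seq_along(model$usage_rxns)) {
      rxn <- model$usage_rxns[[k]]
      mw <- model$enzymes$mw_g_per_mmol[
        model$enzymes$enzyme_id == names(model$usage_rxns)[k]]
      ub[rxn] <- min(ub[rxn], cap / mw)
    }
  }
  list(S = S, lb = lb, ub = ub, mets = mets, rxns = rxns)
}

.set_rxn_bounds <- function(model, id, lb = NULL, ub = NULL) {
  i <- match(id, model$reactions$id)
  if (any(is.na(i))) stop(sprintf("unknown reaction(s): %s",
                                  paste(id[is.na(i)], collapse = ", ")))
  if (!is.null(lb)) model$reactions$lb[i] <- lb
  if (!is.null(ub)) model$reactions$ub[i] <- ub
  model
}

.lp_result <- function(sol, model) {
  usages <- NULL
  if (inherits(model, "ec_model") && sol$status == "optimal") {
    usages <- stats::setNames(sol$x[model$usage_rxns],
                              names(model$usage_rxns))
  }
  structure(list(status = sol$status, objective = sol$objective,
                 fluxes = sol$x, usages = usages,
                 provenance = sol$provenance),
            class = "lp_result")
}

#' Flux balance analysis
#'
#' Solves `max/min c^T v` subject to `S v = 0`, `lb <= v <= ub`.
#'
#' @param model a `stoich_model` or `ec_model`.
#' @param objective named numeric vector of objective coefficients over
#'   reaction ids; defaults to the model's stored objective.
#' @param sense `"max"` (default) or `"min"`.
#' @param solver LP backend passed to [solve_lp()].
#' @return An `lp_result` with `status` (`"optimal"`, `"infeasible"`,
#'   `"maxiter"`), `objective`, the flux vector `fluxes`, and for
#'   enzyme-constrained models the enzyme usage vector `usages`.
#' @export
solve_fba <- function(model, objective = NULL, sense = c("max", "min"),
                      solver = "internal") {
  sense <- match.arg(sense)
  if (is.null(objective)) objective <- model$objective
  if (!length(objective)) stop("no objective given and model stores none")
  mat <- fba_matrices(model)
  obj <- stats::setNames(numeric(length(mat$rxns)), mat$rxns)
  obj[names(objective)] <- objective
  sol <- solve_lp(obj, Aeq = mat$S, beq = numeric(length(mat$mets)),
                  lb = mat$lb, ub = mat$ub, sense = sense, solver = solver)
  .lp_result(sol, model)
}

.single_obj <- function(model, rxn, weight = 1) {
  stats::setNames(weight, rxn)
}

.glucose_rxn <- function(model, glucose = NULL) {
  if (!is.null(glucose)) return(glucose)
  ex <- model$exchanges
  if (!is.null(ex$glucose)) return(ex$glucose)
  cand <- grep("glc|glucose", model$reactions$id, ignore.case = TRUE,
               value = TRUE)
  cand <- setdiff(cand, model$reactions$id[startsWith(model$reactions$id,
                                                      .draw_prefix)])
  if (length(cand) == 1) return(cand)
  stop("cannot identify the glucose uptake reaction; pass `glucose`")
}

#' Minimal glucose uptake at a fixed dilution rate
#'
#' Fixes the growth pseudo-reaction to `D` (both bounds) and minimizes the
#' glucose uptake flux, the behavior expected of glucose-limited chemostat
#' growth. The growth-associated ATP coefficient, if configured, is applied
#' for `D` first.
#'
#' @param model an `ec_model` (or plain `stoich_model`).
#' @param D dilution (growth) rate in 1/h, `>= 0`.
#' @param glucose id of the glucose uptake reaction; default taken from the
#'   model's exchange annotation.
#' @param solver LP backend.
#' @return An `lp_result`; `objective` is `vGlcIN_min`. A `D` beyond the
#'   model's capability yields `status = "infeasible"`, not an error.
#' @export
min_glucose_at_growth <- function(model, D, glucose = NULL, solver = "internal") {
  stopifnot(D >= 0)
  glc <- .glucose_rxn(model, glucose)
  m <- apply_gam(model, D)
  m <- .set_rxn_bounds(m, .growth_rxn(m), lb = D, ub = D)
  solve_fba(m, .single_obj(m, glc), sense = "min", solver = solver)
}

# Deterministic resolution pipeline: optimize the primary single-reaction
# objective, then (for ec models) fix it and minimize the protein pool draw,
# then fix that too and minimize total flux. The last step removes both
# alternate-usage and futile-cycle degeneracy so repeated runs are
# bit-identical and regulated/unregulated runs are comparable flux-by-flux.
.resolve <- function(model, primary_rxn, sense = "min", solver = "internal") {
  s1 <- solve_fba(model, .single_obj(model, primary_rxn), sense = sense,
                  solver = solver)
  if (s1$status != "optimal") return(s1)
  best <- s1
  m <- .fix_rxn(model, primary_rxn, s1$objective)
  if (inherits(model, "ec_model")) {
    s2 <- solve_fba(m, .single_obj(m, .pool_rxn), sense = "min",
                    solver = solver)
    if (s2$status == "optimal") {
      m <- .fix_rxn(m, .pool_rxn, s2$objective)
      s2$objective <- s1$objective
      best <- s2
    }
  }
  all_obj <- stats::setNames(rep(1, nrow(m$reactions)), m$reactions$id)
  s3 <- solve_fba(m, all_obj, sense = "min", solver = solver)
  if (s3$status == "optimal") {
    s3$objective <- s1$objective
    best <- s3
  }
  best
}

.fix_rxn <- function(model, rxn, value, slack = 1e-9) {
  lo <- value - slack * max(1, abs(value))
  hi <- value + slack * max(1, abs(value))
  i <- match(rxn, model$reactions$id)
  .set_rxn_bounds(model, rxn, lb = max(lo, 0), ub = hi)
}

.context_model <- function(model, D, vGlc = NULL, glc_window = NULL,
                           glucose = NULL) {
  glc <- .glucose_rxn(model, glucose)
  m <- apply_gam(model, D)
  m <- .set_rxn_bounds(m, .growth_rxn(m), lb = D, ub = D)
  if (!is.null(vGlc)) m <- .set_rxn_bounds(m, glc, lb = vGlc, ub = vGlc)
  if (!is.null(glc_window)) {
    m <- .set_rxn_bounds(m, glc, lb = glc_window[1], ub = glc_window[2])
  }
  m
}

#' Parsimonious enzyme usages at a fixed (D, vGlc) context
#'
#' Fixes growth and glucose uptake, minimizes the total protein burden
#' (the pool draw, equal to `sum(Mw_j * e_j)`), and breaks remaining
#' degeneracy by a secondary total-flux minimization so that the returned
#' usage vector is unique and reproducible.
#'
#' @param model an `ec_model`.
#' @param D dilution rate (1/h).
#' @param vGlc glucose uptake rate (mmol/gDW/h), typically `vGlcIN_min`.
#' @param glucose,solver see [min_glucose_at_growth()].
#' @return Named numeric vector of enzyme usages `e_opt` (mmol/gDW/h); the
#'   full flux vector is attached as attribute `fluxes`.
#' @export
parsimonious_usages <- function(model, D, vGlc, glucose = NULL,
                                solver = "internal") {
  m <- .context_model(model, D, vGlc = vGlc, glucose = glucose)
  res <- .resolve(m, .pool_rxn, sense = "min", solver = solver)
  if (res$status != "optimal") {
    stop(sprintf(paste0("parsimonious context (D=%g, vGlc=%g) infeasible; ",
                        "re-derive vGlc with min_glucose_at_growth()"),
                 D, vGlc))
  }
  structure(res$usages, fluxes = res$fluxes)
}

#' Enzyme usage variability analysis
#'
#' With growth fixed to `D` and glucose uptake clamped to `vGlc`, runs
#' sequential minimization and maximization of every enzyme usage pseudo
#' reaction, yielding the feasible usage range per enzyme. Enzymes with
#' `e_max = 0` are unusable in the context; those with `e_min > 0` are
#' essential at that operating point.
#'
#' @inheritParams parsimonious_usages
#' @return data.frame with columns `enzyme_id`, `e_min`, `e_max`
#'   (mmol/gDW/h), of class `eva_range`; the `(D, vGlc)` context is recorded
#'   in attributes.
#' @export
enzyme_usage_variability <- function(model, D, vGlc, glucose = NULL,
                                     solver = "internal") {
  m <- .context_model(model, D, vGlc = vGlc, glucose = glucose)
  check <- solve_fba(m, .single_obj(m, .pool_rxn), sense = "min",
                     solver = solver)
  if (check$status != "optimal") {
    stop(sprintf("EVA context (D=%g, vGlc=%g) infeasible", D, vGlc))
  }
  enz <- names(m$usage_rxns)
  e_min <- e_max <- numeric(length(enz))
  for (k in seq_along(enz)) {
    rxn <- m$usage_rxns[[k]]
    lo <- solve_fba(m, .single_obj(m, rxn), sense = "min", solver = solver)
    hi <- solve_fba(m, .single_obj(m, rxn), sense = "max", solver = solver)
    if (lo$status != "optimal" || hi$status != "optimal") {
      stop(sprintf("EVA sub-problem for enzyme '%s' did not solve", enz[k]))
    }
    e_min[k] <- max(lo$objective, 0)
    e_max[k] <- max(hi$objective, e_min[k])
  }
  structure(data.frame(enzyme_id = enz, e_min = e_min, e_max = e_max,
                       stringsAsFactors = FALSE),
            class = c("eva_range", "data.frame"), D = D, vGlc = vGlc)
}

#' @export
print.lp_result <- function(x, ...) {
  cat(sprintf("lp_result: status=%s objective=%s\n", x$status,
              format(x$objective)))
  invisible(x)
}
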