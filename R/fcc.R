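# Flux control coefficients by finite perturbation of enzyme usages.
#
# FCC_ij = (a_i / v_j) dv_j/da_i with a_i = kcat_ij * e_i. In an
# enzyme-constrained model the usage pseudo reaction exposes e_i directly,
# so the coefficient is approximated as (e_i*/v_j*) * Dv_j / D(e_i - e_i*)
# with a perturbation of 0.1% of the parsimonious usage e_i*. When the
# applied bounds forbid the usage perturbation in both directions, the
# enzyme's turnover numbers are perturbed by the same relative amount
# instead (mode "kcat").

.perturb_kcat <- function(model, enzyme, factor) {
  met <- paste0(.prot_prefix, enzyme)
  for (rid in model$kcats$reaction_id[model$kcats$enzyme_id == enzyme]) {
    st <- model$stoich[[rid]]
    st[met] <- st[met] / factor  # coefficient is -1/kcat
    model$stoich[[rid]] <- st
  }
  model
}

#' Flux control coefficient of one enzyme over one flux
#'
#' The context (dilution rate, optionally regulated usage bounds and a
#' glucose uptake window) is solved for its parsimonious reference first;
#' the enzyme usage is then fixed at `e_i* * (1 + delta)` (or `1 - delta`
#' if the upper bound blocks the increase; or the kcat fallback if both
#' directions are blocked) and the glucose-minimizing FBA is re-run.
#'
#' @param model an `ec_model`, with regulated bounds already applied for
#'   hybrid contexts.
#' @param D dilution rate (1/h), fixed during the computation.
#' @param enzyme enzyme id.
#' @param target flux id whose control is measured; defaults to the glucose
#'   uptake reaction.
#' @param glc_window optional `c(lb, ub)` glucose uptake window (hybrid
#'   contexts); `NULL` leaves uptake free.
#' @param delta relative perturbation (default 0.001 = 0.1%).
#' @param solver LP backend.
#' @return data.frame (one row) with `enzyme_id`, `target`, `fcc`, and the
#'   perturbation `mode` (`"usage_up"`, `"usage_down"`, `"kcat"`,
#'   `"zero_usage"`, or `"undefined"` when the reference flux is zero).
#' @export
fcc_single <- function(model, D, enzyme, target = NULL, glc_window = NULL,
                       delta = 0.001, solver = "internal") {
  glc <- .glucose_rxn(model)
  if (is.null(target)) target <- glc
  ctx <- .context_model(model, D, glc_window = glc_window)
  ref <- .resolve(ctx, glc, sense = "min", solver = solver)
  if (ref$status != "optimal") stop(sprintf("FCC context at D=%g infeasible", D))
  .fcc_one(ctx, ref, enzyme, target, glc, delta, solver)
}

.fcc_one <- function(ctx, ref, enzyme, target, glc, delta, solver) {
  tolz <- .boolec_tol$zero_flux
  out <- function(fcc, mode) {
    data.frame(enzyme_id = enzyme, target = target, fcc = fcc, mode = mode,
               stringsAsFactors = FALSE)
  }
  v_ref <- unname(ref$fluxes[target])
  e_ref <- unname(ref$usages[enzyme])
  if (is.na(e_ref)) stop(sprintf("unknown enzyme '%s'", enzyme))
  if (abs(v_ref) < tolz) return(out(NA_real_, "undefined"))
  if (e_ref < tolz) return(out(0, "zero_usage"))
  rxn <- ctx$usage_rxns[[enzyme]]
  i <- match(rxn, ctx$reactions$id)
  lb <- ctx$reactions$lb[i]; ub <- ctx$reactions$ub[i]
  e_ref <- min(max(e_ref, lb), ub)
  feas <- .boolec_tol$feasibility
  up <- e_ref * (1 + delta); down <- e_ref * (1 - delta)
  if (up <= ub + feas && up >= lb - feas) {
    m <- .set_rxn_bounds(ctx, rxn, lb = up, ub = up)
    mode <- "usage_up"; dsign <- 1
  } else if (down >= lb - feas && down <= ub + feas) {
    m <- .set_rxn_bounds(ctx, rxn, lb = down, ub = down)
    mode <- "usage_down"; dsign <- -1
  } else {
    m <- .perturb_kcat(ctx, enzyme, 1 + delta)
    mode <- "kcat"; dsign <- 1
  }
  pert <- .resolve(m, glc, sense = "min", solver = solver)
  if (pert$status != "optimal") {
    # the perturbation is not feasible under the applied constraints;
    # fall back to perturbing the turnover numbers instead
    if (mode != "kcat") {
      m <- .perturb_kcat(ctx, enzyme, 1 + delta)
      mode <- "kcat"; dsign <- 1
      pert <- .resolve(m, glc, sense = "min", solver = solver)
    }
    if (pert$status != "optimal") return(out(NA_real_, "undefined"))
  }
  dv <- unname(pert$fluxes[target]) - v_ref
  fcc <- (dv / v_ref) / (dsign * delta)
  if (abs(fcc) < 1e-6) fcc <- 0
  out(fcc, mode)
}

#' Flux control coefficients of all enzymes over a target flux
#'
#' @inheritParams fcc_single
#' @return data.frame with one row per enzyme (`enzyme_id`, `target`,
#'   `fcc`, `mode`) plus `high_control`, flagging coefficients above 0.05.
#' @export
fcc_all <- function(model, D, target = NULL, glc_window = NULL,
                    delta = 0.001, solver = "internal") {
  glc <- .glucose_rxn(model)
  if (is.null(target)) target <- glc
  ctx <- .context_model(model, D, glc_window = glc_window)
  ref <- .resolve(ctx, glc, sense = "min", solver = solver)
  if (ref$status != "optimal") stop(sprintf("FCC context at D=%g infeasible", D))
  rows <- lapply(names(model$usage_rxns), function(ez) {
    .fcc_one(ctx, ref, ez, target, glc, delta, solver)
  })
  res <- do.call(rbind, rows)
  res$high_control <- !is.na(res$fcc) & res$fcc > 0.05
  res
}
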