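# The chemostat simulation loop coupling the enzyme-constrained and Boolean
# layers, plus deletion strains and model-vs-model flux comparison.
#
# Per dilution rate D the protocol is:
#   1. fix growth to D, minimize glucose uptake            -> vGlcIN_min
#   2. open the uptake window [vmin, (1+SF)*vmin]
#   3. discretize uptake against the threshold, run the Boolean layer to
#      steady state (chained from the previous condition)
#   4. project TF activities, derive per-gene net directions
#   5. parsimonious usages + usage variability at (D, vmin), apply the
#      regulated bounds
#   6. final glucose-minimizing FBA under the regulated bounds

#' Simulation configuration for the hybrid chemostat sweep
#'
#' @param d_grid ascending dilution-rate grid (1/h).
#' @param SF suboptimality factor: allowed relative excess of glucose uptake
#'   over the optimum (default 0.15 = 15%), giving regulation room to act.
#' @param RF regulation factor (fraction of the enzyme-usage variability
#'   range, default 0.05).
#' @param glc_threshold glucose uptake (mmol/gDW/h) separating the "low"
#'   from the "high" Boolean glucose input; `NULL` computes it as the uptake
#'   at the model's critical dilution rate.
#' @param nitrogen Boolean nitrogen input held fixed during the sweep.
#' @param crosstalk_flags,knockouts forwarded to the Boolean layer.
#' @param max_iter Boolean iteration cap per condition.
#' @param solver LP backend.
#' @return A `sim_config` list.
#' @export
sim_config <- function(d_grid = seq(0, 0.4, by = 0.005), SF = 0.15,
                       RF = 0.05, glc_threshold = NULL, nitrogen = 1,
                       crosstalk_flags = NULL, knockouts = character(),
                       max_iter = 100, solver = "internal") {
  stopifnot(SF >= 0, is.null(glc_threshold) || glc_threshold > 0,
            !is.unsorted(d_grid))
  structure(list(d_grid = d_grid, SF = SF, RF = RF,
                 glc_threshold = glc_threshold, nitrogen = nitrogen,
                 crosstalk_flags = crosstalk_flags, knockouts = knockouts,
                 max_iter = max_iter, solver = solver),
            class = "sim_config")
}

#' Discretize a glucose uptake rate against a threshold
#'
#' The boundary itself counts as "low" (strict `>`).
#'
#' @param vGlc glucose uptake rate, `>= 0`.
#' @param threshold threshold uptake rate, `> 0`.
#' @return `0L` (low) or `1L` (high).
#' @export
discretize_glucose <- function(vGlc, threshold) {
  stopifnot(all(vGlc >= 0), threshold > 0)
  as.integer(vGlc > threshold)
}

#' Locate the critical dilution rate of a model
#'
#' Finds the first grid point at which ethanol excretion becomes positive in
#' the glucose-minimizing solution (the respiro-fermentative switch), by
#' bisection over the grid.
#'
#' @param model an `ec_model` with an `ethanol` exchange annotation.
#' @param d_grid ascending dilution-rate grid.
#' @param solver LP backend.
#' @return List with `d_crit`, `vGlc` (uptake at the switch point) or
#'   `NA` values if the grid shows no switch.
#' @export
find_critical_d <- function(model, d_grid = seq(0, 0.4, by = 0.005),
                            solver = "internal") {
  etoh <- model$exchanges$ethanol
  if (is.null(etoh)) stop("model lacks an ethanol exchange annotation")
  glc <- .glucose_rxn(model)
  eth_at <- function(D) {
    m <- .context_model(model, D)
    res <- .resolve(m, glc, sense = "min", solver = solver)
    if (res$status != "optimal") return(NULL)
    list(eth = unname(res$fluxes[etoh]), vglc = unname(res$fluxes[glc]))
  }
  tol <- .boolec_tol$zero_flux
  # along D the model is respiratory, then fermenting, then infeasible;
  # bisect on the monotone indicator "fermenting or infeasible"
  beyond <- function(r) is.null(r) || r$eth > tol
  top <- eth_at(d_grid[length(d_grid)])
  if (!beyond(top)) return(list(d_crit = NA_real_, vGlc = NA_real_))
  first <- eth_at(d_grid[1])
  if (beyond(first)) {
    if (is.null(first)) return(list(d_crit = NA_real_, vGlc = NA_real_))
    return(list(d_crit = d_grid[1], vGlc = first$vglc))
  }
  lo <- 1L; hi <- length(d_grid)  # invariant: beyond(hi), !beyond(lo)
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (beyond(eth_at(d_grid[mid]))) hi <- mid else lo <- mid
  }
  r <- eth_at(d_grid[hi])
  if (is.null(r)) return(list(d_crit = NA_real_, vGlc = NA_real_))
  list(d_crit = d_grid[hi], vGlc = r$vglc)
}

.starved_state <- function(ruleset, cfg) {
  inputs <- stats::setNames(rep(0L, length(ruleset$inputs)), ruleset$inputs)
  res <- run_to_steady_state(ruleset, inputs,
                             crosstalk_flags = cfg$crosstalk_flags,
                             knockouts = cfg$knockouts,
                             max_iter = cfg$max_iter)
  if (is.null(res$steady_state)) stop("starved condition has no steady state")
  res$steady_state
}

#' Simulate a chemostat dilution-rate sweep with the hybrid model
#'
#' Runs the six-step protocol (see the package vignette) at every dilution
#' rate of the configuration grid. The Boolean state is chained: each D
#' starts from the previous D's steady state, the first from the all-starved
#' steady state.
#'
#' @param model a calibrated `ec_model` with exchange annotations
#'   (`glucose`, `oxygen`, `co2`, `ethanol`, `acetate`).
#' @param ruleset a `boolean_ruleset` whose activity projection provides the
#'   transcription-factor states.
#' @param net a [regnet()] wiring TFs to the model's genes.
#' @param cfg a [sim_config()].
#' @return A `sim_result`: list with `per_d` (all six stages' artifacts per
#'   dilution rate), `exchange_curves` (data.frame over the grid),
#'   `threshold`, and the configuration.
#' @export
simulate_dilution_sweep <- function(model, ruleset, net, cfg = sim_config()) {
  ex <- model$exchanges
  if (is.null(ex)) stop("model lacks exchange annotations")
  glc <- .glucose_rxn(model)
  threshold <- cfg$glc_threshold
  if (is.null(threshold)) {
    cr <- find_critical_d(model, solver = cfg$solver)
    if (is.na(cr$vGlc)) stop("cannot derive glucose threshold: no switch found")
    threshold <- cr$vGlc
  }
  bool_state <- .starved_state(ruleset, cfg)
  per_d <- vector("list", length(cfg$d_grid))
  curves <- list()
  tol <- .boolec_tol$zero_flux
  for (i in seq_along(cfg$d_grid)) {
    D <- cfg$d_grid[i]
    stage <- function(what, res) {
      if (inherits(res, "lp_result") && res$status != "optimal") {
        stop(sprintf("D=%g: stage '%s' %s", D, what, res$status))
      }
      res
    }
    s1 <- stage("min_glucose", min_glucose_at_growth(model, D,
                                                     solver = cfg$solver))
    vmin <- s1$objective
    window <- c(vmin, (1 + cfg$SF) * vmin)
    gbit <- discretize_glucose(vmin, threshold)
    inputs <- c(glucose = gbit, nitrogen = as.integer(cfg$nitrogen))
    brun <- run_to_steady_state(ruleset, inputs, initial = bool_state,
                                crosstalk_flags = cfg$crosstalk_flags,
                                knockouts = cfg$knockouts,
                                max_iter = cfg$max_iter)
    if (is.null(brun$steady_state)) {
      stop(sprintf("D=%g: stage 'boolean' reached a limit cycle", D))
    }
    bool_state <- brun$steady_state
    tf_act <- project_activity(bool_state, ruleset, inputs = inputs,
                               knockouts = cfg$knockouts)
    directions <- net_regulation(net, tf_act)
    e_opt <- parsimonious_usages(model, D, vmin, solver = cfg$solver)
    eva <- enzyme_usage_variability(model, D, vmin, solver = cfg$solver)
    regm <- regulate_guarded(model, directions, e_opt, eva, RF = cfg$RF,
                             D = D, glc_window = window, solver = cfg$solver)
    final_model <- .context_model(regm, D, glc_window = window)
    fin <- stage("final_fba", .resolve(final_model, glc, sense = "min",
                                       solver = cfg$solver))
    vfin <- unname(fin$fluxes[glc])
    if (vfin < vmin - tol || vfin > window[2] + tol) {
      stop(sprintf("D=%g: final uptake %.6g outside the SF window", D, vfin))
    }
    usage_rows <- match(model$usage_rxns, regm$reactions$id)
    per_d[[i]] <- list(
      D = D, vGlcIN_min = vmin, glucose_bit = gbit,
      boolean_steady_state = bool_state, tf_activity = tf_act,
      directions = directions,
      regulated_bounds = data.frame(
        enzyme_id = names(model$usage_rxns),
        lb = regm$reactions$lb[usage_rows],
        ub = regm$reactions$ub[usage_rows], stringsAsFactors = FALSE),
      e_opt = e_opt, eva = eva, fluxes = fin$fluxes, usages = fin$usages,
      net_fluxes = net_fluxes(fin$fluxes, model),
      regulated_model = regm, glc_window = window)
    curves[[i]] <- data.frame(
      D = D, glucose = vfin,
      oxygen = unname(fin$fluxes[ex$oxygen]),
      co2 = unname(fin$fluxes[ex$co2]),
      ethanol = unname(fin$fluxes[ex$ethanol]),
      acetate = unname(fin$fluxes[ex$acetate]))
  }
  structure(list(per_d = per_d, exchange_curves = do.call(rbind, curves),
                 threshold = threshold, config = cfg,
                 d_grid = cfg$d_grid),
            class = "sim_result")
}

#' Simulate a deletion strain
#'
#' Knockouts act in the Boolean layer only (presence forced to 0); the
#' downstream regulatory coupling is unchanged. Named strains follow the
#' usual deletions: `"TOR"` removes the TOR complex, `"SNF1"` the Snf1
#' kinase, `"PKA"` the catalytic PKA subunits, `"Reg1"` the Glc7 targeting
#' subunit.
#'
#' @inheritParams simulate_dilution_sweep
#' @param strain one of `"TOR"`, `"SNF1"`, `"PKA"`, `"Reg1"`, or a
#'   character vector of component ids.
#' @return A `sim_result` (see [simulate_dilution_sweep()]).
#' @export
simulate_knockout_strain <- function(model, ruleset, net, strain,
                                     cfg = sim_config()) {
  presets <- list(TOR = "TORC1", SNF1 = "Snf1", PKA = "PKA", Reg1 = "Reg1")
  comps <- if (length(strain) == 1 && strain %in% names(presets)) {
    presets[[strain]]
  } else strain
  unknown <- setdiff(comps, ruleset$components)
  if (length(unknown)) {
    stop(sprintf("unknown Boolean component(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  cfg$knockouts <- unique(c(cfg$knockouts, comps))
  simulate_dilution_sweep(model, ruleset, net, cfg)
}

#' Compare two simulated flux distributions
#'
#' @param a,b `sim_result`s from the same model over the same dilution grid
#'   (e.g. hybrid vs unregulated, or wild type vs knockout).
#' @param eps denominator floor for relative changes on near-zero reference
#'   fluxes.
#' @return List with `per_reaction` (data.frame: D, reaction, flux in both,
#'   relative change, activation status), `summary` per D (mean relative
#'   change over reactions carrying flux in either model, activation /
#'   deactivation counts), and `grand_mean`.
#' @export
compare_flux_distributions <- function(a, b, eps = 1e-6) {
  if (!identical(a$d_grid, b$d_grid)) stop("dilution grids differ")
  tol <- .boolec_tol$zero_flux
  rows <- list(); summ <- list()
  for (i in seq_along(a$d_grid)) {
    va <- a$per_d[[i]]$fluxes
    vb <- b$per_d[[i]]$fluxes
    if (!identical(sort(names(va)), sort(names(vb)))) {
      stop("reaction sets differ between the two results")
    }
    vb <- vb[names(va)]
    rel <- abs(va - vb) / pmax(abs(vb), eps)
    status <- rep("unchanged", length(va))
    status[abs(vb) < tol & abs(va) >= tol] <- "activated"
    status[abs(vb) >= tol & abs(va) < tol] <- "deactivated"
    keep <- abs(va) >= tol | abs(vb) >= tol
    rows[[i]] <- data.frame(D = a$d_grid[i], reaction = names(va),
                            flux_a = as.numeric(va), flux_b = as.numeric(vb),
                            rel_change = as.numeric(rel), status = status,
                            stringsAsFactors = FALSE, row.names = NULL)
    summ[[i]] <- data.frame(D = a$d_grid[i],
                            mean_rel_change = mean(rel[keep]),
                            n_activated = sum(status == "activated"),
                            n_deactivated = sum(status == "deactivated"))
  }
  per_reaction <- do.call(rbind, rows)
  summary <- do.call(rbind, summ)
  keep <- abs(per_reaction$flux_a) >= tol | abs(per_reaction$flux_b) >= tol
  list(per_reaction = per_reaction, summary = summary,
       grand_mean = mean(per_reaction$rel_change[keep]))
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("sim_result over %d dilution rates (threshold %.4g mmol/gDW/h)\n",
              length(x$d_grid), x$threshold))
  print(utils::head(x$exchange_curves))
  invisible(x)
}
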