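# Enzyme-constraint (GECKO-style) transformation of a stoichiometric model.
#
# Enzymes enter the model as pseudo-metabolites consumed by their catalyzed
# reactions with coefficient -1/kcat; per-enzyme usage ("draw") reactions
# supply them from a shared protein pool whose exchange capacity is
# f * sigma * P_tot (g protein per gDW). Reversible reactions are split into
# forward/backward irreversible pairs, and reactions with N isoenzyme arms
# are expanded into N parallel reactions (`_No1..NoN`, GECKO convention).

.pool_met <- "prot_pool"
.pool_rxn <- "prot_pool_exchange"
.prot_prefix <- "prot_"
.draw_prefix <- "draw_prot_"

#' Apply the enzyme-constraint transformation to a stoichiometric model
#'
#' @param model a `stoich_model`.
#' @param enzymes an [enzyme_table()] covering every enzyme-annotated
#'   reaction. A reaction whose rows all carry `NA` kcat is explicitly marked
#'   kcat-free and passes through unconstrained; a gene-annotated reaction
#'   with no entry at all is an error.
#' @param pool_params list with `P_tot` (total cellular protein, g/gDW),
#'   `f` (mass fraction of the proteome covered by the model) and `sigma`
#'   (average enzyme saturation); pool capacity is their product.
#' @return An object of class `ec_model` (also a `stoich_model`) with
#'   additional fields `enzymes`, `kcats`, `pool`, `mapping` (original
#'   reaction to split/arm reaction bookkeeping) and `usage_rxns`.
#' @export
gecko_transform <- function(model, enzymes,
                            pool_params = list(P_tot = 0.46, f = 0.1732,
                                               sigma = 0.48)) {
  stopifnot(inherits(model, "stoich_model"), inherits(enzymes, "enzyme_table"))
  if (any(unlist(pool_params) <= 0)) stop("pool parameters must be positive")
  et <- as.data.frame(enzymes)
  enz_info <- unique(et[, c("enzyme_id", "gene", "mw_g_per_mmol")])
  gene2enz <- stats::setNames(enz_info$enzyme_id, enz_info$gene)

  new_rxn <- list(); new_stoich <- list(); mapping <- list()
  kcat_rows <- list()
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    st <- model$stoich[[r$id]]
    arms <- parse_gene_rule(r$gene_rule)
    rxn_et <- et[et$reaction_id == r$id, , drop = FALSE]
    kcat_free <- FALSE
    if (length(arms)) {
      if (!nrow(rxn_et)) {
        stop(sprintf(paste0("reaction '%s' has a gene rule but no enzyme/kcat",
                            " entry; add a row with NA kcat to mark it",
                            " kcat-free"), r$id))
      }
      if (all(is.na(rxn_et$kcat_per_h))) kcat_free <- TRUE
    }
    directions <- if (r$reversible) c("fwd", "rev") else "fwd"
    n_arms <- if (length(arms) > 1 && !kcat_free) length(arms) else 1L
    for (dir in directions) {
      for (a in seq_len(n_arms)) {
        id <- r$id
        if (r$reversible) id <- paste0(id, "_", dir)
        if (n_arms > 1) id <- paste0(id, "_No", a)
        s <- if (dir == "fwd") st else -st
        ub <- if (dir == "fwd") r$ub else -r$lb
        arm_genes <- if (length(arms) && !kcat_free) {
          if (n_arms > 1) arms[[a]] else unique(unlist(arms))
        } else character()
        if (length(arms) && !kcat_free) {
          # complexes contribute every subunit of the arm
          if (n_arms > 1) arm_set <- arms[[a]] else arm_set <- arms[[1]]
          for (g in arm_set) {
            ez <- gene2enz[[g]]
            if (is.null(ez)) {
              stop(sprintf("gene '%s' (reaction '%s') has no enzyme entry",
                           g, r$id))
            }
            kc <- rxn_et$kcat_per_h[rxn_et$enzyme_id == ez]
            if (!length(kc) || is.na(kc[1])) {
              stop(sprintf("reaction '%s': enzyme '%s' lacks a kcat entry",
                           r$id, ez))
            }
            s[paste0(.prot_prefix, ez)] <- -1 / kc[1]
            kcat_rows[[length(kcat_rows) + 1]] <-
              data.frame(reaction_id = id, enzyme_id = ez, kcat_per_h = kc[1],
                         orig_reaction = r$id, stringsAsFactors = FALSE)
          }
        }
        new_rxn[[length(new_rxn) + 1]] <- data.frame(
          id = id, lb = 0, ub = ub, reversible = FALSE,
          gene_rule = if (length(arm_genes)) paste(arm_genes, collapse = " and ")
                      else r$gene_rule,
          subsystem = r$subsystem, stringsAsFactors = FALSE)
        new_stoich[[id]] <- s
        mapping[[length(mapping) + 1]] <- data.frame(
          orig_id = r$id, split_id = id, direction = dir, arm = a,
          stringsAsFactors = FALSE)
      }
    }
  }

  used_enz <- unique(unlist(lapply(new_stoich, function(s) {
    sub(paste0("^", .prot_prefix), "",
        grep(paste0("^", .prot_prefix), names(s), value = TRUE))
  })))
  enz_info <- enz_info[enz_info$enzyme_id %in% used_enz, , drop = FALSE]

  usage_rxns <- character()
  for (j in seq_len(nrow(enz_info))) {
    ez <- enz_info$enzyme_id[j]
    id <- paste0(.draw_prefix, ez)
    new_rxn[[length(new_rxn) + 1]] <- data.frame(
      id = id, lb = 0, ub = Inf, reversible = FALSE,
      gene_rule = enz_info$gene[j], subsystem = "enzyme_usage",
      stringsAsFactors = FALSE)
    s <- stats::setNames(c(-enz_info$mw_g_per_mmol[j], 1),
                         c(.pool_met, paste0(.prot_prefix, ez)))
    new_stoich[[id]] <- s
    usage_rxns[ez] <- id
  }
  cap <- pool_params$P_tot * pool_params$f * pool_params$sigma
  new_rxn[[length(new_rxn) + 1]] <- data.frame(
    id = .pool_rxn, lb = 0, ub = cap, reversible = FALSE, gene_rule = "",
    subsystem = "enzyme_usage", stringsAsFactors = FALSE)
  new_stoich[[.pool_rxn]] <- stats::setNames(1, .pool_met)

  mets <- rbind(model$metabolites,
                data.frame(id = c(paste0(.prot_prefix, enz_info$enzyme_id),
                                  .pool_met),
                           name = c(paste("enzyme", enz_info$enzyme_id),
                                    "protein pool"),
                           compartment = "enzyme", stringsAsFactors = FALSE))
  reactions <- do.call(rbind, new_rxn)
  mapdf <- do.call(rbind, mapping)
  objective <- model$objective
  # objective reactions keep their id unless split/expanded; remap to fwd arm 1
  for (rid in names(objective)) {
    if (!rid %in% reactions$id) {
      cand <- mapdf$split_id[mapdf$orig_id == rid & mapdf$direction == "fwd"]
      names(objective)[names(objective) == rid] <- cand[1]
    }
  }
  ec <- structure(list(
    metabolites = mets, reactions = reactions, stoich = new_stoich,
    genes = model$genes, objective = objective,
    enzymes = enz_info,
    kcats = if (length(kcat_rows)) do.call(rbind, kcat_rows) else
      data.frame(reaction_id = character(), enzyme_id = character(),
                 kcat_per_h = numeric(), orig_reaction = character()),
    pool = pool_params, mapping = mapdf, usage_rxns = usage_rxns,
    gam = NULL, exchanges = attr(model, "exchanges")),
    class = c("ec_model", "stoich_model"))
  validate_stoich_model(ec)
  ec
}

#' Total protein pool capacity of an enzyme-constrained model
#' @param model an `ec_model`.
#' @return `f * sigma * P_tot` in g/gDW.
#' @export
pool_capacity <- function(model) {
  with(model$pool, P_tot * f * sigma)
}

#' Set the average enzyme saturation factor
#'
#' Rescales the protein pool exchange capacity to `f * sigma * P_tot`.
#'
#' @param model an `ec_model`.
#' @param sigma new saturation factor in (0, 1].
#' @return The updated model.
#' @export
set_sigma <- function(model, sigma) {
  stopifnot(sigma > 0)
  model$pool$sigma <- sigma
  model$reactions$ub[model$reactions$id == .pool_rxn] <- pool_capacity(model)
  model
}

#' Make the growth-associated ATP requirement a function of growth rate
#'
#' The ATP coefficient of the biomass pseudo-reaction becomes piecewise
#' linear in the growth rate: within the respiratory regime it runs from
#' `respiratory_range[1]` at zero growth to `respiratory_range[2]` at the
#' critical dilution rate, then from `fermentative_range[1]` to
#' `fermentative_range[2]` up to `d_max`.
#'
#' @param model an `ec_model`.
#' @param respiratory_range,fermentative_range numeric `(lo, hi)` in
#'   mmol ATP/gDW.
#' @param d_crit critical dilution rate separating the regimes (1/h).
#' @param d_max upper end of the fermentative regime (1/h).
#' @param atp,adp metabolite ids for ATP and ADP in the biomass reaction.
#' @return The updated model; growth-rate-specific coefficients are applied
#'   by the solve routines via [apply_gam()].
#' @export
set_gam <- function(model, respiratory_range, fermentative_range,
                    d_crit, d_max = 0.4, atp = "atp_c", adp = "adp_c") {
  stopifnot(respiratory_range[1] <= respiratory_range[2],
            fermentative_range[1] <= fermentative_range[2])
  bio <- .growth_rxn(model)
  st <- model$stoich[[bio]]
  if (!atp %in% names(st) || st[atp] >= 0) {
    stop(sprintf("biomass reaction '%s' does not consume '%s'", bio, atp))
  }
  model$gam <- list(resp = as.numeric(respiratory_range),
                    ferm = as.numeric(fermentative_range),
                    d_crit = d_crit, d_max = d_max, atp = atp, adp = adp,
                    biomass_rxn = bio, base_stoich = st)
  model
}

#' Growth-associated ATP coefficient at a given growth rate
#' @param model an `ec_model` with a GAM configuration (see [set_gam()]).
#' @param D growth rate (1/h).
#' @return ATP requirement in mmol/gDW.
#' @export
gam_at <- function(model, D) {
  g <- model$gam
  if (is.null(g)) stop("model has no GAM configuration; call set_gam() first")
  lin <- function(range, x0, x1, x) {
    if (x1 <= x0) return(range[1])
    frac <- min(max((x - x0) / (x1 - x0), 0), 1)
    range[1] + frac * (range[2] - range[1])
  }
  if (D <= g$d_crit) lin(g$resp, 0, g$d_crit, D)
  else lin(g$ferm, g$d_crit, g$d_max, D)
}

#' Apply the growth-rate-dependent ATP coefficient to the biomass reaction
#' @param model an `ec_model`.
#' @param D growth rate (1/h).
#' @return Model with the biomass stoichiometry set for growth at `D`; a
#'   model without a GAM configuration is returned unchanged.
#' @export
apply_gam <- function(model, D) {
  g <- model$gam
  if (is.null(g)) return(model)
  st <- g$base_stoich
  gam <- gam_at(model, D)
  delta <- gam - (-st[[g$atp]])
  st[g$atp] <- st[g$atp] - delta
  if (g$adp %in% names(st)) st[g$adp] <- st[g$adp] + delta
  model$stoich[[g$biomass_rxn]] <- st
  model
}

.growth_rxn <- function(model) {
  if (length(model$objective) == 1) return(names(model$objective))
  bio <- grep("biomass|growth", model$reactions$id, ignore.case = TRUE,
              value = TRUE)
  if (length(bio) == 1) return(bio)
  stop("cannot identify a unique growth/biomass pseudo-reaction")
}

#' Net and futile fluxes per original reaction
#'
#' Folds a flux distribution over the split/arm-expanded reactions of an
#' enzyme-constrained model back onto the original reactions:
#' net = forward - backward (each summed over isoenzyme arms),
#' futile = min(forward, backward).
#'
#' @param solution named flux vector over `ec_model` reaction ids.
#' @param model the `ec_model`.
#' @return data.frame with columns `orig_id`, `net`, `futile`.
#' @export
net_fluxes <- function(solution, model) {
  mp <- model$mapping
  missing <- setdiff(mp$split_id, names(solution))
  if (length(missing)) {
    warning(sprintf("fluxes missing for %d reaction(s); treated as 0",
                    length(missing)))
    solution[missing] <- 0
  }
  orig <- unique(mp$orig_id)
  fwd <- vapply(orig, function(o) {
    sum(solution[mp$split_id[mp$orig_id == o & mp$direction == "fwd"]])
  }, numeric(1))
  bwd <- vapply(orig, function(o) {
    sum(solution[mp$split_id[mp$orig_id == o & mp$direction == "rev"]])
  }, numeric(1))
  data.frame(orig_id = orig, net = fwd - bwd, futile = pmin(fwd, bwd),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.ec_model <- function(x, ...) {
  cat(sprintf(paste0("ec_model: %d metabolites, %d reactions ",
                     "(%d enzyme usages), pool capacity %.4g g/gDW\n"),
              nrow(x$metabolites), nrow(x$reactions), length(x$usage_rxns),
              pool_capacity(x)))
  invisible(x)
}
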