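# Signed TF -> gene regulatory layer: maps Boolean transcription-factor
# activities to regulated enzyme-usage bounds on an enzyme-constrained model.

#' Construct / validate a signed regulatory network
#'
#' @param edges data.frame with columns `tf`, `target_gene`, `sign` (+1/-1)
#'   and optionally `source_note` (the `regnet.tsv` dialect; a YEASTRACT
#'   export reshaped to these columns is drop-in).
#' @return Object of class `regnet` (a data.frame).
#' @export
regnet <- function(edges) {
  need <- c("tf", "target_gene", "sign")
  miss <- setdiff(need, names(edges))
  if (length(miss)) stop(sprintf("regnet lacks column(s): %s",
                                 paste(miss, collapse = ", ")))
  if (!all(edges$sign %in% c(-1, 1))) stop("regnet signs must be +1 or -1")
  if (anyDuplicated(edges[, c("tf", "target_gene")])) {
    stop("duplicate (tf, target_gene) edge in regnet")
  }
  if (is.null(edges$source_note)) edges$source_note <- rep("", nrow(edges))
  structure(as.data.frame(edges), class = c("regnet", "data.frame"))
}

#' Read a regulatory network from TSV
#' @param path TSV file with columns `tf`, `target_gene`, `sign`,
#'   `source_note`.
#' @return A [regnet()].
#' @export
read_regnet <- function(path) {
  regnet(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Net regulatory direction per gene
#'
#' For each target gene, the signs of the edges whose transcription factor is
#' active are summed and the sign of the sum is taken, so two active
#' repressors and one active activator give `-1`, and an absolute sum above
#' one does not regulate more strongly. Inactive TFs contribute nothing;
#' active TFs not present in the network roster are ignored with a warning.
#'
#' @param net a [regnet()].
#' @param tf_activity named binary vector of transcription-factor activities
#'   (e.g. from [project_activity()]).
#' @return Named integer vector over the network's target genes with values
#'   in `{-1, 0, +1}`.
#' @export
net_regulation <- function(net, tf_activity) {
  active <- names(tf_activity)[tf_activity == 1]
  genes <- unique(net$target_gene)
  hit <- net[net$tf %in% active, , drop = FALSE]
  sums <- tapply(hit$sign, factor(hit$target_gene, levels = genes), sum,
                 default = 0)
  stats::setNames(as.integer(sign(sums)), genes)
}

#' Enzyme usage reactions affected by a gene
#'
#' Resolves a gene to the usage pseudo-reactions of the enzymes it encodes
#' (for a complex, only the subunit encoded by the gene).
#'
#' @param model an `ec_model`.
#' @param gene gene id.
#' @return Character vector of enzyme ids (possibly empty, with a warning
#'   for an unknown gene or a gene without enzyme usage reactions).
#' @export
gene_to_enzymes <- function(model, gene) {
  hits <- model$enzymes$enzyme_id[model$enzymes$gene == gene]
  if (!length(hits)) {
    warning(sprintf("gene '%s' maps to no enzyme usage reaction", gene))
  }
  hits
}

#' Apply regulated bounds with a joint-feasibility guard
#'
#' Per-enzyme clamping cannot guarantee joint feasibility: an adversarial
#' activity pattern may cap every isoform of an essential reaction at once
#' (individually each cap lies inside its variability range, yet their sum
#' cannot carry the required flux). This wrapper applies
#' [regulated_bounds()], checks the regulated LP context, and if it is
#' infeasible releases the downregulation caps (the upregulation floors are
#' kept) with a warning.
#'
#' @inheritParams regulated_bounds
#' @param D dilution rate of the context (1/h).
#' @param glc_window glucose uptake window `c(lb, ub)`.
#' @param glucose,solver see [min_glucose_at_growth()].
#' @return The regulated model; attribute `relaxed` records whether the
#'   guard had to release the downregulation caps.
#' @export
regulate_guarded <- function(model, directions, e_opt, eva, RF = 0.05,
                             D, glc_window, glucose = NULL,
                             solver = "internal") {
  regm <- regulated_bounds(model, directions, e_opt, eva, RF)
  glc <- .glucose_rxn(model, glucose)
  feasible <- function(m) {
    ctx <- .context_model(m, D, glc_window = glc_window, glucose = glucose)
    solve_fba(ctx, stats::setNames(1, glc), sense = "min",
              solver = solver)$status == "optimal"
  }
  relaxed <- FALSE
  if (!feasible(regm)) {
    down <- names(directions)[directions < 0]
    enz <- unique(unlist(lapply(down, function(g) {
      suppressWarnings(gene_to_enzymes(model, g))
    })))
    rxns <- model$usage_rxns[enz]
    i <- match(rxns, regm$reactions$id)
    j <- match(rxns, model$reactions$id)
    regm$reactions$ub[i] <- model$reactions$ub[j]
    relaxed <- TRUE
    warning(sprintf(paste0("regulated bounds jointly infeasible at D=%g; ",
                           "downregulation caps released"), D))
  }
  attr(regm, "relaxed") <- relaxed
  regm
}

#' Apply regulated enzyme-usage bounds
#'
#' For every enzyme whose gene is upregulated the usage lower bound is
#' raised to `e_opt + RF * (e_max - e_min)`; for a downregulated gene the
#' upper bound is lowered to `e_opt - RF * (e_max - e_min)`. Bounds are then
#' clamped so that `lb <= e_max`, `ub >= 0` and `lb <= ub` (EVA guarantees
#' feasibility only inside the variability range, so clamping preserves LP
#' feasibility); on a collision the lower bound wins. Genes with direction 0
#' leave bounds untouched. Applying the same regulation twice is a no-op.
#'
#' @param model an `ec_model`.
#' @param directions named integer vector over genes, values in `{-1,0,+1}`
#'   (see [net_regulation()]).
#' @param e_opt parsimonious usage vector from [parsimonious_usages()],
#'   computed in the same `(D, vGlc)` context as `eva`.
#' @param eva an `eva_range` from [enzyme_usage_variability()].
#' @param RF regulation factor in `[0, 1]`; default 0.05, i.e. bounds move
#'   by 5% of the usage variability range.
#' @return The model with updated usage-reaction bounds.
#' @export
regulated_bounds <- function(model, directions, e_opt, eva, RF = 0.05) {
  stopifnot(RF >= 0, RF <= 1)
  genes <- names(directions)[directions != 0]
  for (g in genes) {
    enz <- suppressWarnings(gene_to_enzymes(model, g))
    for (ez in enz) {
      row <- match(ez, eva$enzyme_id)
      if (is.na(row)) {
        stop(sprintf("enzyme '%s' (gene '%s') missing from the EVA ranges",
                     ez, g))
      }
      if (is.na(e_opt[ez])) {
        stop(sprintf("enzyme '%s' missing from the parsimonious usages", ez))
      }
      rng <- eva$e_max[row] - eva$e_min[row]
      rxn <- model$usage_rxns[[ez]]
      i <- match(rxn, model$reactions$id)
      if (directions[[g]] > 0) {
        lb <- min(max(e_opt[[ez]] + RF * rng, 0), eva$e_max[row])
        model$reactions$lb[i] <- lb
        if (model$reactions$ub[i] < lb) model$reactions$ub[i] <- lb
      } else {
        ub <- max(e_opt[[ez]] - RF * rng, 0)
        ub <- min(ub, model$reactions$ub[i])
        if (ub < model$reactions$lb[i]) {
          # conflicting up/down on one enzyme: the lower bound wins
          warning(sprintf("regulation conflict on enzyme '%s'; lb kept", ez))
          ub <- model$reactions$lb[i]
        }
        model$reactions$ub[i] <- ub
      }
    }
  }
  model
}
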