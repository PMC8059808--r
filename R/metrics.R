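# Model-evaluation statistics comparing predicted enzyme usages to
# proteomics tables: log-ratio error, permutation-tested Pearson
# correlation, two-sample KS test, isoenzyme presence confusion metrics,
# hypergeometric enrichment with Holm step-down correction, and the
# total-protein-approach rescaling of relative proteomics.

.paired_positive <- function(pred, meas) {
  shared <- intersect(names(pred), names(meas))
  if (!length(shared)) stop("no shared proteins between the two tables")
  p <- pred[shared]; m <- meas[shared]
  keep <- p > 0 & m > 0
  list(pred = p[keep], meas = m[keep], n = sum(keep), shared = length(shared))
}

#' Mean absolute log10 ratio between predicted and measured abundances
#'
#' Pairs with a zero on either side cannot enter a log ratio; they are
#' excluded here (and belong to the presence/absence confusion analysis
#' instead). The retained-pair count is attached so either accounting
#' convention can be audited.
#'
#' @param pred,meas named numeric vectors of abundances (mmol/gDW).
#' @return Mean of `|log10(pred/meas)|` over retained pairs, with
#'   attributes `n_retained` and `n_shared`.
#' @export
mean_abs_log10_ratio <- function(pred, meas) {
  pp <- .paired_positive(pred, meas)
  if (!pp$n) stop("no strictly positive pairs to compare")
  r <- mean(abs(log10(pp$pred / pp$meas)))
  structure(r, n_retained = pp$n, n_shared = pp$shared)
}

#' Pearson correlation with a permutation test
#'
#' Correlates log10 abundances and assesses significance by randomly
#' permuting one vector `n_perm` times; the p-value is the add-one-smoothed
#' fraction of permutations with `|r|` at least as large as observed.
#'
#' @inheritParams mean_abs_log10_ratio
#' @param n_perm number of permutations (default 2000).
#' @param seed RNG seed for the permutations.
#' @return List with `pcc`, `p_value`, `n`.
#' @export
pcc_with_permutation <- function(pred, meas, n_perm = 2000, seed = 1) {
  pp <- .paired_positive(pred, meas)
  if (pp$n < 3) stop("need at least 3 positive pairs")
  x <- log10(pp$pred); y <- log10(pp$meas)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(pcc = NA_real_, p_value = NA_real_, n = pp$n))
  }
  r <- stats::cor(x, y)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  hits <- sum(vapply(seq_len(n_perm), function(i) {
    abs(stats::cor(x, sample(y))) >= abs(r)
  }, logical(1)))
  list(pcc = r, p_value = (1 + hits) / (n_perm + 1), n = pp$n)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Two-sample Kolmogorov-Smirnov test on log10 abundances
#'
#' @inheritParams mean_abs_log10_ratio
#' @return List with the KS statistic `D` and asymptotic `p_value`.
#' @export
ks_two_sample <- function(pred, meas) {
  p <- pred[pred > 0]; m <- meas[meas > 0]
  if (!length(p) || !length(m)) stop("both samples must be non-empty")
  kt <- suppressWarnings(stats::ks.test(log10(p), log10(m)))
  list(D = unname(kt$statistic), p_value = kt$p.value)
}

#' Isoenzyme presence confusion metrics
#'
#' Restricted to reactions catalyzed by two or more isoforms, compares
#' predicted presence (usage above `tol`) with measured presence (abundance
#' above zero) and summarizes the confusion matrix with sensitivity,
#' specificity, precision, accuracy and the Fowlkes-Mallows index
#' (`sqrt(precision * sensitivity)`).
#'
#' @param model an `ec_model` (source of the isoform groupings).
#' @param usages named predicted enzyme usage vector (mmol/gDW/h).
#' @param measured named measured abundance vector; names are enzyme ids.
#' @param tol presence tolerance on usages (default 1e-9 mmol/gDW/h).
#' @return List of class `confusion_summary` with `TP`, `FP`, `TN`, `FN`,
#'   the derived rates, `fmi`, and the per-isoform table.
#' @export
isoenzyme_confusion <- function(model, usages, measured, tol = 1e-9) {
  kc <- model$kcats
  mp <- model$mapping
  # isoforms live on distinct arms; complex subunits share one arm
  multi <- unique(mp$orig_id[mp$arm > 1])
  groups <- lapply(multi, function(o) {
    arms <- mp$split_id[mp$orig_id == o]
    unique(kc$enzyme_id[kc$reaction_id %in% arms])
  })
  names(groups) <- multi
  if (!length(groups)) stop("no reactions with >= 2 isoforms in the model")
  rows <- do.call(rbind, lapply(names(groups), function(o) {
    data.frame(reaction = o, enzyme_id = groups[[o]], stringsAsFactors = FALSE)
  }))
  rows <- rows[rows$enzyme_id %in% names(measured), , drop = FALSE]
  if (!nrow(rows)) stop("no measured isoforms overlap the model")
  pred <- usages[rows$enzyme_id] > tol
  meas <- measured[rows$enzyme_id] > 0
  TP <- sum(pred & meas); FP <- sum(pred & !meas)
  TN <- sum(!pred & !meas); FN <- sum(!pred & meas)
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- safe(TP, TP + FP)
  sensitivity <- safe(TP, TP + FN)
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN,
                 sensitivity = sensitivity,
                 specificity = safe(TN, TN + FP),
                 precision = precision,
                 accuracy = (TP + TN) / length(pred),
                 fmi = sqrt(precision * sensitivity),
                 table = data.frame(rows, predicted = unname(pred),
                                    measured = unname(meas))),
            class = "confusion_summary")
}

#' Hypergeometric gene-set enrichment with Holm step-down correction
#'
#' Tests each gene set for over-representation in the foreground via the
#' hypergeometric upper tail and applies the Holm-Bonferroni step-down
#' procedure at level `alpha`.
#'
#' @param foreground character vector, subset of `background`.
#' @param background character vector (the gene universe).
#' @param gene_sets named list of character vectors over the background.
#' @param alpha family-wise error level (default 0.05).
#' @return data.frame with per-set overlap counts, raw and Holm-adjusted
#'   p-values, and the `enriched` decision.
#' @export
hypergeom_enrichment_holm <- function(foreground, background, gene_sets,
                                      alpha = 0.05) {
  if (!length(background)) stop("empty background")
  if (!all(foreground %in% background)) {
    stop("foreground must be a subset of the background")
  }
  N <- length(background); n <- length(foreground)
  p <- vapply(gene_sets, function(set) {
    set <- intersect(set, background)
    K <- length(set)
    k <- length(intersect(set, foreground))
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  }, numeric(1))
  adj <- stats::p.adjust(p, method = "holm")
  data.frame(set = names(gene_sets),
             size = vapply(gene_sets, function(s)
               length(intersect(s, background)), integer(1)),
             overlap = vapply(gene_sets, function(s)
               length(intersect(s, foreground)), integer(1)),
             p_value = p, p_holm = adj, enriched = adj <= alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Convert relative proteomics to absolute units (total protein approach)
#'
#' Relative abundances are rescaled to whole-cell mass fractions using
#' reference mass fractions (e.g. integrated PaxDB data), then converted to
#' mmol/gDW by dividing by the molecular weight and scaling with the total
#' cellular protein content.
#'
#' @param relative named relative abundances (arbitrary units).
#' @param reference_fractions named whole-cell mass fractions; proteins
#'   missing here are dropped with a warning. Their sum over the table is
#'   the proteome share the table represents.
#' @param mw named molecular weights (g/mmol).
#' @param P_tot total protein content (g/gDW, default 0.46).
#' @return Named numeric vector of abundances in mmol/gDW with attribute
#'   `provenance = "rescaled-relative"`.
#' @export
rescale_total_protein_approach <- function(relative, reference_fractions, mw,
                                           P_tot = 0.46) {
  keep <- names(relative)[names(relative) %in% names(reference_fractions) &
                            names(relative) %in% names(mw)]
  dropped <- setdiff(names(relative), keep)
  if (length(dropped)) {
    warning(sprintf("dropping %d protein(s) missing from the reference",
                    length(dropped)))
  }
  if (!length(keep)) stop("no protein of the table is in the reference")
  rel <- relative[keep]
  share <- sum(reference_fractions[keep])
  mass_frac <- rel / sum(rel) * share
  abund <- mass_frac * P_tot / mw[keep]
  structure(abund, provenance = "rescaled-relative")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf(paste0("confusion: TP=%d FP=%d TN=%d FN=%d | sens=%.3f ",
                     "spec=%.3f prec=%.3f acc=%.3f FMI=%.3f\n"),
              x$TP, x$FP, x$TN, x$FN, x$sensitivity, x$specificity,
              x$precision, x$accuracy, x$fmi))
  invisible(x)
}
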