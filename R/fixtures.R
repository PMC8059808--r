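# Synthetic assets: a miniature central-carbon network with two hexokinase
# isoforms, a two-subunit pyruvate dehydrogenase complex, a promiscuous
# aldehyde dehydrogenase, one reversible reaction and a kcat-free reaction;
# a toy regulatory network wired to the packaged signaling ruleset; and
# synthetic proteomics with log-normal noise. Plus the calibration routines
# (saturation factor, growth-associated ATP).

#' Fixture generation settings
#'
#' The defaults define the study conditions of every packaged simulation:
#' total protein `P_tot` 0.46 g/gDW, modeled proteome fraction `f` 0.1732,
#' average saturation `sigma` 0.48, a target critical dilution rate of
#' 0.285 1/h, and growth-associated ATP running 18-25 mmol/gDW across the
#' respiratory regime and 25-30 across the fermentative one.
#'
#' @param seed integer seed fixing all fixture randomness (proteomics noise).
#' @param preset network preset id (only `"central-carbon"`).
#' @param sigma,f,P_tot protein pool parameters.
#' @param target_dcrit critical dilution rate the calibration targets (1/h).
#' @param gam_resp,gam_ferm GAM ranges (mmol ATP/gDW).
#' @param noise_sigma log10-scale standard deviation of synthetic
#'   proteomics noise.
#' @param dropout fraction of proteins randomly zeroed in synthetic
#'   proteomics.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 7, preset = "central-carbon", sigma = 0.48,
                         f = 0.1732, P_tot = 0.46, target_dcrit = 0.285,
                         gam_resp = c(18, 25), gam_ferm = c(25, 30),
                         noise_sigma = 0.8, dropout = 0.1) {
  stopifnot(preset == "central-carbon", sigma > 0, f > 0, P_tot > 0)
  structure(list(seed = seed, preset = preset, sigma = sigma, f = f,
                 P_tot = P_tot, target_dcrit = target_dcrit,
                 gam_resp = gam_resp, gam_ferm = gam_ferm,
                 noise_sigma = noise_sigma, dropout = dropout),
            class = "fixture_spec")
}

#' Build the miniature central-carbon fixture model
#'
#' A ~20-reaction network spanning glucose uptake, a hexokinase step with a
#' slow (HXK1) and a fast (HXK2) isoform, lumped glycolysis, a lumped
#' NADPH-producing pentose phosphate shunt (gene-annotated but kcat-free),
#' the pyruvate branch point (fermentation via PDC/ADH, respiration via the
#' PDA1/PDB1 PDH complex, lumped TCA and separate internal/external
#' NADH dehydrogenases feeding oxidative phosphorylation, and an acetate
#' branch through the promiscuous Ald6 and Acs1), a free ATP-dissipation
#' reaction and a biomass pseudo-reaction carrying the growth-associated
#' ATP demand. Turnover numbers are set so that respiration is optimal at
#' low dilution rates while the protein pool forces fermentative overflow
#' at high ones.
#'
#' @param spec a [fixture_spec()].
#' @return List with `model` (a `stoich_model`) and `enzymes`
#'   (an [enzyme_table()]).
#' @export
make_fixture_ecmodel <- function(spec = fixture_spec()) {
  mets <- data.frame(
    id = c("glc_c", "g6p_c", "pyr_c", "acald_c", "etoh_c", "ac_c", "accoa_m",
           "nadh_c", "nad_c", "nadh_m", "nad_m", "nadph_c", "nadp_c",
           "atp_c", "adp_c", "o2_c", "co2_c", "glyc_c"),
    name = c("glucose", "glucose 6-phosphate", "pyruvate", "acetaldehyde",
             "ethanol", "acetate", "acetyl-CoA", "NADH", "NAD+",
             "NADH (mit)", "NAD+ (mit)", "NADPH", "NADP+", "ATP", "ADP",
             "oxygen", "carbon dioxide", "glycerol"),
    compartment = c(rep("c", 6), "m", "c", "c", "m", "m", "c", "c", "c",
                    "c", "c", "c", "c"),
    stringsAsFactors = FALSE)
  rx <- function(id, eq, lb = 0, ub = 1000, gene = "", subsystem = "") {
    data.frame(id = id, equation = eq, lb = lb, ub = ub, gene_rule = gene,
               subsystem = subsystem, stringsAsFactors = FALSE)
  }
  reactions <- rbind(
    rx("GLCin", "-> glc_c", subsystem = "exchange"),
    rx("HXK", "glc_c -> g6p_c", gene = "HXK1 or HXK2",
       subsystem = "glycolysis"),
    rx("GLYC", "g6p_c + 2 adp_c + 2 nad_c -> 2 pyr_c + 2 atp_c + 2 nadh_c",
       gene = "GLY1", subsystem = "glycolysis"),
    rx("PPP", "g6p_c + 2 nadp_c -> pyr_c + co2_c + 2 nadph_c",
       gene = "PPP1", subsystem = "pentose phosphate"),
    rx("PDC", "pyr_c -> acald_c + co2_c", gene = "PDC1",
       subsystem = "fermentation"),
    rx("ADH", "acald_c + nadh_c <-> etoh_c + nad_c", lb = -1000,
       gene = "ADH1", subsystem = "fermentation"),
    rx("ALD", "acald_c + nad_c -> ac_c + nadh_c", gene = "ALD6",
       subsystem = "acetate"),
    rx("ALDnadp", "acald_c + nadp_c -> ac_c + nadph_c", gene = "ALD6",
       subsystem = "acetate"),
    rx("ACS", "ac_c + atp_c -> accoa_m + adp_c", gene = "ACS1",
       subsystem = "acetate"),
    rx("PDH", "pyr_c + nad_m -> accoa_m + co2_c + nadh_m",
       gene = "PDA1 and PDB1", subsystem = "TCA"),
    rx("TCA", "accoa_m + 4 nad_m + adp_c -> 2 co2_c + 4 nadh_m + atp_c",
       gene = "TCA1", subsystem = "TCA"),
    rx("NDI", "nadh_m + 0.5 o2_c + 2 adp_c -> nad_m + 2 atp_c",
       gene = "NDI1", subsystem = "oxidative phosphorylation"),
    rx("NDE", "nadh_c + 0.5 o2_c + 2 adp_c -> nad_c + 2 atp_c",
       gene = "NDE1", subsystem = "oxidative phosphorylation"),
    rx("GPD", "g6p_c + 2 nadh_c -> 2 glyc_c + 2 nad_c", gene = "GPD1",
       subsystem = "glycerol"),
    rx("ATPM", "atp_c -> adp_c", subsystem = "maintenance"),
    rx("BIOMASS",
       paste("5 g6p_c + 8 pyr_c + 2.5 nadph_c + 23 atp_c ->",
             "23 adp_c + 2.5 nadp_c"),
       subsystem = "biomass"),
    rx("O2in", "-> o2_c", subsystem = "exchange"),
    rx("CO2out", "co2_c ->", subsystem = "exchange"),
    rx("ETOHout", "etoh_c ->", subsystem = "exchange"),
    rx("ACout", "ac_c ->", subsystem = "exchange"),
    rx("GLYCout", "glyc_c ->", subsystem = "exchange"))
  stoich <- list(); reversible <- logical(nrow(reactions))
  for (i in seq_len(nrow(reactions))) {
    p <- parse_equation(reactions$equation[i])
    stoich[[reactions$id[i]]] <- p$stoich
    reversible[i] <- p$reversible
  }
  rdf <- data.frame(id = reactions$id, lb = reactions$lb, ub = reactions$ub,
                    reversible = reversible, gene_rule = reactions$gene_rule,
                    subsystem = reactions$subsystem, stringsAsFactors = FALSE)
  genes <- c("HXK1", "HXK2", "GLY1", "PPP1", "PDC1", "ADH1", "ALD6", "ACS1",
             "PDA1", "PDB1", "TCA1", "NDI1", "NDE1", "GPD1")
  model <- stoich_model(mets, rdf, stoich, genes,
                        objective = c(BIOMASS = 1))
  attr(model, "exchanges") <- list(glucose = "GLCin", oxygen = "O2in",
                                   co2 = "CO2out", ethanol = "ETOHout",
                                   acetate = "ACout")
  en <- function(ez, gene, mw, rxn, kcat, complex = NA, arm = NA) {
    data.frame(enzyme_id = ez, gene = gene, mw_g_per_mmol = mw,
               reaction_id = rxn, kcat_per_h = kcat, complex_id = complex,
               arm_id = arm, stringsAsFactors = FALSE)
  }
  enzymes <- enzyme_table(rbind(
    en("E_HXK1", "HXK1", 54, "HXK", 2.0e4, arm = "No1"),
    en("E_HXK2", "HXK2", 54, "HXK", 1.2e5, arm = "No2"),
    en("E_GLY1", "GLY1", 450, "GLYC", 2.4e5),
    en("E_PPP1", "PPP1", 120, "PPP", NA),          # explicit kcat-free marker
    en("E_PDC1", "PDC1", 61, "PDC", 1.2e5),
    en("E_ADH1", "ADH1", 37, "ADH", 2.0e5),
    en("E_ALD6", "ALD6", 54, "ALD", 4.0e4),        # promiscuous: two reactions
    en("E_ALD6", "ALD6", 54, "ALDnadp", 4.0e4),
    en("E_ACS1", "ACS1", 79, "ACS", 3.0e4),
    en("E_PDA1", "PDA1", 100, "PDH", 3.6e4, complex = "cplx_PDH"),
    en("E_PDB1", "PDB1", 100, "PDH", 3.6e4, complex = "cplx_PDH"),
    en("E_TCA1", "TCA1", 600, "TCA", 2.0e4),
    en("E_NDI1", "NDI1", 57, "NDI", 5.5e3),
    en("E_NDE1", "NDE1", 63, "NDE", 5.5e3),
    en("E_GPD1", "GPD1", 43, "GPD", 1.0e5)))
  list(model = model, enzymes = enzymes)
}

#' Assemble the calibrated enzyme-constrained fixture model
#'
#' Applies [gecko_transform()] with the fixture's pool parameters and the
#' growth-rate-dependent ATP requirement ([set_gam()]) switching at the
#' spec's target critical dilution rate.
#'
#' @param spec a [fixture_spec()].
#' @return An `ec_model` ready for simulation.
#' @export
make_fixture_hybrid_model <- function(spec = fixture_spec()) {
  parts <- make_fixture_ecmodel(spec)
  ec <- gecko_transform(parts$model, parts$enzymes,
                        pool_params = list(P_tot = spec$P_tot, f = spec$f,
                                           sigma = spec$sigma))
  set_gam(ec, spec$gam_resp, spec$gam_ferm, d_crit = spec$target_dcrit,
          d_max = 0.4)
}

#' Boolean ruleset used by the fixture pipeline
#'
#' The packaged yeast nutrient-signaling ruleset doubles as the fixture
#' ruleset; its transcription factors are what the fixture regulatory
#' network wires to the fixture genes.
#'
#' @param spec a [fixture_spec()] (unused; kept for interface symmetry).
#' @return A `boolean_ruleset`.
#' @export
make_fixture_boolean <- function(spec = fixture_spec()) {
  yeast_ruleset()
}

#' Signed TF-to-gene regulatory network for the fixture
#'
#' Wired so that the low-glucose Boolean steady state (Snf1 pathway active)
#' upregulates the slow hexokinase isoform and the external NADH
#' dehydrogenase and acetate branch while repressing the fast isoform and
#' pyruvate decarboxylase, emulating glucose derepression; the high-glucose
#' state represses the oxidative/acetate genes instead.
#'
#' @param spec a [fixture_spec()].
#' @param model optional `ec_model`; if given, the gene roster is checked
#'   against the model's genes.
#' @return A [regnet()].
#' @export
make_fixture_regnet <- function(spec = fixture_spec(), model = NULL) {
  e <- function(tf, gene, sign, note = "") {
    data.frame(tf = tf, target_gene = gene, sign = sign, source_note = note,
               stringsAsFactors = FALSE)
  }
  net <- regnet(rbind(
    e("Cat8", "HXK1", +1, "derepression of the slow isoform"),
    e("Mig1", "HXK1", -1, "glucose repression"),
    e("Adr1", "HXK2", -1, "fast isoform repressed at low glucose"),
    e("Cat8", "ACS1", +1, "acetate utilization"),
    e("Sip4", "ACS1", +1, "acetate utilization"),
    e("Mig1", "ACS1", -1, "glucose repression"),
    e("Cat8", "NDE1", +1, "cytosolic NADH respiration"),
    e("Mig1", "NDE1", -1, "glucose repression"),
    e("Cat8", "PDC1", -1, "fermentation repressed at low glucose"),
    e("Adr1", "ADH1", +1, "ADH2-like derepression; induces futile cycling"),
    e("Sfp1", "GLY1", +1, "growth program"),
    e("Msn2", "PPP1", +1, "stress-induced PPP")))
  if (!is.null(model)) {
    unknown <- setdiff(unique(net$target_gene), model$genes)
    if (length(unknown)) {
      stop(sprintf("regnet targets unknown gene(s): %s",
                   paste(unknown, collapse = ", ")))
    }
  }
  net
}

#' Synthetic proteomics from predicted usages
#'
#' Multiplies the true usages by `10^N(0, sigma_noise)` and randomly zeroes
#' a `dropout` fraction (missed proteins), deterministically under `seed`.
#'
#' @param usages named numeric vector of enzyme usages (mmol/gDW/h).
#' @param sigma_noise log10-scale noise standard deviation.
#' @param seed integer seed.
#' @param dropout fraction of entries set to zero.
#' @return Named numeric vector with attribute `provenance = "absolute"`.
#' @export
synth_proteomics <- function(usages, sigma_noise = 0.8, seed = 7,
                             dropout = 0.1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  out <- usages * 10^stats::rnorm(length(usages), 0, sigma_noise)
  drop <- stats::runif(length(out)) < dropout
  out[drop] <- 0
  structure(out, provenance = "absolute")
}

#' Fit the average enzyme saturation factor to a target critical rate
#'
#' Bisection on `sigma`: the protein pool capacity scales with `sigma`, and
#' the simulated onset of ethanol excretion (located by bisection over the
#' dilution grid, resolution 0.005 1/h) increases monotonically with it.
#' Stops when the simulated onset matches `target_dcrit` within grid
#' resolution.
#'
#' @param model an `ec_model`.
#' @param target_dcrit target critical dilution rate (1/h).
#' @param d_grid dilution grid used to locate the onset.
#' @param sigma_bounds bracketing interval for the saturation factor.
#' @param solver LP backend.
#' @return The fitted `sigma`, with the calibrated model in attribute
#'   `model` and the achieved onset in attribute `d_crit`.
#' @export
calibrate_sigma <- function(model, target_dcrit,
                            d_grid = seq(0, 0.4, by = 0.005),
                            sigma_bounds = c(0.05, 1), solver = "internal") {
  step <- stats::median(diff(d_grid))
  dstar <- function(sig) {
    find_critical_d(set_sigma(model, sig), d_grid, solver = solver)$d_crit
  }
  lo <- sigma_bounds[1]; hi <- sigma_bounds[2]
  d_lo <- dstar(lo); d_hi <- dstar(hi)
  if (is.na(d_hi) || is.na(d_lo)) {
    # NA at the top means no switch below the grid end (pool never binds)
    if (is.na(d_lo)) stop(sprintf(
      "no switch found at sigma=%g: bracket [%g, %g] does not cover the target",
      lo, lo, hi))
  }
  if (!is.na(d_lo) && d_lo > target_dcrit + step / 2) {
    stop(sprintf("sigma=%g already switches at D=%g > target %g",
                 lo, d_lo, target_dcrit))
  }
  if (!is.na(d_hi) && d_hi < target_dcrit - step / 2) {
    stop(sprintf("even sigma=%g switches at D=%g < target %g",
                 hi, d_hi, target_dcrit))
  }
  best <- NA_real_; best_d <- NA_real_
  for (it in 1:40) {
    mid <- (lo + hi) / 2
    d_mid <- dstar(mid)
    if (!is.na(d_mid) && abs(d_mid - target_dcrit) <= step / 2) {
      best <- mid; best_d <- d_mid
      break
    }
    if (is.na(d_mid) || d_mid > target_dcrit) hi <- mid else lo <- mid
    if (hi - lo < 1e-5) break
  }
  if (is.na(best)) {
    mid <- (lo + hi) / 2
    d_mid <- dstar(mid)
    if (is.na(d_mid) || abs(d_mid - target_dcrit) > step + 1e-12) {
      stop(sprintf(paste0("sigma calibration failed: bracket collapsed to ",
                          "[%g, %g] with onset %s vs target %g"),
                   lo, hi, format(d_mid), target_dcrit))
    }
    best <- mid; best_d <- d_mid
  }
  structure(best, model = set_sigma(model, best), d_crit = best_d)
}

#' Fit the growth-associated ATP ranges to reference exchange fluxes
#'
#' Grid search over per-regime linear GAM parameters (range endpoints),
#' minimizing the median relative error of the predicted glucose, oxygen,
#' CO2 and ethanol exchange fluxes across the reference dilution rates.
#' The two regimes are fitted independently (each GAM value only affects
#' growth rates within its own regime).
#'
#' @param model an `ec_model` with a GAM configuration ([set_gam()]).
#' @param reference data.frame with columns `D`, `glucose`, `oxygen`,
#'   `co2`, `ethanol`.
#' @param candidates numeric vector of candidate range endpoints
#'   (mmol ATP/gDW).
#' @param solver LP backend.
#' @return List with `resp`, `ferm` (fitted `(lo, hi)` per regime),
#'   `median_rel_error`, and the refitted `model`.
#' @export
calibrate_gam <- function(model, reference, candidates = seq(16, 32, by = 2),
                          solver = "internal") {
  if (is.null(model$gam)) stop("model lacks a GAM configuration")
  need <- c("D", "glucose", "oxygen", "co2", "ethanol")
  miss <- setdiff(need, names(reference))
  if (length(miss)) stop(sprintf("reference lacks column(s): %s",
                                 paste(miss, collapse = ", ")))
  if (all(abs(as.matrix(reference[, need[-1]])) < .boolec_tol$zero_flux)) {
    stop("degenerate reference: all exchange fluxes are zero")
  }
  glc <- .glucose_rxn(model)
  ex <- model$exchanges
  d_crit <- model$gam$d_crit
  errs_for <- function(m, Ds) {
    unlist(lapply(Ds, function(D) {
      res <- .resolve(.context_model(m, D), glc, sense = "min",
                      solver = solver)
      if (res$status != "optimal") return(rep(Inf, 4))
      ref <- reference[reference$D == D, ]
      pred <- c(res$fluxes[glc], res$fluxes[ex$oxygen], res$fluxes[ex$co2],
                res$fluxes[ex$ethanol])
      refv <- as.numeric(ref[1, c("glucose", "oxygen", "co2", "ethanol")])
      keep <- abs(refv) > .boolec_tol$zero_flux
      abs(pred[keep] - refv[keep]) / abs(refv[keep])
    }))
  }
  fit_regime <- function(regime) {
    Ds <- if (regime == "resp") reference$D[reference$D <= d_crit]
          else reference$D[reference$D > d_crit]
    if (!length(Ds)) return(list(range = model$gam[[regime]], errs = numeric()))
    best <- NULL; best_err <- Inf
    for (lo in candidates) for (hi in candidates[candidates >= lo]) {
      m <- model
      m$gam[[regime]] <- c(lo, hi)
      e <- errs_for(m, Ds)
      med <- stats::median(e)
      if (med < best_err) {
        best_err <- med; best <- c(lo, hi)
      }
    }
    m <- model; m$gam[[regime]] <- best
    list(range = best, errs = errs_for(m, Ds))
  }
  rr <- fit_regime("resp")
  fr <- fit_regime("ferm")
  out <- model
  out$gam$resp <- rr$range
  out$gam$ferm <- fr$range
  list(resp = rr$range, ferm = fr$range,
       median_rel_error = stats::median(c(rr$errs, fr$errs)),
       model = out)
}
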