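# Shared fixtures: built once per test run and memoized, because the
# sigma calibration costs a few seconds.

.fx_cache <- new.env(parent = emptyenv())

fx_pipeline <- function() {
  if (is.null(.fx_cache$pipe)) {
    spec <- fixture_spec()
    ec <- make_fixture_hybrid_model(spec)
    sig <- calibrate_sigma(ec, spec$target_dcrit)
    model <- attr(sig, "model")
    .fx_cache$pipe <- list(
      spec = spec, model = model, sigma = as.numeric(sig),
      d_crit = attr(sig, "d_crit"),
      ruleset = make_fixture_boolean(spec),
      net = make_fixture_regnet(spec, model),
      threshold = find_critical_d(model)$vGlc)
  }
  .fx_cache$pipe
}

fx_hybrid_at <- function(D) {
  key <- paste0("hyb_", paste(D, collapse = "_"))
  if (is.null(.fx_cache[[key]])) {
    p <- fx_pipeline()
    res <- suppressWarnings(simulate_dilution_sweep(
      p$model, p$ruleset, p$net,
      sim_config(d_grid = D, glc_threshold = p$threshold)))
    .fx_cache[[key]] <- res
  }
  .fx_cache[[key]]
}

# A linear three-reaction chain: uptake (<= cap) -> conversion -> export,
# with an optional enzyme on the conversion step.
chain_model <- function(cap = 10, with_enzyme = FALSE) {
  mets <- data.frame(id = c("a", "b"), name = c("a", "b"),
                     compartment = "c", stringsAsFactors = FALSE)
  rxn <- data.frame(id = c("UP", "CONV", "EX"),
                    lb = 0, ub = c(cap, 1000, 1000), reversible = FALSE,
                    gene_rule = c("", if (with_enzyme) "G1" else "", ""),
                    subsystem = "", stringsAsFactors = FALSE)
  stoich <- list(UP = c(a = 1), CONV = c(a = -1, b = 1), EX = c(b = -1))
  stoich_model(mets, rxn, stoich,
               genes = if (with_enzyme) "G1" else character(),
               objective = c(EX = 1))
}

chain_ec <- function(cap = 10, kcat = 1, mw = 1, pool = 1000) {
  m <- chain_model(cap, with_enzyme = TRUE)
  et <- enzyme_table(data.frame(
    enzyme_id = "E1", gene = "G1", mw_g_per_mmol = mw, reaction_id = "CONV",
    kcat_per_h = kcat, stringsAsFactors = FALSE))
  gecko_transform(m, et, pool_params = list(P_tot = pool, f = 1, sigma = 1))
}

# Toy model with two reactions each carrying two isoforms, for confusion
# metrics over more than one isoenzyme group.
two_isoform_model <- function() {
  mets <- data.frame(id = c("a", "b", "c"), name = c("a", "b", "c"),
                     compartment = "c", stringsAsFactors = FALSE)
  rxn <- data.frame(id = c("UP", "R1", "R2", "EX"),
                    lb = 0, ub = 1000, reversible = FALSE,
                    gene_rule = c("", "G1 or G2", "G3 or G4", ""),
                    subsystem = "", stringsAsFactors = FALSE)
  stoich <- list(UP = c(a = 1), R1 = c(a = -1, b = 1), R2 = c(b = -1, c = 1),
                 EX = c(c = -1))
  m <- stoich_model(mets, rxn, stoich, genes = paste0("G", 1:4),
                    objective = c(EX = 1))
  et <- enzyme_table(data.frame(
    enzyme_id = paste0("E", 1:4), gene = paste0("G", 1:4),
    mw_g_per_mmol = 1, reaction_id = c("R1", "R1", "R2", "R2"),
    kcat_per_h = c(10, 20, 10, 20), stringsAsFactors = FALSE))
  gecko_transform(m, et, pool_params = list(P_tot = 1, f = 1, sigma = 1))
}

toy_oscillator <- function() {
  parse_ruleset(list(
    name = "osc", inputs = list(),
    components = list(
      list(id = "A", class = "metabolite",
           fields = list(value = list(default = 1,
                                      rule = list(`if` = "!B.value",
                                                  then = 1, `else` = 0)))),
      list(id = "B", class = "metabolite",
           fields = list(value = list(default = 0,
                                      rule = list(`if` = "A.value",
                                                  then = 1, `else` = 0)))))))
}
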