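# FBA, glucose minimization, parsimonious usage, and usage variability.

test_that("a single bottleneck sets the FBA optimum", {
  m <- chain_model(cap = 10)
  r <- solve_fba(m)
  expect_equal(r$status, "optimal")
  expect_equal(r$objective, 10, tolerance = 1e-9)
})

test_that("an enzyme capacity bound binds before the uptake bound", {
  # conversion enzyme with kcat 1 and usage capped at 2 limits export to 2,
  # the hand-solved optimum of this LP
  ec <- chain_ec(cap = 10, kcat = 1)
  ec <- .set_rxn_bounds(ec, "draw_prot_E1", ub = 2)
  r <- solve_fba(ec)
  expect_equal(r$objective, 2, tolerance = 1e-9)
  expect_equal(unname(r$usages["E1"]), 2, tolerance = 1e-9)
})

test_that("contradictory bounds give an infeasible status, not an error", {
  m <- chain_model()
  m$reactions$lb[m$reactions$id == "EX"] <- 5
  m$reactions$ub[m$reactions$id == "EX"] <- 5
  m$reactions$ub[m$reactions$id == "UP"] <- 1
  r <- solve_fba(m)
  expect_equal(r$status, "infeasible")
})

test_that("all three solver backends agree where they apply", {
  p <- fx_pipeline()
  a <- min_glucose_at_growth(p$model, 0.1, solver = "internal")
  b <- min_glucose_at_growth(p$model, 0.1, solver = "boot")
  expect_equal(a$objective, b$objective, tolerance = 1e-7)
  # pracma on a small well-behaved problem
  ec <- chain_ec(cap = 10, kcat = 2)
  r1 <- solve_fba(ec, solver = "internal")
  r2 <- solve_fba(ec, solver = "pracma")
  expect_equal(r1$objective, r2$objective, tolerance = 1e-7)
})

test_that("min_glucose_at_growth handles the edges of the feasible range", {
  p <- fx_pipeline()
  r0 <- min_glucose_at_growth(p$model, 0)
  expect_equal(r0$objective, 0, tolerance = 1e-9)   # no maintenance demand
  rx <- min_glucose_at_growth(p$model, 5)
  expect_equal(rx$status, "infeasible")
})

test_that("minimal glucose uptake is monotone in the pool capacity", {
  p <- fx_pipeline()
  vals <- vapply(c(0.3, 0.5, 0.8), function(s) {
    min_glucose_at_growth(set_sigma(p$model, s), 0.32)$objective
  }, numeric(1))
  expect_true(all(diff(vals) <= 1e-9))  # relaxing the pool never hurts
})

test_that("parsimonious usage picks the strictly dominant isoform", {
  p <- fx_pipeline()
  vmin <- min_glucose_at_growth(p$model, 0.1)$objective
  e <- parsimonious_usages(p$model, 0.1, vmin)
  expect_equal(unname(e["E_HXK1"]), 0)          # slow isoform unused
  expect_gt(unname(e["E_HXK2"]), 0)
  # total protein mass agrees with an independent solver's optimum
  ctx <- .context_model(p$model, 0.1, vGlc = vmin)
  cross <- solve_fba(ctx, stats::setNames(1, "prot_pool_exchange"),
                     sense = "min", solver = "boot")
  mass <- sum(p$model$enzymes$mw_g_per_mmol[
    match(names(e), p$model$enzymes$enzyme_id)] * e)
  expect_equal(mass, cross$objective, tolerance = 1e-7)
})

test_that("parsimonious context errors direct the caller to re-derive vGlc", {
  p <- fx_pipeline()
  expect_error(parsimonious_usages(p$model, 0.2, 0.01), "re-derive vGlc")
})

test_that("usage variability brackets essential, redundant and unusable enzymes", {
  p <- fx_pipeline()
  vmin <- min_glucose_at_growth(p$model, 0.1)$objective
  eva <- enzyme_usage_variability(p$model, 0.1, vmin)
  g <- function(ez, col) eva[eva$enzyme_id == ez, col]
  expect_true(all(eva$e_min >= 0))
  expect_true(all(eva$e_min <= eva$e_max + 1e-12))
  # the lumped glycolysis enzyme sits on the only route to biomass
  expect_gt(g("E_GLY1", "e_min"), 0)
  # either hexokinase isoform suffices: both optional, both usable
  expect_equal(g("E_HXK1", "e_min"), 0)
  expect_equal(g("E_HXK2", "e_min"), 0)
  expect_gt(g("E_HXK1", "e_max"), 0)
  expect_gt(g("E_HXK2", "e_max"), 0)
  # the PDH complex is not usable at this operating point
  expect_lt(g("E_PDA1", "e_max"), 1e-9)
})

test_that("EVA ranges agree with per-enzyme optimization by a second solver", {
  p <- fx_pipeline()
  vmin <- min_glucose_at_growth(p$model, 0.2)$objective
  a <- enzyme_usage_variability(p$model, 0.2, vmin, solver = "internal")
  ctx <- .context_model(p$model, 0.2, vGlc = vmin)
  compared <- 0
  for (k in seq_len(nrow(a))) {
    rxn <- p$model$usage_rxns[[a$enzyme_id[k]]]
    lo <- solve_fba(ctx, stats::setNames(1, rxn), "min", solver = "boot")
    hi <- solve_fba(ctx, stats::setNames(1, rxn), "max", solver = "boot")
    if (lo$status == "optimal" && hi$status == "optimal") {
      compared <- compared + 1
      expect_equal(max(lo$objective, 0), a$e_min[k], tolerance = 1e-6,
                   info = a$enzyme_id[k])
      expect_equal(hi$objective, a$e_max[k], tolerance = 1e-6,
                   info = a$enzyme_id[k])
    }
  }
  expect_gte(compared, 8)  # the cross-solver must handle most sub-problems
})

test_that("EVA sandwich: e_min <= e_opt <= e_max in every context", {
  p <- fx_pipeline()
  for (D in c(0.05, 0.15, 0.3)) {
    vmin <- min_glucose_at_growth(p$model, D)$objective
    e <- parsimonious_usages(p$model, D, vmin)
    eva <- enzyme_usage_variability(p$model, D, vmin)
    e <- e[eva$enzyme_id]
    expect_true(all(eva$e_min - 1e-7 <= e), info = paste("D =", D))
    expect_true(all(e <= eva$e_max + 1e-7), info = paste("D =", D))
  }
})

test_that("rescaling kcats and pool together leaves fluxes unchanged", {
  spec <- fixture_spec()
  parts <- make_fixture_ecmodel(spec)
  base <- gecko_transform(parts$model, parts$enzymes,
                          pool_params = list(P_tot = spec$P_tot, f = spec$f,
                                             sigma = spec$sigma))
  et2 <- as.data.frame(parts$enzymes)
  et2$kcat_per_h <- et2$kcat_per_h * 3
  scaled <- gecko_transform(parts$model, enzyme_table(et2),
                            pool_params = list(P_tot = spec$P_tot,
                                               f = spec$f,
                                               sigma = spec$sigma / 3))
  for (D in c(0.1, 0.3)) {
    r1 <- min_glucose_at_growth(base, D)
    r2 <- min_glucose_at_growth(scaled, D)
    expect_equal(r1$objective, r2$objective, tolerance = 1e-6)
    # usages scale inversely with the kcat factor
    e1 <- parsimonious_usages(base, D, r1$objective)
    e2 <- parsimonious_usages(scaled, D, r2$objective)
    expect_equal(unname(e1["E_HXK2"]) / 3, unname(e2["E_HXK2"]),
                 tolerance = 1e-6)
  }
})
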