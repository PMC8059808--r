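# Enzyme-constraint transformation, pool bookkeeping, GAM, net fluxes.

test_that("an enzyme-free reversible reaction splits without enzyme species", {
  mets <- data.frame(id = c("a", "b"), name = c("a", "b"), compartment = "c")
  rxn <- data.frame(id = c("UP", "R", "EX"), lb = c(0, -5, 0),
                    ub = c(10, 10, 10), reversible = c(FALSE, TRUE, FALSE),
                    gene_rule = "", subsystem = "")
  m <- stoich_model(mets, rxn,
                    list(UP = c(a = 1), R = c(a = -1, b = 1), EX = c(b = -1)),
                    objective = c(EX = 1))
  et <- enzyme_table(data.frame(enzyme_id = character(), gene = character(),
                                mw_g_per_mmol = numeric(),
                                reaction_id = character(),
                                kcat_per_h = numeric()))
  ec <- gecko_transform(m, et)
  expect_setequal(ec$reactions$id,
                  c("UP", "R_fwd", "R_rev", "EX", "prot_pool_exchange"))
  expect_equal(ec$reactions$ub[ec$reactions$id == "R_rev"], 5)
  expect_equal(ec$stoich$R_rev, c(a = 1, b = -1))
  expect_equal(length(ec$usage_rxns), 0)
  expect_true(all(ec$reactions$lb >= 0))
})

test_that("fixture transformation matches the hand-enumerated reaction count", {
  parts <- make_fixture_ecmodel()
  ec <- gecko_transform(parts$model, parts$enzymes)
  # hand enumeration: 21 original reactions, +1 for the reversible ADH split,
  # +1 for the second hexokinase arm, +13 enzyme usage reactions (the
  # annotated PPP enzyme is kcat-free and adds none), +1 pool exchange
  expect_equal(nrow(ec$reactions), 21 + 1 + 1 + 13 + 1)
  expect_equal(length(ec$usage_rxns), 13)
  # arm naming follows the GECKO convention
  expect_true(all(c("HXK_No1", "HXK_No2", "ADH_fwd", "ADH_rev") %in%
                    ec$reactions$id))
  # the complex contributes both subunits to the same reaction
  expect_equal(unname(ec$stoich$PDH[c("prot_E_PDA1", "prot_E_PDB1")]),
               rep(-1 / 3.6e4, 2))
  # promiscuous enzyme appears in two reactions
  expect_true(all(c("prot_E_ALD6") %in% names(ec$stoich$ALD)))
  expect_true(all(c("prot_E_ALD6") %in% names(ec$stoich$ALDnadp)))
  # kcat-free reaction passes through unconstrained
  expect_false(any(grepl("^prot_", names(ec$stoich$PPP))))
})

test_that("pool capacity is exactly P_tot * f * sigma", {
  parts <- make_fixture_ecmodel()
  ec <- gecko_transform(parts$model, parts$enzymes,
                        pool_params = list(P_tot = 0.46, f = 0.1732,
                                           sigma = 0.48))
  expect_identical(pool_capacity(ec), 0.46 * 0.1732 * 0.48)
  expect_equal(ec$reactions$ub[ec$reactions$id == "prot_pool_exchange"],
               0.03824256, tolerance = 1e-12)
})

test_that("a gene-annotated reaction without any enzyme entry errors by name", {
  m <- chain_model(with_enzyme = TRUE)
  et <- enzyme_table(data.frame(enzyme_id = character(), gene = character(),
                                mw_g_per_mmol = numeric(),
                                reaction_id = character(),
                                kcat_per_h = numeric()))
  expect_error(gecko_transform(m, et), "CONV")
})

test_that("GECKO round-trip: relaxed ec model reproduces the original optimum", {
  parts <- make_fixture_ecmodel()
  m <- .set_rxn_bounds(parts$model, "GLCin", ub = 10)
  orig <- solve_fba(m)
  et <- as.data.frame(parts$enzymes)
  et$kcat_per_h <- et$kcat_per_h * 1e9   # enzymes essentially free
  ec <- gecko_transform(.set_rxn_bounds(parts$model, "GLCin", ub = 10),
                        enzyme_table(et))
  ec$reactions$ub[ec$reactions$id == "prot_pool_exchange"] <- 1e6
  relax <- solve_fba(ec)
  expect_equal(relax$objective, orig$objective, tolerance = 1e-6)
})

test_that("GAM follows the two-regime linear map of growth rate", {
  ec <- make_fixture_hybrid_model()
  # respiratory regime runs 18 -> 25 between 0 and the critical rate
  expect_equal(gam_at(ec, 0), 18)
  expect_equal(gam_at(ec, 0.285 / 2), (18 + 25) / 2)
  expect_equal(gam_at(ec, 0.285), 25)
  # fermentative regime runs 25 -> 30 up to 0.4
  expect_equal(gam_at(ec, 0.4), 30)
  expect_equal(gam_at(ec, (0.285 + 0.4) / 2), 27.5)
  # degenerate range: constant coefficient
  ec2 <- set_gam(ec, c(20, 20), c(20, 20), d_crit = 0.285)
  expect_equal(gam_at(ec2, 0.1), 20)
  expect_equal(gam_at(ec2, 0.39), 20)
  # the biomass stoichiometry actually moves
  m <- apply_gam(ec, 0.285)
  expect_equal(unname(m$stoich$BIOMASS["atp_c"]), -25)
  expect_equal(unname(m$stoich$BIOMASS["adp_c"]), 25)
})

test_that("set_gam refuses a biomass reaction without ATP", {
  ec <- make_fixture_hybrid_model()
  st <- ec$gam$base_stoich
  ec$gam <- NULL
  ec$stoich$BIOMASS <- st[!names(st) %in% c("atp_c", "adp_c")]
  expect_error(set_gam(ec, c(18, 25), c(25, 30), d_crit = 0.285),
               "does not consume")
})

test_that("net and futile fluxes fold split reactions back together", {
  ec <- make_fixture_hybrid_model()
  v <- stats::setNames(numeric(nrow(ec$reactions)), ec$reactions$id)
  v["ADH_fwd"] <- 5; v["ADH_rev"] <- 2
  v["GLYC"] <- 4
  v["HXK_No1"] <- 1.5; v["HXK_No2"] <- 0.5
  nf <- net_fluxes(v, ec)
  row <- function(id) nf[nf$orig_id == id, ]
  expect_equal(row("ADH")$net, 3)       # forward 5, backward 2
  expect_equal(row("ADH")$futile, 2)
  expect_equal(row("GLYC")$net, 4)      # irreversible: futile 0
  expect_equal(row("GLYC")$futile, 0)
  expect_equal(row("HXK")$net, 2)       # arms sum: 1.5 + 0.5
  expect_equal(row("HXK")$futile, 0)
  # missing entries are warned about and treated as zero
  expect_warning(nf2 <- net_fluxes(v[1:10], ec), "treated as 0")
  expect_true(all(is.finite(nf2$net)))
})

test_that("net fluxes of any feasible solution conserve the original mass balance", {
  p <- fx_pipeline()
  parts <- make_fixture_ecmodel()
  for (D in c(0.1, 0.35)) {
    # original-model balance with the same growth-dependent ATP coefficient
    orig <- parts$model
    orig$stoich$BIOMASS <- apply_gam(p$model, D)$stoich$BIOMASS
    S <- fba_matrices(orig)$S
    res <- min_glucose_at_growth(p$model, D)
    nf <- net_fluxes(res$fluxes, p$model)
    v <- stats::setNames(nf$net, nf$orig_id)[colnames(S)]
    expect_lt(max(abs(S %*% v)), 1e-6)
  }
})

test_that("pool accounting holds for every returned solution", {
  p <- fx_pipeline()
  for (D in c(0.05, 0.2, 0.38)) {
    res <- min_glucose_at_growth(p$model, D)
    mass <- sum(p$model$enzymes$mw_g_per_mmol *
                  res$usages[p$model$enzymes$enzyme_id])
    expect_lte(mass, pool_capacity(p$model) + 1e-9)
  }
})
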