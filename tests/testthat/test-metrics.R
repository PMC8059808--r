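# Evaluation statistics against proteomics tables.

test_that("the mean absolute log10 ratio behaves like a log-scale distance", {
  x <- c(a = 1e-4, b = 2e-5, c = 3e-6)
  expect_equal(as.numeric(mean_abs_log10_ratio(x, x)), 0)
  expect_equal(as.numeric(mean_abs_log10_ratio(c(a = 1e-4), c(a = 1e-5))), 1)
  # symmetry under swapping prediction and measurement
  y <- c(a = 5e-5, b = 1e-4, c = 1e-6)
  expect_equal(as.numeric(mean_abs_log10_ratio(x, y)),
               as.numeric(mean_abs_log10_ratio(y, x)))
  # zero pairs are excluded and the retained count is reported
  y2 <- c(a = 5e-5, b = 0, c = 1e-6)
  r <- mean_abs_log10_ratio(x, y2)
  expect_equal(attr(r, "n_retained"), 2)
  expect_error(mean_abs_log10_ratio(c(q = 1), c(z = 1)), "no shared")
})

test_that("synthetic noise at sigma = 1 recovers the folded-normal mean", {
  set.seed(11)
  usages <- stats::setNames(10^stats::runif(4000, -6, -3),
                            paste0("p", 1:4000))
  prot <- synth_proteomics(usages, sigma_noise = 1, seed = 99, dropout = 0)
  r <- mean_abs_log10_ratio(usages, prot)
  # E|N(0,1)| = sqrt(2/pi) = 0.79788
  expect_equal(as.numeric(r), sqrt(2 / pi), tolerance = 0.05)
})

test_that("permutation-tested correlation hits its analytic corners", {
  x <- stats::setNames(10^seq(-6, -3, length.out = 10), paste0("p", 1:10))
  perfect <- pcc_with_permutation(x, x * 2, n_perm = 199, seed = 1)
  expect_equal(perfect$pcc, 1)
  expect_equal(perfect$p_value, 1 / 200)
  anti <- pcc_with_permutation(x, rev(unname(x)) * stats::setNames(
    rep(1, 10), names(x)), n_perm = 199, seed = 1)
  expect_equal(anti$pcc, -1, tolerance = 1e-12)
  expect_error(pcc_with_permutation(x[1:2], x[1:2]), "at least 3")
})

test_that("permutation p-values are seed-reproducible and null-calibrated", {
  x <- stats::setNames(10^stats::rnorm(12, -4, 1), paste0("p", 1:12))
  y <- stats::setNames(10^stats::rnorm(12, -4, 1), paste0("p", 1:12))
  a <- pcc_with_permutation(x, y, n_perm = 299, seed = 7)
  b <- pcc_with_permutation(x, y, n_perm = 299, seed = 7)
  expect_identical(a$p_value, b$p_value)
  # under independence the p-value is (discretely) uniform
  set.seed(123)
  ps <- replicate(120, {
    x <- stats::setNames(10^stats::rnorm(12, -4, 1), paste0("p", 1:12))
    y <- stats::setNames(10^stats::rnorm(12, -4, 1), paste0("p", 1:12))
    pcc_with_permutation(x, y, n_perm = 199,
                         seed = sample.int(1e6, 1))$p_value
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("the two-sample KS statistic matches a direct ecdf computation", {
  a <- stats::setNames(c(1e-5, 2e-5, 3e-5, 8e-5), paste0("a", 1:4))
  b <- stats::setNames(c(2.5e-5, 6e-5, 9e-5), paste0("b", 1:3))
  res <- ks_two_sample(a, b)
  # independent route: max |ECDF difference| over the pooled sample
  xs <- log10(c(a, b))
  Dhand <- max(abs(stats::ecdf(log10(a))(xs) - stats::ecdf(log10(b))(xs)))
  expect_equal(res$D, Dhand, tolerance = 1e-12)
  expect_equal(ks_two_sample(a, a)$D, 0)
  disjoint <- stats::setNames(c(1, 2, 3) * 1e-2, paste0("c", 1:3))
  expect_equal(ks_two_sample(a, disjoint)$D, 1)
})

test_that("isoenzyme confusion summaries follow the hand arithmetic", {
  m <- two_isoform_model()
  # perfect agreement
  u <- c(E1 = 1e-4, E2 = 0, E3 = 2e-4, E4 = 0)
  meas <- c(E1 = 1, E2 = 0, E3 = 1, E4 = 0)
  cs <- isoenzyme_confusion(m, u, meas)
  expect_equal(cs$fmi, 1)
  expect_equal(cs$accuracy, 1)
  # TP=2, FP=1, FN=1: precision 2/3, sensitivity 2/3, FMI 2/3
  u2 <- c(E1 = 1e-4, E2 = 1e-4, E3 = 1e-4, E4 = 0)
  m2 <- c(E1 = 1, E2 = 0, E3 = 1, E4 = 1)
  cs2 <- isoenzyme_confusion(m2_model <- m, u2, m2)
  expect_equal(cs2$TP, 2); expect_equal(cs2$FP, 1); expect_equal(cs2$FN, 1)
  expect_equal(cs2$precision, 2 / 3)
  expect_equal(cs2$sensitivity, 2 / 3)
  expect_equal(cs2$fmi, 2 / 3)
  # all-absent predictions against some-present truth
  cs3 <- isoenzyme_confusion(m, u2 * 0, m2)
  expect_equal(cs3$sensitivity, 0)
  # no multi-isoform reactions is an error
  expect_error(isoenzyme_confusion(chain_ec(), c(E1 = 1), c(E1 = 1)),
               "no reactions with")
})

test_that("FMI^2 equals precision times sensitivity for random summaries", {
  m <- two_isoform_model()
  set.seed(5)
  for (k in 1:20) {
    u <- stats::setNames(stats::runif(4) * (stats::runif(4) > 0.4), paste0("E", 1:4))
    meas <- stats::setNames(as.numeric(stats::runif(4) > 0.5), paste0("E", 1:4))
    cs <- isoenzyme_confusion(m, u, meas)
    if (!is.na(cs$fmi)) {
      expect_equal(cs$fmi^2, cs$precision * cs$sensitivity, tolerance = 1e-12)
    }
  }
})

test_that("hypergeometric enrichment matches the closed-form tail", {
  bg <- paste0("g", 1:20)
  sets <- list(hit = paste0("g", 1:5), other = paste0("g", 6:15))
  fg <- paste0("g", 1:5)
  res <- hypergeom_enrichment_holm(fg, bg, sets)
  # closed form: P(X >= 5), X ~ Hypergeom(N=20, K=5, n=5)
  expect_equal(res$p_value[res$set == "hit"],
               stats::dhyper(5, 5, 15, 5), tolerance = 1e-12)
  expect_true(res$enriched[res$set == "hit"])
  # a single gene set: Holm equals the raw test
  one <- hypergeom_enrichment_holm(fg, bg, sets["hit"])
  expect_equal(one$p_holm, one$p_value)
  expect_error(hypergeom_enrichment_holm(fg, character(), sets), "empty")
  expect_error(hypergeom_enrichment_holm(c(fg, "zz"), bg, sets), "subset")
})

test_that("Holm correction controls the family-wise error under the null", {
  bg <- paste0("g", 1:40)
  sets <- lapply(1:8, function(i) sample(bg, 10))
  names(sets) <- paste0("s", 1:8)
  set.seed(99)
  fwe <- mean(replicate(400, {
    fg <- sample(bg, 8)
    any(hypergeom_enrichment_holm(fg, bg, sets, alpha = 0.05)$enriched)
  }))
  expect_lte(fwe, 0.07)
})

test_that("the total protein approach rescales to absolute units", {
  # a single protein covering its whole reference: P_tot / Mw
  out <- rescale_total_protein_approach(c(p1 = 7), c(p1 = 1), c(p1 = 50),
                                        P_tot = 0.46)
  expect_equal(unname(out["p1"]), 0.46 / 50)
  # equal mass fractions with a 2:1 Mw ratio give a 1:2 molar ratio
  out2 <- rescale_total_protein_approach(c(p1 = 3, p2 = 3),
                                         c(p1 = 0.5, p2 = 0.5),
                                         c(p1 = 100, p2 = 50))
  expect_equal(unname(out2["p2"] / out2["p1"]), 2)
  expect_warning(
    rescale_total_protein_approach(c(p1 = 1, px = 1), c(p1 = 1),
                                   c(p1 = 10, px = 10)),
    "dropping")
  expect_error(
    suppressWarnings(
      rescale_total_protein_approach(c(px = 1), c(p1 = 1), c(p1 = 10))),
    "no protein")
})
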