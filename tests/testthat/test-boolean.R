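# Boolean engine: parsing, synchronous updates, steady states, knockouts,
# crosstalk toggles, and the packaged yeast signaling ruleset.

test_that("a two-node toy ruleset parses with the right census", {
  rs <- toy_oscillator()
  expect_s3_class(rs, "boolean_ruleset")
  expect_equal(length(rs$components), 2)
  expect_equal(unname(rs$classes), rep("metabolite", 2))
})

test_that("schema violations are rejected at parse time", {
  bad_ref <- list(name = "x", inputs = list(),
                  components = list(
                    list(id = "A", class = "metabolite",
                         fields = list(value = list(
                           default = 0,
                           rule = list(`if` = "Z.value", then = 1,
                                       `else` = 0))))))
  expect_error(parse_ruleset(bad_ref), "undeclared name.*Z.value")
  no_else <- list(name = "x", inputs = list(),
                  components = list(
                    list(id = "A", class = "metabolite",
                         fields = list(value = list(
                           default = 0,
                           rule = list(`if` = "A.value", then = 1))))))
  expect_error(parse_ruleset(no_else), "if/then/else")
  dup <- list(name = "x", inputs = list(),
              components = list(
                list(id = "A", class = "metabolite",
                     fields = list(value = list(default = 0))),
                list(id = "A", class = "metabolite",
                     fields = list(value = list(default = 0)))))
  expect_error(parse_ruleset(dup), "duplicate component")
  no_act <- list(name = "x", inputs = list(),
                 components = list(
                   list(id = "P", class = "protein",
                        fields = list(present = list(default = 1)))))
  expect_error(parse_ruleset(no_act), "activity")
})

test_that("a fixed point returns itself and a cycle is reported first-class", {
  rs <- toy_oscillator()
  # hand iteration: (1,0) -> (1,1) -> (0,1) -> (0,0) -> (1,0): period 4
  st <- c(A.value = 1L, B.value = 0L)
  s1 <- synchronous_step(st, rs, inputs = integer())
  expect_equal(unname(s1), c(1L, 1L))
  s2 <- synchronous_step(s1, rs, inputs = integer())
  expect_equal(unname(s2), c(0L, 1L))
  run <- run_to_steady_state(rs, inputs = integer(), initial = st)
  expect_null(run$steady_state)
  expect_equal(run$cycle$period, 4)
})

test_that("a constant network converges immediately and is step-sound", {
  rs <- parse_ruleset(list(
    name = "const", inputs = list("glucose"),
    components = list(list(id = "A", class = "metabolite",
                           fields = list(value = list(
                             default = 0,
                             rule = list(`if` = "glucose", then = 1,
                                         `else` = 0)))))))
  run <- run_to_steady_state(rs, c(glucose = 1))
  expect_equal(run$iterations, 2)  # one change, one confirmation
  ss <- run$steady_state
  expect_identical(synchronous_step(ss, rs, c(glucose = 1)), ss)
})

test_that("knockouts force presence to zero regardless of rules", {
  rs <- yeast_ruleset()
  run <- run_to_steady_state(rs, c(glucose = 0, nitrogen = 1),
                             knockouts = "Snf1")
  expect_equal(unname(run$steady_state["Snf1.present"]), 0L)
  act <- project_activity(run$steady_state, rs,
                          inputs = c(glucose = 0, nitrogen = 1),
                          knockouts = "Snf1")
  expect_equal(unname(act["Snf1"]), 0L)
  expect_error(run_to_steady_state(rs, c(glucose = 0, nitrogen = 1),
                                   knockouts = "NotAComponent"),
               "unknown knockout")
})

test_that("the yeast ruleset reproduces the glucose-rich steady state", {
  rs <- yeast_ruleset()
  chain <- steady_state_chain(rs, data.frame(glucose = c(0, 1),
                                             nitrogen = c(0, 1)))
  act <- project_activity(chain[[2]]$steady_state, rs,
                          inputs = c(glucose = 1, nitrogen = 1))
  # glucose represses the gluconeogenic program: Mig1 active, Adr1/Cat8/Sip4 off
  expect_equal(unname(act[c("Mig1", "PKA", "TORC1", "Sfp1")]), rep(1L, 4))
  expect_equal(unname(act[c("Cat8", "Sip4", "Adr1", "Snf1", "Msn2")]),
               rep(0L, 5))
})

test_that("glucose depletion activates Adr1 two iterations after Snf1", {
  rs <- yeast_ruleset()
  chain <- steady_state_chain(rs, data.frame(glucose = c(0, 1),
                                             nitrogen = c(0, 1)))
  rich <- chain[[2]]$steady_state
  run <- run_to_steady_state(rs, c(glucose = 0, nitrogen = 1),
                             initial = rich)
  inputs <- c(glucose = 0, nitrogen = 1)
  acts <- t(apply(run$trajectory, 1, project_activity, rules = rs,
                  inputs = inputs))
  snf1_on <- unname(which(acts[, "Snf1"] == 1)[1])
  adr1_on <- unname(which(acts[, "Adr1"] == 1)[1])
  expect_equal(adr1_on - snf1_on, 2)
  ss <- project_activity(run$steady_state, rs, inputs = inputs)
  expect_equal(unname(ss[c("Snf1", "Cat8", "Sip4", "Adr1", "Msn2", "Gis1")]),
               rep(1L, 6))
  expect_equal(unname(ss[c("Mig1", "PKA", "TORC1", "genes_ribosomal")]),
               rep(0L, 4))
})

test_that("on glucose addition the PKA crosstalk turns Adr1 off before Snf1", {
  rs <- yeast_ruleset()
  starved <- steady_state_chain(rs, data.frame(glucose = 0, nitrogen = 1))
  run <- run_to_steady_state(rs, c(glucose = 1, nitrogen = 1),
                             initial = starved[[1]]$steady_state)
  acts <- t(apply(run$trajectory, 1, project_activity, rules = rs,
                  inputs = c(glucose = 1, nitrogen = 1)))
  adr1_off <- which(acts[, "Adr1"] == 0)[1]
  snf1_off <- which(acts[, "Snf1"] == 0)[1]
  expect_lt(adr1_off, snf1_off)
})

test_that("pathway knockouts reproduce the published steady-state shifts", {
  rs <- yeast_ruleset()
  ss_act <- function(glc, nit, kos = character()) {
    run <- run_to_steady_state(rs, c(glucose = glc, nitrogen = nit),
                               knockouts = kos)
    project_activity(run$steady_state, rs,
                     inputs = c(glucose = glc, nitrogen = nit),
                     knockouts = kos)
  }
  # Snf1 deletion in starvation: downstream pattern as if glucose were present
  a <- ss_act(0, 0, "Snf1")
  expect_equal(unname(a[c("Mig1")]), 1L)
  expect_equal(unname(a[c("Cat8", "Sip4", "Adr1")]), rep(0L, 3))
  # ... with PP2A activation turning on the NCR/RTG programs
  expect_equal(unname(a[c("PP2A", "Rtg1", "Gln3", "genes_NCR", "genes_RTG")]),
               rep(1L, 5))
  # adenylate cyclase is relieved but PKA stays off (Krh inhibition)
  expect_equal(unname(a["AC"]), 1L)
  expect_equal(unname(a["PKA"]), 0L)
  # TOR deletion only touches the TORC1 branch
  wt <- ss_act(1, 1)
  tor <- ss_act(1, 1, "TORC1")
  changed <- names(wt)[wt != tor]
  torc1_branch <- c("TORC1", "Sch9", "Sfp1", "PP2A", "Rtg1", "Rtg3", "Gat2",
                    "Gln3", "genes_ribosomal", "genes_NCR", "genes_RTG")
  expect_true(all(changed %in% torc1_branch))
  # Reg1 deletion under high glucose de-represses SNF1 targets except Adr1
  reg1 <- ss_act(1, 1, "Reg1")
  expect_equal(unname(reg1[c("Snf1", "Cat8", "Sip4")]), rep(1L, 3))
  expect_equal(unname(reg1["Adr1"]), unname(wt["Adr1"]))
  # PKA deletion additionally activates Adr1
  pka <- ss_act(1, 1, "PKA")
  expect_equal(unname(pka[c("Snf1", "Cat8", "Adr1", "Msn2")]), rep(1L, 4))
})

test_that("trajectories are bit-deterministic and crosstalk ablation is safe", {
  rs <- yeast_ruleset()
  inputs <- c(glucose = 0, nitrogen = 1)
  r1 <- run_to_steady_state(rs, inputs)
  r2 <- run_to_steady_state(rs, inputs)
  expect_identical(r1$trajectory, r2$trajectory)
  flags <- stats::setNames(rep(FALSE, length(rs$crosstalks)), rs$crosstalks)
  expect_no_error(run_to_steady_state(rs, inputs, crosstalk_flags = flags,
                                      max_iter = 200))
})

test_that("projection translates phosphorylation into activity correctly", {
  rs <- yeast_ruleset()
  st <- initial_state(rs)
  # a present but inhibitory-phosphorylated protein is inactive
  st["Mig1.present"] <- 1L; st["Mig1.state"] <- 1L
  act <- project_activity(st, rs, inputs = c(glucose = 1, nitrogen = 1))
  expect_equal(unname(act["Mig1"]), 0L)
  # a metabolite's activity equals its single field
  st["cAMP.value"] <- 1L
  act <- project_activity(st, rs, inputs = c(glucose = 1, nitrogen = 1))
  expect_equal(unname(act["cAMP"]), 1L)
})
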