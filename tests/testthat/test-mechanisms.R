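# Decomposition arithmetic, contrast coding, invariance properties and
# recovery of configured truth.

test_that("hand-computed 2x2 example decomposes as expected", {
  m <- c(anc0 = 10, anc1 = 8, desc0 = 12, desc1 = 12)
  comp <- decompose_cells(m)
  expect_equal(comp$plasticity, -2)
  expect_equal(comp$genetic_evolution, 2)
  expect_equal(comp$evolution_of_plasticity, 2)
})

test_that("equal cell means give zero components and NA contributions", {
  r <- generate_experiment(noiseless_config())$records
  res <- decompose_transition(r, historical_transitions()[[1]],
                              "fecundity", test = FALSE)
  expect_equal(unname(res$components), c(0, 0, 0))
  expect_true(all(is.na(res$relative_contribution)))
})

test_that("reconstruction identity holds on random cell-mean tables", {
  set.seed(55)
  for (i in 1:200) {
    m <- setNames(rnorm(4, 10, 5), c("anc0", "anc1", "desc0", "desc1"))
    comp <- decompose_cells(m)
    expect_equal(m[["desc1"]],
                 m[["anc0"]] + comp$plasticity + comp$genetic_evolution +
                   comp$evolution_of_plasticity,
                 tolerance = 1e-12)
  }
})

test_that("double 0/1 coding swap: GxE invariant; components flip up to the GxE term", {
  # relabelling both factors maps (anc0,anc1,desc0,desc1) ->
  # (desc1,desc0,anc1,anc0); algebra gives gxe' = gxe,
  # plasticity' = -(plasticity + gxe), genetic' = -(genetic + gxe), so the
  # plain sign flip of plasticity and genetic holds exactly when gxe = 0.
  set.seed(56)
  for (i in 1:50) {
    m <- setNames(rnorm(4, 0, 3), c("anc0", "anc1", "desc0", "desc1"))
    swapped <- c(anc0 = m[["desc1"]], anc1 = m[["desc0"]],
                 desc0 = m[["anc1"]], desc1 = m[["anc0"]])
    a <- decompose_cells(m)
    b <- decompose_cells(swapped)
    expect_equal(b$evolution_of_plasticity, a$evolution_of_plasticity,
                 tolerance = 1e-12)
    expect_equal(b$plasticity,
                 -(a$plasticity + a$evolution_of_plasticity),
                 tolerance = 1e-12)
    expect_equal(b$genetic_evolution,
                 -(a$genetic_evolution + a$evolution_of_plasticity),
                 tolerance = 1e-12)
  }
  # zero-GxE sub-case: the plain sign flip
  m <- c(anc0 = 1, anc1 = 4, desc0 = 2, desc1 = 5)  # gxe = 0
  a <- decompose_cells(m)
  b <- decompose_cells(c(anc0 = 5, anc1 = 2, desc0 = 4, desc1 = 1))
  expect_equal(b$plasticity, -a$plasticity)
  expect_equal(b$genetic_evolution, -a$genetic_evolution)
})

test_that("relative contributions are scale invariant and sum to 100", {
  r <- generate_experiment(small_config(seed = 4))$records
  res <- decompose_transition(r, historical_transitions()[[1]],
                              "size_mm", test = FALSE)
  r2 <- r
  r2$size_mm <- r2$size_mm * 37.5
  res2 <- decompose_transition(r2, historical_transitions()[[1]],
                               "size_mm", test = FALSE)
  expect_equal(res$relative_contribution, res2$relative_contribution,
               tolerance = 1e-9)
  expect_equal(sum(res$relative_contribution), 100, tolerance = 1e-9)
})

test_that("cell means weight genotypes equally under replication imbalance", {
  r <- manual_records()
  # G01 low arm gets extra replicates with extreme values
  extra <- r[r$genotype == "G01" & r$algae_level == "low", ][c(1, 1), ]
  extra$replicate <- 2:3
  extra$fecundity <- 100
  rr <- rbind(r, extra)
  sp <- transition_spec("EP", "EP2", "CTRL", "LA")
  # build a second population so all four cells exist
  r2 <- rr
  r2$population <- "EP2"
  both <- rbind(rr, r2)
  cells <- multistress:::.transition_cells(both, sp, "fecundity")
  # genotype means first: G01 low = (5+100+100)/3, G02 low = 6
  expect_equal(unname(cells["anc1"]), mean(c(205 / 3, 6)))
})

test_that("decomposition recovers configured truth (plasticity -2, genetic +2, GxE +2)", {
  te <- matrix(-2, 1, 1, dimnames = list("HI", "fecundity"))
  pe <- matrix(2, 1, 1, dimnames = list("PP", "fecundity"))
  gxe <- array(2, dim = c(1, 1, 1),
               dimnames = list("PP", "HI", "fecundity"))
  cfg <- synthetic_config(
    populations = c("EP", "PP"), n_genotypes = 10, n_replicates = 10,
    treatment_effects = te, population_effects = pe, gxe_effects = gxe,
    sd_genotype = c(fecundity = 0, size_mm = 0, age_days = 0),
    sd_batch = c(fecundity = 0, size_mm = 0, age_days = 0),
    sd_residual = c(fecundity = 0.1, size_mm = 0.1, age_days = 0.1),
    hazard = no_hazard(), fecundity_mode = "gaussian", seed = 61)
  sp <- transition_spec("EP", "PP", "LI", "HI")
  ests <- t(sapply(1:30, function(i) {
    cfg$seed <- 61L + i
    r <- generate_experiment(cfg)$records
    unlist(decompose_cells(multistress:::.transition_cells(r, sp,
                                                           "fecundity")))
  }))
  mc_se <- apply(ests, 2, sd) / sqrt(nrow(ests))
  truth <- c(plasticity = -2, genetic_evolution = 2,
             evolution_of_plasticity = 2)
  expect_true(all(abs(colMeans(ests) - truth) < 3 * mc_se + 1e-8))
  # configured truth is also recorded in the generator's ground truth
  gt <- generate_experiment(cfg)$truth$decomposition
  row <- gt[gt$transition == "T1->T2 (LI->HI)" & gt$trait == "fecundity", ]
  expect_equal(row$plasticity, -2)
  expect_equal(row$genetic_evolution, 2)
  expect_equal(row$evolution_of_plasticity, 2)
})

test_that("run_historical_transitions attributes pure-plasticity and pure-genetic worlds correctly", {
  te <- matrix(c(-5, 4, -3, 2), 4, 1,
               dimnames = list(c("LA", "HA", "HI", "LI"), "fecundity"))
  cfg <- synthetic_config(treatment_effects = te, n_replicates = 8,
                          sd_residual = c(fecundity = 0.2, size_mm = 0.2,
                                          age_days = 0.2),
                          sd_genotype = c(fecundity = 0, size_mm = 0,
                                          age_days = 0),
                          sd_batch = c(fecundity = 0, size_mm = 0,
                                       age_days = 0),
                          hazard = no_hazard(),
                          fecundity_mode = "gaussian", seed = 71)
  out <- run_historical_transitions(generate_experiment(cfg)$records,
                                    traits = "fecundity", test = FALSE)
  pl <- out[out$component == "plasticity", ]
  expect_true(all(pl$rel_contribution_pct > 95))
  pe <- matrix(c(0, 3, 6), 3, 1,
               dimnames = list(c("EP", "PP", "CWP"), "fecundity"))
  cfg2 <- synthetic_config(population_effects = pe, n_replicates = 8,
                           sd_residual = c(fecundity = 0.2, size_mm = 0.2,
                                           age_days = 0.2),
                           sd_genotype = c(fecundity = 0, size_mm = 0,
                                           age_days = 0),
                           sd_batch = c(fecundity = 0, size_mm = 0,
                                        age_days = 0),
                           hazard = no_hazard(),
                           fecundity_mode = "gaussian", seed = 72)
  out2 <- run_historical_transitions(generate_experiment(cfg2)$records,
                                     traits = "fecundity", test = FALSE)
  ge <- out2[out2$component == "genetic_evolution", ]
  expect_true(all(ge$rel_contribution_pct > 95))
})

test_that("a missing arm skips the transition with a message", {
  r <- generate_experiment(small_config(seed = 12))$records
  r <- r[r$arm != "HAHI", ]
  expect_message(out <- run_historical_transitions(r, traits = "fecundity",
                                                   test = FALSE),
                 "skipping")
  expect_false(any(grepl("HAHI", out$transition)))
  expect_true(any(grepl("HA->LA", out$transition)))
})
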