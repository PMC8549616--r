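# Trait and survival models: closed-form oracles, formula expansion,
# boundary fallback, LMM-vs-OLS agreement, survival recovery and
# order invariance.

test_that("equal group means give a treatment chi-square near zero", {
  set.seed(21)
  r <- generate_experiment(null_config(seed = 21, n_genotypes = 6,
                                       n_replicates = 3))$records
  # force exactly equal algae-arm means for size_mm
  i_ha <- r$arm == "HA"; i_la <- r$arm == "LA"
  r$size_mm[i_ha] <- r$size_mm[i_ha] - mean(r$size_mm[i_ha])
  r$size_mm[i_la] <- r$size_mm[i_la] - mean(r$size_mm[i_la])
  tab <- suppressWarnings(fit_trait_model(r, "size_mm",
                                          design = "pop_algae"))
  row <- tab[tab$term == "algae", ]
  expect_lt(row$chisq, 1e-6)
  expect_gt(row$p, 0.999)
})

test_that("Wald chi-square matches the balanced-design closed-form oracle", {
  # balanced 2 populations x 2 algae levels, zero genotype variance:
  # orthogonality makes the algae coefficient the raw mean difference and
  # its squared Wald statistic Delta^2 / (MSE * (1/n1 + 1/n2)), with MSE
  # from cell fits "row mean + column mean - grand mean".
  set.seed(33)
  n_cell <- 12
  grid <- expand.grid(pop = c("EP", "PP"), algae = c("low", "high"),
                      rep = seq_len(n_cell), stringsAsFactors = FALSE)
  y <- rnorm(nrow(grid)) + ifelse(grid$algae == "high", 0.8, 0)
  r <- data.frame(
    population = grid$pop,
    genotype = sprintf("G%02d", (grid$rep - 1) %% 4 + 1),
    batch = "B1", algae_level = grid$algae,
    insecticide_level = "none", replicate = seq_len(nrow(grid)),
    fecundity = y, size_mm = 1, age_days = 1,
    death_day = 30, event = FALSE, stringsAsFactors = FALSE)
  tab <- fit_trait_model(r, "fecundity", design = "pop_algae",
                         engine = "ols")
  # independent oracle from group means and residual sums of squares
  delta <- mean(y[grid$algae == "high"]) - mean(y[grid$algae == "low"])
  fitv <- ave(y, grid$pop) + ave(y, grid$algae) - mean(y)
  mse <- sum((y - fitv)^2) / (length(y) - 3)
  se2 <- mse * (1 / sum(grid$algae == "high") +
                  1 / sum(grid$algae == "low"))
  expect_equal(tab$chisq[tab$term == "algae"], delta^2 / se2,
               tolerance = 1e-10)
})

test_that("term-test rows match the formula expansion exactly", {
  r <- generate_experiment(small_config(seed = 2))$records
  tab2 <- suppressWarnings(fit_trait_model(r, "fecundity",
                                           design = "pop_algae"))
  expect_equal(tab2$term, c("population", "algae", "population:algae"))
  tab3 <- suppressWarnings(fit_trait_model(r, "age_days",
                                           design = "threeway"))
  expect_equal(tab3$term,
               c("population", "algae", "insecticide",
                 "population:algae", "population:insecticide",
                 "algae:insecticide",
                 "population:algae:insecticide"))
  expect_true(all(tab3$chisq >= 0))
  expect_true(all(tab3$p >= 0 & tab3$p <= 1))
  expect_equal(stats::pchisq(tab3$chisq, tab3$df, lower.tail = FALSE),
               tab3$p, tolerance = 1e-12)
})

test_that("zero genotype variance triggers the OLS fallback and matches the OLS oracle", {
  # genotype means made exactly equal within each population x arm cell, so
  # the between-genotype variance estimate is pinned to the boundary
  cfg <- null_config(seed = 13, n_genotypes = 6, n_replicates = 4)
  r <- generate_experiment(cfg)$records
  key <- paste(r$population, r$arm, r$genotype)
  r$size_mm <- r$size_mm - ave(r$size_mm, key) +
    ave(r$size_mm, paste(r$population, r$arm))
  expect_warning(tab <- fit_trait_model(r, "size_mm", design = "pop_algae"),
                 "boundary")
  expect_equal(attr(tab, "engine"), "ols")
  # OLS oracle via explicit refits per term (type II marginality)
  d <- r[r$arm %in% c("HA", "LA"), ]
  d$algae <- factor(d$algae_level, c("low", "high"))
  d$population <- factor(d$population, c("EP", "PP", "CWP"))
  m_main <- lm(size_mm ~ population + algae, d)
  m_full <- lm(size_mm ~ population * algae, d)
  oracle_term <- function(fit, cols) {
    b <- coef(fit)[cols]
    as.numeric(t(b) %*% solve(vcov(fit)[cols, cols], b))
  }
  expect_equal(tab$chisq[tab$term == "population"],
               oracle_term(m_main, 2:3), tolerance = 1e-8)
  expect_equal(tab$chisq[tab$term == "algae"],
               oracle_term(m_main, 4), tolerance = 1e-8)
  expect_equal(tab$chisq[tab$term == "population:algae"],
               oracle_term(m_full, 5:6), tolerance = 1e-8)
})

test_that("LMM and OLS chi-squares agree within 1% on balanced data without genotype variance", {
  cfg <- null_config(seed = 17, n_genotypes = 8, n_replicates = 3)
  r <- generate_experiment(cfg)$records
  tab_lmm <- suppressMessages(fit_trait_model(r, "age_days",
                                              design = "pop_algae",
                                              engine = "lmm"))
  tab_ols <- fit_trait_model(r, "age_days", design = "pop_algae",
                             engine = "ols")
  expect_equal(tab_lmm$chisq, tab_ols$chisq, tolerance = 0.01)
})

test_that("posthoc contrasts: combinatorics and power", {
  # two populations -> exactly one contrast row
  cfg <- synthetic_config(populations = c("EP", "PP"), n_genotypes = 5,
                          n_replicates = 2, seed = 3)
  r <- generate_experiment(cfg)$records
  ph <- suppressWarnings(posthoc_population_contrasts(r, "fecundity"))
  expect_equal(nrow(ph), 1L)
  expect_match(ph$contrast, "PP - EP")
  # a +3 sd population shift is flagged essentially always
  pe <- matrix(c(12, 0, 0), 3, 1,
               dimnames = list(c("EP", "PP", "CWP"), "fecundity"))
  cfg2 <- synthetic_config(population_effects = pe, n_replicates = 5,
                           hazard = no_hazard(), seed = 29)
  r2 <- generate_experiment(cfg2)$records
  ph2 <- suppressWarnings(posthoc_population_contrasts(r2, "fecundity"))
  flagged <- attr(ph2, "flagged")
  expect_true("EP" %in% names(flagged))
  expect_equal(unname(flagged["EP"]), "higher")
})

test_that("all-censored data yield the no-mortality-signal flag", {
  r <- generate_experiment(noiseless_config())$records
  fit <- fit_survival(r, "threeway")
  expect_true(fit$no_mortality_signal)
  expect_equal(fit$n_events, 0L)
  expect_equal(fit$n_censored, sum(r$arm %in%
                                     c("HAHI", "HALI", "LAHI", "LALI")))
})

test_that("survival fit recovers a rate-ratio-2 log time ratio within 3 SE", {
  # exponential times, hazard ratio 2 between algae arms; continuous days
  cfg <- synthetic_config(
    n_genotypes = 10, n_replicates = 25,
    hazard = list(shape = 1, scale = 30,
                  log_hr_arm = c(LA = log(2)), log_hr_population = NULL),
    censor_day = 40, round_days = FALSE, seed = 41)
  r <- generate_experiment(cfg)$records
  fit <- fit_survival(r, "pop_algae")
  # AFT with shape 1: log time-ratio for LA (reference low) = +ln 2 toward HA
  co <- fit$coefficients
  i <- which(co$term == "algaehigh")
  expect_length(i, 1L)
  expect_lt(abs(co$coef[i] - log(2)), 3 * co$se[i])
})

test_that("survival fit is invariant to record order", {
  r <- generate_experiment(small_config(seed = 6))$records
  f1 <- fit_survival(r, "threeway")
  set.seed(1)
  f2 <- fit_survival(r[sample(nrow(r)), ], "threeway")
  expect_equal(f1$table$chisq, f2$table$chisq, tolerance = 1e-6)
  expect_equal(f1$n_events, f2$n_events)
})
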