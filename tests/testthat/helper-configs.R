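# Shared fixture builders. Everything is generated in code; no files.

# a hazard that never fires within the experiment (all animals censored)
no_hazard <- function() {
  list(shape = 1, scale = 1e9, log_hr_arm = NULL, log_hr_population = NULL)
}

# tiny noiseless world: every effect and sd zero, known intercepts
noiseless_config <- function(seed = 1, ...) {
  synthetic_config(
    trait_intercepts = c(fecundity = 10, size_mm = 3.0, age_days = 10),
    sd_genotype = c(fecundity = 0, size_mm = 0, age_days = 0),
    sd_batch = c(fecundity = 0, size_mm = 0, age_days = 0),
    sd_residual = c(fecundity = 0, size_mm = 0, age_days = 0),
    hazard = no_hazard(), seed = seed, ...)
}

# small default-world config for fast structural tests
small_config <- function(seed = 1, ...) {
  synthetic_config(n_genotypes = 4, n_replicates = 2, seed = seed, ...)
}

# all effects zero, unit residual sd: the null world for type-I checks
null_config <- function(seed, n_genotypes = 5, n_replicates = 2,
                        scale = 1e9) {
  synthetic_config(
    n_genotypes = n_genotypes, n_replicates = n_replicates,
    sd_genotype = c(fecundity = 0, size_mm = 0, age_days = 0),
    sd_batch = c(fecundity = 0, size_mm = 0, age_days = 0),
    sd_residual = c(fecundity = 1, size_mm = 1, age_days = 1),
    hazard = list(shape = 1, scale = scale, log_hr_arm = NULL,
                  log_hr_population = NULL),
    fecundity_mode = "gaussian",
    seed = seed)
}

# a minimal hand-built observation table (3 batches not required)
manual_records <- function() {
  data.frame(
    population = rep("EP", 6),
    genotype = rep(c("G01", "G02"), 3),
    batch = "B1",
    algae_level = rep(c("control", "low", "high"), each = 2),
    insecticide_level = "none",
    replicate = c(1, 1, 1, 1, 1, 1),
    fecundity = c(10, 12, 5, 6, 14, 15),
    size_mm = c(3, 3.1, 2.5, 2.6, 3.2, 3.3),
    age_days = c(10, 10, 12, 12, 9, 9),
    death_day = 30, event = FALSE,
    stringsAsFactors = FALSE)
}
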