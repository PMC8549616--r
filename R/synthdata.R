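# Synthetic common-garden generator. Emulates the statistical structure the
# downstream analysis assumes: temporal populations x clonal genotypes x
# factorial stressor arms x batches, Gaussian traits with a genotype random
# intercept nested in population, configurable treatment / population /
# interaction effects, and a Weibull mortality process with right-censoring.
# Every configured effect is ground truth for recovery tests.

.single_arms <- function() c("HA", "LA", "HI", "LI")
.pair_arms <- function() c("HAHI", "HALI", "LAHI", "LALI")

.effect_matrix <- function(x, rows, traits, what) {
  m <- matrix(0, length(rows), length(traits),
              dimnames = list(rows, traits))
  if (is.null(x)) return(m)
  if (!is.matrix(x)) stop(what, " must be a matrix", call. = FALSE)
  bad <- setdiff(rownames(x), rows)
  if (length(bad)) {
    stop("unknown ", what, " row label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  m[rownames(x), colnames(x)] <- x
  m
}

#' Build a synthetic-experiment configuration
#'
#' The default parameterization is the stated world of the study design:
#' 3 temporal populations (EP, PP, CWP) x 10 clonal genotypes each, the 9
#' factorial treatment arms, 3 experimental batches, and life-history traits
#' on their natural scales (fecundity over first + second brood, size at
#' maturity in mm, age at maturity in days). Effects are additive shifts of
#' cell means and constitute ground truth:
#' \describe{
#'   \item{`population_effects`}{population x trait shifts = genetic
#'     evolution truth.}
#'   \item{`treatment_effects`}{single-arm (HA, LA, HI, LI) x trait shifts =
#'     plasticity truth. The control arm has zero effect by construction.}
#'   \item{`stressor_interactions`}{pair-arm x trait deviations from
#'     additivity: a combined arm's effect is the sum of its two matching
#'     single-arm effects plus this term. 0 = additive truth; a same-sign
#'     deviation = synergism, an opposing one = antagonism.}
#'   \item{`gxe_effects`}{population x arm x trait shifts =
#'     evolution-of-plasticity truth.}
#' }
#' Mortality follows a Weibull proportional-hazards event-time model
#' (`shape = 1` gives the exponential default), right-censored at
#' `censor_day`; animals dying before `maturity_day` have missing trait
#' values (they contribute to survival only).
#'
#' @param populations population labels, oldest first.
#' @param n_genotypes clonal genotypes per population.
#' @param n_replicates animals per genotype x arm.
#' @param n_batches experimental batches; replicates cycle over batches.
#' @param trait_intercepts named baseline per trait.
#' @param population_effects,treatment_effects,stressor_interactions
#'   matrices (rows = labels, cols = traits); missing rows/cols are zero.
#' @param gxe_effects 3-d array `[population, arm, trait]` or NULL (zero).
#' @param sd_genotype,sd_batch,sd_residual named per-trait standard
#'   deviations of genotype intercepts, batch offsets and residuals.
#' @param hazard list with `shape`, `scale` (days), and named log-hazard
#'   shift vectors `log_hr_arm` and `log_hr_population`.
#' @param censor_day end of the experiment (days).
#' @param maturity_day animals dying strictly before this day have missing
#'   fecundity / size / age.
#' @param fecundity_mode `"rounded"` (non-negative rounded Gaussian,
#'   default), `"gaussian"` (continuous), or `"poisson"` (count draw with
#'   the cell mean as rate; residual sd ignored for fecundity).
#' @param round_days record death to whole days (daily observation) or keep
#'   continuous event times.
#' @param seed integer global seed; all module streams derive from it.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(populations = c("EP", "PP", "CWP"),
                             n_genotypes = 10,
                             n_replicates = 3,
                             n_batches = 3,
                             trait_intercepts = c(fecundity = 15,
                                                  size_mm = 2.5,
                                                  age_days = 8),
                             population_effects = NULL,
                             treatment_effects = NULL,
                             stressor_interactions = NULL,
                             gxe_effects = NULL,
                             sd_genotype = c(fecundity = 2.0,
                                             size_mm = 0.10,
                                             age_days = 0.6),
                             sd_batch = c(fecundity = 1.5,
                                          size_mm = 0.08,
                                          age_days = 0.5),
                             sd_residual = c(fecundity = 3.0,
                                             size_mm = 0.15,
                                             age_days = 1.0),
                             hazard = list(shape = 1, scale = 120,
                                           log_hr_arm = c(HI = 0.8, LI = 0.4,
                                                          LA = 0.3,
                                                          HAHI = 0.9,
                                                          HALI = 0.5,
                                                          LAHI = 1.2,
                                                          LALI = 0.9),
                                           log_hr_population = c(EP = 0.3)),
                             censor_day = 30,
                             maturity_day = 5,
                             fecundity_mode = c("rounded", "gaussian",
                                                "poisson"),
                             round_days = TRUE,
                             seed = 1) {
  fecundity_mode <- match.arg(fecundity_mode)
  traits <- names(trait_intercepts)
  if (is.null(traits) || !all(.trait_cols() %in% traits)) {
    stop("trait_intercepts must be named and include ",
         paste(.trait_cols(), collapse = ", "), call. = FALSE)
  }
  counts <- c(n_genotypes = n_genotypes, n_replicates = n_replicates,
              n_batches = n_batches)
  if (any(counts < 1) || length(populations) < 1) {
    stop("all counts must be >= 1", call. = FALSE)
  }
  for (nm in c("sd_genotype", "sd_batch", "sd_residual")) {
    v <- get(nm)
    if (any(v < 0)) stop(nm, " must be >= 0", call. = FALSE)
  }
  if (censor_day <= 0) stop("censor_day must be > 0", call. = FALSE)
  if (is.null(hazard$shape) || hazard$shape <= 0 ||
      is.null(hazard$scale) || hazard$scale <= 0) {
    stop("hazard$shape and hazard$scale must be > 0", call. = FALSE)
  }
  arms <- treatment_arms()$code
  for (v in list(hazard$log_hr_arm %||% numeric(),
                 hazard$log_hr_population %||% numeric())) {
    # labels checked below against arms/populations
  }
  bad <- setdiff(names(hazard$log_hr_arm %||% numeric()), arms)
  if (length(bad)) {
    stop("unknown arm label(s) in hazard$log_hr_arm: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(names(hazard$log_hr_population %||% numeric()), populations)
  if (length(bad)) {
    stop("unknown population label(s) in hazard$log_hr_population: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  cfg <- structure(list(
    populations = populations,
    n_genotypes = as.integer(n_genotypes),
    n_replicates = as.integer(n_replicates),
    n_batches = as.integer(n_batches),
    traits = traits,
    trait_intercepts = trait_intercepts,
    population_effects = .effect_matrix(population_effects, populations,
                                        traits, "population_effects"),
    treatment_effects = .effect_matrix(treatment_effects, .single_arms(),
                                       traits, "treatment_effects"),
    stressor_interactions = .effect_matrix(stressor_interactions,
                                           .pair_arms(), traits,
                                           "stressor_interactions"),
    gxe_effects = gxe_effects,
    sd_genotype = sd_genotype,
    sd_batch = sd_batch,
    sd_residual = sd_residual,
    hazard = hazard,
    censor_day = censor_day,
    maturity_day = maturity_day,
    fecundity_mode = fecundity_mode,
    round_days = round_days,
    seed = as.integer(seed)
  ), class = "synthetic_config")
  if (!is.null(gxe_effects)) {
    d <- dimnames(gxe_effects)
    if (is.null(d) || !all(d[[1]] %in% populations) ||
        !all(d[[2]] %in% arms) || !all(d[[3]] %in% traits)) {
      stop("gxe_effects must be a named [population, arm, trait] array",
           call. = FALSE)
    }
  }
  cfg
}

# Effective mean shift of each arm relative to control: singles as
# configured; pairs = matching algae single + matching insecticide single +
# configured deviation from additivity; CTRL = 0.
.arm_effects <- function(cfg) {
  arms <- treatment_arms()
  out <- matrix(0, nrow(arms), length(cfg$traits),
                dimnames = list(arms$code, cfg$traits))
  out[.single_arms(), ] <- cfg$treatment_effects[.single_arms(), ]
  for (p in .pair_arms()) {
    lv <- arms[arms$code == p, ]
    a_single <- if (lv$algae_level == "high") "HA" else "LA"
    i_single <- if (lv$insecticide_level == "high") "HI" else "LI"
    out[p, ] <- cfg$treatment_effects[a_single, ] +
      cfg$treatment_effects[i_single, ] + cfg$stressor_interactions[p, ]
  }
  out
}

.gxe_lookup <- function(cfg, pop, arm, trait) {
  g <- cfg$gxe_effects
  if (is.null(g)) return(0)
  d <- dimnames(g)
  if (pop %in% d[[1]] && arm %in% d[[2]] && trait %in% d[[3]]) {
    g[pop, arm, trait]
  } else 0
}

# Expected (noiseless) trait value per population x arm x trait.
.true_cell_means <- function(cfg) {
  arms <- treatment_arms()$code
  ae <- .arm_effects(cfg)
  out <- array(0, dim = c(length(cfg$populations), length(arms),
                          length(cfg$traits)),
               dimnames = list(cfg$populations, arms, cfg$traits))
  for (p in cfg$populations) for (a in arms) for (tr in cfg$traits) {
    out[p, a, tr] <- cfg$trait_intercepts[tr] +
      cfg$population_effects[p, tr] + ae[a, tr] +
      .gxe_lookup(cfg, p, a, tr)
  }
  out
}

#' True interaction class implied by a configuration
#'
#' Maps a configured deviation from additivity to the label the additive
#' null-model classifier should recover at large n: zero deviation is
#' additive; a deviation with the same sign as the summed single-stressor
#' effects amplifies them (synergistic); an opposing deviation attenuates
#' them (antagonistic).
#'
#' @param config a `synthetic_config`.
#' @param trait trait name.
#' @param pair combined arm code (`HAHI`, `HALI`, `LAHI`, `LALI`).
#' @return `"additive"`, `"synergistic"` or `"antagonistic"`.
#' @export
truth_interaction_class <- function(config, trait, pair) {
  if (!pair %in% .pair_arms()) {
    stop("unknown pair arm: ", pair, call. = FALSE)
  }
  if (!trait %in% config$traits) {
    stop("unknown trait: ", trait, call. = FALSE)
  }
  lv <- treatment_arms()
  lv <- lv[lv$code == pair, ]
  a_single <- if (lv$algae_level == "high") "HA" else "LA"
  i_single <- if (lv$insecticide_level == "high") "HI" else "LI"
  s <- config$treatment_effects[a_single, trait] +
    config$treatment_effects[i_single, trait]
  dev <- config$stressor_interactions[pair, trait]
  if (dev == 0) return("additive")
  if (sign(dev) == sign(s)) "synergistic" else "antagonistic"
}

#' Generate a synthetic common-garden experiment
#'
#' Draws one record per animal over the full population x genotype x arm x
#' replicate grid. Trait values are intercept + population effect + arm
#' effect + GxE effect + genotype random intercept + batch offset +
#' residual. Event times come from the configured Weibull hazard,
#' right-censored at `censor_day`; animals dying before `maturity_day`
#' contribute survival only (missing traits). Identical config and seed
#' give identical output.
#'
#' @param config a `synthetic_config`.
#' @return list with `records` (observation data.frame, including derived
#'   `arm`) and `truth` (a `ground_truth` object: noiseless cell means,
#'   realized genotype intercepts and batch offsets, true decomposition
#'   components for the historical transitions, true interaction class per
#'   trait x pair).
#' @export
generate_experiment <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  arms <- treatment_arms()
  traits <- cfg$traits
  geno_labels <- sprintf("G%02d", seq_len(cfg$n_genotypes))

  # genotype random intercepts, one stream per population
  geno_int <- array(0, dim = c(length(cfg$populations), cfg$n_genotypes,
                               length(traits)),
                    dimnames = list(cfg$populations, geno_labels, traits))
  for (p in cfg$populations) {
    draws <- with_seed(sub_seed(cfg$seed, paste0("genotype:", p)),
                       stats::rnorm(cfg$n_genotypes * length(traits)))
    geno_int[p, , ] <- matrix(draws, cfg$n_genotypes, length(traits)) *
      rep(cfg$sd_genotype[traits], each = cfg$n_genotypes)
  }

  batch_labels <- sprintf("B%d", seq_len(cfg$n_batches))
  batch_off <- with_seed(sub_seed(cfg$seed, "batch"), {
    m <- matrix(stats::rnorm(cfg$n_batches * length(traits)),
                cfg$n_batches, length(traits),
                dimnames = list(batch_labels, traits))
    m * rep(cfg$sd_batch[traits], each = cfg$n_batches)
  })

  grid <- expand.grid(replicate = seq_len(cfg$n_replicates),
                      arm = arms$code,
                      genotype = geno_labels,
                      population = cfg$populations,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$batch <- batch_labels[(grid$replicate - 1L) %% cfg$n_batches + 1L]
  lv <- arm_levels(grid$arm)
  grid$algae_level <- lv$algae_level
  grid$insecticide_level <- lv$insecticide_level
  n <- nrow(grid)

  cell <- .true_cell_means(cfg)
  mu <- matrix(0, n, length(traits), dimnames = list(NULL, traits))
  for (tr in traits) {
    mu[, tr] <- cell[cbind(grid$population, grid$arm, tr)] +
      geno_int[cbind(grid$population, grid$genotype, tr)] +
      batch_off[cbind(grid$batch, tr)]
  }

  res <- with_seed(sub_seed(cfg$seed, "residual"), {
    matrix(stats::rnorm(n * length(traits)), n, length(traits),
           dimnames = list(NULL, traits)) *
      rep(cfg$sd_residual[traits], each = n)
  })
  vals <- mu + res
  if (cfg$fecundity_mode == "rounded") {
    vals[, "fecundity"] <- pmax(0, round(vals[, "fecundity"]))
  } else if (cfg$fecundity_mode == "poisson") {
    vals[, "fecundity"] <- with_seed(sub_seed(cfg$seed, "fecundity"),
      stats::rpois(n, pmax(mu[, "fecundity"], 1e-8)))
  }
  vals[, "size_mm"] <- pmax(vals[, "size_mm"], 1e-6)
  vals[, "age_days"] <- pmax(vals[, "age_days"], 1e-6)

  # Weibull PH event times: T = scale * (-log U)^(1/shape) * exp(-lp/shape)
  lp <- rep(0, n)
  lha <- cfg$hazard$log_hr_arm %||% numeric()
  lhp <- cfg$hazard$log_hr_population %||% numeric()
  if (length(lha)) {
    i <- match(grid$arm, names(lha))
    lp <- lp + ifelse(is.na(i), 0, lha[pmax(i, 1L)])
  }
  if (length(lhp)) {
    i <- match(grid$population, names(lhp))
    lp <- lp + ifelse(is.na(i), 0, lhp[pmax(i, 1L)])
  }
  u <- with_seed(sub_seed(cfg$seed, "survival"), stats::runif(n))
  tt <- cfg$hazard$scale * (-log(u))^(1 / cfg$hazard$shape) *
    exp(-lp / cfg$hazard$shape)
  event <- tt <= cfg$censor_day
  death <- ifelse(event,
                  if (cfg$round_days) pmax(ceiling(tt), 1) else tt,
                  cfg$censor_day)

  records <- data.frame(
    population = grid$population, genotype = grid$genotype,
    batch = grid$batch, algae_level = grid$algae_level,
    insecticide_level = grid$insecticide_level,
    replicate = grid$replicate,
    fecundity = vals[, "fecundity"], size_mm = vals[, "size_mm"],
    age_days = vals[, "age_days"],
    death_day = death, event = event,
    arm = grid$arm, stringsAsFactors = FALSE)

  immature <- records$event & records$death_day < cfg$maturity_day
  records$fecundity[immature] <- NA_real_
  records$size_mm[immature] <- NA_real_
  records$age_days[immature] <- NA_real_

  truth <- structure(list(
    cell_means = cell,
    genotype_intercepts = geno_int,
    batch_offsets = batch_off,
    decomposition = .truth_decomposition(cfg, cell),
    interaction_class = .truth_interaction_table(cfg),
    config = cfg
  ), class = "ground_truth")

  list(records = records, truth = truth)
}

# True decomposition components from noiseless cell means for the five
# historical / hypothetical transitions (only those whose populations and
# arms exist in the configuration).
.truth_decomposition <- function(cfg, cell) {
  specs <- historical_transitions()
  out <- list()
  for (sp in specs) {
    if (!(sp$ancestral_population %in% cfg$populations &&
          sp$descendant_population %in% cfg$populations)) next
    for (tr in cfg$traits) {
      m <- c(anc0 = cell[sp$ancestral_population, sp$ancestral_arm, tr],
             anc1 = cell[sp$ancestral_population, sp$descendant_arm, tr],
             desc0 = cell[sp$descendant_population, sp$ancestral_arm, tr],
             desc1 = cell[sp$descendant_population, sp$descendant_arm, tr])
      comp <- decompose_cells(m)
      out[[length(out) + 1L]] <- data.frame(
        transition = sp$label, trait = tr,
        plasticity = comp$plasticity,
        genetic_evolution = comp$genetic_evolution,
        evolution_of_plasticity = comp$evolution_of_plasticity,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

.truth_interaction_table <- function(cfg) {
  out <- expand.grid(trait = cfg$traits, pair = .pair_arms(),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$class <- mapply(function(tr, p) truth_interaction_class(cfg, tr, p),
                      out$trait, out$pair)
  out
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("Synthetic common-garden configuration\n")
  cat(sprintf("  populations: %s (%d genotypes each)\n",
              paste(x$populations, collapse = ", "), x$n_genotypes))
  cat(sprintf("  %d replicates / genotype x arm, %d batches, seed %d\n",
              x$n_replicates, x$n_batches, x$seed))
  cat(sprintf("  censoring at day %g; Weibull shape %g, scale %g\n",
              x$censor_day, x$hazard$shape, x$hazard$scale))
  invisible(x)
}
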