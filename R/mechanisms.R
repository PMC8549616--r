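# Decomposition of trait change across a historical transition into
# plasticity, genetic evolution and evolution of plasticity, using the
# 2x2 (population x environment) cell-mean contrasts with 0/1 coding:
#   plasticity            = mean(anc, env1) - mean(anc, env0)
#   genetic evolution     = mean(desc, env0) - mean(anc, env0)
#   evolution of plasticity = [mean(desc, env1) - mean(desc, env0)]
#                           - [mean(anc, env1) - mean(anc, env0)]
# These satisfy the exact reconstruction
#   mean(desc, env1) = mean(anc, env0) + plasticity + genetic + GxE.

#' Define a population x environment transition
#'
#' The ancestral population and environment are coded 0, the descendant
#' population and environment 1, mirroring the planned-contrast coding of
#' the transition analysis.
#'
#' @param ancestral_population,descendant_population population labels.
#' @param ancestral_arm,descendant_arm treatment arm codes standing for the
#'   historical environments.
#' @param label optional display label.
#' @return a `transition_spec` list.
#' @export
transition_spec <- function(ancestral_population, descendant_population,
                            ancestral_arm, descendant_arm, label = NULL) {
  arms <- treatment_arms()$code
  for (a in c(ancestral_arm, descendant_arm)) {
    if (!a %in% arms) stop("unknown arm: ", a, call. = FALSE)
  }
  if (ancestral_population == descendant_population ||
      ancestral_arm == descendant_arm) {
    stop("the four (population, environment) cells must be distinct",
         call. = FALSE)
  }
  structure(list(
    ancestral_population = ancestral_population,
    descendant_population = descendant_population,
    ancestral_arm = ancestral_arm,
    descendant_arm = descendant_arm,
    label = label %||% sprintf("%s->%s (%s->%s)", ancestral_population,
                               descendant_population, ancestral_arm,
                               descendant_arm)),
    class = "transition_spec")
}

#' The two historical transitions and three hypothetical single-stress variants
#'
#' T1 -> T2: EP -> PP under HALI -> HAHI (biocides rose, food stayed high).
#' T2 -> T3: PP -> CWP under HAHI -> LALI (both declined). The single-stress
#' variants probe the same population transitions under one stressor only:
#' LI -> HI (T1), HA -> LA and HI -> LI (T2).
#'
#' @return list of five `transition_spec`s.
#' @export
historical_transitions <- function() {
  list(
    transition_spec("EP", "PP", "HALI", "HAHI", "T1->T2 (HALI->HAHI)"),
    transition_spec("PP", "CWP", "HAHI", "LALI", "T2->T3 (HAHI->LALI)"),
    transition_spec("EP", "PP", "LI", "HI", "T1->T2 (LI->HI)"),
    transition_spec("PP", "CWP", "HA", "LA", "T2->T3 (HA->LA)"),
    transition_spec("PP", "CWP", "HI", "LI", "T2->T3 (HI->LI)")
  )
}

#' Decompose a 2x2 cell-mean table into mechanism components
#'
#' Pure arithmetic on four cell means named `anc0`, `anc1`, `desc0`,
#' `desc1` (population x environment, 0 = ancestral / 1 = descendant).
#'
#' @param m named numeric vector of the four cell means.
#' @return list with `plasticity`, `genetic_evolution`,
#'   `evolution_of_plasticity`.
#' @export
decompose_cells <- function(m) {
  need <- c("anc0", "anc1", "desc0", "desc1")
  if (!all(need %in% names(m))) {
    stop("cell means must be named ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  plast <- m[["anc1"]] - m[["anc0"]]
  gen <- m[["desc0"]] - m[["anc0"]]
  gxe <- (m[["desc1"]] - m[["desc0"]]) - (m[["anc1"]] - m[["anc0"]])
  list(plasticity = plast, genetic_evolution = gen,
       evolution_of_plasticity = gxe)
}

# Cell means for a transition: genotype means first, then averaged, so each
# genotype carries equal weight regardless of replication imbalance.
.transition_cells <- function(records, spec, trait) {
  if (is.null(records$arm)) {
    records$arm <- arm_code(records$algae_level, records$insecticide_level)
  }
  pick <- function(pop, arm) {
    d <- records[records$population == pop & records$arm == arm, ]
    v <- d[[trait]]
    keep <- !is.na(v)
    if (!any(keep)) return(NA_real_)
    mean(tapply(v[keep], d$genotype[keep], mean))
  }
  c(anc0 = pick(spec$ancestral_population, spec$ancestral_arm),
    anc1 = pick(spec$ancestral_population, spec$descendant_arm),
    desc0 = pick(spec$descendant_population, spec$ancestral_arm),
    desc1 = pick(spec$descendant_population, spec$descendant_arm))
}

#' Decompose trait change across one transition
#'
#' Computes the three mechanism components from the 2x2 cell means
#' (genotype means averaged with equal weight), their relative
#' contributions `|c| / (|plasticity| + |genetic| + |GxE|) x 100`, and
#' planned-contrast significance from a two-factor model with 0/1 coding
#' and a genotype random intercept: the environment term tests plasticity,
#' the population term genetic evolution, and their interaction the
#' evolution of plasticity. With all components zero the relative
#' contributions are reported as `NA`.
#'
#' @param records observation records (ideally batch-standardized).
#' @param spec a [transition_spec()].
#' @param trait trait name.
#' @param test run the planned-contrast model (set `FALSE` for cell-mean
#'   arithmetic only, e.g. in large simulations).
#' @return a `decomposition_result` list: `trait`, `transition`,
#'   `components` (named vector), `relative_contribution` (percent),
#'   `tests` (data.frame component, chisq, df, p; `NULL` if `test = FALSE`).
#' @export
decompose_transition <- function(records, spec, trait, test = TRUE) {
  stopifnot(inherits(spec, "transition_spec"))
  m <- .transition_cells(records, spec, trait)
  if (anyNA(m)) {
    empty <- names(m)[is.na(m)]
    stop("empty or all-missing cell(s): ", paste(empty, collapse = ", "),
         " for transition ", spec$label, call. = FALSE)
  }
  comp <- decompose_cells(m)
  cv <- c(plasticity = comp$plasticity,
          genetic_evolution = comp$genetic_evolution,
          evolution_of_plasticity = comp$evolution_of_plasticity)
  tot <- sum(abs(cv))
  rel <- if (tot > 0) abs(cv) / tot * 100 else
    stats::setNames(rep(NA_real_, 3), names(cv))

  tests <- NULL
  if (test) {
    if (is.null(records$arm)) {
      records$arm <- arm_code(records$algae_level,
                              records$insecticide_level)
    }
    d <- records[records$population %in% c(spec$ancestral_population,
                                           spec$descendant_population) &
                   records$arm %in% c(spec$ancestral_arm,
                                      spec$descendant_arm), ]
    d$y <- d[[trait]]
    d <- d[!is.na(d$y), ]
    d$pop01 <- as.numeric(d$population == spec$descendant_population)
    d$env01 <- as.numeric(d$arm == spec$descendant_arm)
    d$geno_id <- interaction(d$population, d$genotype, drop = TRUE)
    e <- .fit_engine("pop01 * env01", d, "auto")
    b <- .engine_coef(e)
    V <- .engine_vcov(e)
    pick <- function(name) {
      z2 <- (b[[name]]^2) / V[name, name]
      c(chisq = z2, df = 1,
        p = stats::pchisq(z2, 1, lower.tail = FALSE))
    }
    tests <- data.frame(
      component = names(cv),
      rbind(pick("env01"), pick("pop01"), pick("pop01:env01")),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  structure(list(trait = trait, transition = spec$label,
                 cell_means = m, components = cv,
                 relative_contribution = rel, tests = tests),
            class = "decomposition_result")
}

#' Run the historical transition decompositions for all traits
#'
#' Applies [decompose_transition()] over the five historical / hypothetical
#' transitions and the three life-history traits. A transition whose
#' required populations or arms are absent is skipped with a message.
#'
#' @param records observation records.
#' @param traits trait names.
#' @param specs list of transitions (default [historical_transitions()]).
#' @param test run planned-contrast models.
#' @return data.frame with one row per transition x trait x component:
#'   `transition, trait, component, estimate, rel_contribution_pct, chisq,
#'   df, p`.
#' @export
run_historical_transitions <- function(records,
                                       traits = .trait_cols(),
                                       specs = historical_transitions(),
                                       test = TRUE) {
  out <- list()
  for (sp in specs) {
    for (tr in traits) {
      res <- tryCatch(decompose_transition(records, sp, tr, test = test),
                      error = function(e) {
                        message("skipping ", sp$label, " / ", tr, ": ",
                                conditionMessage(e))
                        NULL
                      })
      if (is.null(res)) next
      tst <- res$tests
      out[[length(out) + 1L]] <- data.frame(
        transition = sp$label, trait = tr,
        component = names(res$components),
        estimate = unname(res$components),
        rel_contribution_pct = unname(res$relative_contribution),
        chisq = if (is.null(tst)) NA_real_ else tst$chisq,
        df = if (is.null(tst)) NA_real_ else tst$df,
        p = if (is.null(tst)) NA_real_ else tst$p,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out) %||% data.frame()
}

#' @export
print.decomposition_result <- function(x, ...) {
  cat(sprintf("Decomposition of %s, %s\n", x$trait, x$transition))
  df <- data.frame(component = names(x$components),
                   estimate = unname(x$components),
                   rel_pct = unname(x$relative_contribution))
  if (!is.null(x$tests)) df <- cbind(df, x$tests[, c("chisq", "df", "p")])
  print.data.frame(df, digits = 4)
  invisible(x)
}
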