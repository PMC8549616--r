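# Trait and mortality models: Gaussian linear mixed models with a genotype
# random intercept nested in population, per-term Wald chi-square tests
# (Type II by marginality refits, the conventional companion of factorial
# trait ANOVAs), Tukey-adjusted population contrasts, and a parametric
# Weibull accelerated-failure-time survival model.

# --- design handling ---------------------------------------------------

.design_info <- function(design) {
  switch(design,
    pop_algae = list(
      arms = c("HA", "LA"),
      rhs = "population * algae",
      factors = c("algae")),
    pop_insecticide = list(
      arms = c("HI", "LI"),
      rhs = "population * insecticide",
      factors = c("insecticide")),
    threeway = list(
      arms = c("HAHI", "HALI", "LAHI", "LALI"),
      rhs = "population * algae * insecticide",
      factors = c("algae", "insecticide")),
    stop("unknown design: ", design, call. = FALSE))
}

# Subset records to the arms of a design and build analysis factors.
# Reference levels follow the low/control-first convention.
.design_data <- function(records, design,
                         populations = c("EP", "PP", "CWP")) {
  info <- .design_info(design)
  if (is.null(records$arm)) {
    records$arm <- arm_code(records$algae_level, records$insecticide_level)
  }
  d <- records[records$arm %in% info$arms, , drop = FALSE]
  if (!nrow(d)) stop("no records in arms ", paste(info$arms, collapse = ","),
                     call. = FALSE)
  pops <- intersect(populations, unique(d$population))
  d$population <- factor(d$population, levels = pops)
  if ("algae" %in% info$factors) {
    d$algae <- factor(d$algae_level, levels = c("low", "high"))
  }
  if ("insecticide" %in% info$factors) {
    d$insecticide <- factor(d$insecticide_level, levels = c("low", "high"))
  }
  d$geno_id <- interaction(d$population, d$genotype, drop = TRUE)
  list(data = d, info = info)
}

# --- fitting engines ---------------------------------------------------

# Fit y ~ rhs with a genotype-in-population random intercept; fall back to
# OLS (with a warning) when the random-effect variance sits on the boundary.
.fit_engine <- function(rhs, data, engine = c("auto", "lmm", "ols")) {
  engine <- match.arg(engine)
  if (engine != "ols" && length(unique(data$geno_id)) > 1L) {
    f <- stats::as.formula(paste("y ~", rhs, "+ (1 | geno_id)"))
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(f, data = data,
                 control = lme4::lmerControl(check.conv.singular =
                                               "ignore"))))
    vc <- as.data.frame(lme4::VarCorr(fit))
    if (vc$vcov[vc$grp == "geno_id"] > 1e-8 || engine == "lmm") {
      return(structure(list(fit = fit, engine = "lmm"),
                       class = "ms_engine"))
    }
    warning("genotype variance estimated at the boundary (0); ",
            "falling back to ordinary least squares", call. = FALSE)
  }
  f <- stats::as.formula(paste("y ~", rhs))
  structure(list(fit = stats::lm(f, data = data), engine = "ols"),
            class = "ms_engine")
}

.engine_coef <- function(e) {
  if (e$engine == "lmm") lme4::fixef(e$fit) else stats::coef(e$fit)
}
.engine_vcov <- function(e) as.matrix(stats::vcov(e$fit))
.engine_assign <- function(e) {
  mm <- stats::model.matrix(e$fit)
  attr(mm, "assign")
}
.engine_terms <- function(e) {
  tl <- attr(stats::terms(stats::formula(e$fit, fixed.only = TRUE)),
             "term.labels")
  tl[tl != "(1 | geno_id)" & !grepl("geno_id", tl, fixed = TRUE)]
}

# Wald chi-square for one term of a fitted model, using the columns the
# term owns in the model matrix.
.wald_term <- function(e, term) {
  tl <- .engine_terms(e)
  idx <- match(term, tl)
  if (is.na(idx)) stop("term not in model: ", term, call. = FALSE)
  cols <- which(.engine_assign(e) == idx)
  b <- .engine_coef(e)[cols]
  V <- .engine_vcov(e)[cols, cols, drop = FALSE]
  chi <- as.numeric(t(b) %*% solve(V, b))
  c(chisq = chi, df = length(cols),
    p = stats::pchisq(chi, length(cols), lower.tail = FALSE))
}

# term a "contains" term t when t's factors are a strict subset of a's
.term_contains <- function(a, t) {
  fa <- strsplit(a, ":", fixed = TRUE)[[1]]
  ft <- strsplit(t, ":", fixed = TRUE)[[1]]
  all(ft %in% fa) && length(fa) > length(ft)
}

#' Fit a trait model and return a term-test table
#'
#' Fits a Gaussian linear mixed model of a standardized life-history trait
#' with genotype as a random intercept nested within population, on the
#' arm subset of the declared design:
#' `pop_algae` (HA vs LA), `pop_insecticide` (HI vs LI), or `threeway`
#' (the four combined-stressor arms, algae x insecticide factorial).
#' Per fixed-effect term it reports a Wald chi-square, its degrees of
#' freedom and p-value. The default Type II tests respect marginality: the
#' test of a term comes from the model containing that term and every term
#' that does not contain it. Type III (sum-to-zero coding, full-model Wald)
#' and likelihood-ratio (ML refits) variants are available. When the
#' genotype variance is estimated at the boundary the fit falls back to
#' ordinary least squares with a warning.
#'
#' @param records observation records (ideally batch-standardized).
#' @param trait one of `fecundity`, `size_mm`, `age_days`.
#' @param design `"pop_algae"`, `"pop_insecticide"` or `"threeway"`.
#' @param type `"II"` (default), `"III"` or `"LR"`.
#' @param engine `"auto"` (LMM with OLS boundary fallback), `"lmm"`, or
#'   `"ols"`.
#' @return an `anova_table` data.frame with columns
#'   `term`, `chisq`, `df`, `p`.
#' @export
fit_trait_model <- function(records, trait,
                            design = c("threeway", "pop_algae",
                                       "pop_insecticide"),
                            type = c("II", "III", "LR"),
                            engine = c("auto", "lmm", "ols")) {
  design <- match.arg(design)
  type <- match.arg(type)
  engine <- match.arg(engine)
  dd <- .design_data(records, design)
  d <- dd$data
  d$y <- d[[trait]]
  d <- d[!is.na(d$y), , drop = FALSE]
  for (f in c("population", dd$info$factors)) {
    if (nlevels(droplevels(d[[f]])) < 2L) {
      stop("factor '", f, "' has fewer than 2 levels in the data subset",
           call. = FALSE)
    }
  }
  full_rhs <- dd$info$rhs
  tl <- attr(stats::terms(stats::as.formula(paste("y ~", full_rhs))),
             "term.labels")

  # decide the engine once, on the full model
  full <- .fit_engine(full_rhs, d, engine)
  eng_used <- if (engine == "auto") full$engine else engine

  rows <- vector("list", length(tl))
  if (type == "II") {
    for (i in seq_along(tl)) {
      t_i <- tl[i]
      keep <- tl[!vapply(tl, .term_contains, logical(1), t = t_i)]
      rhs_i <- paste(keep, collapse = " + ")
      e <- if (setequal(keep, tl)) full else .fit_engine(rhs_i, d, eng_used)
      rows[[i]] <- .wald_term(e, t_i)
    }
  } else if (type == "III") {
    d3 <- d
    ctr <- stats::contr.sum
    for (f in c("population", dd$info$factors)) {
      stats::contrasts(d3[[f]]) <- ctr(nlevels(d3[[f]]))
    }
    e <- .fit_engine(full_rhs, d3, eng_used)
    for (i in seq_along(tl)) rows[[i]] <- .wald_term(e, tl[i])
  } else { # likelihood ratio, ML refits
    for (i in seq_along(tl)) {
      t_i <- tl[i]
      keep <- tl[!vapply(tl, .term_contains, logical(1), t = t_i)]
      with_t <- paste(keep, collapse = " + ")
      without_t <- paste(setdiff(keep, t_i), collapse = " + ")
      if (without_t == "") without_t <- "1"
      if (eng_used == "lmm") {
        f1 <- stats::as.formula(paste("y ~", with_t, "+ (1 | geno_id)"))
        f0 <- stats::as.formula(paste("y ~", without_t, "+ (1 | geno_id)"))
        m1 <- suppressWarnings(lme4::lmer(f1, d, REML = FALSE))
        m0 <- suppressWarnings(lme4::lmer(f0, d, REML = FALSE))
        ll <- 2 * (stats::logLik(m1) - stats::logLik(m0))
        df <- attr(stats::logLik(m1), "df") - attr(stats::logLik(m0), "df")
      } else {
        m1 <- stats::lm(stats::as.formula(paste("y ~", with_t)), d)
        m0 <- stats::lm(stats::as.formula(paste("y ~", without_t)), d)
        ll <- 2 * (stats::logLik(m1) - stats::logLik(m0))
        df <- attr(stats::logLik(m1), "df") - attr(stats::logLik(m0), "df")
      }
      chi <- max(0, as.numeric(ll))
      rows[[i]] <- c(chisq = chi, df = df,
                     p = stats::pchisq(chi, df, lower.tail = FALSE))
    }
  }
  out <- data.frame(term = tl, do.call(rbind, rows),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, class = c("anova_table", "data.frame"),
            trait = trait, design = design, type = type,
            engine = eng_used,
            formula = paste("y ~", full_rhs))
}

#' Tukey-adjusted pairwise population contrasts
#'
#' After the factorial model, compares population adjusted means (fixed
#' effects averaged over the treatment factors of the design) for all
#' population pairs, with single-step studentized-range (Tukey) adjustment.
#'
#' @param records observation records.
#' @param trait trait name.
#' @param design design subset (default `threeway`).
#' @param alpha flagging level.
#' @return data.frame of contrasts (`contrast`, `estimate`, `se`, `t`,
#'   `df`, `p_adj`) with an `emmeans` attribute (population adjusted means)
#'   and a `flagged` attribute naming populations whose every contrast is
#'   significant at `alpha`, with direction.
#' @export
posthoc_population_contrasts <- function(records, trait,
                                         design = "threeway",
                                         alpha = 0.05) {
  dd <- .design_data(records, design)
  d <- dd$data
  d$y <- d[[trait]]
  d <- d[!is.na(d$y), , drop = FALSE]
  pops <- levels(droplevels(d$population))
  if (length(pops) < 2L) stop("fewer than 2 populations", call. = FALSE)
  d$population <- droplevels(d$population)
  e <- .fit_engine(dd$info$rhs, d, "auto")
  b <- .engine_coef(e)
  V <- .engine_vcov(e)

  # reference grid over all factor combinations, averaged per population
  grid_args <- list(population = pops)
  for (f in dd$info$factors) grid_args[[f]] <- levels(d[[f]])
  grid <- do.call(expand.grid, c(grid_args, stringsAsFactors = TRUE))
  for (f in names(grid_args)) {
    grid[[f]] <- factor(grid[[f]], levels = grid_args[[f]])
  }
  ff <- stats::as.formula(paste("~", dd$info$rhs))
  X <- stats::model.matrix(ff, grid)
  L <- t(vapply(pops, function(p) colMeans(X[grid$population == p, ,
                                             drop = FALSE]),
                numeric(ncol(X))))
  emm <- as.numeric(L %*% b)
  names(emm) <- pops

  k <- length(pops)
  combs <- utils::combn(k, 2)
  df_resid <- nrow(d) - length(b)
  rows <- apply(combs, 2, function(ij) {
    l <- L[ij[2], ] - L[ij[1], ]
    est <- sum(l * b)
    se <- sqrt(as.numeric(t(l) %*% V %*% l))
    tval <- est / se
    p <- stats::ptukey(sqrt(2) * abs(tval), nmeans = k, df = df_resid,
                       lower.tail = FALSE)
    c(estimate = est, se = se, t = tval, df = df_resid, p_adj = p)
  })
  out <- data.frame(contrast = apply(combs, 2, function(ij)
    paste(pops[ij[2]], "-", pops[ij[1]])),
    t(rows), stringsAsFactors = FALSE, row.names = NULL)

  flagged <- character()
  for (p in pops) {
    inv <- grepl(p, out$contrast, fixed = TRUE)
    if (all(out$p_adj[inv] < alpha)) {
      dir <- if (emm[p] > mean(emm[setdiff(pops, p)])) "higher" else "lower"
      flagged <- c(flagged, stats::setNames(dir, p))
    }
  }
  structure(out, emmeans = emm, flagged = flagged, trait = trait)
}

#' Fit a parametric Weibull survival model
#'
#' Accelerated-failure-time Weibull model on (death day, event flag) with
#' the factorial fixed terms of the declared design; per-term Wald
#' chi-square tests follow the same Type II marginality scheme as
#' [fit_trait_model()]. With zero events a degenerate fit flagged
#' `"no mortality signal"` is returned instead of an error.
#'
#' @param records observation records.
#' @param design design subset, as in [fit_trait_model()].
#' @return a `survival_fit` list: `table` (term, chisq, df, p),
#'   `coefficients` (AFT coefficients with standard errors), `n_events`,
#'   `n_censored`, `distribution`, `no_mortality_signal`.
#' @export
fit_survival <- function(records, design = c("threeway", "pop_algae",
                                             "pop_insecticide")) {
  design <- match.arg(design)
  dd <- .design_data(records, design)
  d <- dd$data
  if (any(d$death_day <= 0)) stop("non-positive death_day", call. = FALSE)
  n_ev <- sum(d$event)
  if (n_ev == 0L) {
    return(structure(list(
      table = NULL, coefficients = NULL,
      n_events = 0L, n_censored = nrow(d),
      distribution = "weibull",
      no_mortality_signal = TRUE), class = "survival_fit"))
  }
  tl <- attr(stats::terms(stats::as.formula(paste("~", dd$info$rhs))),
             "term.labels")
  fit_rhs <- function(rhs) {
    f <- stats::as.formula(paste("survival::Surv(death_day, event) ~", rhs))
    survival::survreg(f, data = d, dist = "weibull")
  }
  wald_sv <- function(fit, term, rhs) {
    tl_i <- attr(stats::terms(stats::as.formula(paste("~", rhs))),
                 "term.labels")
    idx <- match(term, tl_i)
    asg <- attr(stats::model.matrix(stats::as.formula(paste("~", rhs)), d),
                "assign")
    cols <- which(asg == idx)
    b <- stats::coef(fit)[cols]
    V <- stats::vcov(fit)[cols, cols, drop = FALSE]
    chi <- as.numeric(t(b) %*% solve(V, b))
    c(chisq = chi, df = length(cols),
      p = stats::pchisq(chi, length(cols), lower.tail = FALSE))
  }
  rows <- vector("list", length(tl))
  for (i in seq_along(tl)) {
    keep <- tl[!vapply(tl, .term_contains, logical(1), t = tl[i])]
    rhs_i <- paste(keep, collapse = " + ")
    rows[[i]] <- wald_sv(fit_rhs(rhs_i), tl[i], rhs_i)
  }
  full <- fit_rhs(dd$info$rhs)
  sm <- summary(full)$table
  structure(list(
    table = data.frame(term = tl, do.call(rbind, rows),
                       stringsAsFactors = FALSE, row.names = NULL),
    coefficients = data.frame(term = rownames(sm),
                              coef = sm[, "Value"],
                              se = sm[, "Std. Error"],
                              row.names = NULL, stringsAsFactors = FALSE),
    n_events = n_ev, n_censored = nrow(d) - n_ev,
    distribution = "weibull",
    no_mortality_signal = FALSE), class = "survival_fit")
}

#' @export
print.anova_table <- function(x, ...) {
  cat(sprintf("Trait term tests (%s, Wald type %s, engine %s)\n",
              attr(x, "design"), attr(x, "type"), attr(x, "engine")))
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' @export
print.survival_fit <- function(x, ...) {
  if (x$no_mortality_signal) {
    cat("Survival fit: no mortality signal (0 events,",
        x$n_censored, "censored)\n")
  } else {
    cat(sprintf("Weibull AFT fit: %d events, %d censored\n",
                x$n_events, x$n_censored))
    print.data.frame(x$table, digits = 4)
  }
  invisible(x)
}
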