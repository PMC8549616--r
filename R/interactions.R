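# Additive null-model analysis of stressor pairs. Single-stressor effects
# are expressed as standardized mean differences against the shared control
# group; the additive prediction for a pair is E_mix = E_A + E_B, and the
# observed combined-arm effect is classified against it using the 95%
# bootstrap confidence interval of the observed effect.

#' Standardized effect size of a treatment against its control
#'
#' `d = (mean(treatment) - mean(control)) / sigma`, where `sigma` is the
#' sample standard deviation of the pooled (concatenated) treatment and
#' control values — the "shared standard deviation" convention. The
#' classical two-group pooled-variance denominator is available via
#' `sd_method = "pooled_var"`. The 95% confidence interval comes from a
#' bias-corrected nonparametric bootstrap (treatment and control resampled
#' independently), seeded for reproducibility; set `boot = 0` to skip the
#' interval.
#'
#' @param treatment_values,control_values numeric vectors (missing values
#'   dropped); at least 2 non-missing values on each side.
#' @param boot bootstrap resamples (default 2000; 0 disables the CI).
#' @param seed integer seed for the bootstrap.
#' @param conf confidence level.
#' @param sd_method `"concatenated"` (default) or `"pooled_var"`.
#' @return an `effect_size` list: `d`, `mean_diff`, `sd_pooled`,
#'   `n_treatment`, `n_control`, `ci_low`, `ci_high`.
#' @export
effect_size <- function(treatment_values, control_values, boot = 2000,
                        seed = 1, conf = 0.95,
                        sd_method = c("concatenated", "pooled_var")) {
  sd_method <- match.arg(sd_method)
  tv <- treatment_values[!is.na(treatment_values)]
  cv <- control_values[!is.na(control_values)]
  if (length(tv) < 2L || length(cv) < 2L) {
    stop("need >= 2 non-missing values on both sides (got ",
         length(tv), " treatment, ", length(cv), " control)",
         call. = FALSE)
  }
  sd_of <- function(t, c) {
    if (sd_method == "concatenated") stats::sd(c(t, c)) else {
      nt <- length(t); nc <- length(c)
      sqrt(((nt - 1) * stats::var(t) + (nc - 1) * stats::var(c)) /
             (nt + nc - 2))
    }
  }
  s <- sd_of(tv, cv)
  if (!is.finite(s) || s <= 0) {
    stop("pooled standard deviation is zero (all values identical)",
         call. = FALSE)
  }
  d_hat <- (mean(tv) - mean(cv)) / s
  ci <- c(NA_real_, NA_real_)
  if (boot > 0) {
    ci <- with_seed(seed, {
      nt <- length(tv); nc <- length(cv)
      it <- matrix(sample.int(nt, nt * boot, replace = TRUE), ncol = boot)
      ic <- matrix(sample.int(nc, nc * boot, replace = TRUE), ncol = boot)
      mt <- matrix(tv[it], ncol = boot)
      mc <- matrix(cv[ic], ncol = boot)
      sum_t <- colSums(mt); sum_c <- colSums(mc)
      ss <- colSums(mt^2) + colSums(mc^2)
      n <- nt + nc
      m_all <- (sum_t + sum_c) / n
      sd_all <- sqrt(pmax((ss - n * m_all^2) / (n - 1), 0))
      if (sd_method == "pooled_var") {
        v_t <- (colSums(mt^2) - nt * (sum_t / nt)^2) / (nt - 1)
        v_c <- (colSums(mc^2) - nc * (sum_c / nc)^2) / (nc - 1)
        sd_all <- sqrt(pmax(((nt - 1) * v_t + (nc - 1) * v_c) /
                              (nt + nc - 2), 0))
      }
      db <- (sum_t / nt - sum_c / nc) / sd_all
      db <- db[is.finite(db)]
      if (!length(db)) c(NA_real_, NA_real_) else {
        # bias-corrected percentile interval
        prop <- mean(db < d_hat)
        z0 <- stats::qnorm(min(max(prop, 1 / (length(db) + 1)),
                               1 - 1 / (length(db) + 1)))
        a <- (1 - conf) / 2
        probs <- stats::pnorm(2 * z0 + stats::qnorm(c(a, 1 - a)))
        unname(stats::quantile(db, probs, type = 7))
      }
    })
  }
  structure(list(d = d_hat, mean_diff = mean(tv) - mean(cv),
                 sd_pooled = s, n_treatment = length(tv),
                 n_control = length(cv),
                 ci_low = ci[1], ci_high = ci[2], conf = conf),
            class = "effect_size")
}

#' Classify a stressor pair against the additive null model
#'
#' The additive prediction is `e_mix = dA + dB`. If `e_mix` lies inside the
#' 95% confidence interval of the observed joint effect the pair is
#' additive. Otherwise, under the default magnitude-along-direction rule,
#' an observed effect larger in magnitude than the prediction (same
#' direction) is synergistic and a smaller one antagonistic; an observed
#' effect of opposite sign is antagonistic with `reversal = TRUE`. The
#' literal smaller/larger-than-the-CI reading is available via
#' `rule = "literal"`. When genotype-level interaction contrasts are
#' supplied, a one-sample t-test of the contrasts against zero
#' (df = n - 1) quantifies the deviation from additivity.
#'
#' @param dA,dB single-stressor `effect_size` objects.
#' @param observed_joint `effect_size` of the combined arm (must carry a
#'   bootstrap CI).
#' @param contrasts optional numeric vector of genotype-level deviations
#'   `d_mix_g - d_A_g - d_B_g` for the t-test.
#' @param rule `"magnitude"` (default) or `"literal"`.
#' @return an `interaction_call` list: `e_mix`, `d_obs`, `ci_low`,
#'   `ci_high`, `classification`, `reversal`, `t`, `df`, `p`.
#' @export
classify_interaction <- function(dA, dB, observed_joint, contrasts = NULL,
                                 rule = c("magnitude", "literal")) {
  rule <- match.arg(rule)
  for (x in list(dA, dB, observed_joint)) {
    stopifnot(inherits(x, "effect_size"))
  }
  if (is.na(observed_joint$ci_low) || is.na(observed_joint$ci_high)) {
    stop("observed joint effect carries no confidence interval; ",
         "compute it with boot > 0", call. = FALSE)
  }
  e_mix <- dA$d + dB$d
  obs <- observed_joint$d
  lo <- observed_joint$ci_low
  hi <- observed_joint$ci_high
  reversal <- FALSE
  if (e_mix >= lo && e_mix <= hi) {
    cls <- "additive"
  } else if (rule == "magnitude") {
    if (e_mix != 0 && sign(obs) != 0 && sign(obs) != sign(e_mix)) {
      cls <- "antagonistic"
      reversal <- TRUE
    } else if (abs(obs) > abs(e_mix)) {
      cls <- "synergistic"
    } else {
      cls <- "antagonistic"
    }
  } else { # literal wording: prediction below CI -> antagonistic, above -> synergistic
    cls <- if (e_mix < lo) "antagonistic" else "synergistic"
  }
  tt <- c(t = NA_real_, df = NA_real_, p = NA_real_)
  if (!is.null(contrasts)) {
    ct <- contrasts[is.finite(contrasts)]
    if (length(ct) >= 2L && stats::sd(ct) > 0) {
      tv <- mean(ct) / (stats::sd(ct) / sqrt(length(ct)))
      tt <- c(t = tv, df = length(ct) - 1,
              p = 2 * stats::pt(abs(tv), length(ct) - 1,
                                lower.tail = FALSE))
    }
  }
  structure(list(e_mix = e_mix, d_obs = obs, ci_low = lo, ci_high = hi,
                 classification = cls, reversal = reversal,
                 t = tt[["t"]], df = tt[["df"]], p = tt[["p"]]),
            class = "interaction_call")
}

# single arms feeding each pair's additive prediction
.pair_singles <- function(pair) {
  lv <- treatment_arms()
  lv <- lv[lv$code == pair, ]
  c(algae = if (lv$algae_level == "high") "HA" else "LA",
    insecticide = if (lv$insecticide_level == "high") "HI" else "LI")
}

#' Survey all stressor-pair interactions
#'
#' For every population x trait x combined arm, computes the two matching
#' single-stressor effect sizes and the observed joint effect (all against
#' the population's control arm), classifies the interaction against the
#' additive null, runs the genotype-level contrast t-test, and summarizes
#' class percentages overall and per trait. Traits are standardized per
#' batch first (pipeline convention) unless `standardize = FALSE`.
#' Cells whose arms are missing or degenerate are skipped with a message
#' and excluded from the percentage denominators.
#'
#' @param records observation records.
#' @param traits trait names.
#' @param bootstrap bootstrap resamples for the observed joint CI.
#' @param seed integer seed; each cell derives its own stream.
#' @param standardize apply [standardize_batches()] first.
#' @param mode standardization mode.
#' @param rule classification rule, see [classify_interaction()].
#' @param t_test compute the genotype-level contrast t-test per cell
#'   (disable in large simulations where only the class labels matter).
#' @return list with `calls` (one row per classified cell) and `summary`
#'   (percentages per class, overall and per trait).
#' @export
interaction_survey <- function(records, traits = .trait_cols(),
                               bootstrap = 2000, seed = 1,
                               standardize = TRUE,
                               mode = "paper_literal",
                               rule = "magnitude", t_test = TRUE) {
  if (standardize) records <- standardize_batches(records, mode = mode)
  if (is.null(records$arm)) {
    records$arm <- arm_code(records$algae_level, records$insecticide_level)
  }
  pops <- unique(records$population)
  pairs <- .pair_arms()
  calls <- list()
  for (pop in pops) {
    dpop <- records[records$population == pop, ]
    for (tr in traits) {
      ctrl <- dpop[[tr]][dpop$arm == "CTRL"]
      arm_vals <- function(a) dpop[[tr]][dpop$arm == a]
      geno_d <- function(a, s) {
        # genotype-level effect size with the arm-level pooled sd
        sapply(sort(unique(dpop$genotype)), function(g) {
          t_g <- dpop[[tr]][dpop$arm == a & dpop$genotype == g]
          c_g <- dpop[[tr]][dpop$arm == "CTRL" & dpop$genotype == g]
          t_g <- t_g[!is.na(t_g)]; c_g <- c_g[!is.na(c_g)]
          if (!length(t_g) || !length(c_g)) return(NA_real_)
          (mean(t_g) - mean(c_g)) / s
        })
      }
      for (pair in pairs) {
        singles <- .pair_singles(pair)
        cell_seed <- sub_seed(seed, paste("cell", pop, tr, pair))
        res <- tryCatch({
          dA <- effect_size(arm_vals(singles[["algae"]]), ctrl, boot = 0)
          dB <- effect_size(arm_vals(singles[["insecticide"]]), ctrl,
                            boot = 0)
          dJ <- effect_size(arm_vals(pair), ctrl, boot = bootstrap,
                            seed = cell_seed)
          contr <- if (t_test) {
            geno_d(pair, dJ$sd_pooled) -
              geno_d(singles[["algae"]], dA$sd_pooled) -
              geno_d(singles[["insecticide"]], dB$sd_pooled)
          } else NULL
          cl <- classify_interaction(dA, dB, dJ, contrasts = contr,
                                     rule = rule)
          data.frame(population = pop, trait = tr, pair = pair,
                     dA = dA$d, dB = dB$d, e_mix = cl$e_mix,
                     d_obs = cl$d_obs, ci_low = cl$ci_low,
                     ci_high = cl$ci_high, class = cl$classification,
                     reversal = cl$reversal, t = cl$t, df = cl$df,
                     p = cl$p, stringsAsFactors = FALSE)
        }, error = function(e) {
          message("skipping ", pop, "/", tr, "/", pair, ": ",
                  conditionMessage(e))
          NULL
        })
        if (!is.null(res)) calls[[length(calls) + 1L]] <- res
      }
    }
  }
  calls <- do.call(rbind, calls) %||% data.frame()
  summary <- .interaction_summary(calls, traits)
  list(calls = calls, summary = summary)
}

.interaction_summary <- function(calls, traits) {
  classes <- c("additive", "synergistic", "antagonistic")
  pct <- function(d) {
    n <- nrow(d)
    vapply(classes, function(cl) {
      if (n == 0) NA_real_ else 100 * sum(d$class == cl) / n
    }, numeric(1))
  }
  rows <- list(data.frame(scope = "overall", t(pct(calls)),
                          n = nrow(calls), stringsAsFactors = FALSE))
  for (tr in traits) {
    d <- calls[calls$trait == tr, , drop = FALSE]
    rows[[length(rows) + 1L]] <- data.frame(scope = tr, t(pct(d)),
                                            n = nrow(d),
                                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  names(out) <- c("scope", classes, "n")
  out
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("d = %.4f (n = %d vs %d, sd = %.4f)", x$d, x$n_treatment,
              x$n_control, x$sd_pooled))
  if (!is.na(x$ci_low)) {
    cat(sprintf(", %d%% CI [%.4f, %.4f]", round(100 * x$conf), x$ci_low,
                x$ci_high))
  }
  cat("\n")
  invisible(x)
}

#' @export
print.interaction_call <- function(x, ...) {
  cat(sprintf("predicted e_mix = %.3f, observed %.3f [%.3f, %.3f] -> %s%s\n",
              x$e_mix, x$d_obs, x$ci_low, x$ci_high, x$classification,
              if (x$reversal) " (reversal)" else ""))
  invisible(x)
}
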