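# Orchestration: simulate (or read) -> standardize -> trait + survival
# models -> transition decompositions -> interaction survey -> ternary
# trade-offs, as one configured, logged, deterministic run.

#' Build a pipeline run configuration
#'
#' Exactly one of `input` (CSV path) or `synthetic` (a
#' [synthetic_config()]) must be given. All randomness flows from `seed`
#' (the synthetic config keeps its own seed; `seed` drives the bootstrap).
#'
#' @param input path to an observations CSV, or `NULL`.
#' @param synthetic a `synthetic_config`, or `NULL`.
#' @param out_dir output directory (created if needed).
#' @param standardize_mode [standardize_batches()] mode.
#' @param test_type term-test type for [fit_trait_model()].
#' @param bootstrap bootstrap resamples for the interaction survey.
#' @param rule interaction classification rule.
#' @param seed integer seed.
#' @return a `run_config` list.
#' @export
run_config <- function(input = NULL, synthetic = NULL, out_dir = ".",
                       standardize_mode = "paper_literal",
                       test_type = "II", bootstrap = 2000,
                       rule = "magnitude", seed = 1) {
  if (is.null(input) == is.null(synthetic)) {
    stop("exactly one of `input` and `synthetic` must be set",
         call. = FALSE)
  }
  structure(list(input = input, synthetic = synthetic, out_dir = out_dir,
                 standardize_mode = standardize_mode,
                 test_type = test_type, bootstrap = bootstrap,
                 rule = rule, seed = as.integer(seed)),
            class = "run_config")
}

.write_stage <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

#' Run the full analysis pipeline
#'
#' Executes every stage, writes one CSV per stage plus a JSON manifest with
#' md5 checksums, versions, the seed, and a log of skipped cells. A stage
#' failure is reported with its stage name; partially computable stages
#' (e.g. an interaction survey with missing arms) degrade gracefully.
#'
#' @param config a [run_config()].
#' @return the manifest list, invisibly; files are written to
#'   `config$out_dir`: `standardized.csv`, `table1_style.csv`,
#'   `survival.csv`, `mechanisms.csv`, `interaction_calls.csv`,
#'   `interaction_summary.csv`, `ternary.csv`, `manifest.json` (and
#'   `simulated.csv` + `ground_truth.json` for synthetic input).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- character()
  note <- function(...) {
    log[[length(log) + 1L]] <<- sprintf(...)
  }
  files <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_stage(name, conditionMessage(e))
    })
  }
  out <- function(f) file.path(config$out_dir, f)

  # --- input ---
  if (!is.null(config$synthetic)) {
    gen <- stage("simulate", generate_experiment(config$synthetic))
    records <- gen$records
    files["simulated"] <- .write_stage(records[, .obs_cols()],
                                       out("simulated.csv"))
    truth <- gen$truth
    jsonlite::write_json(list(
      cell_means = truth$cell_means,
      decomposition = truth$decomposition,
      interaction_class = truth$interaction_class,
      seed = config$synthetic$seed),
      out("ground_truth.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    files["ground_truth"] <- out("ground_truth.json")
    note("simulated %d records (seed %d)", nrow(records),
         config$synthetic$seed)
  } else {
    records <- stage("read", read_observations(config$input, quiet = TRUE))
    note("read %d records from %s", nrow(records), config$input)
  }

  # --- standardize ---
  std <- stage("standardize",
               standardize_batches(records, mode = config$standardize_mode))
  files["standardized"] <- .write_stage(std[, .obs_cols()],
                                        out("standardized.csv"))

  # --- trait models + survival ---
  t1 <- list(); sv <- list()
  for (design in c("pop_algae", "pop_insecticide", "threeway")) {
    for (tr in .trait_cols()) {
      tab <- tryCatch(
        suppressWarnings(fit_trait_model(std, tr, design = design,
                                         type = config$test_type)),
        error = function(e) {
          note("models: skipped %s/%s (%s)", design, tr,
               conditionMessage(e))
          NULL
        })
      if (!is.null(tab)) {
        t1[[length(t1) + 1L]] <- cbind(design = design, trait = tr,
                                       as.data.frame(tab))
      }
    }
    fit <- tryCatch(fit_survival(std, design = design),
                    error = function(e) {
                      note("survival: skipped %s (%s)", design,
                           conditionMessage(e))
                      NULL
                    })
    if (!is.null(fit)) {
      if (fit$no_mortality_signal) {
        note("survival: %s has no mortality signal", design)
      } else {
        sv[[length(sv) + 1L]] <- cbind(design = design, fit$table)
      }
    }
  }
  files["table1_style"] <- .write_stage(do.call(rbind, t1),
                                        out("table1_style.csv"))
  files["survival"] <- .write_stage(
    if (length(sv)) do.call(rbind, sv) else
      data.frame(design = character(), term = character(),
                 chisq = numeric(), df = numeric(), p = numeric()),
    out("survival.csv"))

  # --- mechanisms ---
  mech <- stage("mechanisms", withCallingHandlers(
    run_historical_transitions(std),
    message = function(m) {
      note("mechanisms: %s", trimws(conditionMessage(m)))
      invokeRestart("muffleMessage")
    }))
  files["mechanisms"] <- .write_stage(mech, out("mechanisms.csv"))

  # --- interactions ---
  surv <- stage("interactions", withCallingHandlers(
    interaction_survey(records, bootstrap = config$bootstrap,
                       seed = config$seed,
                       mode = config$standardize_mode,
                       rule = config$rule),
    message = function(m) {
      note("interactions: %s", trimws(conditionMessage(m)))
      invokeRestart("muffleMessage")
    }))
  files["interaction_calls"] <- .write_stage(surv$calls,
                                             out("interaction_calls.csv"))
  files["interaction_summary"] <- .write_stage(
    surv$summary, out("interaction_summary.csv"))

  # --- trade-offs ---
  tern <- stage("tradeoffs", ternary_coordinates(std))
  files["ternary"] <- .write_stage(tern, out("ternary.csv"))

  manifest <- list(
    seed = config$seed,
    standardize_mode = config$standardize_mode,
    test_type = config$test_type,
    bootstrap = config$bootstrap,
    rule = config$rule,
    versions = list(
      multistress = as.character(utils::packageVersion("multistress")),
      R = paste(R.version$major, R.version$minor, sep = "."),
      lme4 = as.character(utils::packageVersion("lme4")),
      survival = as.character(utils::packageVersion("survival"))),
    files = lapply(files, function(f) list(
      path = basename(f), md5 = unname(tools::md5sum(f)))),
    log = log)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
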