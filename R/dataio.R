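# Tabular data model: treatment arms, CSV dialect, validation and the
# per-batch control standardization applied before every downstream analysis.

#' The nine treatment arms of the factorial design
#'
#' Two algae (food) levels and two insecticide (Carbaryl) concentrations are
#' applied singly and in factorial combination, alongside a stress-free
#' control fed ad libitum. Arm codes follow the field convention:
#' HA/LA = high/low algae, HI/LI = high/low insecticide, and the four
#' combinations HAHI, HALI, LAHI, LALI. The code is a bijection with the
#' (algae_level, insecticide_level) pair.
#'
#' Concentration metadata: algae in mg C/L (0.8 control feeding, 0.2 low,
#' 2.4 high), Carbaryl in micrograms/L (0 none, 4 low, 8 high).
#'
#' @return a data.frame with columns `code`, `algae_level`,
#'   `insecticide_level`, `algae_mgC`, `carbaryl_ugL`.
#' @export
treatment_arms <- function() {
  data.frame(
    code = c("CTRL", "HA", "LA", "HI", "LI", "HAHI", "HALI", "LAHI", "LALI"),
    algae_level = c("control", "high", "low", "control", "control",
                    "high", "high", "low", "low"),
    insecticide_level = c("none", "none", "none", "high", "low",
                          "high", "low", "high", "low"),
    algae_mgC = c(0.8, 2.4, 0.2, 0.8, 0.8, 2.4, 2.4, 0.2, 0.2),
    carbaryl_ugL = c(0, 0, 0, 8, 4, 8, 4, 8, 4),
    stringsAsFactors = FALSE
  )
}

#' Map (algae_level, insecticide_level) pairs to arm codes
#'
#' @param algae_level character vector in `{control, low, high}`.
#' @param insecticide_level character vector in `{none, low, high}`.
#' @return character vector of arm codes.
#' @export
arm_code <- function(algae_level, insecticide_level) {
  arms <- treatment_arms()
  key <- paste(algae_level, insecticide_level, sep = "|")
  tab <- stats::setNames(arms$code,
                         paste(arms$algae_level, arms$insecticide_level,
                               sep = "|"))
  out <- tab[key]
  if (anyNA(out)) {
    bad <- unique(key[is.na(out)])
    stop("unknown treatment level combination(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  unname(out)
}

#' Expand an arm code back to its factor levels
#'
#' @param code character vector of arm codes.
#' @return data.frame with `algae_level` and `insecticide_level`.
#' @export
arm_levels <- function(code) {
  arms <- treatment_arms()
  i <- match(code, arms$code)
  if (anyNA(i)) {
    stop("unknown arm code(s): ",
         paste(unique(code[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  arms[i, c("algae_level", "insecticide_level")]
}

.trait_cols <- function() c("fecundity", "size_mm", "age_days")

.obs_cols <- function() {
  c("population", "genotype", "batch", "algae_level", "insecticide_level",
    "replicate", "fecundity", "size_mm", "age_days", "death_day", "event")
}

#' Validate a table of observation records
#'
#' Checks labels, trait ranges, the censoring invariant (a censored animal's
#' `death_day` equals the common censoring day) and duplicate
#' (population, genotype, arm, batch, replicate) keys. Errors name the
#' offending row and field.
#'
#' @param records data.frame of observation records.
#' @param populations allowed population labels.
#' @param check_ranges enforce raw-scale trait ranges (fecundity >= 0,
#'   size/age > 0). Disable when reading batch-standardized files, whose
#'   traits are legitimately negative.
#' @return the validated records, invisibly augmented with an `arm` column.
#' @export
validate_observations <- function(records,
                                  populations = c("EP", "PP", "CWP"),
                                  check_ranges = TRUE) {
  need <- setdiff(.obs_cols(), names(records))
  if (length(need)) {
    stop("missing column(s): ", paste(need, collapse = ", "), call. = FALSE)
  }
  bad_pop <- which(!records$population %in% populations)
  if (length(bad_pop)) {
    stop(sprintf("row %d: unknown population '%s'", bad_pop[1],
                 records$population[bad_pop[1]]), call. = FALSE)
  }
  arms <- treatment_arms()
  bad_a <- which(!records$algae_level %in% unique(arms$algae_level))
  if (length(bad_a)) {
    stop(sprintf("row %d: unknown algae_level '%s'", bad_a[1],
                 records$algae_level[bad_a[1]]), call. = FALSE)
  }
  bad_i <- which(!records$insecticide_level %in%
                   unique(arms$insecticide_level))
  if (length(bad_i)) {
    stop(sprintf("row %d: unknown insecticide_level '%s'", bad_i[1],
                 records$insecticide_level[bad_i[1]]), call. = FALSE)
  }
  for (fld in if (check_ranges) c("fecundity", "size_mm", "age_days")
       else character()) {
    v <- records[[fld]]
    lim <- if (fld == "fecundity") 0 else .Machine$double.eps
    bad <- which(!is.na(v) & v < lim)
    if (length(bad)) {
      stop(sprintf("row %d: field '%s' must be %s (got %g)", bad[1], fld,
                   if (fld == "fecundity") ">= 0" else "> 0", v[bad[1]]),
           call. = FALSE)
    }
  }
  bad_d <- which(is.na(records$death_day) | records$death_day <= 0)
  if (length(bad_d)) {
    stop(sprintf("row %d: field 'death_day' must be > 0", bad_d[1]),
         call. = FALSE)
  }
  if (!is.logical(records$event)) {
    stop("field 'event' must be logical", call. = FALSE)
  }
  cens <- records$death_day[!records$event]
  if (length(cens) && length(unique(cens)) > 1L) {
    stop("censored records carry differing death_day values; ",
         "event = FALSE requires death_day equal to the censoring day",
         call. = FALSE)
  }
  records$arm <- arm_code(records$algae_level, records$insecticide_level)
  key <- paste(records$population, records$genotype, records$arm,
               records$batch, records$replicate, sep = "|")
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop(sprintf("row %d: duplicate (population, genotype, arm, batch, replicate) key '%s'",
                 dup[1], key[dup[1]]), call. = FALSE)
  }
  invisible(records)
}

#' Read observation records from the long-format CSV dialect
#'
#' Dialect: UTF-8, comma-separated, header
#' `population,genotype,batch,algae_level,insecticide_level,replicate,fecundity,size_mm,age_days,death_day,event`;
#' missing trait cells are empty. Records are validated and an `arm` code
#' column is derived; a per population x arm row-count summary is emitted
#' as a message.
#'
#' @param path CSV file path.
#' @param quiet suppress the row-count summary message.
#' @param check_ranges enforce raw-scale trait ranges; set `FALSE` for
#'   batch-standardized files.
#' @return a validated data.frame of observation records with `arm` column.
#' @export
read_observations <- function(path, quiet = FALSE, check_ranges = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(
                          population = "character", genotype = "character",
                          batch = "character",
                          algae_level = "character",
                          insecticide_level = "character",
                          replicate = "integer",
                          fecundity = "numeric", size_mm = "numeric",
                          age_days = "numeric", death_day = "numeric",
                          event = "logical"))
  df <- validate_observations(df, check_ranges = check_ranges)
  if (!quiet) {
    tab <- table(df$population, df$arm)
    message(sprintf("read %d records: %d populations x %d arms (batches: %s)",
                    nrow(df), nrow(tab), ncol(tab),
                    paste(sort(unique(df$batch)), collapse = ",")))
  }
  df
}

#' Write observation records in the long-format CSV dialect
#'
#' @param records data.frame of observation records.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(records, path) {
  utils::write.csv(records[, .obs_cols()], path, row.names = FALSE,
                   na = "", quote = FALSE)
  invisible(path)
}

#' Standardize traits against the per-batch control group
#'
#' Experiments run in several batches are put on a common footing using the
#' control arm of each batch. Two modes:
#' \describe{
#'   \item{`paper_literal`}{subtract the control-group sample standard
#'     deviation: `y - sd(control)` computed per batch and trait. This is a
#'     constant per-batch shift whose size tracks control spread, not
#'     control location.}
#'   \item{`mean_centered`}{subtract the control-group mean:
#'     `y - mean(control)`, the conventional batch-location correction.}
#' }
#' Both are per-batch affine shifts, so all within-batch differences are
#' preserved exactly. Missing trait values propagate; nothing is imputed.
#' The control statistic uses the sample (n-1) standard deviation and only
#' control-arm records of the same batch.
#'
#' @param records data.frame of observation records (validated or raw).
#' @param mode `"paper_literal"` (default) or `"mean_centered"`.
#' @param traits trait columns to standardize.
#' @return records with standardized trait columns.
#' @export
standardize_batches <- function(records,
                                mode = c("paper_literal", "mean_centered"),
                                traits = .trait_cols()) {
  mode <- match.arg(mode)
  if (is.null(records$arm)) {
    records$arm <- arm_code(records$algae_level, records$insecticide_level)
  }
  batches <- unique(records$batch)
  for (b in batches) {
    in_b <- records$batch == b
    ctrl <- in_b & records$arm == "CTRL"
    if (!any(ctrl)) {
      stop(sprintf("batch '%s' has no control-arm records", b),
           call. = FALSE)
    }
    for (tr in traits) {
      v <- records[[tr]][ctrl]
      v <- v[!is.na(v)]
      if (length(v) < 2L) {
        stop(sprintf(
          "batch '%s': control %s has %d non-missing value(s); need >= 2",
          b, tr, length(v)), call. = FALSE)
      }
      shift <- if (mode == "paper_literal") stats::sd(v) else mean(v)
      records[[tr]][in_b] <- records[[tr]][in_b] - shift
    }
  }
  records
}
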