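# Ternary trade-off coordinates among fecundity, size at maturity and age
# at maturity. Each trait is z-scored across the whole dataset, placed into
# its percentile bin (1..100, average ranks so ties share a bin), and each
# animal's three bins are normalized to a three-part proportion; groups are
# the mean of individual proportions, renormalized to sum to one.
# Because binning is rank-based the coordinates are invariant to any
# strictly increasing transform of a single trait; the z-scoring step is
# rank-neutral but retained for fidelity to the stated procedure.

#' Ternary trade-off coordinates per population x arm
#'
#' Individuals missing any of the three traits are excluded from this
#' analysis only. Binning is dataset-wide, so positions are comparable
#' across treatments.
#'
#' @param records observation records.
#' @param traits the three traits, in coordinate order.
#' @return data.frame `population, arm, f_fecundity, f_size, f_age, n`;
#'   each coordinate in \[0, 1\], rows summing to 1.
#' @export
ternary_coordinates <- function(records,
                                traits = c("fecundity", "size_mm",
                                           "age_days")) {
  stopifnot(length(traits) == 3L)
  if (is.null(records$arm)) {
    records$arm <- arm_code(records$algae_level, records$insecticide_level)
  }
  keep <- stats::complete.cases(records[, traits])
  d <- records[keep, , drop = FALSE]
  if (!nrow(d)) stop("no records with all three traits present",
                     call. = FALSE)
  n <- nrow(d)
  bins <- sapply(traits, function(tr) {
    v <- d[[tr]]
    if (stats::sd(v) == 0) {
      stop("trait '", tr, "' is constant; percentile bins undefined",
           call. = FALSE)
    }
    z <- (v - mean(v)) / stats::sd(v)         # rank-neutral, kept for fidelity
    r <- rank(z, ties.method = "average")
    pmax(ceiling(100 * r / n), 1)
  })
  prop <- bins / rowSums(bins)

  key <- paste(d$population, d$arm, sep = "|")
  groups <- unique(key)
  out <- do.call(rbind, lapply(groups, function(k) {
    i <- key == k
    m <- colMeans(prop[i, , drop = FALSE])
    m <- m / sum(m)
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    data.frame(population = parts[1], arm = parts[2],
               f_fecundity = m[1], f_size = m[2], f_age = m[3],
               n = sum(i), stringsAsFactors = FALSE, row.names = NULL)
  }))
  out[order(out$population, out$arm), , drop = FALSE]
}
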