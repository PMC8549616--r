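# Internal helpers shared across modules.

#' Derive a reproducible sub-seed from a global seed and a stream tag
#'
#' All randomness in the package flows from one integer seed; independent
#' random streams (genotype draws, batch draws, residuals, survival,
#' bootstrap cells) are keyed by a string tag so that subsets of a run are
#' reproducible on their own. The derived seed is always in \[1, 2^31 - 2\].
#'
#' @param seed integer global seed.
#' @param tag character stream label.
#' @return an integer seed.
#' @export
sub_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  codes <- utf8ToInt(tag)
  # small polynomial string hash, kept well inside double precision
  h <- 0
  for (k in codes) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 48271 + h) %% 2147483645 + 1)
}

# Evaluate `code` under a local RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() with a consistent prefix so CLI errors are attributable to a stage
stop_stage <- function(stage, msg) {
  stop(sprintf("[%s] %s", stage, msg), call. = FALSE)
}
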