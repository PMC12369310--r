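#' Derive a per-stage random seed
#'
#' The pipeline uses one master seed but several stochastic stages (spike
#' simulation, NNMF restarts, k-means, surrogate shuffles). Each stage draws
#' from its own reproducible stream so that adding draws to one stage never
#' perturbs another. The stage seed is a deterministic hash of the master
#' seed and the stage name, kept below 2^31 - 1.
#'
#' @param seed Integer master seed.
#' @param stage Character stage name, e.g. `"nnmf"`.
#' @return A single integer in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @examples
#' stage_seed(7, "nnmf")
#' stage_seed(7, "kmeans")
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.character(stage), length(stage) == 1L, nzchar(stage))
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% m
  # mix the master seed in with two multiplicative rounds
  s <- (abs(as.numeric(seed)) %% m)
  x <- (h + 1) * 48271 %% m
  x <- (x + s * 69621) %% m
  x <- (x * 16807 + h + s) %% m
  as.integer(x %% (m - 2)) + 1L
}

#' Evaluate an expression under a stage-specific seed
#'
#' Sets the RNG to a stream derived from `(seed, stage)`, evaluates `expr`,
#' and restores the caller's RNG state afterwards.
#'
#' @inheritParams stage_seed
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_stage_seed <- function(seed, stage, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stage_seed(seed, stage))
  expr
}
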