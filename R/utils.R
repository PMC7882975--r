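#' Derive a reproducible sub-stream seed from a global seed and a stage name
#'
#' Experiments are driven by one global integer seed; each stage (landscape
#' generation, background draws, subsampling, member fits, ...) derives its own
#' seed by stable hashing of `(seed, stage)`, so a stage can be rerun in
#' isolation and still reproduce the exact stream it saw inside the full run.
#'
#' The hash is a plain polynomial rolling hash over the stage string, folded
#' with the seed modulo a Mersenne prime; it is implementation-stable (no
#' dependence on R's own RNG or on platform hashing).
#'
#' @param seed Integer global seed.
#' @param stage Character scalar naming the stage.
#' @return An integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
#' @examples
#' substream_seed(1, "landscape") != substream_seed(1, "background")
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage),
            length(stage) == 1L)
  m <- 2147483647 # 2^31 - 1, keeps exact double arithmetic well below 2^53
  h <- as.double(seed) %% m
  for (k in utf8ToInt(stage)) {
    h <- (h * 131 + k) %% m
  }
  as.integer(h)
}

#' Round half away from zero (round-half-up for non-negative input)
#'
#' Fractional subsample sizes use commercial rounding, not banker's rounding:
#' `round_half_up(0.5) == 1`. For example 5% of 670 presence cells is 33.5,
#' retained as 34.
#'
#' @param x Numeric vector, assumed non-negative in this package's use.
#' @return Integer vector.
#' @export
round_half_up <- function(x) {
  as.integer(floor(x + 0.5 + 1e-9))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Inverse logit
#' @noRd
plogis_ <- function(x) 1 / (1 + exp(-x))
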