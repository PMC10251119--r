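#' Park-Miller minimal-standard random number stream
#'
#' The simulator draws every random number from a Park-Miller
#' (Lehmer) multiplicative congruential generator,
#' \eqn{s' = 16807 \, s \bmod (2^{31} - 1)}, with the deviate
#' \eqn{u = s' / (2^{31} - 1) \in (0, 1)}. One stream is consumed per
#' run, so a seed fully determines a run's randomness and the same seed
#' can be replayed with altered kinetics -- the core experimental
#' manipulation this package supports.
#'
#' @param state Current generator state, an integer in
#'   `[1, 2^31 - 2]`. The seed is the initial state.
#' @return `park_miller_next()` returns a list with elements `state`
#'   (the advanced state) and `deviate` (a uniform deviate in (0, 1)).
#' @examples
#' s <- park_miller_next(1)
#' s$state # 16807
#' park_miller_next(s$state)$state # 282475249
#' @export
park_miller_next <- function(state) {
  check_pm_state(state)
  pm_next_cpp(state)
}

#' Draw a block of uniform deviates from a Park-Miller stream
#'
#' @inheritParams park_miller_next
#' @param n Number of deviates to draw.
#' @return List with `state` (advanced state) and `deviates`
#'   (numeric vector of length `n`).
#' @export
park_miller_draws <- function(state, n) {
  check_pm_state(state)
  stopifnot(is.numeric(n), length(n) == 1, n >= 1)
  pm_draws_cpp(state, as.integer(n))
}

check_pm_state <- function(state) {
  if (!is.numeric(state) || length(state) != 1 || is.na(state) ||
      state != trunc(state) || state < 1 || state > 2^31 - 2) {
    abort("Park-Miller state/seed must be a single integer in [1, 2^31 - 2]",
          class = "driftbalance_invalid_seed")
  }
  invisible(state)
}
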