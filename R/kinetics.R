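#' Monod kinetic parameter set
#'
#' Bundles the three Monod parameters of a heterotroph: the maximum
#' specific growth rate `mu_max` (1/h), the half-saturation constant
#' `K_s` (kg m^-3) and the biomass yield on substrate (kg biomass per
#' kg substrate). The defaults are the baseline organism used
#' throughout: `mu_max = 1` 1/h, `K_s = 3.5e-5` kg m^-3, yield 0.61.
#'
#' @param mu_max Maximum specific growth rate (1/h), > 0.
#' @param K_s Half-saturation constant (kg m^-3), > 0.
#' @param yield Biomass yield (kg/kg), > 0.
#' @return An object of class `kinetics` (named list).
#' @examples
#' kinetics()
#' kinetics(mu_max = 1.2, K_s = 1.75e-5)
#' @export
kinetics <- function(mu_max = 1, K_s = 3.5e-5, yield = 0.61) {
  stopifnot(is.numeric(mu_max), is.numeric(K_s), is.numeric(yield))
  if (mu_max <= 0 || K_s <= 0 || yield <= 0) {
    abort("all kinetic parameters must be strictly positive",
          class = "driftbalance_invalid_kinetics")
  }
  structure(list(mu_max = mu_max, K_s = K_s, yield = yield),
            class = "kinetics")
}

#' @export
print.kinetics <- function(x, ...) {
  cat(sprintf("Monod kinetics: mu_max = %g 1/h, K_s = %g kg m^-3, yield = %g\n",
              x$mu_max, x$K_s, x$yield))
  invisible(x)
}

#' Monod growth rate
#'
#' Specific growth rate at substrate concentration `S`:
#' \eqn{\mu = \mu_{max} S / (K_s + S)}. Vectorised over `S`.
#'
#' @param kin A [kinetics()] object.
#' @param S Substrate concentration(s), kg m^-3, >= 0.
#' @return Growth rate(s) in 1/h, bounded in `[0, mu_max)`.
#' @examples
#' monod_rate(kinetics(), 1e-4) # 0.7407... at the bulk concentration
#' monod_rate(kinetics(), kinetics()$K_s) # exactly mu_max / 2
#' @export
monod_rate <- function(kin, S) {
  stopifnot(inherits(kin, "kinetics"))
  if (any(S < 0)) {
    abort("substrate concentration must be non-negative",
          class = "driftbalance_negative_substrate")
  }
  kin$mu_max * S / (kin$K_s + S)
}

#' Apply a percent change to Monod kinetics
#'
#' Scales `K_s` and/or `mu_max` by `(1 + pct/100)`; yield is untouched.
#' This is the kinetic alteration handed to a re-run's loser lineage.
#'
#' @param kin A [kinetics()] object.
#' @param dKs_pct,dmu_pct Percent changes (e.g. -50 to 50).
#' @return A new `kinetics` object.
#' @export
alter_kinetics <- function(kin, dKs_pct = 0, dmu_pct = 0) {
  stopifnot(inherits(kin, "kinetics"))
  if (dKs_pct <= -100) {
    abort("dKs_pct <= -100 would make K_s non-positive",
          class = "driftbalance_invalid_kinetics")
  }
  if (dmu_pct <= -100) {
    abort("dmu_pct <= -100 would make mu_max non-positive",
          class = "driftbalance_invalid_kinetics")
  }
  kinetics(mu_max = kin$mu_max * (1 + dmu_pct / 100),
           K_s = kin$K_s * (1 + dKs_pct / 100),
           yield = kin$yield)
}
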