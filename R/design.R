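#' The full factorial design grid
#'
#' All combinations of the four experimental factors: spacing (2.5, 5,
#' 10 cell diameters), initial population size (4, 9, 16), and percent
#' changes to the loser's half-saturation constant and maximum growth
#' rate (-50 to 50 in steps of 10). The full grid has
#' `3 * 3 * 11 * 11 = 1089` combinations, ordered by spacing, then
#' population, then `dKs_pct`, then `dmu_pct`, all ascending.
#'
#' @param spacings,populations,dKs_pct,dmu_pct Factor levels; defaults
#'   are the full design.
#' @return Tibble with columns `spacing, n_initial, dKs_pct, dmu_pct`.
#' @examples
#' nrow(factor_grid()) # 1089
#' @export
factor_grid <- function(spacings = c(2.5, 5, 10),
                        populations = c(4, 9, 16),
                        dKs_pct = seq(-50, 50, by = 10),
                        dmu_pct = seq(-50, 50, by = 10)) {
  tidyr::expand_grid(spacing = sort(spacings),
                     n_initial = sort(as.integer(populations)),
                     dKs_pct = sort(dKs_pct),
                     dmu_pct = sort(dmu_pct))
}

#' Enumerate a paired-seed run manifest
#'
#' Crosses a factor grid with seeds `1..n_seeds` (or an explicit seed
#' vector). The same seeds are reused across every combination -- the
#' paired design that lets a re-run replay exactly the randomness of
#' its baseline.
#'
#' @param grid A [factor_grid()] (or any combination tibble).
#' @param n_seeds Number of seeds.
#' @param seeds Optional explicit seed vector (overrides `n_seeds`).
#' @return Manifest tibble: the grid columns plus `seed`; one row per
#'   (combination, seed).
#' @examples
#' nrow(enumerate_runs(factor_grid(), 120)) # 130680
#' @export
enumerate_runs <- function(grid, n_seeds = 120, seeds = NULL) {
  if (is.null(seeds)) {
    stopifnot(n_seeds >= 1)
    seeds <- seq_len(n_seeds)
  }
  purrr::walk(seeds, check_pm_state)
  if (anyDuplicated(seeds)) {
    abort("seeds must be distinct", class = "driftbalance_config_error")
  }
  tidyr::expand_grid(grid, seed = as.integer(seeds))
}

#' Identify the biggest loser of a run
#'
#' The lineage with the lowest final relative biomass; ties resolve to
#' the lowest lineage id.
#'
#' @param result A `run_result`, or a numeric vector of per-lineage
#'   final fractions (lineage ids taken as positions).
#' @return The losing lineage id (integer).
#' @examples
#' biggest_loser(c(0.50, 0.30, 0.15, 0.05)) # 4
#' biggest_loser(c(0.25, 0.25, 0.25, 0.25)) # 1, tie rule
#' @export
biggest_loser <- function(result) {
  fractions <- if (inherits(result, "run_result")) {
    result$final_fractions
  } else {
    result
  }
  if (length(fractions) == 0) {
    abort("cannot identify a loser in an empty result",
          class = "driftbalance_empty_result")
  }
  as.integer(which.min(fractions)) # which.min takes the first minimum
}

#' Build the re-run configuration for a baseline run
#'
#' Replays a baseline run's seed with the baseline's biggest loser
#' given kinetics scaled by `(1 + pct/100)`; all other lineages keep
#' the base kinetics. With `dKs_pct = dmu_pct = 0` the re-run
#' reproduces the baseline exactly.
#'
#' @param baseline A `run_result` from a baseline (no-override) run.
#' @param dKs_pct,dmu_pct Percent changes applied to the loser's
#'   half-saturation constant and maximum growth rate.
#' @return A [sim_config()] with `loser_override` set.
#' @export
rerun_config <- function(baseline, dKs_pct = 0, dmu_pct = 0) {
  stopifnot(inherits(baseline, "run_result"))
  cfg <- baseline$config
  cfg$loser_override <- list(lineage_id = baseline$loser_id,
                             dKs_pct = dKs_pct, dmu_pct = dmu_pct)
  # validate percent changes against the base kinetics
  alter_kinetics(cfg$base_kinetics, dKs_pct, dmu_pct)
  cfg
}

#' Build a re-run manifest from a baseline run table
#'
#' For every baseline run (rows of a long run table produced by
#' [simulate_runs()] with no kinetic override), emits one manifest row
#' per kinetic alteration in `grid`, carrying over the baseline's
#' crowding condition, seed and loser lineage.
#'
#' @param baseline_runs Long run table of baseline runs.
#' @param grid Tibble of `dKs_pct, dmu_pct` levels (defaults to the
#'   full 11 x 11 sweep).
#' @return Manifest tibble: `n_initial, spacing, seed, loser_id,
#'   dKs_pct, dmu_pct`.
#' @export
rerun_manifest <- function(baseline_runs,
                           grid = tidyr::expand_grid(
                             dKs_pct = seq(-50, 50, by = 10),
                             dmu_pct = seq(-50, 50, by = 10))) {
  baseline_runs <- tibble::as_tibble(baseline_runs)
  losers <- baseline_runs |>
    dplyr::filter(.data$is_loser) |>
    dplyr::select("n_initial", "spacing", "seed",
                  loser_id = "lineage_id")
  if (any(abs(grid$dKs_pct) > 0 | abs(grid$dmu_pct) > 0) &&
      any(grid$dKs_pct <= -100)) {
    abort("dKs_pct <= -100 would make K_s non-positive",
          class = "driftbalance_invalid_kinetics")
  }
  tidyr::expand_grid(losers, grid)
}
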