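#' Configuration of one biofilm simulation run
#'
#' Collects every physical, kinetic and numerical parameter of a run.
#' Defaults are the study conditions: identical founder cells of
#' diameter 1e-6 m on an evenly spaced square grid at the base of a
#' cuboid 2e-4 m tall, bulk substrate 1e-4 kg m^-3 held at the top
#' boundary, periodic X/Y, division threshold 1.36e-6 m, and growth
#' until biomass occupies 20% of the full cuboid volume.
#'
#' The cuboid's X and Y edges are `sqrt(n_initial) * spacing *
#' initial_diameter`, so founders are uniformly spaced under the
#' periodic wrap.
#'
#' `domain_height` and `voxel_edge` are the resolution knobs for
#' desk-scale work: shrinking the height shrinks the biomass volume
#' needed to hit the stop fraction (the stop fraction is always
#' measured against the full cuboid). Dimensionless outcomes
#' (per-lineage biomass fractions and thriving probabilities) are the
#' quantities of interest and are insensitive to the biomass density
#' convention.
#'
#' @param n_initial Founder count; a perfect square (4, 9 or 16 in the
#'   factorial design).
#' @param spacing Founder separation in cell diameters (2.5, 5 or 10 in
#'   the design).
#' @param seed Positive integer seed for the Park-Miller stream, in
#'   `[1, 2^31 - 2]`.
#' @param initial_diameter Founder diameter (m).
#' @param division_diameter Division threshold diameter (m).
#' @param base_kinetics A [kinetics()] object shared by all founders.
#' @param domain_height Cuboid height (m).
#' @param stop_volume_fraction Stop when biomass reaches this fraction
#'   of the cuboid volume, in (0, 1).
#' @param bulk_concentration Substrate concentration fixed at the top
#'   boundary and used as the initial field value (kg m^-3).
#' @param substrate_diffusivity Substrate diffusion coefficient
#'   (m^2 s^-1); default 2.3e-9, a small solute in water.
#' @param voxel_edge Substrate grid voxel edge (m); rounded so voxels
#'   tile the domain.
#' @param biomass_density Dry biomass density rho (kg m^-3) in the
#'   sphere convention `m = rho * pi * d^3 / 6`. Any positive constant
#'   leaves dimensionless results unchanged.
#' @param dt Growth time step (h). The default `NULL` selects adaptive
#'   stepping: each step advances by `0.1 / max(mu)` over the current
#'   cells (so the fastest cell's relative mass change stays below
#'   ~10%), capped at `dt_max`. A fixed positive value disables
#'   adaptivity.
#' @param dt_max Upper bound on the adaptive step (h); reached only
#'   when the whole population is strongly substrate-starved.
#' @param loser_override Optional list
#'   `list(lineage_id =, dKs_pct =, dmu_pct =)` giving one lineage
#'   altered kinetics (the re-run protocol).
#' @param max_steps Step cap before the run errors out.
#' @param relax_tol Relative overlap tolerance of the mechanical
#'   relaxation (fraction of the pair's summed radii).
#' @param relax_max_iter Iteration cap for a standalone
#'   [relax_cells()] call (a warning is raised if reached).
#' @param relax_sweeps_per_step Sweep budget per growth step inside
#'   [simulate_run()]; overlaps left at the budget carry over and
#'   relax during subsequent steps (the count of such steps is
#'   reported in the run result).
#' @param substrate_tol Substrate solver convergence tolerance
#'   (relative to the bulk concentration).
#' @param substrate_max_iter Substrate solver sweep cap.
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_initial = 4, spacing = 5, seed = 1)
#' cfg$domain_width # 2 * 5 * 1e-6 m
#' @export
sim_config <- function(n_initial = 9,
                       spacing = 5,
                       seed = 1,
                       initial_diameter = 1e-6,
                       division_diameter = 1.36e-6,
                       base_kinetics = kinetics(),
                       domain_height = 2e-4,
                       stop_volume_fraction = 0.20,
                       bulk_concentration = 1e-4,
                       substrate_diffusivity = 2.3e-9,
                       voxel_edge = 5e-6,
                       biomass_density = 150,
                       dt = NULL,
                       dt_max = 24,
                       loser_override = NULL,
                       max_steps = 100000,
                       relax_tol = 1e-3,
                       relax_max_iter = 10000,
                       relax_sweeps_per_step = 20,
                       substrate_tol = 1e-5,
                       substrate_max_iter = 20000) {
  m <- sqrt(n_initial)
  if (length(n_initial) != 1 || n_initial < 1 || m != round(m)) {
    abort("n_initial must be a perfect square (e.g. 4, 9, 16)",
          class = "driftbalance_config_error")
  }
  check_pm_state(seed)
  stopifnot(inherits(base_kinetics, "kinetics"),
            spacing > 0, initial_diameter > 0,
            division_diameter > initial_diameter,
            domain_height > 0, bulk_concentration > 0,
            substrate_diffusivity > 0, voxel_edge > 0, biomass_density > 0)
  if (stop_volume_fraction <= 0 || stop_volume_fraction >= 1) {
    abort("stop_volume_fraction must lie in (0, 1)",
          class = "driftbalance_config_error")
  }
  if (!is.null(loser_override)) {
    stopifnot(is.list(loser_override),
              all(c("lineage_id", "dKs_pct", "dmu_pct") %in%
                    names(loser_override)))
    if (loser_override$lineage_id < 1 ||
        loser_override$lineage_id > n_initial) {
      abort("loser_override$lineage_id must name one of the founder lineages",
            class = "driftbalance_config_error")
    }
    # validates the percent changes
    alter_kinetics(base_kinetics, loser_override$dKs_pct,
                   loser_override$dmu_pct)
  }
  cfg <- list(
    n_initial = as.integer(n_initial), spacing = spacing,
    seed = as.integer(seed),
    initial_diameter = initial_diameter,
    division_diameter = division_diameter,
    base_kinetics = base_kinetics,
    domain_width = m * spacing * initial_diameter,
    domain_height = domain_height,
    stop_volume_fraction = stop_volume_fraction,
    bulk_concentration = bulk_concentration,
    substrate_diffusivity = substrate_diffusivity,
    voxel_edge = voxel_edge,
    biomass_density = biomass_density,
    dt = dt, dt_max = dt_max,
    loser_override = loser_override,
    max_steps = as.integer(max_steps),
    relax_tol = relax_tol, relax_max_iter = as.integer(relax_max_iter),
    relax_sweeps_per_step = as.integer(relax_sweeps_per_step),
    substrate_tol = substrate_tol,
    substrate_max_iter = as.integer(substrate_max_iter))
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d founders, %.1f diameters apart, seed %d\n",
    x$n_initial, x$spacing, x$seed))
  cat(sprintf("  domain %.3g x %.3g x %.3g m, stop at %.0f%% biomass volume\n",
              x$domain_width, x$domain_width, x$domain_height,
              100 * x$stop_volume_fraction))
  if (!is.null(x$loser_override)) {
    cat(sprintf("  loser override: lineage %d, dKs %+g%%, dmu %+g%%\n",
                x$loser_override$lineage_id, x$loser_override$dKs_pct,
                x$loser_override$dmu_pct))
  }
  invisible(x)
}

# fixed step if requested, otherwise a negative sentinel selecting the
# adaptive scheme in the C++ loop
effective_dt <- function(config) {
  if (!is.null(config$dt)) config$dt else -1
}

# conservative fixed step for single-step R-level work: <= 10% relative mass
# change for the fastest kinetics present (including a loser override)
default_fixed_dt <- function(config) {
  mu <- config$base_kinetics$mu_max
  if (!is.null(config$loser_override)) {
    mu <- max(mu, mu * (1 + config$loser_override$dmu_pct / 100))
  }
  0.1 / mu
}

#' Desk-scale preset of the simulation conditions
#'
#' The study conditions shrunk to laptop scale while preserving the
#' substrate supply/demand regime. The domain height is reduced, and
#' the diffusivity is reduced by the square of the height ratio so the
#' dimensionless group governing diffusion limitation
#' (uptake demand / diffusive supply, proportional to `H^2 / D`) is
#' unchanged from the full-scale conditions. The voxel grid is
#' refined to ~2 cell diameters so within-film substrate gradients --
#' the mechanism by which early random divisions compound into drift
#' -- remain resolved.
#'
#' @param ... Passed on to [sim_config()] (e.g. `n_initial`,
#'   `spacing`, `seed`, `loser_override`).
#' @param domain_height Reduced cuboid height (m).
#' @param full_height The full-scale height being emulated (m).
#' @param full_diffusivity Diffusivity at full scale (m^2 s^-1).
#' @return A [sim_config()].
#' @export
sim_config_desk <- function(..., domain_height = 1e-5,
                            full_height = 2e-4,
                            full_diffusivity = 2.3e-9) {
  sim_config(...,
             domain_height = domain_height,
             substrate_diffusivity =
               full_diffusivity * (domain_height / full_height)^2,
             voxel_edge = 2e-6)
}

# substrate grid dimensions matching the C++ rounding
grid_dims <- function(config) {
  nx <- max(1L, as.integer(round(config$domain_width / config$voxel_edge)))
  h <- config$domain_width / nx
  nz <- max(1L, as.integer(round(config$domain_height / h)))
  list(nx = nx, ny = nx, nz = nz, h = h)
}

#' Read or write a simulation configuration as YAML
#'
#' The YAML keys mirror the [sim_config()] arguments;
#' `base_kinetics` is a mapping with keys `mu_max`, `K_s`, `yield`, and
#' `loser_override` (if present) a mapping with `lineage_id`,
#' `dKs_pct`, `dmu_pct`.
#'
#' @param path File path.
#' @param config A `sim_config` object (for writing).
#' @return `read_sim_config()` returns a `sim_config`;
#'   `write_sim_config()` returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$base_kinetics)) {
    raw$base_kinetics <- do.call(kinetics, raw$base_kinetics)
  }
  do.call(sim_config, raw)
}

#' @rdname read_sim_config
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  out <- unclass(config)
  out$base_kinetics <- unclass(out$base_kinetics)
  out$domain_width <- NULL # derived
  yaml::write_yaml(out, path)
  invisible(path)
}
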