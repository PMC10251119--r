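#' Initialise the founder population and substrate field
#'
#' Places `sqrt(n) x sqrt(n)` identical founder cells on an evenly
#' spaced grid at the base of the cuboid (cell centres at one radius
#' above the substratum), assigns lineage identifiers 1..n in row-major
#' order, and fills the substrate voxel grid uniformly at the bulk
#' concentration. Under the periodic X/Y wrap every nearest-neighbour
#' centre distance equals `spacing * initial_diameter`, including
#' across the domain edges.
#'
#' @param config A [sim_config()].
#' @return A list with `cells` (a tibble: `x, y, z, diameter, mass,
#'   lineage, mu_max, K_s`, one row per founder) and `field` (a
#'   [substrate_field()]).
#' @examples
#' pop <- init_population(sim_config(n_initial = 4, spacing = 2.5))
#' pop$cells
#' @export
init_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  m <- as.integer(sqrt(config$n_initial))
  step <- config$spacing * config$initial_diameter
  coords <- (seq_len(m) - 0.5) * step
  grid <- tidyr::expand_grid(gy = coords, gx = coords) # row-major lineages
  kin <- config$base_kinetics
  rho <- config$biomass_density
  d0 <- config$initial_diameter
  cells <- tibble::tibble(
    x = grid$gx, y = grid$gy, z = d0 / 2,
    diameter = d0,
    mass = rho * pi * d0^3 / 6,
    lineage = seq_len(config$n_initial),
    mu_max = kin$mu_max,
    K_s = kin$K_s)
  if (!is.null(config$loser_override)) {
    ov <- config$loser_override
    altered <- alter_kinetics(kin, ov$dKs_pct, ov$dmu_pct)
    cells$mu_max[cells$lineage == ov$lineage_id] <- altered$mu_max
    cells$K_s[cells$lineage == ov$lineage_id] <- altered$K_s
  }
  list(cells = cells, field = substrate_field(config))
}

#' Substrate voxel field
#'
#' A 3-D voxel grid of substrate concentrations over the cuboid,
#' initialised uniformly at the bulk concentration. The top voxel layer
#' communicates with a fixed-value bulk boundary; the bottom is
#' zero-flux; X/Y are periodic.
#'
#' @param config A [sim_config()].
#' @return An object of class `substrate_field`: a list with `conc`
#'   (3-D array, kg m^-3), `voxel_edge` (m) and `bulk` (kg m^-3).
#' @export
substrate_field <- function(config) {
  g <- grid_dims(config)
  structure(
    list(conc = array(config$bulk_concentration, dim = c(g$nx, g$ny, g$nz)),
         voxel_edge = g$h,
         bulk = config$bulk_concentration),
    class = "substrate_field")
}

#' @export
print.substrate_field <- function(x, ...) {
  d <- dim(x$conc)
  cat(sprintf(
    "<substrate_field> %d x %d x %d voxels (edge %.3g m), bulk %.3g kg m^-3\n",
    d[1], d[2], d[3], x$voxel_edge, x$bulk))
  cat(sprintf("  concentration range [%.3g, %.3g]\n",
              min(x$conc), max(x$conc)))
  invisible(x)
}
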