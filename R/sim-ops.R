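#' Divide a cell into two daughters
#'
#' The first daughter receives a biomass fraction drawn uniformly from
#' (0.4, 0.6); the second receives the remainder, so mass is conserved
#' exactly. Both daughters inherit the parent's lineage and kinetics.
#' The daughters are placed tangent to each other along a direction
#' drawn uniformly on the unit sphere, centred on the parent position.
#' Three Park-Miller draws are consumed in fixed order: biomass
#' fraction, direction z-component, azimuth.
#'
#' @param cell One-row tibble (or list) with `x, y, z, diameter, mass,
#'   lineage, mu_max, K_s`.
#' @param state Park-Miller state.
#' @param config A [sim_config()] supplying the division threshold and
#'   the mass-diameter density convention.
#' @return List with `daughters` (two-row tibble) and `state`.
#' @export
divide_cell <- function(cell, state, config = sim_config()) {
  cell <- as.list(cell)
  if (cell$diameter <= config$division_diameter) {
    abort(sprintf(
      "cell diameter %.3g m is not above the division threshold %.3g m",
      cell$diameter, config$division_diameter),
      class = "driftbalance_division_error")
  }
  rho <- config$biomass_density
  dr <- division_draws_cpp(state)
  m1 <- dr$f * cell$mass
  m2 <- cell$mass - m1
  d1 <- diam_from_mass(m1, rho)
  d2 <- diam_from_mass(m2, rho)
  half <- (d1 + d2) / 4 # half of the tangent centre separation r1 + r2
  u <- c(dr$ux, dr$uy, dr$uz)
  daughters <- tibble::tibble(
    x = cell$x + c(half, -half) * u[1],
    y = cell$y + c(half, -half) * u[2],
    z = pmax(c(d1, d2) / 2, cell$z + c(half, -half) * u[3]),
    diameter = c(d1, d2),
    mass = c(m1, m2),
    lineage = rep(cell$lineage, 2),
    mu_max = rep(cell$mu_max, 2),
    K_s = rep(cell$K_s, 2))
  L <- config$domain_width
  daughters$x <- daughters$x %% L
  daughters$y <- daughters$y %% L
  list(daughters = daughters, state = dr$state)
}

diam_from_mass <- function(mass, density) {
  (6 * mass / (density * pi))^(1 / 3)
}

#' First-daughter biomass fractions along a division stream
#'
#' Draws the biomass fractions that `n` consecutive divisions would
#' hand to their first daughters, consuming the Park-Miller stream in
#' the same fixed order as [divide_cell()] (fraction, direction
#' z-component, azimuth -- three draws per division). Useful for
#' calibration checks of the 40-60% uniform allocation rule without
#' simulating geometry.
#'
#' @param state Park-Miller state (the seed for a fresh stream).
#' @param n Number of divisions.
#' @return List with `fractions` (numeric, each in (0.4, 0.6)) and the
#'   advanced `state`.
#' @examples
#' f <- division_fractions(1, 1000)$fractions
#' range(f)
#' @export
division_fractions <- function(state, n) {
  check_pm_state(state)
  dr <- pm_draws_cpp(state, 3L * as.integer(n))
  list(fractions = 0.4 + 0.2 * dr$deviates[seq(1, by = 3,
                                               length.out = n)],
       state = dr$state)
}

#' Mechanically relax overlapping cells
#'
#' Repeatedly pushes every overlapping sphere pair apart along the line
#' of centres, half the overlap each, until the worst relative overlap
#' drops below `config$relax_tol` or the iteration cap is reached (a
#' warning is raised and the current state returned). X/Y positions
#' wrap periodically; z is clamped to keep cells above the substratum.
#' This emulates the "shoving into empty space" that follows division
#' without calibrating explicit contact mechanics.
#'
#' @param cells Tibble with at least `x, y, z, diameter`.
#' @param config A [sim_config()].
#' @return The relaxed cells tibble (other columns preserved), with
#'   attributes `iterations` and `converged`.
#' @export
relax_cells <- function(cells, config = sim_config()) {
  res <- relax_cells_cpp(cells$x, cells$y, cells$z, cells$diameter,
                         config$domain_width, config$domain_width,
                         config$domain_height, config$relax_tol,
                         config$relax_max_iter)
  if (!res$converged) {
    warn(sprintf("relaxation hit the iteration cap (%d) before converging",
                 config$relax_max_iter))
  }
  out <- cells
  out$x <- res$x
  out$y <- res$y
  out$z <- res$z
  attr(out, "iterations") <- res$iterations
  attr(out, "converged") <- res$converged
  out
}

#' Solve the substrate field to diffusion-reaction steady state
#'
#' Given the current biomass distribution, solves
#' \eqn{D \nabla^2 S = \sum \mu_i m_i / Y} (uptake apportioned to each
#' cell's voxel) with the top boundary fixed at the bulk concentration,
#' a zero-flux floor and periodic X/Y walls. Growth is slow relative to
#' diffusion at these length scales, so the field is treated as
#' quasi-static: each growth step sees the steady state for the current
#' biomass.
#'
#' @param field A [substrate_field()].
#' @param cells Cells tibble (`x, y, z, mass, mu_max, K_s`).
#' @param config A [sim_config()].
#' @return The updated `substrate_field`; concentrations lie in
#'   `[0, bulk]` everywhere.
#' @export
solve_substrate <- function(field, cells, config = sim_config()) {
  stopifnot(inherits(field, "substrate_field"))
  d <- dim(field$conc)
  D_h <- config$substrate_diffusivity * 3600 # m^2/h
  res <- solve_substrate_cpp(
    as.numeric(field$conc), d[1], d[2], d[3], field$voxel_edge,
    field$bulk, D_h,
    cells$x, cells$y, cells$z, cells$mass, cells$mu_max, cells$K_s,
    config$base_kinetics$yield, config$substrate_tol,
    config$substrate_max_iter,
    config$domain_width, config$domain_width, config$domain_height)
  field$conc <- array(res$S, dim = d)
  field
}

#' Advance the population one growth step
#'
#' Each cell's mass is multiplied by `exp(mu * dt)` with `mu` the Monod
#' rate at its voxel's substrate concentration; diameters follow the
#' sphere-density convention; cells above the division threshold divide
#' (consuming the Park-Miller stream in cell-index order); and the
#' population is mechanically relaxed.
#'
#' @param cells Cells tibble.
#' @param field A [substrate_field()] (typically fresh from
#'   [solve_substrate()]).
#' @param dt Time step (h); `dt = 0` returns the state unchanged.
#' @param state Park-Miller state.
#' @param config A [sim_config()].
#' @return List with `cells` (updated tibble) and `state`.
#' @export
grow_step <- function(cells, field, dt, state, config = sim_config()) {
  stopifnot(dt >= 0)
  check_pm_state(state)
  d <- dim(field$conc)
  res <- grow_step_cpp(
    cells$x, cells$y, cells$z, cells$diameter, cells$mass,
    as.integer(cells$lineage), cells$mu_max, cells$K_s,
    as.numeric(field$conc), d[1], d[2], d[3], field$voxel_edge,
    dt, config$biomass_density, config$division_diameter, state,
    config$domain_width, config$domain_width, config$domain_height,
    config$relax_tol, config$relax_max_iter)
  out <- tibble::tibble(
    x = res$x, y = res$y, z = res$z, diameter = res$diameter,
    mass = res$mass, lineage = res$lineage, mu_max = res$mumax,
    K_s = res$Ks)
  if (!res$relax_converged) {
    warn("relaxation hit the iteration cap during grow_step")
  }
  list(cells = out, state = res$state)
}
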