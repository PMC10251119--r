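#' Run one biofilm simulation to the stop criterion
#'
#' Alternates quasi-static substrate solves with growth steps until the
#' summed cell volume reaches `stop_volume_fraction` of the cuboid.
#' Output is bit-identical for identical `(config, seed)`.
#'
#' @param config A [sim_config()].
#' @param return_cells If `TRUE`, the final cell table is attached
#'   (positions, diameters, masses, lineages).
#' @return An object of class `run_result`: per-lineage final relative
#'   biomass (`final_fractions`, summing to 1), the `loser_id`
#'   (minimum fraction, ties to the lowest lineage id), the three-way
#'   `status` classification of each lineage, `n_steps`, `n_cells`,
#'   the achieved `volume_fraction`, the count of relaxation-cap
#'   warnings, the seed and a config echo.
#' @examples
#' \donttest{
#' cfg <- sim_config(n_initial = 4, spacing = 5, seed = 7,
#'                   domain_height = 1e-5)
#' res <- simulate_run(cfg)
#' res$final_fractions
#' tidy(res)
#' }
#' @export
simulate_run <- function(config, return_cells = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  pop <- init_population(config)
  cells <- pop$cells
  kin <- config$base_kinetics
  g <- grid_dims(config)
  res <- run_sim_cpp(
    cells$x, cells$y, cells$z, cells$diameter, cells$mass,
    as.integer(cells$lineage), cells$mu_max, cells$K_s, kin$yield,
    config$domain_width, config$domain_width, config$domain_height,
    config$bulk_concentration, config$substrate_diffusivity * 3600,
    config$voxel_edge, effective_dt(config), config$dt_max,
    config$biomass_density,
    config$division_diameter, config$stop_volume_fraction,
    config$seed, config$max_steps, config$relax_tol,
    config$relax_sweeps_per_step, config$substrate_tol,
    config$substrate_max_iter, return_cells)
  fractions <- res$lineage_mass / sum(res$lineage_mass)
  n <- config$n_initial
  out <- structure(list(
    final_fractions = setNames(fractions, seq_len(n)),
    loser_id = biggest_loser(fractions),
    status = classify_status(fractions, expected_abundance(1, n)),
    n_steps = res$n_steps,
    n_cells = res$n_cells,
    sim_time = res$sim_time,
    volume_fraction = res$volume_fraction,
    relax_warnings = res$relax_warnings,
    seed = config$seed,
    config = config), class = "run_result")
  if (return_cells) out$cells <- tibble::as_tibble(res$cells)
  out
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf(
    "<run_result> seed %d: %d lineages, %d cells after %d steps (%.1f%% volume)\n",
    x$seed, length(x$final_fractions), x$n_cells, x$n_steps,
    100 * x$volume_fraction))
  cat("  fractions:", paste(sprintf("%.3f", x$final_fractions),
                            collapse = " "), "\n")
  cat(sprintf("  biggest loser: lineage %d (%s)\n", x$loser_id,
              x$status[x$loser_id]))
  invisible(x)
}

#' Tidy a run result into the long run-table schema
#'
#' One row per lineage with the schema consumed by every downstream
#' stage: `run_id, seed, n_initial, spacing, dKs_pct, dmu_pct,
#' lineage_id, final_fraction, is_loser, status`. `dKs_pct`/`dmu_pct`
#' echo the loser override (0 for baseline runs).
#'
#' @param x A `run_result`.
#' @param run_id Optional identifier; a descriptive default is built
#'   from the design coordinates and seed.
#' @param ... Unused.
#' @return A tibble, one row per lineage.
#' @export
tidy.run_result <- function(x, run_id = NULL, ...) {
  cfg <- x$config
  ov <- cfg$loser_override
  dKs <- if (is.null(ov)) 0 else ov$dKs_pct
  dmu <- if (is.null(ov)) 0 else ov$dmu_pct
  if (is.null(run_id)) {
    run_id <- sprintf("n%d_s%g_K%+g_u%+g_seed%d", cfg$n_initial,
                      cfg$spacing, dKs, dmu, x$seed)
  }
  tibble::tibble(
    run_id = run_id,
    seed = x$seed,
    n_initial = cfg$n_initial,
    spacing = cfg$spacing,
    dKs_pct = dKs,
    dmu_pct = dmu,
    lineage_id = seq_along(x$final_fractions),
    final_fraction = as.numeric(x$final_fractions),
    is_loser = seq_along(x$final_fractions) == x$loser_id,
    status = x$status)
}

#' @export
glance.run_result <- function(x, ...) {
  tibble::tibble(seed = x$seed, n_lineages = length(x$final_fractions),
                 n_cells = x$n_cells, n_steps = x$n_steps,
                 volume_fraction = x$volume_fraction,
                 relax_warnings = x$relax_warnings,
                 loser_id = x$loser_id)
}

#' Execute a manifest of simulation runs
#'
#' Runs one simulation per manifest row and binds the tidy run tables.
#' Manifest columns `n_initial`, `spacing` and `seed` override the base
#' config; optional columns `dKs_pct`, `dmu_pct` and `loser_id`
#' (all three non-missing) install a loser kinetics override, which is
#' how re-run manifests are executed.
#'
#' @param manifest Data frame of runs (see [enumerate_runs()],
#'   [rerun_manifest()]).
#' @param config Base [sim_config()] supplying everything the manifest
#'   does not vary.
#' @param progress Print a line every `progress` runs (0 = quiet).
#' @return Long run-table tibble (one row per lineage per run).
#' @export
simulate_runs <- function(manifest, config = sim_config(), progress = 0) {
  manifest <- tibble::as_tibble(manifest)
  stopifnot(all(c("seed") %in% names(manifest)))
  cols <- names(manifest)
  rows <- seq_len(nrow(manifest))
  out <- purrr::map(rows, function(i) {
    row <- as.list(manifest[i, ])
    cfg <- config
    if ("n_initial" %in% cols) cfg$n_initial <- as.integer(row$n_initial)
    if ("spacing" %in% cols) cfg$spacing <- row$spacing
    cfg$domain_width <- sqrt(cfg$n_initial) * cfg$spacing *
      cfg$initial_diameter
    cfg$seed <- as.integer(row$seed)
    has_override <- "loser_id" %in% cols && !is.na(row$loser_id)
    if (has_override) {
      cfg$loser_override <- list(lineage_id = as.integer(row$loser_id),
                                 dKs_pct = row$dKs_pct,
                                 dmu_pct = row$dmu_pct)
    } else {
      cfg$loser_override <- NULL
    }
    if (progress > 0 && i %% progress == 0) {
      message(sprintf("run %d/%d", i, nrow(manifest)))
    }
    tidy(simulate_run(cfg))
  })
  dplyr::bind_rows(out)
}
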