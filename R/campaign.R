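#' Configure a drift-versus-selection campaign
#'
#' A campaign is the end-to-end protocol at configurable scale:
#' baseline runs over the crowding conditions and seeds, biggest-loser
#' identification, paired-seed re-runs over the kinetic alteration
#' grid, classification, probability maps, logistic threshold fits and
#' their regressions on `dKs_pct`, and (when the design spans several
#' crowding levels) the descriptive models. Defaults reproduce the
#' full factorial design at a reduced seed count; `sim` carries
#' resolution overrides for [sim_config()] (desk-scale work typically
#' reduces `domain_height`).
#'
#' @param populations,spacings,dKs_levels,dmu_levels Factor levels.
#' @param n_seeds Seeds per combination (paired across combinations).
#' @param seed_offset Global offset added to the seed integers so
#'   campaigns are reproducible and individually re-runnable.
#' @param sim Named list of overrides passed to the config
#'   constructor.
#' @param desk_scale Use the [sim_config_desk()] preset (reduced
#'   height with supply/demand-preserving diffusivity) as the base;
#'   `FALSE` uses the full-scale [sim_config()] conditions.
#' @param fit_models Fit the MLR/GAM descriptions when the design
#'   allows (`"auto"`), or skip (`"none"`).
#' @param progress Progress interval for [simulate_runs()].
#' @return List of class `campaign_config`.
#' @export
campaign_config <- function(populations = c(4, 9, 16),
                            spacings = c(2.5, 5, 10),
                            dKs_levels = seq(-50, 50, by = 10),
                            dmu_levels = seq(-50, 50, by = 10),
                            n_seeds = 5,
                            seed_offset = 0,
                            sim = list(),
                            desk_scale = TRUE,
                            fit_models = c("auto", "none"),
                            progress = 0) {
  fit_models <- match.arg(fit_models)
  stopifnot(n_seeds >= 1, seed_offset >= 0)
  structure(list(populations = populations, spacings = spacings,
                 dKs_levels = dKs_levels, dmu_levels = dmu_levels,
                 n_seeds = n_seeds, seed_offset = seed_offset,
                 sim = sim, desk_scale = desk_scale,
                 fit_models = fit_models,
                 progress = progress),
            class = "campaign_config")
}

#' Run a full campaign
#'
#' Executes every stage in order and (optionally) writes each artifact
#' as headed CSV (JSON for model reports) into `out_dir`. Outputs are
#' byte-identical across repeated invocations with the same
#' configuration.
#'
#' @param campaign A [campaign_config()].
#' @param out_dir Optional output directory (created if missing).
#' @return List with `baseline_runs`, `loser_table`, `rerun_runs`,
#'   `pmap`, `fairness`, `balance`, `balance_regression`, `models`
#'   (possibly NULL), and `manifest` (seeds and stage row counts).
#' @export
run_campaign <- function(campaign, out_dir = NULL) {
  stopifnot(inherits(campaign, "campaign_config"))
  base_cfg <- if (isTRUE(campaign$desk_scale)) {
    do.call(sim_config_desk, campaign$sim)
  } else {
    do.call(sim_config, campaign$sim)
  }
  seeds <- campaign$seed_offset + seq_len(campaign$n_seeds)
  crowding <- tidyr::expand_grid(
    spacing = sort(campaign$spacings),
    n_initial = sort(as.integer(campaign$populations)))
  baseline_manifest <- enumerate_runs(crowding, seeds = seeds)
  baseline_runs <- simulate_runs(baseline_manifest, base_cfg,
                                 progress = campaign$progress)
  loser_table <- baseline_runs |>
    dplyr::filter(.data$is_loser) |>
    dplyr::select("n_initial", "spacing", "seed",
                  loser_id = "lineage_id")
  kin_grid <- tidyr::expand_grid(dKs_pct = sort(campaign$dKs_levels),
                                 dmu_pct = sort(campaign$dmu_levels))
  rr_manifest <- rerun_manifest(baseline_runs, kin_grid)
  rerun_runs <- simulate_runs(rr_manifest, base_cfg,
                              progress = campaign$progress)
  pmap <- compute_pthrive(rerun_runs, loser_table)
  fairness <- fairness_by_condition(baseline_runs)
  balance <- fit_balance(pmap)
  balance_regression <- tryCatch(
    dplyr::bind_rows(lapply(c("mu50", "spread95", "spread68"),
                            function(r) regress_balance(balance, r))),
    error = function(e) {
      message("balance regression skipped: ", conditionMessage(e))
      NULL
    })
  models <- NULL
  if (campaign$fit_models == "auto" &&
      length(unique(pmap$dmu_pct)) >= 5 &&
      length(unique(pmap$dKs_pct)) >= 5) {
    models <- list(mlr = fit_mlr(pmap), gam = tryCatch(
      fit_gam(pmap), error = function(e) {
        message("GAM skipped: ", conditionMessage(e))
        NULL
      }))
  }
  manifest <- list(
    seeds = seeds,
    n_baseline_runs = nrow(baseline_manifest),
    n_rerun_runs = nrow(rr_manifest),
    n_pmap_entries = nrow(pmap),
    sim_overrides = campaign$sim,
    package_version = as.character(utils::packageVersion("driftbalance")))
  out <- list(baseline_runs = baseline_runs, loser_table = loser_table,
              rerun_runs = rerun_runs, pmap = pmap, fairness = fairness,
              balance = balance, balance_regression = balance_regression,
              models = models, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(baseline_runs, file.path(out_dir, "baseline_runs.csv"))
    readr::write_csv(rerun_runs, file.path(out_dir, "rerun_runs.csv"))
    readr::write_csv(loser_table, file.path(out_dir, "loser_table.csv"))
    readr::write_csv(pmap, file.path(out_dir, "pmap.csv"))
    readr::write_csv(fairness, file.path(out_dir, "fairness.csv"))
    readr::write_csv(balance, file.path(out_dir, "balance.csv"))
    if (!is.null(balance_regression)) {
      readr::write_csv(balance_regression,
                       file.path(out_dir, "balance_regression.csv"))
    }
    if (!is.null(models)) {
      write_model_report(models$mlr, file.path(out_dir, "model_mlr.json"))
      if (!is.null(models$gam)) {
        write_model_report(models$gam, file.path(out_dir, "model_gam.json"))
      }
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(out)
}

#' Synthesize a probability map with known logistic structure
#'
#' Builds a `p_thrive` surface from known threshold parameters -- a
#' stand-in for the simulator when testing the fitting stages. For
#' each crowding condition, the true `mu50` moves linearly along the
#' `dKs_pct` axis (the "cliff" geometry) and the thriving probability
#' at each grid point follows the logistic curve; observed
#' `p_thrive` is `Binomial(n_seeds, p) / n_seeds` (or the analytic
#' probability when `n_seeds = Inf`).
#'
#' @param truth Tibble with one row per crowding condition:
#'   `n_initial, spacing, k, mu50_intercept, mu50_slope` (true
#'   `mu50 = mu50_intercept + mu50_slope * dKs_pct`; `k` is the
#'   logistic steepness, negative for curves increasing with `dmu`).
#'   Default: nine conditions with steepness and cliff position
#'   varying across crowding.
#' @param n_seeds Seeds per grid point (binomial denominator); `Inf`
#'   for the analytic noiseless limit.
#' @param seed Seed for the binomial sampling.
#' @param dKs_levels,dmu_levels Kinetic grid (defaults: the full
#'   11 x 11 design, 121 points per crowding condition).
#' @return A `pthrive_map` tibble with the usual columns plus
#'   `true_p`.
#' @examples
#' pm <- generate_fixture_pmap(n_seeds = Inf)
#' nrow(pm) # 9 * 121
#' @export
generate_fixture_pmap <- function(truth = fixture_truth(),
                                  n_seeds = 120, seed = 1,
                                  dKs_levels = seq(-50, 50, by = 10),
                                  dmu_levels = seq(-50, 50, by = 10)) {
  truth <- tibble::as_tibble(truth)
  stopifnot(all(c("n_initial", "spacing", "k", "mu50_intercept",
                  "mu50_slope") %in% names(truth)),
            all(abs(truth$k) > 0))
  grid <- tidyr::expand_grid(truth,
                             dKs_pct = sort(dKs_levels),
                             dmu_pct = sort(dmu_levels)) |>
    dplyr::mutate(
      mu50_true = .data$mu50_intercept + .data$mu50_slope * .data$dKs_pct,
      true_p = 1 / (1 + exp(-.data$k * (.data$mu50_true - .data$dmu_pct))))
  if (is.infinite(n_seeds)) {
    grid$n_seeds <- Inf
    grid$n_thrive <- NA_integer_
    grid$p_thrive <- grid$true_p
  } else {
    set.seed(seed)
    grid$n_seeds <- n_seeds
    grid$n_thrive <- rbinom(nrow(grid), n_seeds, grid$true_p)
    grid$p_thrive <- grid$n_thrive / n_seeds
  }
  out <- grid |>
    dplyr::select("n_initial", "spacing", "dKs_pct", "dmu_pct",
                  "n_seeds", "n_thrive", "p_thrive", "true_p")
  class(out) <- c("pthrive_map", class(out))
  out
}

#' @rdname generate_fixture_pmap
#' @export
fixture_truth <- function() {
  tidyr::expand_grid(spacing = c(2.5, 5, 10),
                     n_initial = c(4L, 9L, 16L)) |>
    dplyr::mutate(
      # steeper cliffs at loose spacing, wider at moderate spacing;
      # cliff position rises with crowding
      k = -c(0.30, 0.25, 0.20, 0.12, 0.10, 0.08, 0.25, 0.20, 0.15),
      mu50_intercept = c(10, 14, 18, 12, 16, 22, 8, 12, 15),
      mu50_slope = c(0.9, 0.95, 1.0, 0.6, 0.7, 0.8, 0.35, 0.45, 0.55))
}
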