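#' Aggregate re-runs into a thriving-probability map
#'
#' For each design combination `(n_initial, spacing, dKs_pct,
#' dmu_pct)`, `p_thrive` is the fraction of seeds in which the
#' baseline's biggest loser ended the re-run classified as thriving.
#' The paired-seed design requires exactly one loser-status record per
#' (combination, seed): missing seeds and duplicates are hard errors
#' rather than silently renormalised fractions.
#'
#' @param rerun_table Long run table of re-runs (rows for all
#'   lineages are accepted; only the loser rows, where the lineage id
#'   equals the overridden lineage, are used). Must carry `dKs_pct`,
#'   `dmu_pct` and a `loser_id` column *or* `is_loser`-style
#'   identification via the `loser_id` argument below.
#' @param loser_table Optional tibble `n_initial, spacing, seed,
#'   loser_id` from the baseline runs; if supplied, loser rows are
#'   selected by joining on it (the re-run's own `is_loser` flag is
#'   *not* used, since the altered lineage need no longer be the
#'   minimum).
#' @return A `pthrive_map` tibble: `n_initial, spacing, dKs_pct,
#'   dmu_pct, n_seeds, n_thrive, p_thrive`, long form, one row per
#'   combination.
#' @export
compute_pthrive <- function(rerun_table, loser_table = NULL) {
  rr <- tibble::as_tibble(rerun_table)
  need <- c("n_initial", "spacing", "dKs_pct", "dmu_pct", "seed",
            "lineage_id", "status")
  missing_cols <- setdiff(need, names(rr))
  if (length(missing_cols) > 0) {
    abort(paste("rerun table lacks columns:",
                paste(missing_cols, collapse = ", ")),
          class = "driftbalance_schema_error")
  }
  if (is.null(loser_table)) {
    if (!"loser_id" %in% names(rr)) {
      abort("supply a loser_table or a loser_id column identifying the altered lineage",
            class = "driftbalance_schema_error")
    }
    loser_rows <- dplyr::filter(rr, .data$lineage_id == .data$loser_id)
  } else {
    loser_rows <- dplyr::inner_join(
      rr, tibble::as_tibble(loser_table),
      by = c("n_initial", "spacing", "seed")) |>
      dplyr::filter(.data$lineage_id == .data$loser_id)
  }
  dup <- loser_rows |>
    dplyr::count(.data$n_initial, .data$spacing, .data$dKs_pct,
                 .data$dmu_pct, .data$seed) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("duplicate loser-status records for ", nrow(dup),
                 " (combination, seed) pairs, e.g. n_initial=",
                 dup$n_initial[1], " spacing=", dup$spacing[1],
                 " dKs=", dup$dKs_pct[1], " dmu=", dup$dmu_pct[1],
                 " seed=", dup$seed[1]),
          class = "driftbalance_duplicate_records")
  }
  # every combination must cover the same seed set
  seeds <- sort(unique(loser_rows$seed))
  gaps <- loser_rows |>
    dplyr::group_by(.data$n_initial, .data$spacing, .data$dKs_pct,
                    .data$dmu_pct) |>
    dplyr::summarise(
      missing = paste(setdiff(seeds, .data$seed), collapse = ","),
      .groups = "drop") |>
    dplyr::filter(.data$missing != "")
  if (nrow(gaps) > 0) {
    abort(paste0("missing seeds for ", nrow(gaps),
                 " combinations; first gap: n_initial=", gaps$n_initial[1],
                 " spacing=", gaps$spacing[1], " dKs=", gaps$dKs_pct[1],
                 " dmu=", gaps$dmu_pct[1], " seeds {", gaps$missing[1], "}"),
          class = "driftbalance_missing_seeds")
  }
  out <- loser_rows |>
    dplyr::group_by(.data$n_initial, .data$spacing, .data$dKs_pct,
                    .data$dmu_pct) |>
    dplyr::summarise(n_seeds = dplyr::n(),
                     n_thrive = sum(.data$status == "thriving"),
                     p_thrive = .data$n_thrive / .data$n_seeds,
                     .groups = "drop")
  class(out) <- c("pthrive_map", class(out))
  out
}

#' Flag empirical monotonicity violations in a probability map
#'
#' Selection should act monotonically: at fixed crowding and `dKs_pct`,
#' `p_thrive` should not decrease as `dmu_pct` increases, beyond
#' binomial noise. Adjacent-level decreases larger than `tol` standard
#' errors are flagged for QC.
#'
#' @param pmap A `pthrive_map`.
#' @param tol Allowed decrease in units of the pooled binomial
#'   standard error.
#' @return Tibble of flagged adjacent pairs (possibly empty).
#' @export
qc_monotonicity <- function(pmap, tol = 3) {
  pmap |>
    tibble::as_tibble() |>
    dplyr::arrange(.data$n_initial, .data$spacing, .data$dKs_pct,
                   .data$dmu_pct) |>
    dplyr::group_by(.data$n_initial, .data$spacing, .data$dKs_pct) |>
    dplyr::mutate(
      drop = dplyr::lag(.data$p_thrive) - .data$p_thrive,
      se = sqrt(pmax(.data$p_thrive * (1 - .data$p_thrive), 0.25 / 4) /
                  .data$n_seeds),
      flagged = !is.na(.data$drop) & .data$drop > tol * sqrt(2) * .data$se) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$flagged) |>
    dplyr::select(-"flagged")
}

#' Heat-map of a thriving-probability surface
#'
#' One panel per crowding condition, `dmu_pct` on x, `dKs_pct` on y,
#' fill = `p_thrive`.
#'
#' @param object A `pthrive_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pthrive_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$dmu_pct, .data$dKs_pct,
                                       fill = .data$p_thrive)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$n_initial),
      cols = ggplot2::vars(.data$spacing),
      labeller = ggplot2::label_both) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "% change in mu_max", y = "% change in K_s",
                  fill = "p(thrive)")
}
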