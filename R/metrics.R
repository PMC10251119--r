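#' Expected (neutral) lineage abundance
#'
#' With `N` identical founders and no drift, every lineage would hold
#' an equal share of the total biomass: `X_E = X_t / N`.
#'
#' @param X_t Total biomass (any consistent unit; 1 for fractions).
#' @param N Number of founder lineages, >= 1.
#' @return The neutral expectation `X_E`.
#' @examples
#' expected_abundance(1, 4) # 0.25
#' @export
expected_abundance <- function(X_t, N) {
  if (length(N) != 1 || N < 1) {
    abort("N must be a positive lineage count",
          class = "driftbalance_config_error")
  }
  stopifnot(X_t >= 0)
  X_t / N
}

#' Three-way lineage survival classification
#'
#' Relative to the neutral expectation `X_E`, a lineage is
#' `languishing` when `X_i < 0.3 * X_E`, `thriving` when
#' `X_i > 0.9 * X_E`, and `barely_surviving` on the closed interval
#' between (both boundaries inclusive). The thriving cutoff sits below
#' `X_E` itself so that lineages doing clearly well are not penalised
#' when a single dominant lineage depresses everyone else's share.
#'
#' @param X_i Lineage abundance(s), >= 0 (vectorised).
#' @param X_E Neutral expectation, > 0.
#' @param languish_below,thrive_above Multipliers of `X_E` defining the
#'   class boundaries.
#' @return Character vector: `"languishing"`, `"barely_surviving"` or
#'   `"thriving"`.
#' @examples
#' classify_status(c(0.05, 0.2, 0.3), expected_abundance(1, 4))
#' @export
classify_status <- function(X_i, X_E, languish_below = 0.3,
                            thrive_above = 0.9) {
  stopifnot(languish_below > 0, thrive_above > languish_below)
  if (X_E <= 0) {
    abort("X_E must be positive", class = "driftbalance_config_error")
  }
  if (any(X_i < 0)) {
    abort("abundances must be non-negative",
          class = "driftbalance_config_error")
  }
  dplyr::case_when(
    X_i < languish_below * X_E ~ "languishing",
    X_i > thrive_above * X_E ~ "thriving",
    .default = "barely_surviving")
}

#' (Re)classify a long run table
#'
#' Recomputes the `status` column of a run table from its
#' `final_fraction` values, using each run's own lineage count for the
#' neutral expectation. Useful when ingesting externally produced run
#' tables that lack the classification.
#'
#' @param runs Long run table (see [tidy.run_result()] for the schema).
#' @inheritParams classify_status
#' @return The run table with a fresh `status` column.
#' @export
classify_runs <- function(runs, languish_below = 0.3, thrive_above = 0.9) {
  runs |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$run_id) |>
    dplyr::mutate(status = classify_status(
      .data$final_fraction, expected_abundance(1, dplyr::n()),
      languish_below, thrive_above)) |>
    dplyr::ungroup()
}

#' Chi-square fairness test on biggest-loser counts
#'
#' Treats the founder sites of one crowding condition like dice: under
#' pure drift each site should be the biggest loser equally often over
#' the seeds. Tests the observed per-site loser counts against the
#' uniform expectation with a chi-square goodness-of-fit test, judged
#' at a Bonferroni-corrected level `alpha / m` where `m` is the number
#' of crowding conditions tested (9 for the full 3 x 3 design).
#'
#' @param counts Named or unnamed vector of per-site loser counts (one
#'   entry per founder site).
#' @param m Bonferroni divisor: how many crowding conditions are being
#'   tested in the family. Default 9.
#' @param alpha Family-wise level before correction.
#' @param simulate_p Use a Monte-Carlo p-value (for small desk-scale
#'   seed counts where asymptotics are shaky).
#' @param B Monte-Carlo replicates when `simulate_p = TRUE`.
#' @return Tibble with `statistic, df, p_value, alpha_corrected,
#'   significant, n_runs, n_sites, m`.
#' @examples
#' fairness_test(c(30, 30, 30, 30)) # statistic 0, not significant
#' @export
fairness_test <- function(counts, m = 9, alpha = 0.05,
                          simulate_p = FALSE, B = 10000) {
  stopifnot(m >= 1, length(counts) >= 2)
  if (sum(counts) == 0) {
    abort("all-zero loser counts: nothing to test",
          class = "driftbalance_empty_result")
  }
  ht <- suppressWarnings(chisq.test(
    counts, p = rep(1 / length(counts), length(counts)),
    simulate.p.value = simulate_p, B = B))
  level <- alpha / m
  tibble::tibble(
    statistic = unname(ht$statistic),
    df = if (simulate_p) NA_real_ else unname(ht$parameter),
    p_value = ht$p.value,
    alpha_corrected = level,
    significant = ht$p.value < level,
    n_runs = sum(counts),
    n_sites = length(counts),
    m = m)
}

#' Per-condition fairness tests on a baseline run table
#'
#' Tallies, for each crowding condition, how often each founder site
#' was the biggest loser across seeds and applies [fairness_test()]
#' with `m` equal to the number of conditions present.
#'
#' @param baseline_runs Long run table of baseline (identical-kinetics)
#'   runs.
#' @inheritParams fairness_test
#' @return Tibble with one row per crowding condition.
#' @export
fairness_by_condition <- function(baseline_runs, alpha = 0.05,
                                  simulate_p = FALSE, B = 10000) {
  losers <- baseline_runs |>
    tibble::as_tibble() |>
    dplyr::filter(.data$is_loser)
  conds <- dplyr::distinct(losers, .data$n_initial, .data$spacing)
  m <- nrow(conds)
  losers |>
    dplyr::group_by(.data$n_initial, .data$spacing) |>
    dplyr::group_modify(function(df, key) {
      counts <- tabulate(df$lineage_id, nbins = key$n_initial[[1]])
      fairness_test(counts, m = m, alpha = alpha,
                    simulate_p = simulate_p, B = B)
    }) |>
    dplyr::ungroup()
}
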