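# Desk-scale configurations shared across tests. The desk preset keeps the
# full-scale supply/demand regime (H^2/D preserved) while shrinking the
# biomass volume needed to reach the stop criterion.
desk4 <- function(seed = 1, ...) {
  sim_config_desk(n_initial = 4, spacing = 5, seed = seed, ...)
}

desk9 <- function(seed = 1, ...) {
  sim_config_desk(n_initial = 9, spacing = 10, seed = seed, ...)
}

# noiseless logistic profile at the design dmu levels
logistic_profile <- function(k, mu50, dmu = seq(-50, 50, by = 10)) {
  tibble::tibble(dmu_pct = dmu,
                 p_thrive = 1 / (1 + exp(-k * (mu50 - dmu))))
}

# small hand-made re-run table (long schema) for aggregation tests
toy_rerun_table <- function() {
  combos <- tidyr::expand_grid(dKs_pct = 0, dmu_pct = c(-10, 0, 10))
  seeds <- 1:4
  tidyr::expand_grid(combos, seed = seeds) |>
    dplyr::mutate(
      run_id = sprintf("toy_%g_%g_%d", dKs_pct, dmu_pct, seed),
      n_initial = 4L, spacing = 5,
      lineage_id = 2L, loser_id = 2L,
      final_fraction = 0.25,
      is_loser = TRUE,
      status = c("languishing", "languishing", "languishing", "languishing",
                 "languishing", "thriving", "languishing", "barely_surviving",
                 "thriving", "thriving", "thriving", "languishing"))
}
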