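toy_campaign <- function(out_dir = NULL) {
  cc <- campaign_config(populations = 4, spacings = 5, dKs_levels = 0,
                        dmu_levels = c(-20, 0, 20), n_seeds = 4,
                        fit_models = "none")
  run_campaign(cc, out_dir = out_dir)
}

test_that("fixture maps have the right shape and the noiseless limit", {
  pm <- generate_fixture_pmap(n_seeds = Inf)
  expect_equal(nrow(pm), 9 * 121) # 11 x 11 grid per crowding condition
  counts <- dplyr::count(pm, .data$n_initial, .data$spacing)
  expect_true(all(counts$n == 121))
  # noiseless limit: fits recover the planted parameters to 1e-6
  one <- dplyr::filter(pm, n_initial == 9, spacing == 5, dKs_pct == 0)
  fit <- fit_logistic(one)
  truth <- dplyr::filter(fixture_truth(), n_initial == 9, spacing == 5)
  expect_equal(fit$k, truth$k, tolerance = 1e-6)
  expect_equal(fit$mu50, truth$mu50_intercept, tolerance = 1e-6)
  # finite seeds: binomial draws are reproducible under the same seed
  a <- generate_fixture_pmap(n_seeds = 120, seed = 3)
  b <- generate_fixture_pmap(n_seeds = 120, seed = 3)
  expect_identical(a, b)
  expect_true(all(abs(a$p_thrive - a$true_p) <= 1))
})

test_that("a toy campaign runs end-to-end and is self-consistent", {
  res <- toy_campaign()
  expect_equal(nrow(res$baseline_runs), 4 * 4) # 4 seeds x 4 lineages
  expect_equal(nrow(res$loser_table), 4)
  expect_equal(nrow(res$pmap), 3) # one dKs level x three dmu levels
  expect_true(all(res$pmap$n_seeds == 4))
  expect_equal(nrow(res$fairness), 1)
  # the pmap agrees with a manual recount of the re-run table
  manual <- res$rerun_runs |>
    dplyr::inner_join(res$loser_table,
                      by = c("n_initial", "spacing", "seed")) |>
    dplyr::filter(.data$lineage_id == .data$loser_id) |>
    dplyr::group_by(.data$dmu_pct) |>
    dplyr::summarise(p = mean(.data$status == "thriving"))
  expect_equal(res$pmap$p_thrive, manual$p)
})

test_that("campaign artifacts are byte-identical across repeats", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  toy_campaign(out_dir = d1)
  toy_campaign(out_dir = d2)
  files <- list.files(d1)
  expect_true(all(c("baseline_runs.csv", "rerun_runs.csv", "pmap.csv",
                    "fairness.csv", "balance.csv", "manifest.json")
                  %in% files))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("CSV artifacts re-enter the pipeline through the readers", {
  d <- withr::local_tempdir()
  res <- toy_campaign(out_dir = d)
  runs <- read_run_table(file.path(d, "rerun_runs.csv"))
  expect_equal(nrow(runs), nrow(res$rerun_runs))
  pm <- read_pthrive_map(file.path(d, "pmap.csv"))
  expect_s3_class(pm, "pthrive_map")
  expect_equal(pm$p_thrive, res$pmap$p_thrive)
  # round-trip: recomputing the map from the re-read run table matches
  pm2 <- compute_pthrive(runs, res$loser_table)
  expect_equal(pm2$p_thrive, res$pmap$p_thrive)
  # schema violations are rejected
  bad <- file.path(d, "bad.csv")
  readr::write_csv(dplyr::select(res$rerun_runs, -"status"), bad)
  expect_error(read_run_table(bad), class = "driftbalance_schema_error")
})

test_that("a missing re-run row is caught at the map stage", {
  res <- toy_campaign()
  # drop specifically a loser-lineage record from one re-run
  joined <- dplyr::inner_join(res$rerun_runs, res$loser_table,
                              by = c("n_initial", "spacing", "seed"))
  victim <- which(joined$lineage_id == joined$loser_id)[1]
  broken <- res$rerun_runs[-victim, ]
  expect_error(compute_pthrive(broken, res$loser_table),
               class = "driftbalance_missing_seeds")
})
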