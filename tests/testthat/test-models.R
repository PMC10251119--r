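test_that("the pseudo-probability logit matches its printed arithmetic", {
  eps <- 1e-6
  expect_equal(logit_eps(1), log(1 / eps + eps), tolerance = 1e-12)
  expect_equal(logit_eps(1), 13.8155, tolerance = 1e-4)
  expect_equal(logit_eps(0), log(eps), tolerance = 1e-12)
  expect_equal(logit_eps(0), -13.8155, tolerance = 1e-4)
  expect_equal(logit_eps(0.5), -9.99996e-7, tolerance = 1e-4)
  expect_error(logit_eps(1.01), class = "driftbalance_domain_error")
  expect_error(logit_eps(-0.01), class = "driftbalance_domain_error")
})

test_that("the transform round-trips through its inverse", {
  p <- seq(0.001, 0.999, length.out = 101)
  expect_equal(inv_logit_eps(logit_eps(p)), p, tolerance = 1e-5)
  # and the inverse is exact algebraically in the other direction
  y <- seq(-10, 10, length.out = 51)
  expect_equal(logit_eps(pmin(pmax(inv_logit_eps(y), 0), 1)), y,
               tolerance = 1e-9)
})

test_that("noiseless MLR responses recover their coefficients", {
  grid <- factor_grid()
  # coefficients kept small enough that eta stays inside +/- 12, where
  # the transform is exactly invertible without clipping
  beta <- c(1, 0.06, -0.04, -0.1, 0.2, 0.003, -0.002)
  eta <- with(grid, beta[1] + beta[2] * dmu_pct + beta[3] * dKs_pct +
                beta[4] * n_initial + beta[5] * spacing +
                beta[6] * dmu_pct * spacing + beta[7] * dKs_pct * spacing)
  pmap <- grid |>
    dplyr::rename(dmu_pct = dmu_pct, dKs_pct = dKs_pct) |>
    dplyr::mutate(p_thrive = pmin(pmax(inv_logit_eps(eta), 0), 1),
                  n_seeds = Inf, n_thrive = NA_integer_)
  fit <- fit_mlr(pmap)
  expect_equal(unname(coef(fit$fit)),
               c(beta[1], beta[2], beta[3], beta[4], beta[5],
                 beta[6], beta[7]),
               tolerance = 1e-8)
  m <- model_metrics(fit)
  expect_lt(m$rmse, 1e-6)
  expect_gt(m$r_squared, 1 - 1e-9)
})

test_that("MLR coefficients equal the normal-equations solution", {
  set.seed(3)
  toy <- tidyr::expand_grid(n_initial = c(4L, 9L), spacing = c(2.5, 5),
                            dKs_pct = c(-20, 0, 20),
                            dmu_pct = c(-30, 10)) |>
    dplyr::slice_head(n = 20) |>
    dplyr::mutate(p_thrive = runif(20, 0.05, 0.95))
  fit <- fit_mlr(toy, interactions = FALSE)
  X <- cbind(1, toy$dmu_pct, toy$dKs_pct, toy$n_initial, toy$spacing)
  y <- logit_eps(toy$p_thrive)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(unname(coef(fit$fit)), as.numeric(beta), tolerance = 1e-10)
})

test_that("a rank-deficient design names the aliased term", {
  pmap <- generate_fixture_pmap(n_seeds = Inf) |>
    dplyr::mutate(copy = dmu_pct)
  expect_error(fit_mlr(pmap, terms = c("mu_p", "K_p", "copy")),
               class = "driftbalance_rank_deficient")
})

test_that("a pure-noise regressor is rarely significant", {
  pm0 <- generate_fixture_pmap(n_seeds = Inf)
  set.seed(11)
  hits <- 0
  for (i in 1:100) {
    pm <- pm0
    pm$noise <- rnorm(nrow(pm))
    fit <- fit_mlr(pm, terms = c("mu_p", "K_p", "N0", "s_i", "noise"))
    pv <- tidy(fit)
    hits <- hits + (pv$p_value[pv$term == "noise"] <= 0.05)
  }
  expect_lte(hits, 10) # ~5% expected under the null
})

test_that("MLR fit quality is insensitive to the pseudo-probability", {
  pm <- generate_fixture_pmap(n_seeds = 120, seed = 3) |>
    dplyr::filter(p_thrive > 0.02, p_thrive < 0.98) # interior data
  r <- sapply(c(1e-8, 1e-6, 1e-4), function(e) {
    model_metrics(fit_mlr(pm, eps = e))$rmse
  })
  expect_lt(max(r) - min(r), 0.01)
})

test_that("smooths of a linear surface collapse to ~1 degree of freedom", {
  grid <- tidyr::expand_grid(n_initial = 9L, spacing = 5,
                             dKs_pct = seq(-50, 50, 5),
                             dmu_pct = seq(-50, 50, 5))
  set.seed(2)
  # a little observation noise so cross-validation has something to
  # penalise; on exactly interpolable data the criterion is indifferent
  pmap <- grid |>
    dplyr::mutate(p_thrive = 0.5 + 0.004 * dmu_pct - 0.002 * dKs_pct +
                    rnorm(dplyr::n(), 0, 0.01))
  fit <- fit_gam(pmap, terms = c("s(mu_p, k = 5)", "s(K_p, k = 5)"))
  edf <- summary(fit$fit)$s.table[, "edf"]
  expect_equal(unname(edf), c(1, 1), tolerance = 0.2)
})

test_that("GAM predictions may exceed [0,1] and carry a flag", {
  pm <- generate_fixture_pmap(n_seeds = 120, seed = 9)
  fit <- fit_gam(pm)
  pred <- predict(fit)
  expect_false(is.null(attr(pred, "out_of_range")))
  m <- model_metrics(fit)
  expect_gte(m$rmse, 0)
  expect_true(is.finite(m$aic))
})

test_that("model metrics match a direct loop on a toy table", {
  full <- generate_fixture_pmap(n_seeds = 120, seed = 4)
  pm <- full[seq(1, nrow(full), by = 109), ][1:10, ] # spread across blocks
  fit <- fit_mlr(pm, interactions = FALSE)
  pred <- predict(fit)
  m <- model_metrics(fit)
  acc <- 0
  for (i in 1:10) acc <- acc + (pm$p_thrive[i] - pred[i])^2
  expect_equal(m$rmse, sqrt(acc / 10), tolerance = 1e-12)
  # degenerate cases of R^2
  expect_equal(model_metrics(fit)$r_squared,
               1 - sum((pm$p_thrive - pred)^2) /
                 sum((pm$p_thrive - mean(pm$p_thrive))^2))
})

test_that("backward selection drops noise interactions, keeps structure", {
  # truth: mains mu_p, K_p and their product drive the response
  grid <- tidyr::expand_grid(n_initial = c(4L, 9L, 16L),
                             spacing = c(2.5, 5, 10),
                             dKs_pct = seq(-50, 50, 25),
                             dmu_pct = seq(-50, 50, 25))
  set.seed(21)
  successes <- 0
  for (rep in 1:50) {
    pmap <- grid |>
      dplyr::mutate(eta = 0.04 * dmu_pct - 0.04 * dKs_pct +
                      0.0012 * dmu_pct * dKs_pct + rnorm(dplyr::n(), 0, 0.5),
                    p_thrive = pmin(pmax(inv_logit_eps(eta), 0), 1))
    sel <- backward_select(pmap, type = "mlr",
                           terms = c("mu_p", "K_p", "N0", "s_i",
                                     "mu_p:K_p", "mu_p:K_p:N0"))
    keep_true <- all(c("mu_p", "K_p", "mu_p:K_p") %in% sel$terms)
    drop_noise <- !"mu_p:K_p:N0" %in% sel$terms
    successes <- successes + (keep_true && drop_noise)
  }
  expect_gte(successes, 45) # >= 90% of replicates
})

test_that("selection is a fixed point when every term is significant", {
  grid <- tidyr::expand_grid(n_initial = c(4L, 9L, 16L),
                             spacing = c(2.5, 5, 10),
                             dKs_pct = seq(-50, 50, 25),
                             dmu_pct = seq(-50, 50, 25))
  set.seed(5)
  pmap <- grid |>
    dplyr::mutate(eta = 0.05 * dmu_pct - 0.05 * dKs_pct - 0.05 * n_initial +
                    0.2 * spacing + rnorm(dplyr::n(), 0, 0.2),
                  p_thrive = pmin(pmax(inv_logit_eps(eta), 0), 1))
  sel <- backward_select(pmap, type = "mlr",
                         terms = c("mu_p", "K_p", "N0", "s_i"))
  expect_setequal(sel$terms, c("mu_p", "K_p", "N0", "s_i"))
  expect_equal(nrow(sel$dropped), 0)
})

test_that("main effects survive while their interaction is retained", {
  # N0 main is null, but the mu_p:N0 interaction is strong
  grid <- tidyr::expand_grid(n_initial = c(4L, 9L, 16L),
                             spacing = c(2.5, 5, 10),
                             dKs_pct = seq(-50, 50, 25),
                             dmu_pct = seq(-50, 50, 25))
  set.seed(9)
  pmap <- grid |>
    dplyr::mutate(eta = 0.05 * dmu_pct + 0.004 * dmu_pct * n_initial +
                    rnorm(dplyr::n(), 0, 0.3),
                  p_thrive = pmin(pmax(inv_logit_eps(eta), 0), 1))
  sel <- backward_select(pmap, type = "mlr",
                         terms = c("mu_p", "N0", "s_i", "mu_p:N0"))
  expect_true(all(c("mu_p", "N0", "mu_p:N0") %in% sel$terms))
})

test_that("GAM backward selection runs and reports per-term p-values", {
  pm <- generate_fixture_pmap(n_seeds = 120, seed = 6)
  sel <- backward_select(pm, type = "gam", terms = c(
    "s(mu_p, k = 5)", "s(K_p, k = 5)", "s(N0, k = 3)", "s(s_i, k = 3)",
    "te(mu_p, K_p, k = c(5, 5))"))
  expect_true("te(mu_p, K_p, k = c(5, 5))" %in% sel$fit$terms)
  expect_s3_class(sel$fit, "gam_fit")
})

test_that("model reports serialise to JSON", {
  pm <- generate_fixture_pmap(n_seeds = 120, seed = 6)
  fit <- fit_mlr(pm)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_report(fit, path)
  rep <- jsonlite::read_json(path)
  expect_equal(rep$type, "mlr")
  expect_true(all(c("terms", "coefficients", "metrics") %in% names(rep)))
})
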