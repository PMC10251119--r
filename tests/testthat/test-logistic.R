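test_that("noiseless profiles recover their parameters to 1e-6", {
  cases <- list(c(-0.2, 15), c(-0.1, -10), c(-0.35, 30), c(0.15, 5))
  for (cs in cases) {
    prof <- logistic_profile(cs[1], cs[2])
    fit <- fit_logistic(prof)
    expect_true(fit$converged)
    expect_equal(fit$k, cs[1], tolerance = 1e-6)
    expect_equal(fit$mu50, cs[2], tolerance = 1e-6)
    # the fitted curve passes through 0.5 at mu50
    expect_equal(predict(fit, fit$mu50), 0.5, tolerance = 1e-12)
  }
})

test_that("flat profiles are flagged degenerate, not errors", {
  flat <- tibble::tibble(dmu_pct = seq(-50, 50, 10), p_thrive = 0.5)
  fit <- fit_logistic(flat)
  expect_false(fit$converged)
  expect_identical(fit$k, 0)
  expect_true(is.na(fit$mu50))
  zeros <- tibble::tibble(dmu_pct = seq(-50, 50, 10), p_thrive = 0)
  expect_false(fit_logistic(zeros)$converged)
  expect_error(spread_from_fit(fit_logistic(zeros)),
               class = "driftbalance_fit_error")
})

test_that("input validation rejects short or out-of-range profiles", {
  expect_error(fit_logistic(tibble::tibble(dmu_pct = 1:3,
                                           p_thrive = c(0, 0.5, 1))),
               class = "driftbalance_fit_error")
  expect_error(fit_logistic(tibble::tibble(dmu_pct = 1:5,
                                           p_thrive = c(0, 0.5, 1, 2, 1))),
               class = "driftbalance_fit_error")
})

test_that("an extrapolated mu50 is flagged", {
  prof <- logistic_profile(-0.1, 60) # cliff beyond the swept range
  fit <- fit_logistic(prof)
  expect_true(fit$converged)
  expect_true(fit$extrapolated)
})

test_that("spread closed forms match numerical curve inversion", {
  fit <- fit_logistic(logistic_profile(-0.2, 15))
  sp <- spread_from_fit(fit)
  expect_equal(sp$spread95, 2 * log(39) / 0.2, tolerance = 1e-9)
  expect_equal(sp$spread68, 2 * log(0.84 / 0.16) / 0.2, tolerance = 1e-9)
  # invert the fitted curve numerically with uniroot
  inv_num <- function(p) {
    uniroot(function(m) predict(fit, m) - p, c(-500, 500),
            tol = 1e-12)$root
  }
  expect_equal(abs(inv_num(0.975) - inv_num(0.025)), sp$spread95,
               tolerance = 1e-8)
  expect_equal(abs(inv_num(0.84) - inv_num(0.16)), sp$spread68,
               tolerance = 1e-8)
  # closed-form inversion agrees too
  expect_equal(invert_logistic(fit, 0.5), fit$mu50, tolerance = 1e-9)
  # the spread ratio is a k-free algebraic constant
  for (k in c(-0.05, -0.2, 0.4)) {
    f <- fit_logistic(logistic_profile(k, 0))
    s <- spread_from_fit(f)
    expect_equal(s$spread95 / s$spread68, log(39) / log(5.25),
                 tolerance = 1e-9)
  }
})

test_that("the binomial GLM route agrees with least squares on clean data", {
  prof <- logistic_profile(-0.2, 15) |>
    dplyr::mutate(n_seeds = 120, n_thrive = round(p_thrive * 120),
                  p_thrive = n_thrive / 120)
  f_nls <- fit_logistic(prof)
  f_glm <- fit_logistic(prof, method = "glm")
  expect_true(f_glm$converged)
  expect_equal(f_glm$k, f_nls$k, tolerance = 0.05)
  expect_equal(f_glm$mu50, f_nls$mu50, tolerance = 0.5)
})

test_that("balance fits recover the planted cliff structure per condition", {
  pm <- generate_fixture_pmap(n_seeds = Inf)
  bal <- fit_balance(pm)
  expect_s3_class(bal, "balance_table")
  truth <- fixture_truth()
  merged <- dplyr::inner_join(
    bal, truth, by = c("n_initial", "spacing"))
  conv <- merged[merged$converged, ]
  expect_gt(nrow(conv), 80)
  expect_equal(conv$k.x, conv$k.y, tolerance = 1e-4)
  expect_equal(conv$mu50,
               conv$mu50_intercept + conv$mu50_slope * conv$dKs_pct,
               tolerance = 1e-4)
})

test_that("balance regression matches the closed-form OLS solution", {
  # exact line: slope 1, intercept 10
  bal <- tibble::tibble(n_initial = 9L, spacing = 5,
                        dKs_pct = seq(-50, 50, 10),
                        k = -0.2, mu50 = 10 + dKs_pct,
                        spread95 = 30, spread68 = 15,
                        converged = TRUE, extrapolated = FALSE)
  reg <- suppressWarnings(regress_balance(bal, "mu50")) # perfect fit
  expect_equal(reg$slope, 1, tolerance = 1e-12)
  expect_equal(reg$intercept, 10, tolerance = 1e-12)
  expect_equal(reg$r_squared, 1, tolerance = 1e-12)
  # noisy data against the normal equations
  set.seed(7)
  bal$mu50 <- 10 + 0.5 * bal$dKs_pct + rnorm(11)
  reg2 <- regress_balance(bal, "mu50")
  X <- cbind(1, bal$dKs_pct)
  beta <- solve(t(X) %*% X, t(X) %*% bal$mu50)
  expect_equal(reg2$intercept, beta[1], tolerance = 1e-10)
  expect_equal(reg2$slope, beta[2], tolerance = 1e-10)
  # a zero-slope response is detected as such
  bal$mu50 <- 10 + rnorm(11, sd = 0.1)
  reg3 <- regress_balance(bal, "mu50")
  expect_lt(abs(reg3$slope), 0.05)
  expect_gt(reg3$p_value, 0.05)
})

test_that("non-converged fits are excluded with a message, few points error", {
  bal <- tibble::tibble(n_initial = 9L, spacing = 5,
                        dKs_pct = seq(-20, 20, 10), k = -0.2,
                        mu50 = 10 + dKs_pct, spread95 = 30, spread68 = 15,
                        converged = c(TRUE, TRUE, TRUE, TRUE, FALSE),
                        extrapolated = FALSE)
  expect_message(reg <- suppressWarnings(regress_balance(bal, "mu50")),
                 "excluded 1")
  expect_equal(reg$n_used, 4)
  bal$converged <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_error(suppressMessages(regress_balance(bal, "mu50")),
               class = "driftbalance_fit_error")
})
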