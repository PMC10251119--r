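#' Fit the logistic thriving-threshold model along one K_s line
#'
#' Fits `p_thrive = 1 / (1 + exp(-k * (mu50 - dmu)))` to a profile of
#' thriving probabilities along the `dmu_pct` axis at fixed crowding
#' and `dKs_pct`, by least squares on the probability scale. `mu50` is
#' the percent change in `mu_max` giving 50% thriving odds; `k` sets
#' the steepness. With the curve written in this form, profiles that
#' *increase* with `dmu` have negative `k`; spreads therefore use
#' `|k|`.
#'
#' Profiles whose observed probability range is below 0.1 (all-fail or
#' all-thrive lines) do not identify the parameters; they return a fit
#' flagged `converged = FALSE` rather than an error. A fitted `mu50`
#' outside the swept `dmu_pct` range is flagged `extrapolated`.
#'
#' @param profile Data frame with columns `dmu_pct` and `p_thrive`
#'   (and, for `method = "glm"`, `n_thrive` and `n_seeds`).
#' @param method `"nls"` (default): nonlinear least squares on the
#'   probability scale, matching the sigmoid-profile fitting the
#'   pipeline is built around. `"glm"`: binomial logistic regression
#'   on the thriving counts, useful for uncertainty quantification.
#' @param degenerate_range Observed `p` range below which the profile
#'   is declared degenerate.
#' @return An object of class `logistic_fit` with elements `k`,
#'   `mu50`, `converged`, `extrapolated`, `rss`, `n_points`, `method`
#'   and the profile `data`.
#' @examples
#' prof <- tibble::tibble(dmu_pct = seq(-50, 50, 10),
#'                        p_thrive = 1 / (1 + exp(0.2 * (15 - dmu_pct))))
#' fit <- fit_logistic(prof)
#' c(fit$k, fit$mu50) # ~ (-0.2, 15)
#' @export
fit_logistic <- function(profile, method = c("nls", "glm"),
                         degenerate_range = 0.1) {
  method <- match.arg(method)
  profile <- tibble::as_tibble(profile)
  stopifnot(all(c("dmu_pct", "p_thrive") %in% names(profile)))
  if (nrow(profile) < 4) {
    abort("need at least 4 profile points to fit the logistic",
          class = "driftbalance_fit_error")
  }
  p <- profile$p_thrive
  mu <- profile$dmu_pct
  if (any(p < 0 | p > 1)) {
    abort("p_thrive values must lie in [0, 1]",
          class = "driftbalance_fit_error")
  }
  out <- list(k = 0, mu50 = NA_real_, converged = FALSE,
              extrapolated = FALSE, rss = NA_real_,
              n_points = nrow(profile), method = method, data = profile)
  class(out) <- "logistic_fit"
  if (diff(range(p)) < degenerate_range) {
    return(out)
  }
  # start values from a clamped-logit linear fit:
  # logit(p) = k * mu50 - k * dmu
  pc <- pmin(pmax(p, 1e-3), 1 - 1e-3)
  start_lm <- lm(qlogis(pc) ~ mu)
  b0 <- unname(coef(start_lm)[1])
  b1 <- unname(coef(start_lm)[2])
  if (!is.finite(b1) || b1 == 0) b1 <- 1e-3 * sign(sum(diff(p)) + 1e-12)
  if (method == "glm") {
    stopifnot(all(c("n_thrive", "n_seeds") %in% names(profile)))
    fit <- stats::glm(cbind(n_thrive, n_seeds - n_thrive) ~ dmu_pct,
                      family = stats::binomial(), data = profile)
    bg <- unname(coef(fit))
    out$k <- -bg[2]
    out$mu50 <- -bg[1] / bg[2]
    out$rss <- sum((p - predict(fit, type = "response"))^2)
    out$glm_fit <- fit
    out$converged <- fit$converged && abs(bg[2]) > 1e-10
  } else {
    # Levenberg-Marquardt on the probability scale with an analytic
    # Jacobian (the low-level interface is robust to exact zero-residual
    # solutions on noiseless profiles)
    residual_fn <- function(par) plogis(par[1] + par[2] * mu) - p
    jacobian_fn <- function(par) {
      q <- plogis(par[1] + par[2] * mu)
      w <- q * (1 - q)
      cbind(w, mu * w)
    }
    lm_fit <- tryCatch(
      minpack.lm::nls.lm(
        par = c(b0, b1), fn = residual_fn, jac = jacobian_fn,
        control = minpack.lm::nls.lm.control(maxiter = 500,
                                             ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(lm_fit) || !lm_fit$info %in% 1:4) {
      return(out)
    }
    cf <- lm_fit$par
    if (!all(is.finite(cf)) || abs(cf[2]) < 1e-10) {
      return(out)
    }
    out$k <- -cf[2]
    out$mu50 <- -cf[1] / cf[2]
    out$rss <- sum(lm_fit$fvec^2)
    out$converged <- TRUE
  }
  if (out$converged && is.finite(out$mu50)) {
    out$extrapolated <- out$mu50 < min(mu) || out$mu50 > max(mu)
  }
  out
}

#' Evaluate a fitted logistic curve
#'
#' @param object A `logistic_fit`.
#' @param dmu_pct Percent changes in `mu_max` at which to evaluate.
#' @param ... Unused.
#' @return Predicted thriving probabilities.
#' @export
predict.logistic_fit <- function(object, dmu_pct = object$data$dmu_pct,
                                 ...) {
  if (!object$converged) {
    abort("cannot predict from a non-converged logistic fit",
          class = "driftbalance_fit_error")
  }
  1 / (1 + exp(-object$k * (object$mu50 - dmu_pct)))
}

#' Invert a fitted logistic curve
#'
#' The `dmu_pct` at which the fitted curve attains probability `p`:
#' `mu50 + log((1 - p) / p) / k`.
#'
#' @param fit A converged `logistic_fit`.
#' @param p Probability in (0, 1).
#' @return `dmu_pct` value(s).
#' @export
invert_logistic <- function(fit, p) {
  if (!fit$converged) {
    abort("cannot invert a non-converged logistic fit",
          class = "driftbalance_fit_error")
  }
  stopifnot(all(p > 0 & p < 1))
  fit$mu50 + log((1 - p) / p) / fit$k
}

#' Drift-selection spread widths from a logistic fit
#'
#' The widths of the `dmu_pct` interval over which the fitted thriving
#' probability lies in `[0.025, 0.975]` (`spread95`) or `[0.16, 0.84]`
#' (`spread68`) -- the zones where drift and selection both matter.
#' Closed forms from inverting the logistic:
#' `spread95 = 2 log(0.975/0.025) / |k|`,
#' `spread68 = 2 log(0.84/0.16) / |k|`.
#'
#' @param fit A converged `logistic_fit`.
#' @return Tibble with `spread95` and `spread68` (percent-change
#'   units of `mu_max`).
#' @export
spread_from_fit <- function(fit) {
  if (!inherits(fit, "logistic_fit") || !fit$converged) {
    abort("spread requires a converged logistic fit",
          class = "driftbalance_fit_error")
  }
  tibble::tibble(spread95 = 2 * log(0.975 / 0.025) / abs(fit$k),
                 spread68 = 2 * log(0.84 / 0.16) / abs(fit$k))
}

#' @export
print.logistic_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("<logistic_fit> k = %.4g, mu50 = %.4g%s (%d points, %s)\n",
                x$k, x$mu50,
                if (x$extrapolated) " [extrapolated]" else "",
                x$n_points, x$method))
  } else {
    cat("<logistic_fit> degenerate profile; not converged\n")
  }
  invisible(x)
}

#' @export
tidy.logistic_fit <- function(x, ...) {
  tibble::tibble(term = c("k", "mu50"),
                 estimate = c(x$k, x$mu50))
}

#' @export
glance.logistic_fit <- function(x, ...) {
  sp <- if (x$converged) spread_from_fit(x) else
    tibble::tibble(spread95 = NA_real_, spread68 = NA_real_)
  tibble::tibble(k = x$k, mu50 = x$mu50, spread95 = sp$spread95,
                 spread68 = sp$spread68, rss = x$rss,
                 n_points = x$n_points, converged = x$converged,
                 extrapolated = x$extrapolated)
}

#' @export
autoplot.logistic_fit <- function(object, ...) {
  gg <- ggplot2::ggplot(object$data,
                        ggplot2::aes(.data$dmu_pct, .data$p_thrive)) +
    ggplot2::geom_point(shape = 1, size = 2) +
    ggplot2::labs(x = "% change in mu_max", y = "p(thrive)")
  if (object$converged) {
    grid <- tibble::tibble(
      dmu_pct = seq(min(object$data$dmu_pct), max(object$data$dmu_pct),
                    length.out = 200))
    grid$p_thrive <- predict(object, grid$dmu_pct)
    gg <- gg + ggplot2::geom_line(data = grid, colour = "grey40") +
      ggplot2::geom_vline(xintercept = object$mu50, linetype = 2)
  }
  gg
}

#' Parametric-bootstrap confidence intervals for a logistic fit
#'
#' Resamples binomial thriving counts from the fitted curve
#' (`n_seeds` trials per profile point), refits each resample, and
#' builds confidence intervals for `k` and `mu50` from the bootstrap
#' standard errors with a Student-t quantile on
#' `n_points - 2` degrees of freedom -- a finite-sample correction
#' appropriate for the short (11-point) profiles these sweeps produce.
#'
#' @param fit A converged `logistic_fit`.
#' @param n_seeds Binomial denominator at each profile point.
#' @param B Bootstrap replicates.
#' @param level Confidence level.
#' @return Tibble with one row per parameter: `term, estimate,
#'   std_error, conf_low, conf_high`.
#' @export
bootstrap_logistic_ci <- function(fit, n_seeds = 120, B = 199,
                                  level = 0.95) {
  if (!inherits(fit, "logistic_fit") || !fit$converged) {
    abort("bootstrap requires a converged logistic fit",
          class = "driftbalance_fit_error")
  }
  dmu <- fit$data$dmu_pct
  p_hat <- predict(fit, dmu)
  ks <- ms <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    pb <- rbinom(length(dmu), n_seeds, p_hat) / n_seeds
    fb <- fit_logistic(tibble::tibble(dmu_pct = dmu, p_thrive = pb),
                       degenerate_range = fit$degenerate_range %||% 0.1)
    if (fb$converged) {
      ks[b] <- fb$k
      ms[b] <- fb$mu50
    }
  }
  tq <- stats::qt(1 - (1 - level) / 2, df = length(dmu) - 2)
  mk <- function(term, est, draws) {
    se <- stats::sd(draws, na.rm = TRUE)
    tibble::tibble(term = term, estimate = est, std_error = se,
                   conf_low = est - tq * se, conf_high = est + tq * se)
  }
  dplyr::bind_rows(mk("k", fit$k, ks), mk("mu50", fit$mu50, ms))
}

#' Fit logistic thresholds along every K_s line of a probability map
#'
#' Groups a probability map by crowding condition and `dKs_pct`, fits
#' [fit_logistic()] to each `(dmu_pct, p_thrive)` profile, and collects
#' the threshold parameters and spread widths.
#'
#' @param pmap A `pthrive_map` (long form).
#' @inheritParams fit_logistic
#' @return A `balance_table` tibble: `n_initial, spacing, dKs_pct, k,
#'   mu50, spread95, spread68, converged, extrapolated`.
#' @export
fit_balance <- function(pmap, method = c("nls", "glm"),
                        degenerate_range = 0.1) {
  method <- match.arg(method)
  out <- pmap |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$n_initial, .data$spacing, .data$dKs_pct) |>
    dplyr::group_modify(function(df, key) {
      g <- if (nrow(df) < 4) {
        # too few sweep points to identify the curve: record as
        # non-converged rather than aborting a partial sweep
        tibble::tibble(k = 0, mu50 = NA_real_, spread95 = NA_real_,
                       spread68 = NA_real_, converged = FALSE,
                       extrapolated = FALSE)
      } else {
        glance(fit_logistic(df, method = method,
                            degenerate_range = degenerate_range))
      }
      g[c("k", "mu50", "spread95", "spread68", "converged",
          "extrapolated")]
    }) |>
    dplyr::ungroup()
  class(out) <- c("balance_table", class(out))
  out
}

#' Regress threshold parameters on the half-saturation change
#'
#' Within each crowding condition, ordinary least-squares regression of
#' a balance parameter (`mu50`, `spread95` or `spread68`) on
#' `dKs_pct`, using converged fits only. The slope measures how much
#' extra growth-rate advantage compensates a worsening half-saturation
#' constant.
#'
#' @param balance A `balance_table` from [fit_balance()].
#' @param response One of `"mu50"`, `"spread95"`, `"spread68"`.
#' @return Tibble with one row per crowding condition: `n_initial,
#'   spacing, response, slope, intercept, r_squared, p_value, n_used,
#'   n_excluded`.
#' @export
regress_balance <- function(balance, response = c("mu50", "spread95",
                                                  "spread68")) {
  response <- match.arg(response)
  balance |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$n_initial, .data$spacing) |>
    dplyr::group_modify(function(df, key) {
      use <- df[df$converged & is.finite(df[[response]]), ]
      n_excl <- nrow(df) - nrow(use)
      if (nrow(use) < 3) {
        abort(sprintf(
          "fewer than 3 converged fits for n_initial=%s spacing=%s",
          key$n_initial[[1]], key$spacing[[1]]),
          class = "driftbalance_fit_error")
      }
      if (n_excl > 0) {
        message(sprintf(
          "regress_balance: excluded %d non-converged fits (n=%s, spacing=%s)",
          n_excl, key$n_initial[[1]], key$spacing[[1]]))
      }
      fit <- lm(stats::reformulate("dKs_pct", response), data = use)
      sm <- summary(fit)
      tibble::tibble(
        response = response,
        slope = unname(coef(fit)[2]),
        intercept = unname(coef(fit)[1]),
        r_squared = sm$r.squared,
        p_value = sm$coefficients[2, 4],
        n_used = nrow(use),
        n_excluded = n_excl)
    }) |>
    dplyr::ungroup()
}
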