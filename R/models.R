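#' Pseudo-probability logit transform
#'
#' The log-odds transform used for the linear description of
#' `p_thrive`, with a small pseudo-probability `eps` guarding both the
#' division and the logarithm: `log(p / (1 - p + eps) + eps)`.
#' Exact zeros and ones map to finite values (about -13.8 and +13.8
#' for the default `eps`).
#'
#' @param p Probabilities in `[0, 1]`.
#' @param eps Pseudo-probability, default `1e-6`.
#' @return Transformed values.
#' @examples
#' logit_eps(c(0, 0.5, 1))
#' @export
logit_eps <- function(p, eps = 1e-6) {
  if (any(p < 0 | p > 1)) {
    abort("p must lie in [0, 1]", class = "driftbalance_domain_error")
  }
  log(p / (1 - p + eps) + eps)
}

#' @rdname logit_eps
#' @param y Values on the transformed scale.
#' @export
inv_logit_eps <- function(y, eps = 1e-6) {
  g <- exp(y) - eps
  g * (1 + eps) / (1 + g)
}

# design columns used by the descriptive models
model_frame <- function(pmap, eps = 1e-6) {
  pmap <- tibble::as_tibble(pmap)
  need <- c("n_initial", "spacing", "dKs_pct", "dmu_pct", "p_thrive")
  missing_cols <- setdiff(need, names(pmap))
  if (length(missing_cols) > 0) {
    abort(paste("probability map lacks columns:",
                paste(missing_cols, collapse = ", ")),
          class = "driftbalance_schema_error")
  }
  out <- tibble::tibble(
    mu_p = pmap$dmu_pct, K_p = pmap$dKs_pct,
    N0 = as.numeric(pmap$n_initial), s_i = pmap$spacing,
    si_f = factor(pmap$spacing),
    p_thrive = pmap$p_thrive,
    y = logit_eps(pmap$p_thrive, eps))
  # extra numeric covariates pass through so custom term sets can use them
  extra <- setdiff(names(pmap), c(need, "n_seeds", "n_thrive", "true_p"))
  for (nm in extra) {
    if (is.numeric(pmap[[nm]]) && !nm %in% names(out)) {
      out[[nm]] <- pmap[[nm]]
    }
  }
  out
}

term_vars <- function(term) {
  v <- all.vars(stats::reformulate(term))
  core <- setdiff(v, "si_f")
  if ("si_f" %in% v) core <- union(core, "s_i")
  core
}

term_order <- function(term) length(term_vars(term))

# a term is droppable when no other retained term strictly contains its
# variable set (marginality; also encodes "main effects retained while part
# of a retained interaction")
droppable_terms <- function(terms) {
  vars <- lapply(terms, term_vars)
  keep <- vapply(seq_along(terms), function(i) {
    !any(vapply(seq_along(terms), function(j) {
      j != i && all(vars[[i]] %in% vars[[j]]) &&
        length(vars[[j]]) > length(vars[[i]])
    }, logical(1)))
  }, logical(1))
  terms[keep]
}

#' Multiple linear regression description of a probability map
#'
#' Ordinary least squares on the `eps`-guarded log-odds of `p_thrive`
#' with terms in the percent kinetic changes (`mu_p`, `K_p`), initial
#' population size (`N0`) and spacing (`s_i`). The default term set is
#' the mains plus the `mu_p:s_i` and `K_p:s_i` interactions; set
#' `interactions = FALSE` for the main-effects-only baseline, or pass
#' an explicit `terms` character vector.
#'
#' Predictions are back-transformed through the inverse transform and
#' clipped to `[0, 1]`, so the reported RMSE is commensurable with the
#' GAM's probability-scale RMSE.
#'
#' @param pmap A `pthrive_map` (long form).
#' @param interactions Include the spacing-by-kinetics interactions.
#' @param terms Optional explicit term vector (overrides
#'   `interactions`).
#' @param eps Pseudo-probability for the transform.
#' @return Object of class `c("mlr_fit", "descriptive_fit")`; see
#'   [model_metrics()], [tidy.descriptive_fit()].
#' @export
fit_mlr <- function(pmap, interactions = TRUE, terms = NULL, eps = 1e-6) {
  mf <- model_frame(pmap, eps)
  if (is.null(terms)) {
    terms <- c("mu_p", "K_p", "N0", "s_i")
    if (interactions) terms <- c(terms, "mu_p:s_i", "K_p:s_i")
  }
  fml <- stats::reformulate(terms, response = "y")
  fit <- lm(fml, data = mf)
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    abort(paste("rank-deficient design; aliased terms:",
                paste(bad, collapse = ", ")),
          class = "driftbalance_rank_deficient")
  }
  structure(list(fit = fit, terms = terms, eps = eps, data = mf,
                 type = "mlr", clipped = TRUE),
            class = c("mlr_fit", "descriptive_fit"))
}

#' Generalized additive description of a probability map
#'
#' Penalized-spline additive model fitted directly to `p_thrive`
#' (Gaussian response on the probability scale; the fit is not
#' constrained to `[0, 1]` and predictions are reported unclipped with
#' a flag). The default term set has univariate smooths of the four
#' factors, tensor-product smooths of the two- and three-way
#' interactions `mu_p:K_p`, `mu_p:s_i`, `K_p:s_i`, `mu_p:K_p:N0`,
#' `mu_p:K_p:s_i`, and a by-factor smooth of `N0` within each spacing.
#' Smoothing parameters are chosen by generalized cross-validation.
#'
#' @param pmap A `pthrive_map`.
#' @param terms Optional explicit term vector of smooth specifications.
#' @param k_cont Basis dimension per continuous marginal (`mu_p`,
#'   `K_p`); the design levels (3 values) cap `N0`/`s_i` marginals
#'   at 3.
#' @return Object of class `c("gam_fit", "descriptive_fit")`.
#' @export
fit_gam <- function(pmap, terms = NULL, k_cont = 5) {
  mf <- model_frame(pmap)
  n_si <- length(unique(mf$s_i))
  n_n0 <- length(unique(mf$N0))
  kd <- min(3, n_n0)
  ks <- min(3, n_si)
  if (is.null(terms)) {
    terms <- c(
      sprintf("s(mu_p, k = %d)", k_cont),
      sprintf("s(K_p, k = %d)", k_cont),
      if (n_n0 >= 3) sprintf("s(N0, k = %d)", kd) else "N0",
      if (n_si >= 3) sprintf("s(s_i, k = %d)", ks) else "s_i",
      sprintf("te(mu_p, K_p, k = c(%d, %d))", k_cont, k_cont),
      if (n_si >= 3)
        sprintf("te(mu_p, s_i, k = c(%d, %d))", k_cont, ks),
      if (n_si >= 3)
        sprintf("te(K_p, s_i, k = c(%d, %d))", k_cont, ks),
      if (n_n0 >= 3 && n_si >= 2)
        sprintf("s(N0, by = si_f, k = %d)", kd),
      if (n_n0 >= 3)
        sprintf("te(mu_p, K_p, N0, k = c(%d, %d, %d))", k_cont, k_cont, kd),
      if (n_si >= 3)
        sprintf("te(mu_p, K_p, s_i, k = c(%d, %d, %d))", k_cont, k_cont, ks))
  }
  fml <- as.formula(paste("p_thrive ~", paste(terms, collapse = " + ")))
  fit <- tryCatch(
    mgcv::gam(fml, data = mf, method = "GCV.Cp"),
    error = function(e) {
      abort(paste("GAM smoothing failed to converge:",
                  conditionMessage(e)),
            class = "driftbalance_fit_error")
    })
  structure(list(fit = fit, terms = terms, data = mf, type = "gam",
                 clipped = FALSE),
            class = c("gam_fit", "descriptive_fit"))
}

#' Predict thriving probabilities from a descriptive model
#'
#' MLR predictions are back-transformed to the probability scale and
#' clipped to `[0, 1]`; GAM predictions are returned as fitted
#' (possibly outside `[0, 1]`, with the `out_of_range` attribute
#' counting offenders).
#'
#' @param object A `descriptive_fit`.
#' @param newdata Optional probability map to predict for (defaults to
#'   the training map).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.descriptive_fit <- function(object, newdata = NULL, ...) {
  mf <- if (is.null(newdata)) object$data else model_frame(newdata)
  raw <- as.numeric(predict(object$fit, newdata = mf))
  if (object$type == "mlr") {
    p <- inv_logit_eps(raw, object$eps)
    pmin(pmax(p, 0), 1)
  } else {
    structure(raw, out_of_range = sum(raw < 0 | raw > 1))
  }
}

#' Fit quality of a descriptive model on the probability scale
#'
#' RMSE and R-squared between predicted and observed `p_thrive`
#' (probability scale for both model families, so the two are directly
#' comparable), plus the AIC of the fitted likelihood.
#'
#' @param fit A `descriptive_fit`.
#' @param pmap Optional map to evaluate on (defaults to training data).
#' @return Tibble with `rmse, r_squared, aic, n`.
#' @export
model_metrics <- function(fit, pmap = NULL) {
  mf <- if (is.null(pmap)) fit$data else model_frame(pmap)
  obs <- mf$p_thrive
  pred <- as.numeric(predict(fit, newdata = if (is.null(pmap)) NULL
                             else pmap))
  rmse <- sqrt(mean((obs - pred)^2))
  ss_res <- sum((obs - pred)^2)
  ss_tot <- sum((obs - mean(obs))^2)
  tibble::tibble(rmse = rmse,
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else
                   NA_real_,
                 aic = AIC(fit$fit),
                 n = length(obs))
}

# per-term p-values for the current fit, named by term label
term_pvalues <- function(fit) {
  if (fit$type == "mlr") {
    dr <- stats::drop1(fit$fit, test = "F")
    pv <- dr[["Pr(>F)"]]
    names(pv) <- rownames(dr)
    pv <- pv[!is.na(pv)]
    # map formula labels back to our term strings
    out <- setNames(rep(NA_real_, length(fit$terms)), fit$terms)
    for (tm in fit$terms) {
      hit <- which(rownames(dr) == tm)
      if (length(hit) == 1) out[tm] <- dr[["Pr(>F)"]][hit]
    }
    out[!is.na(out)]
  } else {
    sm <- summary(fit$fit)
    st <- sm$s.table
    pt <- sm$p.table
    canon <- function(s) {
      s <- gsub("\\s+", "", s)
      s <- gsub(",k=c\\([^)]*\\)", "", s)
      gsub(",k=[0-9]+", "", s)
    }
    out <- setNames(rep(NA_real_, length(fit$terms)), fit$terms)
    st_canon <- canon(rownames(st))
    for (tm in fit$terms) {
      base <- canon(tm)
      if (grepl("^s\\(|^te\\(", base)) {
        if (grepl("by=si_f", base, fixed = TRUE)) {
          # by-factor smooth: one fitted smooth per level; use the
          # smallest p so the term survives if any level matters
          var <- sub("^s\\(([^,]*),.*$", "\\1", base)
          rows <- grep(paste0("^s\\(", var, "\\):si_f"), rownames(st))
        } else {
          rows <- which(st_canon == base)
        }
        if (length(rows) > 0) out[tm] <- min(st[rows, "p-value"])
      } else {
        hit <- which(rownames(pt) == tm)
        if (length(hit) == 1) out[tm] <- pt[hit, 4]
      }
    }
    out[!is.na(out)]
  }
}

#' Backward term selection for the descriptive models
#'
#' Starting from a factorial term set (by default: up to three-way
#' interactions), iteratively removes the least significant term among
#' the highest-order terms whose p-value exceeds `alpha`, refitting
#' after each removal. A term is only ever removed when no retained
#' term contains it, so main effects are kept whenever they are part
#' of a retained (significant) interaction.
#'
#' @param pmap A `pthrive_map`.
#' @param type `"mlr"` or `"gam"`.
#' @param alpha Significance threshold, default 0.05.
#' @param terms Optional starting term set; defaults to the factorial
#'   set up to three-way interactions for the MLR, or the standard
#'   smooth set for the GAM (see [fit_gam()]).
#' @param max_steps Safety cap on removals.
#' @return List of class `model_selection` with the final `fit`, the
#'   retained `terms` and a `dropped` tibble recording each removal
#'   (term, p-value, step).
#' @export
backward_select <- function(pmap, type = c("mlr", "gam"), alpha = 0.05,
                            terms = NULL, max_steps = 50) {
  type <- match.arg(type)
  if (is.null(terms)) {
    terms <- if (type == "mlr") {
      v <- c("mu_p", "K_p", "N0", "s_i")
      c(v, utils::combn(v, 2, paste, collapse = ":"),
        utils::combn(v, 3, paste, collapse = ":"))
    } else {
      NULL # fit_gam's default set
    }
  }
  refit <- function(tms) {
    if (type == "mlr") fit_mlr(pmap, terms = tms) else
      fit_gam(pmap, terms = tms)
  }
  fit <- refit(terms)
  terms <- fit$terms
  dropped <- tibble::tibble(step = integer(), term = character(),
                            p_value = double())
  for (step in seq_len(max_steps)) {
    pv <- term_pvalues(fit)
    cand <- intersect(droppable_terms(fit$terms), names(pv))
    cand <- cand[pv[cand] > alpha]
    if (length(cand) == 0) break
    orders <- vapply(cand, term_order, numeric(1))
    cand <- cand[orders == max(orders)]
    victim <- cand[which.max(pv[cand])]
    dropped <- dplyr::bind_rows(dropped, tibble::tibble(
      step = step, term = victim, p_value = unname(pv[victim])))
    terms <- setdiff(fit$terms, victim)
    if (length(terms) == 0) break
    fit <- refit(terms)
  }
  structure(list(fit = fit, terms = fit$terms, dropped = dropped,
                 alpha = alpha, type = type),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat(sprintf("<model_selection> %s, %d terms retained, %d dropped\n",
              toupper(x$type), length(x$terms), nrow(x$dropped)))
  if (nrow(x$dropped) > 0) {
    cat("  dropped:", paste(x$dropped$term, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy coefficients / smooth terms of a descriptive model
#'
#' For the MLR: coefficient estimates, standard errors and p-values.
#' For the GAM: one row per smooth with effective degrees of freedom
#' and approximate Wald p-value, plus parametric terms.
#'
#' @param x A `descriptive_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.descriptive_fit <- function(x, ...) {
  if (x$type == "mlr") {
    sm <- summary(x$fit)$coefficients
    tibble::tibble(term = rownames(sm), estimate = sm[, 1],
                   std_error = sm[, 2], statistic = sm[, 3],
                   p_value = sm[, 4])
  } else {
    sm <- summary(x$fit)
    st <- sm$s.table
    pt <- sm$p.table
    dplyr::bind_rows(
      tibble::tibble(term = rownames(pt), type = "parametric",
                     estimate = pt[, 1], edf = NA_real_,
                     p_value = pt[, 4]),
      tibble::tibble(term = rownames(st), type = "smooth",
                     estimate = NA_real_, edf = st[, "edf"],
                     p_value = st[, "p-value"]))
  }
}

#' @export
glance.descriptive_fit <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(type = x$type,
                                  n_terms = length(x$terms)),
                   model_metrics(x))
}

#' @export
print.descriptive_fit <- function(x, ...) {
  m <- model_metrics(x)
  cat(sprintf("<%s_fit> %d terms; RMSE %.4f, R^2 %.3f, AIC %.1f\n",
              x$type, length(x$terms), m$rmse, m$r_squared, m$aic))
  invisible(x)
}

#' Write a descriptive-model report as JSON
#'
#' Terms, tidy coefficients/EDFs and p-values, and probability-scale
#' fit metrics, in one JSON document.
#'
#' @param fit A `descriptive_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_report <- function(fit, path) {
  report <- list(type = fit$type, terms = fit$terms,
                 coefficients = tidy(fit), metrics = model_metrics(fit))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
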