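#' Maximum-likelihood logistic propensity fit
#'
#' Fits `Pr(Z = 1 | x)` by logistic regression (via [stats::glm.fit()]) on a
#' numeric design matrix. An intercept column is prepended. Errors on rank
#' deficiency (naming the collinear columns) and on (quasi-)separation, where
#' fitted probabilities collapse to 0 or 1.
#'
#' @param z Integer 0/1 vector (1 = minority).
#' @param x Numeric matrix of covariates, one row per subject (no intercept
#'   column).
#' @return A list with `coefficients` (named, intercept first), `fitted`
#'   (probabilities in (0,1)), `iterations`, and `converged`.
#' @export
fit_logistic_ml <- function(z, x) {
  x <- as.matrix(x)
  if (is.null(colnames(x)) && ncol(x) > 0) {
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  }
  design <- cbind(`(Intercept)` = 1, x)
  if (nrow(design) <= ncol(design)) {
    abort("More design columns than subjects.", class = "deweight_fit_error")
  }
  qd <- qr(design)
  if (qd$rank < ncol(design)) {
    dropped <- colnames(design)[qd$pivot[(qd$rank + 1):ncol(design)]]
    abort(sprintf("Design matrix is rank deficient; collinear column(s): %s",
                  paste(dropped, collapse = ", ")),
          class = "deweight_fit_error")
  }
  fit <- suppressWarnings(
    stats::glm.fit(design, z, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-12,
                                                maxit = 100))
  )
  e <- fit$fitted.values
  eps <- 1e-10
  if (!fit$converged || any(e < eps) || any(e > 1 - eps)) {
    abort(paste0(
      "Logistic fit did not converge to interior probabilities ",
      "(perfect or quasi-separation likely)."
    ), class = "deweight_separation_error")
  }
  list(
    coefficients = setNames(fit$coefficients, colnames(design)),
    fitted = as.numeric(e),
    iterations = fit$iter,
    converged = TRUE
  )
}

# Balance-equation residual (mean form) for the just-identified
# covariate-balancing score. `design` includes the intercept column.
cbps_residual <- function(beta, z, design, estimand) {
  eta <- drop(design %*% beta)
  # 1/e = 1 + exp(-eta), 1/(1-e) = 1 + exp(eta), e/(1-e) = exp(eta);
  # evaluated group-wise to stay finite under overflow
  c_i <- switch(estimand,
    ate = ifelse(z == 1, 1 + exp(-eta), -(1 + exp(eta))),
    att = ifelse(z == 1, 1, -exp(eta))
  )
  drop(crossprod(design, c_i)) / length(z)
}

# The balance equations are the stationarity conditions of a smooth convex
# objective (the dual of an exponential tilting problem): with eta = x'beta,
#   ATE: f = mean[ Z exp(-eta) + (1-Z) exp(eta) - (2Z-1) eta ]
#   ATT: f = mean[ (1-Z) exp(eta) - Z eta ]
# and in both cases the gradient equals minus the mean-form balance
# residual, so damped Newton on f is globally convergent whenever a
# balancing solution exists.
cbps_objective <- function(beta, z, design, estimand) {
  eta <- drop(design %*% beta)
  # evaluate group-wise so an overflowing exp() in the other group cannot
  # produce 0 * Inf
  val <- switch(estimand,
    ate = ifelse(z == 1, exp(-eta), exp(eta)) - (2 * z - 1) * eta,
    att = ifelse(z == 1, -eta, exp(eta))
  )
  mean(val)
}

cbps_hessian <- function(beta, z, design, estimand) {
  eta <- drop(design %*% beta)
  w <- switch(estimand,
    ate = ifelse(z == 1, exp(-eta), exp(eta)),
    att = ifelse(z == 1, 0, exp(eta))
  )
  crossprod(design, design * w) / length(z)
}

#' Just-identified covariate-balancing propensity score (CBPS)
#'
#' Chooses logistic coefficients so the weighted covariate balance equations
#' hold exactly rather than maximizing the likelihood. For the ATE the
#' conditions are `mean([Z/e - (1-Z)/(1-e)] x) = 0`; for the ATT,
#' `mean([Z - (1-Z) e/(1-e)] x) = 0`. For the ATO the maximum-likelihood fit
#' is returned unchanged, because overlap weights attain exact balance at the
#' ML solution. Solved by damped Newton iteration started at the ML
#' coefficients; columns are rescaled internally for conditioning and the
#' coefficients back-transformed.
#'
#' @inheritParams fit_logistic_ml
#' @param estimand One of `"ate"`, `"att"`, `"ato"`.
#' @param tol Convergence tolerance on the max-norm of the mean-form balance
#'   residual.
#' @param max_iter Maximum Newton iterations.
#' @return As [fit_logistic_ml()], plus `residual_norm` (max-norm of the
#'   balance residual at the solution) and `estimand`.
#' @export
fit_cbps <- function(z, x, estimand = c("ate", "att", "ato"),
                     tol = 1e-8, max_iter = 200) {
  estimand <- arg_match(estimand)
  ml <- fit_logistic_ml(z, x)
  if (estimand == "ato") {
    ml$estimand <- "ato"
    ml$residual_norm <- NA_real_
    return(ml)
  }
  x <- as.matrix(x)
  scales <- if (ncol(x) > 0) apply(x, 2, sd) else numeric(0)
  scales[!is.finite(scales) | scales == 0] <- 1
  xs <- sweep(x, 2, scales, "/")
  design <- cbind(1, xs)
  beta <- ml$coefficients * c(1, scales)

  r <- cbps_residual(beta, z, design, estimand)
  f <- cbps_objective(beta, z, design, estimand)
  iter <- 0L
  while (max(abs(r)) > tol && iter < max_iter) {
    iter <- iter + 1L
    H <- cbps_hessian(beta, z, design, estimand)
    # Newton direction for minimizing f: H step = -grad f = r
    step <- tryCatch(solve(H, r), error = function(e) NULL)
    if (is.null(step)) {
      H <- H + diag(1e-8, ncol(H))
      step <- solve(H, r)
    }
    lambda <- 1
    repeat {
      beta_new <- beta + lambda * step
      f_new <- cbps_objective(beta_new, z, design, estimand)
      if (is.finite(f_new) && f_new <= f - 1e-4 * lambda * sum(r * step)) break
      lambda <- lambda / 2
      if (lambda < 1e-14) break
    }
    if (lambda < 1e-14) break
    beta <- beta_new
    f <- f_new
    r <- cbps_residual(beta, z, design, estimand)
  }
  if (max(abs(r)) > tol) {
    abort(sprintf(
      "CBPS balance equations did not converge (residual max-norm %.3e after %d iterations).",
      max(abs(r)), iter
    ), class = "deweight_fit_error")
  }
  e <- expit(drop(design %*% beta))
  list(
    coefficients = setNames(beta / c(1, scales), names(ml$coefficients)),
    fitted = as.numeric(e),
    iterations = iter,
    converged = TRUE,
    residual_norm = max(abs(r)),
    estimand = estimand
  )
}

#' Fit a propensity score model for disparity analysis
#'
#' Estimates one of the three propensity scores of the deweighting framework:
#'
#' * `model = "ses"`: the SES-only score `e(x^s)`. SES covariates are
#'   categorical, so the model (all main effects and interactions) is
#'   saturated and the fit equals the minority proportion within each SES
#'   subgroup.
#' * `model = "full"`, `stratify = TRUE` (default): the SES-stratum-specific
#'   health-status score (SSHS-PS) — the full score `e(x)` fitted within each
#'   SES subgroup on the main effects of the health-status covariates.
#' * `model = "full"`, `stratify = FALSE`: a pooled logistic model on SES and
#'   health-status main effects.
#' * `model = "health"`: the health-status-only score `e(x^h)`, pooled.
#'
#' @param data A `disparity_df`.
#' @param model `"full"`, `"ses"`, or `"health"`.
#' @param method `"cbps"` (just-identified covariate balancing, the default)
#'   or `"ml"` (maximum likelihood). Ignored for `model = "ses"`, where both
#'   coincide with the saturated fit.
#' @param estimand Estimand whose balance conditions the CBPS targets
#'   (`"ate"`, `"att"`, `"ato"`).
#' @param stratify Fit the full model separately within each SES subgroup.
#' @param on_stratum_error For stratified fits: `"error"` (default) fails
#'   naming the stratum; `"pool"` falls back to a pooled health-status model
#'   for strata that cannot be fitted, with a message.
#' @return A `ps_fit` object: list with `ps` (per-subject probabilities),
#'   `model`, `method`, `estimand`, `stratified`, `strata` (per-stratum
#'   convergence tibble) and `coefficients`.
#' @export
fit_ps <- function(data, model = c("full", "ses", "health"),
                   method = c("cbps", "ml"),
                   estimand = c("ate", "att", "ato"),
                   stratify = NULL,
                   on_stratum_error = c("error", "pool")) {
  model <- arg_match(model)
  method <- arg_match(method)
  estimand <- arg_match(estimand)
  on_stratum_error <- arg_match(on_stratum_error)
  roles <- roles_of(data)
  z <- data$.z

  if (model == "ses") {
    return(fit_ses_ps(data))
  }

  fitter <- function(z, x) {
    if (method == "ml") fit_logistic_ml(z, x) else fit_cbps(z, x, estimand)
  }

  if (model == "health" || isFALSE(stratify)) {
    x <- if (model == "health") {
      encode_columns(data, roles$health)
    } else {
      cbind(encode_columns(data, roles$ses), encode_columns(data, roles$health))
    }
    fit <- fitter(z, x)
    strata <- tibble::tibble(
      .g = NA_integer_, n = length(z), iterations = fit$iterations,
      residual_norm = fit$residual_norm %||% NA_real_, pooled_fallback = FALSE
    )
    return(new_ps_fit(fit$fitted, model, method, estimand,
                      stratified = FALSE, strata = strata,
                      coefficients = list(fit$coefficients)))
  }

  # Stratified full model: health-status main effects within each subgroup.
  g <- data$.g
  ps <- numeric(nrow(data))
  coefs <- list()
  records <- vector("list", max(g))
  pooled <- NULL
  for (r in sort(unique(g))) {
    idx <- which(g == r)
    x_r <- encode_columns(data[idx, , drop = FALSE], roles$health)
    fit_r <- tryCatch(
      fitter(z[idx], x_r),
      error = function(e) e
    )
    fallback <- FALSE
    if (inherits(fit_r, "error")) {
      if (on_stratum_error == "error") {
        abort(sprintf("Propensity fit failed in SES subgroup %d: %s",
                      r, conditionMessage(fit_r)),
              class = "deweight_fit_error")
      }
      if (is.null(pooled)) {
        pooled <- fitter(z, encode_columns(data, roles$health))
      }
      inform(sprintf(
        "SES subgroup %d could not be fitted (%s); using pooled health-status model.",
        r, conditionMessage(fit_r)
      ))
      fit_r <- list(fitted = pooled$fitted[idx],
                    coefficients = pooled$coefficients,
                    iterations = pooled$iterations,
                    residual_norm = pooled$residual_norm %||% NA_real_)
      fallback <- TRUE
    }
    ps[idx] <- fit_r$fitted
    coefs[[as.character(r)]] <- fit_r$coefficients
    records[[r]] <- tibble::tibble(
      .g = r, n = length(idx), iterations = fit_r$iterations,
      residual_norm = fit_r$residual_norm %||% NA_real_,
      pooled_fallback = fallback
    )
  }
  new_ps_fit(ps, "full", method, estimand, stratified = TRUE,
             strata = dplyr::bind_rows(records), coefficients = coefs)
}

#' Saturated SES-only propensity score
#'
#' The SES covariates are categorical, so the logistic model with all main
#' effects and interactions is saturated: the fitted score for every subject
#' in SES subgroup `r` is the subgroup's minority proportion. A subgroup with
#' no minority or no majority subjects violates positivity and is an error
#' (no silent clipping).
#'
#' @param data A `disparity_df`.
#' @return A `ps_fit` with `model = "ses"`.
#' @export
fit_ses_ps <- function(data) {
  roles_of(data)
  cat <- ses_subgroups(data)
  bad <- cat$.g[cat$n_minority == 0 | cat$n_majority == 0]
  if (length(bad) > 0) {
    abort(sprintf(
      "Positivity violated: SES subgroup(s) %s lack minority or majority subjects.",
      paste(bad, collapse = ", ")
    ), class = "deweight_positivity_error")
  }
  prop <- cat$n_minority / cat$n
  ps <- prop[match(data$.g, cat$.g)]
  strata <- tibble::tibble(.g = cat$.g, n = cat$n, iterations = 0L,
                           residual_norm = 0, pooled_fallback = FALSE)
  new_ps_fit(ps, "ses", "saturated", estimand = NA_character_,
             stratified = TRUE, strata = strata,
             coefficients = list(setNames(prop, paste0("subgroup_", cat$.g))))
}

new_ps_fit <- function(ps, model, method, estimand, stratified, strata,
                       coefficients) {
  check_prob_open(ps)
  structure(
    list(ps = as.numeric(ps), model = model, method = method,
         estimand = estimand, stratified = stratified, strata = strata,
         coefficients = coefficients),
    class = "ps_fit"
  )
}

#' @export
print.ps_fit <- function(x, ...) {
  cat(sprintf("# ps_fit: %s model, %s, %s%s\n",
              x$model, x$method,
              if (is.na(x$estimand)) "saturated" else x$estimand,
              if (x$stratified) sprintf(", %d stratum fits", nrow(x$strata)) else ""))
  cat(sprintf("# fitted range: [%.4f, %.4f]\n", min(x$ps), max(x$ps)))
  invisible(x)
}

#' @describeIn fit_ps Per-stratum convergence records as a tibble.
#' @param x A `ps_fit`.
#' @param ... Unused.
#' @export
tidy.ps_fit <- function(x, ...) x$strata

#' @describeIn fit_ps One-row model summary.
#' @export
glance.ps_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model, method = x$method, estimand = x$estimand,
    stratified = x$stratified, n = sum(x$strata$n),
    min_ps = min(x$ps), max_ps = max(x$ps),
    max_residual = suppressWarnings(max(x$strata$residual_norm, na.rm = TRUE))
  )
}
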