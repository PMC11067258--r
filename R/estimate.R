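new_disparity_est <- function(estimate, mu1, mu0, se, conf_low, conf_high,
                              estimand, method, n1, n0, conf_level,
                              p_value = NA_real_, binary = NA) {
  structure(
    list(estimate = estimate, mu1 = mu1, mu0 = mu0, se = se,
         conf_low = conf_low, conf_high = conf_high, estimand = estimand,
         method = method, n1 = n1, n0 = n0, conf_level = conf_level,
         p_value = p_value, binary = binary),
    class = "disparity_est"
  )
}

hajek_means <- function(y, z, weight) {
  w1 <- weight[z == 1]
  w0 <- weight[z == 0]
  if (sum(w1) <= 0 || sum(w0) <= 0) {
    abort("Zero total weight in a group.", class = "deweight_error")
  }
  c(mu1 = sum(w1 * y[z == 1]) / sum(w1),
    mu0 = sum(w0 * y[z == 0]) / sum(w0))
}

# Taylor-linearization variance of a Hajek mean with fixed weights:
# V = sum(w^2 (y - mu)^2) / (sum w)^2.
hajek_var <- function(y, w, mu) sum(w^2 * (y - mu)^2) / sum(w)^2

#' Weighted disparity estimate
#'
#' The Hajek difference of weighted outcome means,
#' `tau = sum(w1 Z Y)/sum(w1 Z) - sum(w0 (1-Z) Y)/sum(w0 (1-Z))`,
#' for a given weight set. Invariant to rescaling the weights of either
#' group. The default standard error is a fixed-weight Taylor linearization
#' of the two Hajek means with independent groups (uncertainty from
#' propensity estimation is ignored); a subject-resampling bootstrap within
#' groups is available as a cross-check. Intervals use normal quantiles.
#'
#' @param data A `disparity_df`.
#' @param weights A `weight_set` aligned with `data` (see
#'   [disparity_weights()]).
#' @param conf_level Confidence level (default 0.95).
#' @param ci_method `"linearization"` (default) or `"bootstrap"`.
#' @param boot_reps Bootstrap replicates when `ci_method = "bootstrap"`.
#' @return A `disparity_est`: point estimate (`mu1 - mu0`, outcome scale),
#'   group means, standard error and confidence bounds. For a binary outcome
#'   the print method reports percentage points; the stored values stay on
#'   the raw scale. Use [tidy()] for a one-row tibble.
#' @export
estimate_disparity <- function(data, weights, conf_level = 0.95,
                               ci_method = c("linearization", "bootstrap"),
                               boot_reps = 2000) {
  ci_method <- arg_match(ci_method)
  roles <- roles_of(data)
  stopifnot(inherits(weights, "weight_set"))
  if (nrow(weights) != nrow(data) || !identical(weights$z, data$.z)) {
    abort("Weight set is not aligned with the data.", class = "deweight_error")
  }
  y <- as.numeric(data[[roles$outcome]])
  z <- data$.z
  w <- weights$weight
  mus <- hajek_means(y, z, w)
  est <- unname(mus["mu1"] - mus["mu0"])

  if (sum(z == 1) < 2 || sum(z == 0) < 2) {
    abort("Each group needs at least 2 subjects for a variance estimate.",
          class = "deweight_error")
  }
  if (ci_method == "linearization") {
    se <- sqrt(hajek_var(y[z == 1], w[z == 1], mus["mu1"]) +
                 hajek_var(y[z == 0], w[z == 0], mus["mu0"]))
  } else {
    i1 <- which(z == 1)
    i0 <- which(z == 0)
    reps <- vapply(seq_len(boot_reps), function(b) {
      s1 <- sample(i1, length(i1), replace = TRUE)
      s0 <- sample(i0, length(i0), replace = TRUE)
      sum(w[s1] * y[s1]) / sum(w[s1]) - sum(w[s0] * y[s0]) / sum(w[s0])
    }, numeric(1))
    se <- stats::sd(reps)
  }
  zq <- qnorm(1 - (1 - conf_level) / 2)
  new_disparity_est(
    estimate = est, mu1 = unname(mus["mu1"]), mu0 = unname(mus["mu0"]),
    se = se, conf_low = est - zq * se, conf_high = est + zq * se,
    estimand = attr(weights, "estimand"), method = attr(weights, "method"),
    n1 = sum(z), n0 = sum(1 - z), conf_level = conf_level,
    binary = all(y %in% c(0, 1))
  )
}

#' Unadjusted group difference
#'
#' Crude minority-minus-majority difference in outcome means. For a binary
#' outcome this is the difference of proportions with an unpooled
#' normal-approximation interval and two-sided p-value; for a continuous
#' outcome the point estimate and a two-sample normal interval are returned
#' without a proportion test.
#'
#' @param data A `disparity_df`.
#' @param conf_level Confidence level.
#' @return A `disparity_est` with `method = "unadjusted"`.
#' @export
unadjusted_difference <- function(data, conf_level = 0.95) {
  roles <- roles_of(data)
  y <- as.numeric(data[[roles$outcome]])
  z <- data$.z
  n1 <- sum(z)
  n0 <- sum(1 - z)
  mu1 <- mean(y[z == 1])
  mu0 <- mean(y[z == 0])
  est <- mu1 - mu0
  binary <- all(y %in% c(0, 1))
  if (binary) {
    se <- sqrt(mu1 * (1 - mu1) / n1 + mu0 * (1 - mu0) / n0)
    p <- 2 * pnorm(-abs(est / se))
  } else {
    se <- sqrt(var(y[z == 1]) / n1 + var(y[z == 0]) / n0)
    p <- NA_real_
  }
  zq <- qnorm(1 - (1 - conf_level) / 2)
  new_disparity_est(est, mu1, mu0, se, est - zq * se, est + zq * se,
                    estimand = "crude", method = "unadjusted",
                    n1 = n1, n0 = n0, conf_level = conf_level,
                    p_value = p, binary = binary)
}

#' @export
print.disparity_est <- function(x, ...) {
  scale <- if (isTRUE(x$binary)) 100 else 1
  unit <- if (isTRUE(x$binary)) " percentage points" else ""
  cat(sprintf("# disparity_est: %s / %s\n", x$estimand, x$method))
  cat(sprintf("estimate %.2f%s (%d%% CI %.2f to %.2f), se %.3f\n",
              x$estimate * scale, unit, round(100 * x$conf_level),
              x$conf_low * scale, x$conf_high * scale, x$se * scale))
  cat(sprintf("group means: minority %.4f, majority %.4f (n = %d / %d)\n",
              x$mu1, x$mu0, x$n1, x$n0))
  if (!is.na(x$p_value)) cat(sprintf("p-value %.3f\n", x$p_value))
  invisible(x)
}

#' @describeIn estimate_disparity One-row tibble of the estimate. With
#'   `percent = TRUE` the estimate, bounds and se are multiplied by 100
#'   (percentage points, for binary outcomes).
#' @param x A `disparity_est`.
#' @param percent Report on the percentage-point scale.
#' @param ... Unused.
#' @export
tidy.disparity_est <- function(x, percent = FALSE, ...) {
  s <- if (percent) 100 else 1
  tibble::tibble(
    estimand = x$estimand, method = x$method,
    estimate = x$estimate * s, mu1 = x$mu1 * s, mu0 = x$mu0 * s,
    std.error = x$se * s, conf.low = x$conf_low * s,
    conf.high = x$conf_high * s, p.value = x$p_value
  )
}

#' @describeIn estimate_disparity One-row fit summary.
#' @export
glance.disparity_est <- function(x, ...) {
  tibble::tibble(estimand = x$estimand, method = x$method,
                 n_minority = x$n1, n_majority = x$n0,
                 conf_level = x$conf_level, binary_outcome = x$binary)
}

#' Weighted characteristics of the target populations
#'
#' Weighted covariate means by group — the weighted "Table 1" describing the
#' hypothetical populations the weights create. For each covariate `j`,
#' `m1 = sum(w1 Z X_j)/sum(w1 Z)` and `m0 = sum(w0 (1-Z) X_j)/sum(w0 (1-Z))`.
#' Categorical covariates are dummy-encoded (most frequent level as
#' reference), and the weighted group totals (sums of weights) are attached
#' as attributes `n1_weighted` / `n0_weighted` — the "N" rows of a weighted
#' characteristics table.
#'
#' @param data A `disparity_df`.
#' @param weights A `weight_set` aligned with `data`, or `NULL` for
#'   unweighted (raw) group means.
#' @param covariates Covariate names; defaults to all SES and health-status
#'   covariates.
#' @return A tibble: `covariate`, `m1` (weighted minority mean), `m0`
#'   (weighted majority mean), `raw1`, `raw0` (unweighted group means).
#' @export
weighted_characteristics <- function(data, weights = NULL, covariates = NULL) {
  roles <- roles_of(data)
  covariates <- covariates %||% c(roles$ses, roles$health)
  z <- data$.z
  w <- if (is.null(weights)) rep(1, nrow(data)) else {
    stopifnot(inherits(weights, "weight_set"))
    weights$weight
  }
  xmat <- encode_columns(data, covariates)
  res <- purrr::map_dfr(colnames(xmat), function(nm) {
    xj <- xmat[, nm]
    tibble::tibble(
      covariate = nm,
      m1 = wmean(xj[z == 1], w[z == 1]),
      m0 = wmean(xj[z == 0], w[z == 0]),
      raw1 = mean(xj[z == 1]),
      raw0 = mean(xj[z == 0])
    )
  })
  attr(res, "n1_weighted") <- sum(w[z == 1])
  attr(res, "n0_weighted") <- sum(w[z == 0])
  res
}
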