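# Selection functions g(e) defining the target population tilts.
g_fun <- function(estimand) {
  switch(estimand,
    ate = function(e) rep(1, length(e)),
    att = function(e) e,
    ato = function(e) e * (1 - e)
  )
}

#' Balancing weights for a named estimand
#'
#' Given propensity scores `e` and a selection function `g` (ATE: `g = 1`;
#' ATT: `g = e`; ATO: `g = e(1-e)`), the balancing weights are
#' `omega1 = g(e)/e` for the minority group and `omega0 = g(e)/(1-e)` for the
#' majority group, tilting both groups toward the target population `g f`.
#'
#' @param ps A `ps_fit` or a numeric vector of probabilities in (0,1).
#' @param estimand `"ate"`, `"att"`, or `"ato"`.
#' @return A tibble with columns `omega1`, `omega0` (one row per subject).
#' @export
balancing_weights <- function(ps, estimand = c("ate", "att", "ato")) {
  estimand <- arg_match(estimand)
  e <- if (inherits(ps, "ps_fit")) ps$ps else as.numeric(ps)
  if (any(e <= 0 | e >= 1)) {
    abort("Propensity scores must be strictly inside (0, 1).",
          class = "deweight_positivity_error")
  }
  g <- g_fun(estimand)(e)
  tibble::tibble(omega1 = g / e, omega0 = g / (1 - e))
}

new_weight_set <- function(data, omega1, omega0, estimand, method) {
  if (any(!is.finite(omega1)) || any(!is.finite(omega0)) ||
      any(omega1 < 0) || any(omega0 < 0)) {
    abort("Weights must be finite and nonnegative.",
          class = "deweight_error")
  }
  w <- tibble::tibble(
    .row = seq_len(nrow(data)),
    z = data$.z,
    omega1 = omega1,
    omega0 = omega0,
    weight = ifelse(data$.z == 1, omega1, omega0)
  )
  attr(w, "estimand") <- estimand
  attr(w, "method") <- method
  class(w) <- c("weight_set", class(w))
  w
}

#' Deweighting weights: balance health status, preserve SES
#'
#' Divides the full-propensity balancing weights by the SES-only balancing
#' weights, `omega_z = omega_z^B(x) / omega_z^B(x^s)`, so health status is
#' balanced conditional on SES while each group keeps its own marginal SES
#' distribution. Closed forms: ATE `(e(x^s)/e(x), (1-e(x^s))/(1-e(x)))`;
#' ATT `(1, [e(x)/(1-e(x))] / [e(x^s)/(1-e(x^s))])`; ATO
#' `((1-e(x))/(1-e(x^s)), e(x)/e(x^s))`.
#'
#' @param data A `disparity_df`.
#' @param ps_full A `ps_fit` (or probability vector) for the full propensity
#'   score, typically the SES-stratum-specific health-status fit.
#' @param ps_ses A `ps_fit` (or probability vector) for the SES-only score.
#' @param estimand `"ate"`, `"att"`, or `"ato"`.
#' @return A `weight_set` tibble: `.row`, `z`, `omega1`, `omega0`, and
#'   `weight` (the group-appropriate weight for each subject), with the
#'   estimand and method recorded as attributes. Weights are unnormalized;
#'   every downstream estimator is scale invariant.
#' @export
deweighting_weights <- function(data, ps_full, ps_ses,
                                estimand = c("ate", "att", "ato")) {
  estimand <- arg_match(estimand)
  roles <- roles_of(data)
  if (length(roles$ses) == 0 || length(roles$health) == 0) {
    abort("Deweighting requires both SES and health-status covariates.",
          class = "deweight_validation_error")
  }
  e_full <- if (inherits(ps_full, "ps_fit")) ps_full$ps else as.numeric(ps_full)
  e_ses <- if (inherits(ps_ses, "ps_fit")) ps_ses$ps else as.numeric(ps_ses)
  if (length(e_full) != nrow(data) || length(e_ses) != nrow(data)) {
    abort("Propensity vectors must align with the data rows.",
          class = "deweight_error")
  }
  wb_full <- balancing_weights(e_full, estimand)
  wb_ses <- balancing_weights(e_ses, estimand)
  new_weight_set(data,
                 omega1 = wb_full$omega1 / wb_ses$omega1,
                 omega0 = wb_full$omega0 / wb_ses$omega0,
                 estimand = estimand, method = "deweighting")
}

#' Comparator weights without deweighting
#'
#' Plain balancing weights for a named propensity model: `full_ps` (pooled
#' main-effects full score), `sshs_ps` (SES-stratum-specific health-status
#' score; its balancing weights are the "SSHS weights"), or `health_ps`
#' (health-status-only score). These are the comparators the deweighting
#' method is evaluated against.
#'
#' @inheritParams deweighting_weights
#' @param ps A `ps_fit` or probability vector for the named model.
#' @param method Label: `"full_ps"`, `"sshs_ps"`, or `"health_ps"`.
#' @return A `weight_set`.
#' @export
comparator_weights <- function(data, ps,
                               estimand = c("ate", "att", "ato"),
                               method = c("full_ps", "sshs_ps", "health_ps")) {
  estimand <- arg_match(estimand)
  method <- arg_match(method)
  roles_of(data)
  e <- if (inherits(ps, "ps_fit")) ps$ps else as.numeric(ps)
  if (length(e) != nrow(data)) {
    abort("Propensity vector must align with the data rows.",
          class = "deweight_error")
  }
  wb <- balancing_weights(e, estimand)
  new_weight_set(data, wb$omega1, wb$omega0, estimand, method)
}

#' Fit propensity models and build disparity weights in one call
#'
#' High-level front end: fits whichever propensity scores the requested
#' method needs (SES-stratum-specific full score and saturated SES score for
#' `"deweighting"` and `"sshs_ps"`; pooled models for `"full_ps"` and
#' `"health_ps"`) and returns the weight set. The fitted `ps_fit` objects are
#' attached as attributes `ps_full` / `ps_ses` for reuse in diagnostics.
#'
#' @inheritParams fit_ps
#' @param estimand `"ate"`, `"att"`, or `"ato"`.
#' @param method `"deweighting"` (default), `"full_ps"`, `"sshs_ps"`, or
#'   `"health_ps"`.
#' @param ps_method Propensity estimator, `"cbps"` (default) or `"ml"`.
#' @return A `weight_set`.
#' @export
disparity_weights <- function(data, estimand = c("ate", "att", "ato"),
                              method = c("deweighting", "full_ps",
                                         "sshs_ps", "health_ps"),
                              ps_method = c("cbps", "ml"),
                              on_stratum_error = c("error", "pool")) {
  estimand <- arg_match(estimand)
  method <- arg_match(method)
  ps_method <- arg_match(ps_method)
  w <- switch(method,
    deweighting = {
      ps_full <- fit_ps(data, "full", ps_method, estimand,
                        on_stratum_error = on_stratum_error)
      ps_ses <- fit_ses_ps(data)
      out <- deweighting_weights(data, ps_full, ps_ses, estimand)
      attr(out, "ps_full") <- ps_full
      attr(out, "ps_ses") <- ps_ses
      out
    },
    sshs_ps = {
      ps_full <- fit_ps(data, "full", ps_method, estimand,
                        on_stratum_error = on_stratum_error)
      out <- comparator_weights(data, ps_full, estimand, "sshs_ps")
      attr(out, "ps_full") <- ps_full
      out
    },
    full_ps = {
      ps_full <- fit_ps(data, "full", ps_method, estimand, stratify = FALSE)
      out <- comparator_weights(data, ps_full, estimand, "full_ps")
      attr(out, "ps_full") <- ps_full
      out
    },
    health_ps = {
      ps_h <- fit_ps(data, "health", ps_method, estimand)
      out <- comparator_weights(data, ps_h, estimand, "health_ps")
      attr(out, "ps_full") <- ps_h
      out
    }
  )
  w
}

#' Summarize a weight set
#'
#' Effective sample sizes and dispersion of the weights by group. The
#' effective sample size is `(sum w)^2 / sum(w^2)`.
#'
#' @param w A `weight_set`.
#' @param flag_multiple Weights above this multiple of the group mean are
#'   counted as large.
#' @return A tibble with one row per group: `group`, `n`, `sum_weight`,
#'   `ess`, `min`, `max`, `cv`, `n_large`.
#' @export
weight_summary <- function(w, flag_multiple = 10) {
  stopifnot(inherits(w, "weight_set"))
  w |>
    dplyr::mutate(group = ifelse(.data$z == 1, "minority", "majority")) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      sum_weight = sum(.data$weight),
      ess = sum(.data$weight)^2 / sum(.data$weight^2),
      min = min(.data$weight),
      max = max(.data$weight),
      cv = stats::sd(.data$weight) / mean(.data$weight),
      n_large = sum(.data$weight > flag_multiple * mean(.data$weight)),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$group))
}
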