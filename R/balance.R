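# Absolute standardized mean difference (ASMD) diagnostics measuring
# concordance with the IOM disparity definition: D (between-group balance),
# D1/D0 (how much the weights alter each group's own SES distribution) and
# D_r (between-group health-status balance within each SES subgroup). All
# denominators are unweighted standard deviations; a zero denominator is
# reported as value 0 with a "degenerate" flag rather than NaN.

asmd_pooled <- function(x1, x0, m1, m0) {
  s2 <- (var(x1) + var(x0)) / 2
  if (!is.finite(s2) || s2 == 0) {
    return(c(value = 0, degenerate = 1))
  }
  c(value = abs(m1 - m0) / sqrt(s2), degenerate = 0)
}

#' Between-group weighted ASMD
#'
#' `D(X_j) = |m1 - m0| / sqrt((s1^2 + s0^2)/2)`: the absolute difference of
#' weighted group means divided by the pooled unweighted group standard
#' deviations.
#'
#' @param data A `disparity_df`.
#' @param weights A `weight_set`, or `NULL` for unit weights.
#' @param covariates Covariate names; defaults to all SES and health-status
#'   covariates. Categorical covariates are dummy-encoded.
#' @return A tibble: `covariate`, `value`, `degenerate` (zero pooled SD).
#' @export
asmd_between <- function(data, weights = NULL, covariates = NULL) {
  roles <- roles_of(data)
  covariates <- covariates %||% c(roles$ses, roles$health)
  z <- data$.z
  if (sum(z) < 2 || sum(1 - z) < 2) {
    abort("Each group needs at least 2 subjects.", class = "deweight_error")
  }
  w <- if (is.null(weights)) rep(1, nrow(data)) else weights$weight
  xmat <- encode_columns(data, covariates)
  purrr::map_dfr(colnames(xmat), function(nm) {
    xj <- xmat[, nm]
    r <- asmd_pooled(xj[z == 1], xj[z == 0],
                     wmean(xj[z == 1], w[z == 1]),
                     wmean(xj[z == 0], w[z == 0]))
    tibble::tibble(covariate = nm, value = r[["value"]],
                   degenerate = r[["degenerate"]] == 1)
  })
}

#' SES-alteration metrics D1 and D0
#'
#' How much a weight set alters one group's own SES distribution:
#' `|unweighted group mean - weighted group mean| / unweighted group SD`,
#' per SES covariate (single-group SD denominator). `D1` uses the minority
#' group and its `omega1` weights; `D0` the majority group and `omega0`.
#' Constant weights within the group give 0 for every SES covariate.
#'
#' @param data A `disparity_df`.
#' @param weights A `weight_set`.
#' @param group `"minority"` (D1) or `"majority"` (D0).
#' @return A tibble: `covariate`, `value`, `degenerate`.
#' @export
ses_alteration <- function(data, weights, group = c("minority", "majority")) {
  group <- arg_match(group)
  roles <- roles_of(data)
  stopifnot(inherits(weights, "weight_set"))
  z_target <- if (group == "minority") 1L else 0L
  idx <- data$.z == z_target
  if (!any(idx)) abort("Requested group is empty.", class = "deweight_error")
  w <- weights$weight[idx]
  xmat <- encode_columns(data, roles$ses)
  purrr::map_dfr(colnames(xmat), function(nm) {
    xj <- xmat[idx, nm]
    s <- sd(xj)
    if (!is.finite(s) || s == 0) {
      return(tibble::tibble(covariate = nm, value = 0, degenerate = TRUE))
    }
    tibble::tibble(
      covariate = nm,
      value = abs(mean(xj) - wmean(xj, w)) / s,
      degenerate = FALSE
    )
  })
}

#' Within-subgroup health-status balance D_r
#'
#' For each SES subgroup `r` and health-status covariate: the absolute
#' difference of weighted group means among subjects with `G = r`, divided by
#' the pooled unweighted within-subgroup group SDs. Cells where either group
#' has fewer than 2 subjects in the subgroup are flagged `insufficient_n`
#' (value `NA`); zero pooled SD cells are flagged `degenerate` (value 0).
#'
#' @param data A `disparity_df`.
#' @param weights A `weight_set`, or `NULL` for unit weights.
#' @return A tibble: `subgroup`, `covariate`, `value`, `degenerate`,
#'   `insufficient_n`.
#' @export
subgroup_health_balance <- function(data, weights = NULL) {
  roles <- roles_of(data)
  z <- data$.z
  g <- data$.g
  w <- if (is.null(weights)) rep(1, nrow(data)) else weights$weight
  xmat <- encode_columns(data, roles$health)
  purrr::map_dfr(sort(unique(g)), function(r) {
    in_r <- g == r
    i1 <- in_r & z == 1
    i0 <- in_r & z == 0
    purrr::map_dfr(colnames(xmat), function(nm) {
      if (sum(i1) < 2 || sum(i0) < 2) {
        return(tibble::tibble(subgroup = r, covariate = nm, value = NA_real_,
                              degenerate = FALSE, insufficient_n = TRUE))
      }
      res <- asmd_pooled(xmat[i1, nm], xmat[i0, nm],
                         wmean(xmat[i1, nm], w[i1]),
                         wmean(xmat[i0, nm], w[i0]))
      tibble::tibble(subgroup = r, covariate = nm, value = res[["value"]],
                     degenerate = res[["degenerate"]] == 1,
                     insufficient_n = FALSE)
    })
  })
}

#' IOM-concordance balance report
#'
#' Assembles the three diagnostics for one or more weight sets: D1 and D0
#' (SES alteration) and D_r (within-subgroup health-status
#' balance). Any non-degenerate entry above the threshold (default 0.1, the
#' conventional imbalance cutoff) flags the weight set as not
#' IOM-concordant.
#'
#' @param data A `disparity_df`.
#' @param weight_sets A `weight_set` or a (optionally named) list of them.
#' @param threshold Flagging threshold on the ASMD scale.
#' @return A `balance_report` tibble in long format: `method`, `estimand`,
#'   `metric` (`"D1"`, `"D0"`, `"Dr"`), `subgroup` (`NA` for D1/D0),
#'   `covariate`, `value`, `flagged`, `degenerate`, `insufficient_n`; with a
#'   per-weight-set concordance summary in `attr(, "concordance")`.
#' @export
concordance_report <- function(data, weight_sets, threshold = 0.1) {
  if (inherits(weight_sets, "weight_set")) weight_sets <- list(weight_sets)
  if (is.null(names(weight_sets))) {
    names(weight_sets) <- vapply(weight_sets, function(w)
      paste(attr(w, "method"), attr(w, "estimand"), sep = "_"), character(1))
  }
  rows <- purrr::imap_dfr(weight_sets, function(w, nm) {
    d1 <- ses_alteration(data, w, "minority") |>
      dplyr::mutate(metric = "D1", subgroup = NA_integer_,
                    insufficient_n = FALSE)
    d0 <- ses_alteration(data, w, "majority") |>
      dplyr::mutate(metric = "D0", subgroup = NA_integer_,
                    insufficient_n = FALSE)
    dr <- subgroup_health_balance(data, w) |>
      dplyr::mutate(metric = "Dr")
    dplyr::bind_rows(d1, d0, dr) |>
      dplyr::mutate(
        weight_set = nm,
        method = attr(w, "method") %||% NA_character_,
        estimand = attr(w, "estimand") %||% NA_character_
      )
  })
  rows <- rows |>
    dplyr::mutate(flagged = !.data$degenerate & !.data$insufficient_n &
                    !is.na(.data$value) & .data$value > threshold) |>
    dplyr::select("weight_set", "method", "estimand", "metric", "subgroup",
                  "covariate", "value", "flagged", "degenerate",
                  "insufficient_n")
  concordance <- rows |>
    dplyr::group_by(.data$weight_set, .data$method, .data$estimand) |>
    dplyr::summarise(
      n_flagged = sum(.data$flagged),
      max_value = max(.data$value[!.data$insufficient_n], na.rm = TRUE),
      iom_concordant = sum(.data$flagged) == 0,
      .groups = "drop"
    )
  attr(rows, "threshold") <- threshold
  attr(rows, "concordance") <- concordance
  class(rows) <- c("balance_report", class(rows))
  rows
}

#' @export
print.balance_report <- function(x, ...) {
  cat(sprintf("# balance_report (threshold %.2f)\n", attr(x, "threshold")))
  print(attr(x, "concordance"))
  NextMethod()
}

#' Love plot of a balance report
#'
#' Dot plot of the ASMD metrics per covariate, faceted by metric (and
#' subgroup for D_r), with a dashed line at the flagging threshold.
#'
#' @param object A `balance_report` from [concordance_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.balance_report <- function(object, ...) {
  df <- dplyr::filter(object, !.data$insufficient_n)
  df$panel <- ifelse(df$metric == "Dr",
                     paste0("Dr (subgroup ", df$subgroup, ")"), df$metric)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, y = .data$covariate,
                                   colour = .data$weight_set)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = attr(object, "threshold"),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "Absolute standardized mean difference", y = NULL,
                  colour = "Weights") +
    ggplot2::theme_minimal()
}
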