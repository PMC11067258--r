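# Synthetic-data generator for validating the deweighting pipeline. The
# generative factorization is Z ~ Bernoulli(p), X^s | Z from a race-specific
# joint table over binary SES cells, X^h | Z, X^s multivariate normal with a
# race shift and SES shifts on the mean (shared covariance), and a logistic
# outcome in (Z, X^s, X^h). Both propensity scores are then available in
# closed form via Bayes' rule, so oracle estimand values never depend on
# estimated models.

# Plackett construction: 2x2 joint from two Bernoulli marginals and an odds
# ratio.
joint_from_marginals <- function(p_a, p_b, or) {
  stopifnot(p_a > 0, p_a < 1, p_b > 0, p_b < 1, or > 0)
  p11 <- if (abs(or - 1) < 1e-12) {
    p_a * p_b
  } else {
    s <- 1 + (p_a + p_b) * (or - 1)
    (s - sqrt(s^2 - 4 * or * (or - 1) * p_a * p_b)) / (2 * (or - 1))
  }
  # cells in lexicographic order of (a, b): (0,0), (0,1), (1,0), (1,1)
  cells <- c(1 - p_a - p_b + p11, p_b - p11, p_a - p11, p11)
  if (any(cells <= 0)) {
    abort("Marginals and odds ratio imply a non-positive SES cell probability.",
          class = "deweight_validation_error")
  }
  cells
}

ar1_cov <- function(k, rho = 0.3) rho^abs(outer(seq_len(k), seq_len(k), "-"))

#' Configuration for the synthetic disparity generator
#'
#' The defaults mimic the shape of the right-heart-catheterization
#' application — a ~17% minority share, two binary SES indicators
#' ("education", "income") whose race-specific marginals and within-race
#' association match the study's weighted characteristics, five correlated
#' health-status covariates shifted by both race and SES, and a binary
#' outcome with roughly 40-45% prevalence depending on race, SES and health
#' status. This is a structural fixture for validation, not a model of the
#' real data.
#'
#' @param n Default sample size for [simulate_disparity()].
#' @param p_minority Marginal minority probability.
#' @param ses_names Names of the binary SES variables (J of them).
#' @param ses_marginals List with elements `minority` and `majority`, each a
#'   length-J vector of SES success probabilities (used with
#'   `ses_odds_ratio` when `J = 2` and `ses_joint` is not given).
#' @param ses_odds_ratio Within-race odds ratio between the two SES
#'   variables (J = 2 only).
#' @param ses_joint Optional list with `minority` and `majority` probability
#'   vectors over the `2^J` SES cells in lexicographic order; overrides the
#'   marginal construction and is required when `J != 2`.
#' @param health_names Names of the K health-status covariates.
#' @param race_shift Length-K mean shift of the health covariates for the
#'   minority group.
#' @param ses_shift K x J matrix: mean shift of each health covariate per
#'   unit of each SES variable. Set to zero to make health status
#'   independent of SES given race.
#' @param health_cov K x K positive-definite covariance of the health
#'   covariates (default AR(1) with correlation 0.3).
#' @param outcome_coefs List of log-odds coefficients: `intercept`, `group`,
#'   `ses` (length J), `health` (length K).
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n = 5000,
                       p_minority = 0.171,
                       ses_names = c("edu", "income"),
                       ses_marginals = list(
                         minority = c(0.186, 0.116),
                         majority = c(0.304, 0.258)
                       ),
                       ses_odds_ratio = 5.7,
                       ses_joint = NULL,
                       health_names = paste0("h", 1:5),
                       race_shift = c(0.5, -0.4, 0.3, -0.3, 0.2),
                       ses_shift = NULL,
                       health_cov = NULL,
                       outcome_coefs = NULL) {
  j <- length(ses_names)
  k <- length(health_names)
  stopifnot(j >= 1, k >= 1, n >= 2, p_minority > 0, p_minority < 1)
  race_shift <- rep_len(race_shift, k)
  ses_shift <- ses_shift %||%
    matrix(rep_len(c(0.3, 0.2, -0.2, 0.3, 0.1, 0.2, 0.3, 0.1, -0.2, 0.2),
                   k * j), nrow = k, ncol = j)
  stopifnot(nrow(ses_shift) == k, ncol(ses_shift) == j)
  health_cov <- health_cov %||% ar1_cov(k)
  stopifnot(isSymmetric(unname(health_cov)), nrow(health_cov) == k)
  ev <- eigen(health_cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    abort("health_cov must be positive definite.",
          class = "deweight_validation_error")
  }
  outcome_coefs <- outcome_coefs %||% list(
    intercept = -0.55, group = -0.10,
    ses = rep_len(c(0.40, 0.40), j),
    health = rep_len(c(0.50, -0.35, 0.30, 0.25, -0.30), k)
  )
  stopifnot(length(outcome_coefs$ses) == j,
            length(outcome_coefs$health) == k)

  # lexicographic cell order with the first SES variable slowest
  cells <- expand.grid(rev(rep(list(c(0, 1)), j)))[, rev(seq_len(j)),
                                                   drop = FALSE]
  colnames(cells) <- ses_names
  if (is.null(ses_joint)) {
    if (j != 2) {
      abort("Provide `ses_joint` explicitly when the number of SES variables is not 2.",
            class = "deweight_validation_error")
    }
    ses_joint <- list(
      minority = joint_from_marginals(ses_marginals$minority[1],
                                      ses_marginals$minority[2],
                                      ses_odds_ratio),
      majority = joint_from_marginals(ses_marginals$majority[1],
                                      ses_marginals$majority[2],
                                      ses_odds_ratio)
    )
  }
  for (gp in c("minority", "majority")) {
    p <- ses_joint[[gp]]
    if (length(p) != nrow(cells) || any(p <= 0) ||
        abs(sum(p) - 1) > 1e-8) {
      abort(sprintf(
        "ses_joint$%s must be %d positive probabilities summing to 1 (positivity by construction).",
        gp, nrow(cells)
      ), class = "deweight_validation_error")
    }
  }
  structure(
    list(n = n, p_minority = p_minority, ses_names = ses_names,
         ses_marginals = ses_marginals,
         ses_cells = tibble::as_tibble(cells), ses_joint = ses_joint,
         health_names = health_names, race_shift = race_shift,
         ses_shift = ses_shift, health_cov = health_cov,
         outcome_coefs = outcome_coefs),
    class = "sim_config"
  )
}

# Per-subject health-covariate mean, n x K.
health_mean <- function(z, xs, config) {
  outer(z, config$race_shift) + xs %*% t(config$ses_shift)
}

outcome_logit <- function(z, xs, xh, config) {
  oc <- config$outcome_coefs
  oc$intercept + oc$group * z + drop(xs %*% oc$ses) + drop(xh %*% oc$health)
}

#' Generate a synthetic disparity dataset
#'
#' Draws minority membership, SES cell, health-status covariates and a
#' binary outcome from the generative model in a [sim_config()].
#' Reproducible given the same config and seed; all randomness flows through
#' R's generator as seeded here.
#'
#' @param config A `sim_config`.
#' @param seed Optional integer seed.
#' @param n Sample size; defaults to `config$n`.
#' @return A `disparity_df` with group column `group` (1 = minority),
#'   outcome `y`, the SES and health columns named by the config, and the
#'   config attached as attribute `sim_config`.
#' @export
simulate_disparity <- function(config, seed = NULL, n = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- n %||% config$n
  k <- length(config$health_names)
  z <- rbinom(n, 1, config$p_minority)
  n_cells <- nrow(config$ses_cells)
  cell <- integer(n)
  cell[z == 1] <- sample.int(n_cells, sum(z), replace = TRUE,
                             prob = config$ses_joint$minority)
  cell[z == 0] <- sample.int(n_cells, sum(1 - z), replace = TRUE,
                             prob = config$ses_joint$majority)
  xs <- as.matrix(config$ses_cells)[cell, , drop = FALSE]
  mu <- health_mean(z, xs, config)
  xh <- mu + matrix(rnorm(n * k), n, k) %*% chol(config$health_cov)
  colnames(xh) <- config$health_names
  y <- rbinom(n, 1, expit(outcome_logit(z, xs, xh, config)))
  out <- dplyr::bind_cols(
    tibble::tibble(group = z, y = y),
    tibble::as_tibble(xs),
    tibble::as_tibble(xh)
  )
  d <- as_disparity_data(out, group = "group", outcome = "y",
                         ses = config$ses_names,
                         health = config$health_names)
  attr(d, "sim_config") <- config
  d
}

#' True propensity scores under the generative model
#'
#' Computes `Pr(Z = 1 | x)` analytically via Bayes' rule over the
#' race-specific densities of the config: the SES-only score from the cell
#' tables, and the full score by adding the Gaussian log-likelihood ratio of
#' the health covariates (linear in `x^h` because the covariance is shared).
#'
#' @param data A data frame containing the config's SES and health columns
#'   (e.g. from [simulate_disparity()]).
#' @param config The `sim_config` that generated the data.
#' @param model `"full"` or `"ses"`.
#' @return Numeric vector of true propensities.
#' @export
true_propensity <- function(data, config, model = c("full", "ses")) {
  model <- arg_match(model)
  stopifnot(inherits(config, "sim_config"))
  xs <- as.matrix(data[config$ses_names])
  key_cells <- do.call(paste, as.data.frame(as.matrix(config$ses_cells)))
  cell <- match(do.call(paste, as.data.frame(xs)), key_cells)
  if (anyNA(cell)) {
    abort("SES values outside the config's cell table.",
          class = "deweight_error")
  }
  p1 <- config$p_minority
  odds_ses <- (p1 * config$ses_joint$minority[cell]) /
    ((1 - p1) * config$ses_joint$majority[cell])
  if (model == "ses") {
    return(odds_ses / (1 + odds_ses))
  }
  xh <- as.matrix(data[config$health_names])
  delta <- config$race_shift
  d <- solve(config$health_cov, delta)
  centre <- xs %*% t(config$ses_shift) + matrix(delta / 2, nrow(xs),
                                                length(delta), byrow = TRUE)
  log_lr <- drop((xh - centre) %*% d)
  odds <- odds_ses * exp(log_lr)
  odds / (1 + odds)
}

#' Oracle value of the disparity estimand
#'
#' Evaluates the target weighted average controlled difference by Monte
#' Carlo: a large population is drawn from the config, the deweighting
#' weights are formed from the *true* propensity scores, and the true
#' conditional outcome means (not noisy outcomes) are averaged under them.
#' The Monte-Carlo standard error comes from the ratio-estimator
#' linearization on the simulated draws and scales as `1/sqrt(n_oracle)`.
#'
#' @param config A `sim_config`.
#' @param estimand `"ate"`, `"att"`, or `"ato"`.
#' @param n_oracle Number of Monte-Carlo draws.
#' @param seed Optional integer seed.
#' @return A one-row tibble: `estimand`, `tau`, `mu1`, `mu0`, `mc_se`,
#'   `n_oracle`.
#' @export
oracle_truth <- function(config, estimand = c("ate", "att", "ato"),
                         n_oracle = 1e6, seed = NULL) {
  estimand <- arg_match(estimand)
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_oracle)
  k <- length(config$health_names)
  z <- rbinom(n, 1, config$p_minority)
  n_cells <- nrow(config$ses_cells)
  cell <- integer(n)
  cell[z == 1] <- sample.int(n_cells, sum(z), replace = TRUE,
                             prob = config$ses_joint$minority)
  cell[z == 0] <- sample.int(n_cells, sum(1 - z), replace = TRUE,
                             prob = config$ses_joint$majority)
  xs <- as.matrix(config$ses_cells)[cell, , drop = FALSE]
  colnames(xs) <- config$ses_names
  mu <- health_mean(z, xs, config)
  xh <- mu + matrix(rnorm(n * k), n, k) %*% chol(config$health_cov)
  colnames(xh) <- config$health_names
  draws <- cbind(tibble::as_tibble(xs), tibble::as_tibble(xh))

  e_full <- true_propensity(draws, config, "full")
  e_ses <- true_propensity(draws, config, "ses")
  wb_full <- balancing_weights(e_full, estimand)
  wb_ses <- balancing_weights(e_ses, estimand)
  omega1 <- (wb_full$omega1 / wb_ses$omega1)[z == 1]
  omega0 <- (wb_full$omega0 / wb_ses$omega0)[z == 0]

  m1 <- expit(outcome_logit(1, xs[z == 1, , drop = FALSE],
                            xh[z == 1, , drop = FALSE], config))
  m0 <- expit(outcome_logit(0, xs[z == 0, , drop = FALSE],
                            xh[z == 0, , drop = FALSE], config))
  mu1 <- sum(omega1 * m1) / sum(omega1)
  mu0 <- sum(omega0 * m0) / sum(omega0)
  v1 <- sum(omega1^2 * (m1 - mu1)^2) / sum(omega1)^2
  v0 <- sum(omega0^2 * (m0 - mu0)^2) / sum(omega0)^2
  tibble::tibble(
    estimand = estimand, tau = mu1 - mu0, mu1 = mu1, mu0 = mu0,
    mc_se = sqrt(v1 + v0), n_oracle = n
  )
}
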