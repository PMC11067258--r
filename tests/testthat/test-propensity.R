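# Independent Newton-Raphson logistic oracle used to check fit_logistic_ml.
nr_logistic <- function(z, design, iter = 50) {
  beta <- rep(0, ncol(design))
  for (i in seq_len(iter)) {
    p <- 1 / (1 + exp(-drop(design %*% beta)))
    grad <- crossprod(design, z - p)
    hess <- crossprod(design, design * (p * (1 - p)))
    beta <- beta + solve(hess, grad)
  }
  drop(beta)
}

test_that("ML logistic fit matches closed forms and an independent Newton oracle", {
  z <- c(1, 1, 0, 0, 0, 1)
  # intercept-only: fitted probability is the minority proportion
  fit0 <- fit_logistic_ml(z, matrix(numeric(0), nrow = 6, ncol = 0))
  expect_equal(fit0$fitted, rep(mean(z), 6), tolerance = 1e-10)

  x <- matrix(c(0.3, -1.2, 0.5, 2.0, -0.7, 0.1), ncol = 1)
  fit <- fit_logistic_ml(z, x)
  oracle <- nr_logistic(z, cbind(1, x))
  expect_equal(unname(fit$coefficients), oracle, tolerance = 1e-8)
  # mean preservation with intercept: sum(Z) = sum(e)
  expect_equal(sum(fit$fitted), sum(z), tolerance = 1e-8)
})

test_that("ML fit errors on separation and rank deficiency", {
  z <- c(1, 1, 1, 0, 0, 0)
  x_sep <- matrix(c(2, 3, 4, -1, -2, -3), ncol = 1)
  expect_error(fit_logistic_ml(z, x_sep),
               class = "deweight_separation_error")
  x_rank <- cbind(a = c(1, 2, 1, 3, 2, 1), b = 2 * c(1, 2, 1, 3, 2, 1))
  expect_error(fit_logistic_ml(z, x_rank), "b",
               class = "deweight_fit_error")
})

test_that("saturated SES score equals subgroup minority proportions", {
  # two subgroups with (n1, n0) = (1, 3) and (3, 1)
  d <- manual_data(
    z = c(1, 0, 0, 0, 1, 1, 1, 0),
    y = rbinom(8, 1, .5),
    ses = c(0, 0, 0, 0, 1, 1, 1, 1),
    health = rnorm(8)
  )
  fit <- fit_ses_ps(d)
  expect_equal(fit$ps, c(rep(0.25, 4), rep(0.75, 4)))

  # symmetric subgroup (2, 2)
  d2 <- manual_data(c(1, 1, 0, 0), c(0, 1, 0, 1), rep(1, 4), rnorm(4))
  expect_equal(fit_ses_ps(d2)$ps, rep(0.5, 4))

  # a subgroup without minority subjects violates positivity
  d3 <- manual_data(c(1, 0, 0, 0), c(0, 1, 0, 1), c(0, 0, 1, 1), rnorm(4))
  expect_error(fit_ses_ps(d3), "subgroup",
               class = "deweight_positivity_error")
})

test_that("just-identified CBPS solves the balance equations exactly", {
  set.seed(31)
  z <- rbinom(60, 1, 0.4)
  z[1:3] <- 1; z[4:6] <- 0
  x <- cbind(rnorm(60), rnorm(60, z, 1))

  # intercept-only ATE: unique root is e = n1/N
  fit0 <- fit_cbps(z, matrix(numeric(0), nrow = 60, ncol = 0), "ate")
  expect_equal(fit0$fitted, rep(mean(z), 60), tolerance = 1e-7)

  for (est in c("ate", "att")) {
    fit <- fit_cbps(z, x, est)
    design <- cbind(1, x)
    e <- fit$fitted
    resid <- if (est == "ate") {
      crossprod(design, z / e - (1 - z) / (1 - e)) / length(z)
    } else {
      crossprod(design, z - (1 - z) * e / (1 - e)) / length(z)
    }
    expect_lt(max(abs(resid)), 1e-6)
  }

  # ATT with intercept: sum over controls of e/(1-e) equals n1
  fit_att <- fit_cbps(z, x, "att")
  e <- fit_att$fitted
  expect_equal(sum((e / (1 - e))[z == 0]), sum(z), tolerance = 1e-6)

  # ATE: weighted covariate means equal across groups in the target pop
  fit_ate <- fit_cbps(z, x, "ate")
  e <- fit_ate$fitted
  m1 <- colSums(x[z == 1, ] / e[z == 1]) / sum(1 / e[z == 1])
  m0 <- colSums(x[z == 0, ] / (1 - e[z == 0])) / sum(1 / (1 - e[z == 0]))
  expect_equal(m1, m0, tolerance = 1e-8)
})

test_that("CBPS coefficients agree with an independent minimizer on a small system", {
  set.seed(8)
  z <- rep(c(1, 0), each = 4)
  x <- matrix(c(0.5, 1.2, -0.3, 0.8, -1.0, 0.2, 0.6, -0.4), ncol = 1)
  fit <- fit_cbps(z, x, "ate")
  # oracle: direct Nelder-Mead minimization of the squared balance residual
  resid2 <- function(beta) {
    e <- 1 / (1 + exp(-drop(cbind(1, x) %*% beta)))
    r <- crossprod(cbind(1, x), z / e - (1 - z) / (1 - e))
    sum(r^2)
  }
  oracle <- stats::optim(c(0, 0), resid2,
                         control = list(reltol = 1e-14, maxit = 5000))
  expect_equal(unname(fit$coefficients), oracle$par, tolerance = 1e-4)
})

test_that("CBPS for the overlap estimand returns the ML fit", {
  set.seed(4)
  z <- rbinom(40, 1, .5)
  x <- matrix(rnorm(40), ncol = 1)
  expect_equal(fit_cbps(z, x, "ato")$fitted, fit_logistic_ml(z, x)$fitted)
})

test_that("stratified fitting nests the pooled and saturated fits", {
  d <- simulate_disparity(test_config(), seed = 21, n = 600)

  # R = 1: stratified fit equals the pooled fit
  raw <- as.data.frame(d)
  raw$edu <- 0; raw$income <- 0
  d1 <- as_disparity_data(raw[setdiff(names(raw), c(".z", ".g"))],
                          "group", "y", c("edu", "income"), paste0("h", 1:3))
  for (m in c("ml", "cbps")) {
    strat <- fit_ps(d1, "full", m, "att")
    pooled <- fit_ps(d1, "health", m, "att")
    expect_equal(strat$ps, pooled$ps, tolerance = 1e-10)
  }

  # intercept-only per-stratum models reduce to the saturated SES score
  d0 <- as_disparity_data(as.data.frame(d)[c("group", "y", "edu", "income")],
                          "group", "y", c("edu", "income"), character(0))
  strat0 <- fit_ps(d0, "full", "ml", "att")
  expect_equal(strat0$ps, fit_ses_ps(d0)$ps, tolerance = 1e-8)

  # stratified CBPS-ATE: within-stratum balance residual at solver tolerance
  # (small strata can produce extreme scores, warned about and tolerated)
  fit <- suppressWarnings(fit_ps(d, "full", "cbps", "ate"))
  expect_true(all(fit$strata$residual_norm < 1e-6))
  expect_equal(nrow(fit$strata), max(d$.g))
})

test_that("failing strata error by name or fall back to the pooled model", {
  d <- simulate_disparity(test_config(), seed = 55, n = 300)
  raw <- as.data.frame(d)[setdiff(names(as.data.frame(d)), c(".z", ".g"))]
  # make subgroup (1,1) tiny: 2 minority + 2 majority, fewer rows than
  # health columns + intercept, so its per-stratum fit cannot run
  raw$edu[raw$edu == 1 & raw$income == 1] <- 0
  top <- c(which(raw$group == 1)[1:2], which(raw$group == 0)[1:2])
  raw$edu[top] <- 1; raw$income[top] <- 1
  d2 <- as_disparity_data(raw, "group", "y", c("edu", "income"),
                          paste0("h", 1:3))
  r_small <- unique(d2$.g[d2$edu == 1 & d2$income == 1])
  expect_error(fit_ps(d2, "full", "ml", "att"),
               paste0("subgroup ", r_small), class = "deweight_fit_error")
  expect_message(
    fit <- fit_ps(d2, "full", "ml", "att", on_stratum_error = "pool"),
    "pooled"
  )
  expect_true(fit$strata$pooled_fallback[fit$strata$.g == r_small])
  expect_true(all(fit$ps > 0 & fit$ps < 1))
})
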