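# Brute-force recomputation of the three concordance metrics with plain
# loops, independent of the package's vectorized implementation.
brute_metrics <- function(data, w) {
  roles <- attr(data, "roles")
  z <- data$.z
  g <- data$.g
  out <- list()
  for (nm in roles$ses) {
    x <- as.numeric(data[[nm]])
    for (side in c(1, 0)) {
      idx <- which(z == side)
      ww <- w$weight[idx]
      val <- abs(mean(x[idx]) - sum(x[idx] * ww) / sum(ww)) / sd(x[idx])
      out[[length(out) + 1]] <- data.frame(
        metric = if (side == 1) "D1" else "D0",
        covariate = nm, subgroup = NA, value = val
      )
    }
  }
  for (r in sort(unique(g))) {
    for (nm in roles$health) {
      x <- as.numeric(data[[nm]])
      i1 <- which(g == r & z == 1); i0 <- which(g == r & z == 0)
      m1 <- sum(x[i1] * w$weight[i1]) / sum(w$weight[i1])
      m0 <- sum(x[i0] * w$weight[i0]) / sum(w$weight[i0])
      s2 <- (var(x[i1]) + var(x[i0])) / 2
      out[[length(out) + 1]] <- data.frame(
        metric = "Dr", covariate = nm, subgroup = r,
        value = abs(m1 - m0) / sqrt(s2)
      )
    }
  }
  do.call(rbind, out)
}

test_that("ASMD formulas match hand arithmetic", {
  # equal means, unequal variances: D = 0
  d <- manual_data(c(1, 1, 0, 0), c(1, 0, 1, 0), c(0, 1, 0, 1), c(0, 2, 1, 1))
  w <- comparator_weights(d, rep(0.5, 4), "ate", "health_ps")
  a <- asmd_between(d, w, covariates = "h1")
  expect_equal(a$value, 0)

  # D1 with weights (1, 3) on SES values (0, 1)
  w$weight[w$z == 1] <- c(1, 3)
  d1 <- ses_alteration(d, w, "minority")
  expect_equal(d1$value, abs(0.5 - 0.75) / sd(c(0, 1)))

  # constant weights in a group: zero alteration
  w$weight[w$z == 1] <- c(5, 5)
  expect_equal(ses_alteration(d, w, "minority")$value, 0)
})

test_that("zero-SD covariates are flagged degenerate, not NaN", {
  d <- manual_data(c(1, 1, 0, 0), c(1, 0, 1, 0), c(1, 1, 1, 1), c(2, 2, 2, 2))
  w <- comparator_weights(d, rep(0.3, 4), "att", "health_ps")
  a <- asmd_between(d, w)
  expect_true(all(a$degenerate))
  expect_true(all(a$value == 0))
  expect_true(all(ses_alteration(d, w, "majority")$degenerate))
})

test_that("pooled just-identified CBPS zeroes the between-group ASMD", {
  d <- simulate_disparity(test_config(), seed = 23, n = 1500)
  fit <- fit_ps(d, "full", "cbps", "ate", stratify = FALSE)
  w <- comparator_weights(d, fit, "ate", "full_ps")
  a <- asmd_between(d, w)
  expect_lt(max(a$value), 1e-6)
})

test_that("stratified ML with overlap deweighting achieves exact within-stratum balance", {
  d <- simulate_disparity(test_config(), seed = 27, n = 2000)
  ps_full <- fit_ps(d, "full", "ml", "ato")
  w <- deweighting_weights(d, ps_full, fit_ses_ps(d), "ato")
  dr <- subgroup_health_balance(d, w)
  expect_true(all(!dr$insufficient_n))
  expect_lt(max(dr$value), 1e-8)
})

test_that("with a single subgroup D_r reduces to the between-group ASMD", {
  d <- simulate_disparity(test_config(), seed = 35, n = 400)
  raw <- as.data.frame(d)
  raw$edu <- 0; raw$income <- 0
  d1 <- as_disparity_data(raw[setdiff(names(raw), c(".z", ".g"))],
                          "group", "y", c("edu", "income"), paste0("h", 1:3))
  w <- suppressWarnings(disparity_weights(d1, "ate", "health_ps"))
  dr <- subgroup_health_balance(d1, w)
  a <- asmd_between(d1, w, covariates = paste0("h", 1:3))
  expect_equal(dr$value, a$value)
})

test_that("metrics are invariant to affine transformation of a covariate", {
  d <- simulate_disparity(test_config(), seed = 44, n = 600)
  # health-status weights leave real residual imbalance, so the compared
  # metrics are well away from zero
  w <- suppressWarnings(disparity_weights(d, "ate", "health_ps"))
  raw <- as.data.frame(d)
  raw$h1 <- -3.2 * raw$h1 + 11
  d2 <- as_disparity_data(raw[setdiff(names(raw), c(".z", ".g"))],
                          "group", "y", c("edu", "income"), paste0("h", 1:3))
  expect_equal(asmd_between(d2, w)$value, asmd_between(d, w)$value,
               tolerance = 1e-10)
  expect_equal(subgroup_health_balance(d2, w)$value,
               subgroup_health_balance(d, w)$value, tolerance = 1e-10)
})

test_that("concordance report matches a brute-force recomputation", {
  d <- simulate_disparity(test_config(), seed = 50, n = 1000)
  # deliberately imbalanced weights: SSHS (no deweighting)
  w <- suppressWarnings(disparity_weights(d, "ate", "sshs_ps"))
  rep <- concordance_report(d, w)
  oracle <- brute_metrics(d, w)
  merged <- merge(as.data.frame(rep), oracle,
                  by = c("metric", "covariate", "subgroup"))
  expect_gt(nrow(merged), 0)
  expect_equal(merged$value.x, merged$value.y, tolerance = 1e-10)
  expect_setequal(
    paste(merged$metric, merged$covariate, merged$subgroup)[merged$flagged],
    paste(merged$metric, merged$covariate,
          merged$subgroup)[merged$value.y > 0.1]
  )
})

test_that("unit weights give zero alteration and raw within-stratum ASMDs", {
  d <- simulate_disparity(test_config(), seed = 61, n = 800)
  unit <- comparator_weights(d, rep(0.5, nrow(d)), "ate", "health_ps")
  rep <- concordance_report(d, unit)
  expect_true(all(rep$value[rep$metric %in% c("D1", "D0")] == 0))
  raw_dr <- subgroup_health_balance(d, NULL)
  expect_equal(rep$value[rep$metric == "Dr"], raw_dr$value)
})

test_that("subgroup cells with too few subjects are flagged and excluded", {
  d <- manual_data(
    z = c(1, 1, 0, 0, 1, 0, 0),
    y = rbinom(7, 1, .5),
    ses = c(0, 0, 0, 0, 1, 1, 1),
    health = rnorm(7)
  )
  w <- comparator_weights(d, rep(0.4, 7), "ate", "health_ps")
  dr <- subgroup_health_balance(d, w)
  expect_true(dr$insufficient_n[dr$subgroup == 2])
  expect_false(dr$insufficient_n[dr$subgroup == 1])
  rep <- concordance_report(d, w)
  expect_false(any(rep$flagged[rep$insufficient_n]))
})

test_that("autoplot returns a ggplot love plot", {
  d <- simulate_disparity(test_config(), seed = 71, n = 500)
  w <- suppressWarnings(disparity_weights(d, "att", "deweighting"))
  p <- autoplot(concordance_report(d, w))
  expect_s3_class(p, "ggplot")
})
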