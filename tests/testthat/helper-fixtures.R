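# Small fixtures built in code.

toy_data <- function() {
  as_disparity_data(
    data.frame(
      grp = c(1, 1, 0, 0),
      y = c(1, 0, 1, 0),
      ses1 = c(0, 1, 0, 1),
      h1 = c(1.2, -0.5, 0.3, 0.8)
    ),
    group = "grp", outcome = "y", ses = "ses1", health = "h1"
  )
}

# Disparity data built directly from vectors/matrices, bypassing the
# generator, for hand-computed oracles.
manual_data <- function(z, y, ses, health) {
  df <- data.frame(grp = z, y = y)
  ses <- as.data.frame(ses)
  health <- as.data.frame(health)
  names(ses) <- paste0("s", seq_along(ses))
  names(health) <- paste0("h", seq_along(health))
  as_disparity_data(cbind(df, ses, health), group = "grp", outcome = "y",
                    ses = names(ses), health = names(health))
}

# A synthetic table shaped like the public right-heart-catheterization file
# (canonical column names, plausible codes); values are random, not real.
synthetic_rhc_table <- function(n = 3000, seed = 421) {
  set.seed(seed)
  income_levels <- c("Under $11k", "$11-$25k", "$25-$50k", "> $50k")
  cat1_levels <- c("ARF", "CHF", "Cirrhosis", "Colon Cancer", "Coma",
                   "COPD", "Lung Cancer", "MOSF w/Malignancy",
                   "MOSF w/Sepsis")
  d <- data.frame(
    race = sample(c("black", "white", "other"), n, TRUE, c(.3, .65, .05)),
    swang1 = sample(c("No RHC", "RHC"), n, TRUE, c(.6, .4)),
    edu = round(runif(n, 0, 20)),
    income = sample(income_levels, n, TRUE),
    sex = sample(c("Male", "Female"), n, TRUE),
    ca = sample(c("No", "Yes", "Metastatic"), n, TRUE, c(.75, .17, .08)),
    cat1 = sample(cat1_levels, n, TRUE),
    dnr1 = sample(c("No", "Yes"), n, TRUE, c(.88, .12))
  )
  for (nm in deweight:::rhc_continuous) d[[nm]] <- rnorm(n, 50, 10)
  for (nm in deweight:::rhc_comorbidity) d[[nm]] <- rbinom(n, 1, 0.15)
  d
}

# Small config used throughout: 3 health covariates keeps stratum fits fast
# and root-findable at modest n.
test_config <- function(...) {
  args <- utils::modifyList(
    list(health_names = paste0("h", 1:3), race_shift = c(0.5, -0.4, 0.3)),
    list(...)
  )
  do.call(sim_config, args)
}
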