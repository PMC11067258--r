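# Preprocessing recipe for the public right-heart-catheterization (RHC)
# study table (SUPPORT; available from the Vanderbilt biostatistics data
# repository). The recipe restricts to black and white patients, codes black
# as the minority group, codes receipt of RHC as the outcome, builds two
# binary SES indicators (high-school education or more; income $25K or
# greater) and 27 numeric health-status columns: 20 continuous variables and
# dummy indicators for sex, cancer (2), disease category (3) and DNR status.

rhc_continuous <- c(
  "age", "das2d3pc", "aps1", "scoma1", "meanbp1", "wblc1", "hrt1", "resp1",
  "temp1", "pafi1", "alb1", "hema1", "bili1", "crea1", "sod1", "pot1",
  "paco21", "ph1", "wtkilo1"
)

rhc_comorbidity <- c(
  "cardiohx", "chfhx", "dementhx", "psychhx", "chrpulhx", "renalhx",
  "liverhx", "gibledhx", "malighx", "immunhx", "transhx", "amihx"
)

rhc_required <- c("race", "swang1", "edu", "income", "sex", "ca", "cat1",
                  "dnr1", rhc_continuous, rhc_comorbidity)

#' Preprocess the public right-heart-catheterization table
#'
#' Applies the study recipe to the canonical RHC file: keeps black and white
#' patients (minority = black), outcome 1 if RHC was received, SES covariates
#' `edu_hs` (>= high-school education) and `income_25k` (income >= $25K), and
#' 27 numeric health-status columns (20 continuous, including the comorbidity
#' count, plus dummies for sex, cancer, pooled disease category and DNR
#' status, each with the most frequent level as reference). Disease
#' categories are pooled to ARF / CHF / MOSF / Other.
#'
#' @param raw The RHC table with its canonical column names (e.g. as read
#'   from `rhc.csv`), one row per patient.
#' @return A `disparity_df` with `rhc` as the outcome column.
#' @export
rhc_recipe <- function(raw) {
  raw <- tibble::as_tibble(raw)
  missing_cols <- setdiff(rhc_required, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("RHC table is missing canonical column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "deweight_schema_error")
  }
  race <- tolower(as.character(raw$race))
  unknown <- setdiff(unique(race), c("black", "white", "other"))
  if (length(unknown) > 0) {
    abort(sprintf("Unknown race code(s): %s", paste(unknown, collapse = ", ")),
          class = "deweight_validation_error")
  }
  d <- raw[race %in% c("black", "white"), , drop = FALSE]
  if (nrow(d) == 0) {
    abort("No black or white patients remain after filtering.",
          class = "deweight_validation_error")
  }

  out <- tibble::tibble(
    race = tolower(as.character(d$race)),
    rhc = as.integer(as.character(d$swang1) == "RHC"),
    edu_hs = as.integer(d$edu >= 12),
    income_25k = as.integer(as.character(d$income) %in%
                              c("$25-$50k", "> $50k")),
    num_comorb = rowSums(d[rhc_comorbidity])
  )
  for (nm in rhc_continuous) out[[nm]] <- as.numeric(d[[nm]])

  cat1 <- as.character(d$cat1)
  disease <- dplyr::case_when(
    cat1 == "ARF" ~ "ARF",
    cat1 == "CHF" ~ "CHF",
    grepl("^MOSF", cat1) ~ "MOSF",
    .default = "Other"
  )
  dummies <- cbind(
    encode_column(as.character(d$sex), "sex"),
    encode_column(as.character(d$ca), "cancer"),
    encode_column(disease, "disease"),
    encode_column(as.character(d$dnr1), "dnr")
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(dummies))

  health <- c("num_comorb", rhc_continuous, colnames(dummies))
  as_disparity_data(out, group = "race", minority = "black",
                    outcome = "rhc", ses = c("edu_hs", "income_25k"),
                    health = health)
}
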