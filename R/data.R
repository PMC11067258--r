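#' Tag a subject-level table with disparity-analysis roles
#'
#' Converts a data frame of per-subject records into a `disparity_df`: a
#' tibble carrying a binary minority indicator `.z`, the outcome, the SES
#' (socioeconomic status) covariates, the health-status covariates, and an
#' SES-subgroup index `.g`. All downstream propensity, weighting, estimation
#' and balance functions consume this object.
#'
#' Subgroups are the distinct observed combinations of the SES covariates,
#' indexed `1..R` in lexicographic order of their value tuples, so the index
#' is stable across runs and row permutations.
#'
#' @param data A data frame with one row per subject.
#' @param group Name of the binary group column.
#' @param outcome Name of the outcome column (binary 0/1 or numeric).
#' @param ses Character vector of SES covariate names (categorical or 0/1).
#' @param health Character vector of health-status covariate names; must be
#'   numeric (dummy-encode categoricals first, or use [rhc_recipe()]).
#' @param minority Value of `group` identifying the minority group. Required
#'   unless the group column is already coded 0/1 (or logical), in which case
#'   1 (`TRUE`) is the minority. Never inferred from frequency.
#' @param na_action `"fail"` (default) errors listing columns with missing
#'   values; `"omit"` drops incomplete rows and reports how many.
#'
#' @return A `disparity_df` tibble: the original columns plus `.z` (1 =
#'   minority) and `.g` (SES-subgroup index).
#' @seealso [ses_subgroups()], [read_disparity_data()], [rhc_recipe()]
#' @export
#' @examples
#' d <- data.frame(
#'   race = c("b", "b", "w", "w"), y = c(1, 0, 1, 0),
#'   edu = c(0, 1, 0, 1), sev = c(1.2, -0.5, 0.3, 0.8)
#' )
#' as_disparity_data(d, group = "race", minority = "b",
#'                   outcome = "y", ses = "edu", health = "sev")
as_disparity_data <- function(data, group, outcome, ses, health,
                              minority = NULL,
                              na_action = c("fail", "omit")) {
  na_action <- arg_match(na_action)
  stopifnot(is.data.frame(data))
  data <- tibble::as_tibble(data)

  roles <- list(group = group, outcome = outcome,
                ses = as.character(ses), health = as.character(health),
                minority = minority)
  all_cols <- c(group, outcome, roles$ses, roles$health)
  if (anyDuplicated(all_cols)) {
    abort(
      sprintf("Role columns must be disjoint; duplicated: %s",
              paste(unique(all_cols[duplicated(all_cols)]), collapse = ", ")),
      class = "deweight_schema_error"
    )
  }
  missing_cols <- setdiff(all_cols, names(data))
  if (length(missing_cols) > 0) {
    abort(
      sprintf("Column(s) not found in data: %s",
              paste(missing_cols, collapse = ", ")),
      class = "deweight_schema_error"
    )
  }

  # Missing-value policy
  has_na <- vapply(all_cols, function(nm) anyNA(data[[nm]]), logical(1))
  if (any(has_na)) {
    if (na_action == "fail") {
      abort(
        sprintf("Missing values in column(s): %s (use na_action = \"omit\" to drop rows)",
                paste(all_cols[has_na], collapse = ", ")),
        class = "deweight_validation_error"
      )
    }
    keep <- stats::complete.cases(data[all_cols])
    inform(sprintf("Dropped %d row(s) with missing values.", sum(!keep)))
    data <- data[keep, , drop = FALSE]
  }
  if (nrow(data) == 0) {
    abort("No subjects remain after validation.", class = "deweight_validation_error")
  }

  # Group coding
  gvals <- data[[group]]
  levs <- unique(gvals)
  if (length(levs) != 2) {
    abort(
      sprintf("Group column '%s' must have exactly 2 observed levels, found %d.",
              group, length(levs)),
      class = "deweight_validation_error"
    )
  }
  if (is.null(minority)) {
    if (is.logical(gvals) ||
        (is.numeric(gvals) && all(gvals %in% c(0, 1)))) {
      z <- as.integer(gvals)
    } else {
      abort(
        sprintf("Specify `minority =` for group column '%s'; it is not coded 0/1.", group),
        class = "deweight_validation_error"
      )
    }
  } else {
    if (!minority %in% gvals) {
      abort(sprintf("Minority level '%s' not present in group column '%s'.",
                    minority, group),
            class = "deweight_validation_error")
    }
    z <- as.integer(gvals == minority)
  }
  if (sum(z) == 0 || sum(z) == length(z)) {
    abort("Both groups must contain at least one subject.",
          class = "deweight_validation_error")
  }

  # Health covariates must already be numeric
  bad <- roles$health[!vapply(roles$health, function(nm)
    is.numeric(data[[nm]]) || is.logical(data[[nm]]), logical(1))]
  if (length(bad) > 0) {
    abort(
      sprintf("Health-status column(s) must be numeric (dummy-encode first): %s",
              paste(bad, collapse = ", ")),
      class = "deweight_validation_error"
    )
  }

  data$.z <- z
  data$.g <- make_subgroup_index(data[roles$ses])
  attr(data, "roles") <- roles
  class(data) <- c("disparity_df", class(tibble::tibble()))
  data
}

# Lexicographic 1-based subgroup index over distinct SES value tuples.
make_subgroup_index <- function(x_s) {
  if (ncol(x_s) == 0L) return(rep(1L, nrow(x_s)))
  if (nrow(x_s) == 0L) abort("Empty SES table.", class = "deweight_validation_error")
  key <- do.call(paste, c(lapply(x_s, as.character), sep = "\r"))
  lev <- do.call(order, lapply(x_s[!duplicated(key), , drop = FALSE], as.character))
  ordered_keys <- unique(key)[lev]
  match(key, ordered_keys)
}

#' @export
print.disparity_df <- function(x, ...) {
  r <- attr(x, "roles")
  cat(sprintf(
    "# disparity_df: %d subjects (%d minority, %d majority), %d SES subgroup(s)\n",
    nrow(x), sum(x$.z), sum(1 - x$.z), max(x$.g)
  ))
  health_lab <- paste(head(r$health, 4), collapse = ",")
  if (length(r$health) > 4) health_lab <- paste0(health_lab, ",...")
  cat(sprintf("# roles: group=%s outcome=%s ses=[%s] health=[%s]\n",
              r$group, r$outcome, paste(r$ses, collapse = ","), health_lab))
  NextMethod()
}

roles_of <- function(data) {
  r <- attr(data, "roles")
  if (is.null(r)) {
    abort("Expected a disparity_df (see as_disparity_data()).",
          class = "deweight_error")
  }
  r
}

#' SES-subgroup catalog
#'
#' One row per observed SES combination: the subgroup index, the SES values,
#' and the minority/majority counts. The index matches the `.g` column of the
#' data.
#'
#' @param data A `disparity_df`.
#' @return A tibble with columns `.g`, one column per SES covariate,
#'   `n_minority`, `n_majority`, `n`.
#' @export
ses_subgroups <- function(data) {
  roles <- roles_of(data)
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(".g", roles$ses)))) |>
    dplyr::summarise(
      n_minority = sum(.data$.z),
      n_majority = sum(1 - .data$.z),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$.g)
}

#' Read a subject-level table and tag roles
#'
#' Thin wrapper around [readr::read_csv()] / [readr::read_tsv()] (chosen by
#' file extension) followed by [as_disparity_data()].
#'
#' @inheritParams as_disparity_data
#' @param path Path to a delimited text file with a header row.
#' @return A `disparity_df`.
#' @export
read_disparity_data <- function(path, group, outcome, ses, health,
                                minority = NULL,
                                na_action = c("fail", "omit")) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "deweight_schema_error")
  }
  reader <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) {
    readr::read_tsv
  } else {
    readr::read_csv
  }
  raw <- reader(path, show_col_types = FALSE, progress = FALSE)
  as_disparity_data(raw, group = group, outcome = outcome, ses = ses,
                    health = health, minority = minority,
                    na_action = na_action)
}

#' Write a disparity dataset back to delimited text
#'
#' Writes the subject table (original columns, without the derived `.z` and
#' `.g` columns) as CSV. Re-reading with the same roles reproduces the
#' dataset, including the subgroup index, exactly.
#'
#' @param data A `disparity_df`.
#' @param path Output CSV path.
#' @param keep_derived Also write `.z` and `.g` (default `FALSE`).
#' @return `path`, invisibly.
#' @export
write_disparity_data <- function(data, path, keep_derived = FALSE) {
  out <- as.data.frame(data)
  if (!keep_derived) out <- out[setdiff(names(out), c(".z", ".g"))]
  readr::write_csv(tibble::as_tibble(out), path, progress = FALSE)
  invisible(path)
}
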