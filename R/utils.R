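# Internal helpers shared across modules.

expit <- function(x) stats::plogis(x)

# Hajek (self-normalized) weighted mean; weights need not sum to 1.
wmean <- function(x, w) {
  sw <- sum(w)
  if (sw <= 0) abort("Total weight is not positive.", class = "deweight_error")
  sum(w * x) / sw
}

# Dummy-encode a categorical vector with the most frequent level as reference.
# Returns a numeric matrix with one column per non-reference level, named
# "<name>_<level>". A numeric column is returned unchanged (single column).
encode_column <- function(x, name) {
  if (is.numeric(x) || is.logical(x)) {
    m <- matrix(as.numeric(x), ncol = 1)
    colnames(m) <- name
    return(m)
  }
  x <- as.character(x)
  tab <- sort(table(x), decreasing = TRUE)
  ref <- names(tab)[1L]
  levs <- setdiff(names(tab), ref)
  m <- vapply(levs, function(l) as.numeric(x == l), numeric(length(x)))
  if (length(levs) == 1L) m <- matrix(m, ncol = 1)
  colnames(m) <- paste(name, levs, sep = "_")
  attr(m, "reference") <- ref
  m
}

# Build the numeric design matrix (no intercept) for a set of columns.
encode_columns <- function(data, cols) {
  if (length(cols) == 0L) {
    return(matrix(numeric(0), nrow = nrow(data), ncol = 0))
  }
  mats <- lapply(cols, function(nm) encode_column(data[[nm]], nm))
  do.call(cbind, mats)
}

check_prob_open <- function(e, what = "propensity score", tol = 1e-6) {
  if (any(e <= 0 | e >= 1)) {
    abort(
      sprintf("Estimated %s at 0 or 1; positivity is violated.", what),
      class = "deweight_positivity_error"
    )
  }
  n_extreme <- sum(e < tol | e > 1 - tol)
  if (n_extreme > 0) {
    warn(sprintf(
      "%d %s value(s) outside [%g, %g]; weights may be unstable.",
      n_extreme, what, tol, 1 - tol
    ))
  }
  invisible(e)
}
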