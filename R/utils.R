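# Internal helpers: condition classes, column checks, grouped moment engine.

tc_format_error <- function(msg, ...) {
  abort(msg, class = "tilecall_format_error", ...)
}

tc_data_error <- function(msg, ...) {
  abort(msg, class = "tilecall_data_error", ...)
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    tc_format_error(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# Sample sheet conventions: condition must be exactly the two levels below.
.conditions <- c("control", "treatment")

check_samples <- function(samples) {
  check_columns(samples, c("sample_id", "condition", "block"), "sample sheet")
  bad <- setdiff(unique(samples$condition), .conditions)
  if (length(bad) > 0) {
    tc_format_error(sprintf(
      "condition must be one of {%s}; found: %s",
      paste(.conditions, collapse = ", "), paste(bad, collapse = ", ")
    ))
  }
  if (anyDuplicated(samples$sample_id)) {
    tc_format_error("duplicate sample_id in sample sheet")
  }
  invisible(samples)
}

# Intensity tables are tibbles with a probe_id column plus one numeric column
# per sample; this extracts the numeric part as a matrix.
intensity_matrix <- function(intensities, samples = NULL) {
  check_columns(intensities, "probe_id", "intensity table")
  cols <- setdiff(names(intensities), "probe_id")
  if (!is.null(samples)) {
    missing <- setdiff(samples$sample_id, cols)
    if (length(missing) > 0) {
      tc_format_error(sprintf(
        "intensity table lacks sample column(s): %s",
        paste(missing, collapse = ", ")
      ))
    }
    cols <- samples$sample_id
  }
  m <- as.matrix(intensities[cols])
  if (!is.numeric(m)) tc_format_error("intensity columns must be numeric")
  rownames(m) <- intensities$probe_id
  m
}

# Grouped first/second moments via rowsum(); the workhorse behind every test
# in the cascade. Two-pass so constant groups get an exact zero sum of squares.
grouped_moments <- function(value, key) {
  key <- as.character(key)
  ones <- rep(1, length(value))
  n <- rowsum(ones, key)
  s <- rowsum(value, key)
  m <- s / n
  centred <- value - m[key, 1L]
  ss <- rowsum(centred * centred, key)
  tibble(
    key = rownames(n),
    n = as.vector(n),
    mean = as.vector(m),
    ss = as.vector(ss)
  )
}

# One-sample two-tailed t against mean zero, from moments. Zero-variance
# groups: p = 1 when the mean is exactly zero (no evidence), otherwise the
# p -> 0 limit with a degenerate flag.
t_from_moments <- function(n, mean, ss) {
  var <- ifelse(n > 1, ss / (n - 1), NA_real_)
  se <- sqrt(var / n)
  t <- ifelse(se > 0, mean / se, ifelse(mean == 0, 0, Inf * sign(mean)))
  p <- ifelse(
    n < 2, NA_real_,
    ifelse(se > 0, 2 * pt(-abs(mean / se), df = n - 1),
           ifelse(mean == 0, 1, 0))
  )
  tibble(t_stat = t, p_value = p,
         degenerate = n >= 2 & se == 0 & mean != 0)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
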