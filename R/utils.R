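`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
stop_gp <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "gammaprev_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

assert_number <- function(x, name, lower = -Inf, upper = Inf,
                          strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_gp(sprintf("'%s' must be a single finite number", name), "gammaprev_domain_error")
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop_gp(sprintf("'%s' = %g is outside its admissible range", name, x),
            "gammaprev_domain_error")
  invisible(x)
}

## Population (divide-by-n) variance: the moment convention used throughout,
## so that the Bhatia-Davis bound var <= (1 - mean) * mean holds exactly for
## any bounded sample.
pop_var <- function(x) {
  m <- mean(x)
  v <- mean(x * x) - m * m
  max(v, 0)
}

## z-score a numeric vector; error if degenerate
zscore <- function(x) {
  if (length(x) < 2L)
    stop_gp("need at least 2 values to rescale", "gammaprev_domain_error")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop_gp("cannot rescale values with zero standard deviation",
            "gammaprev_domain_error")
  (x - mean(x)) / s
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop_gp(sprintf("%s is missing required column(s): %s", what,
                    paste(missing, collapse = ", ")),
            "gammaprev_format_error")
  invisible(df)
}
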