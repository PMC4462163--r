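`%||%` <- function(a, b) if (is.null(a)) b else a

# row-numbered validation error; rows are 1-based data rows (header excluded)
stop_rows <- function(msg, rows) {
  stop(sprintf("%s (row%s %s)", msg, if (length(rows) > 1L) "s" else "",
               paste(rows, collapse = ", ")), call. = FALSE)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_upper = TRUE, allow_lower = TRUE) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop(sprintf("'%s' must be finite numeric", name), call. = FALSE)
  bad <- (if (allow_lower) x < lower else x <= lower) |
         (if (allow_upper) x > upper else x >= upper)
  if (any(bad))
    stop(sprintf("'%s' out of range [%s, %s%s: %s", name, lower, upper,
                 if (allow_upper) "]" else ")",
                 paste(utils::head(x[bad], 3), collapse = ", ")), call. = FALSE)
  invisible(x)
}
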