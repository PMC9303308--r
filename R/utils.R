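# Classed error conditions so callers and tests can distinguish failure modes.
ts_stop <- function(class, fmt, ...) {
  msg <- if (length(list(...)) > 0L) sprintf(fmt, ...) else fmt
  stop(structure(
    class = c(class, "twistspacer_error", "error", "condition"),
    list(message = msg, call = sys.call(-1L))
  ))
}

stop_invalid <- function(fmt, ...) ts_stop("twistspacer_invalid_argument", fmt, ...)
stop_missing_reference <- function(fmt, ...) ts_stop("twistspacer_missing_reference", fmt, ...)
stop_insufficient_data <- function(fmt, ...) ts_stop("twistspacer_insufficient_data", fmt, ...)
stop_format <- function(fmt, ...) ts_stop("twistspacer_format_error", fmt, ...)
stop_out_of_range <- function(fmt, ...) ts_stop("twistspacer_out_of_range", fmt, ...)
stop_usage <- function(fmt, ...) ts_stop("twistspacer_usage_error", fmt, ...)

assert_number <- function(x, name, lower = -Inf, upper = Inf, allow_vector = FALSE) {
  if (!is.numeric(x) || any(!is.finite(x)) ||
      (!allow_vector && length(x) != 1L)) {
    stop_invalid("`%s` must be %s finite numeric value(s)",
                 name, if (allow_vector) "" else "a single")
  }
  if (any(x < lower) || any(x > upper)) {
    stop_invalid("`%s` must lie in [%g, %g]", name, lower, upper)
  }
  invisible(x)
}

#' Convert between degrees and radians
#'
#' All angles are stored internally in radians (the published twist stiffness
#' is per squared radian); user-facing I/O is in degrees.
#'
#' @param deg,rad angle(s) to convert.
#' @return numeric vector of converted angles.
#' @export
deg2rad <- function(deg) deg * pi / 180

#' @rdname deg2rad
#' @export
rad2deg <- function(rad) rad * 180 / pi

# Spacer lengths: the formula is defined for any n >= 1 but the model has only
# been validated on 15-19 nt spacers; warn outside that window, refuse absurd n.
check_spacer_length <- function(n, name = "n") {
  if (!is.numeric(n) || length(n) == 0L || any(!is.finite(n))) {
    stop_invalid("`%s` must be finite numeric spacer length(s)", name)
  }
  if (any(n < 1 | n > 30)) {
    stop_invalid("`%s` must lie in [1, 30] nucleotides (got %s)",
                 name, paste(n[n < 1 | n > 30], collapse = ", "))
  }
  if (any(n < 15 | n > 19)) {
    warning("spacer length outside the validated 15-19 nt range; ",
            "model predictions there are extrapolations", call. = FALSE)
  }
  invisible(n)
}

check_sigma <- function(sigma, name = "sigma") {
  if (!is.numeric(sigma) || length(sigma) == 0L || any(!is.finite(sigma))) {
    stop_invalid("`%s` must be finite numeric superhelical density value(s)", name)
  }
  invisible(sigma)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
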