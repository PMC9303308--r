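#' Read an in vitro transcription table
#'
#' TSV with columns `promoter_id`, `sigma`, `spacer_len`, `activity` and an
#' optional `replicate`.
#'
#' @param file path to a TSV file.
#' @return data frame of measurements.
#' @export
read_invitro_table <- function(file) {
  df <- read.delim(file, stringsAsFactors = FALSE)
  need <- c("promoter_id", "sigma", "spacer_len", "activity")
  if (!all(need %in% names(df))) {
    stop_format("in vitro table must have columns %s", paste(need, collapse = ", "))
  }
  if (any(!is.finite(df$activity)) || any(df$activity <= 0)) {
    stop_invalid("all activities must be finite and > 0")
  }
  df
}

#' Normalise activities to the reference spacer length
#'
#' For each measurement, the natural-log ratio of its activity to the
#' reference-spacer (`n_ref`) activity at the same superhelical density. With
#' replicated reference measurements the geometric mean is used, so that
#' reference points map to exactly 0. This normalisation removes the basal
#' rate and every spacer-independent supercoiling effect, leaving the
#' orientational-energy difference plus the promoter-specific offset.
#'
#' @param data data frame with columns `sigma`, `spacer_len`, `activity` (and
#'   optionally `promoter_id`).
#' @param n_ref reference spacer length (default 17).
#' @param sigma_tol sigma-matching tolerance: 0 (default) requires an exact
#'   match; a positive value matches each point to the nearest reference
#'   sigma within the tolerance (for digitised datasets, 0.002 is suggested).
#' @return data frame with columns `sigma`, `spacer_len`, `log_ratio` (plus
#'   `promoter_id` if present).
#' @export
normalize_to_reference <- function(data, n_ref = 17, sigma_tol = 0) {
  need <- c("sigma", "spacer_len", "activity")
  if (!is.data.frame(data) || !all(need %in% names(data))) {
    stop_format("`data` must have columns %s", paste(need, collapse = ", "))
  }
  if (any(!is.finite(data$activity)) || any(data$activity <= 0)) {
    stop_invalid("all activities must be finite and > 0")
  }
  ref <- data[data$spacer_len == n_ref, , drop = FALSE]
  if (nrow(ref) == 0L) {
    stop_missing_reference("no measurement at the reference spacer length %g", n_ref)
  }
  # geometric mean of the reference activity at each reference sigma
  ref_sig <- sort(unique(ref$sigma))
  ref_log <- vapply(ref_sig, function(s) mean(log(ref$activity[ref$sigma == s])),
                    numeric(1L))
  idx <- vapply(data$sigma, function(s) {
    d <- abs(ref_sig - s)
    i <- which.min(d)
    if (d[i] <= max(sigma_tol, 0)) i else NA_integer_
  }, integer(1L))
  if (anyNA(idx)) {
    miss <- sort(unique(data$sigma[is.na(idx)]))
    stop_missing_reference(
      "no reference (n = %g) measurement at sigma = %s",
      n_ref, paste(signif(miss, 6), collapse = ", "))
  }
  out <- data.frame(sigma = data$sigma, spacer_len = data$spacer_len,
                    log_ratio = log(data$activity) - ref_log[idx])
  if ("promoter_id" %in% names(data)) out$promoter_id <- data$promoter_id
  out
}

#' Fit the promoter-specific intercept for one spacer length
#'
#' The slope of the normalised log-ratio against sigma is fully predicted by
#' the model; only the sigma-independent offset `Q_sp` is promoter-specific.
#' This fits that offset by least squares: the mean residual after subtracting
#' the parameter-free orientational part, with a Student 95% confidence
#' interval. The slope is *not* fitted.
#'
#' @param points normalised points (output of [normalize_to_reference()]) for
#'   a single spacer length, or a larger table together with `n`.
#' @param n spacer length to fit; defaults to the single length present.
#' @param params a [twist_params()] object.
#' @param conf_level confidence level (default 0.95).
#' @return list with `q_sp`, `ci`, `se`, `df`, `n_points`, `spacer_len`.
#' @export
fit_intercept <- function(points, n = NULL, params = twist_params(),
                          conf_level = 0.95) {
  if (!is.data.frame(points) || !all(c("sigma", "spacer_len", "log_ratio") %in% names(points))) {
    stop_format("`points` must have columns sigma, spacer_len, log_ratio")
  }
  if (is.null(n)) {
    n <- unique(points$spacer_len)
    if (length(n) != 1L) stop_invalid("`points` holds several spacer lengths; give `n`")
  }
  pts <- points[points$spacer_len == n, , drop = FALSE]
  if (nrow(pts) < 2L) {
    stop_insufficient_data("need at least 2 points to fit an intercept (got %d)", nrow(pts))
  }
  model_part <- orientational_energy(pts$sigma, params$n_ref, params) -
    orientational_energy(pts$sigma, n, params)
  resid <- pts$log_ratio - model_part
  m <- length(resid)
  est <- mean(resid)
  se <- sd(resid) / sqrt(m)
  half <- qt(1 - (1 - conf_level) / 2, df = m - 1L) * se
  list(q_sp = est, ci = c(lower = est - half, upper = est + half),
       se = se, df = m - 1L, n_points = m, spacer_len = n)
}

#' Test the fitted slope against the parameter-free prediction
#'
#' Ordinary least-squares fit of the normalised log-ratio on sigma for one
#' spacer length, compared with the model's predicted slope. The predicted
#' slope is the exact derivative evaluated at the dataset's mean sigma,
#' `-k_theta * alpha0^2 * (n - n_ref) * (1 + mean(sigma))`; the pure
#' linearised value is reported alongside. Compatibility is summarised by the
#' z-statistic `(fitted - predicted) / SE` and its two-sided normal p-value.
#'
#' @inheritParams fit_intercept
#' @return list with `fitted_slope`, `se`, `predicted_slope`,
#'   `linearized_slope`, `z`, `p_value`, `intercept`, `n_points`,
#'   `spacer_len`.
#' @export
slope_consistency_test <- function(points, n = NULL, params = twist_params()) {
  if (!is.data.frame(points) || !all(c("sigma", "spacer_len", "log_ratio") %in% names(points))) {
    stop_format("`points` must have columns sigma, spacer_len, log_ratio")
  }
  if (is.null(n)) {
    n <- unique(points$spacer_len)
    if (length(n) != 1L) stop_invalid("`points` holds several spacer lengths; give `n`")
  }
  pts <- points[points$spacer_len == n, , drop = FALSE]
  if (nrow(pts) < 3L) {
    stop_insufficient_data("need at least 3 points for a slope test (got %d)", nrow(pts))
  }
  fit <- lm(log_ratio ~ sigma, data = pts)
  sm <- summary(fit)$coefficients
  fitted_slope <- unname(coef(fit)["sigma"])
  se <- sm["sigma", "Std. Error"]
  predicted <- relative_expression_slope(n, params, linearized = FALSE,
                                         sigma = mean(pts$sigma))
  linearized <- relative_expression_slope(n, params, linearized = TRUE)
  z <- if (se > 0) (fitted_slope - predicted) / se else
    ifelse(abs(fitted_slope - predicted) < 1e-8, 0, Inf)
  list(fitted_slope = fitted_slope, se = se, predicted_slope = predicted,
       linearized_slope = linearized, z = z, p_value = 2 * pnorm(-abs(z)),
       intercept = unname(coef(fit)["(Intercept)"]), n_points = nrow(pts),
       spacer_len = n)
}

#' Full in vitro analysis report
#'
#' Normalises a titration dataset to the reference spacer and, for every
#' non-reference spacer length, fits the promoter-specific intercept and runs
#' the slope-consistency test.
#'
#' @param data in vitro measurement data frame (see [read_invitro_table()]).
#' @param n_ref reference spacer length.
#' @param params a [twist_params()] object.
#' @param sigma_tol sigma-matching tolerance (see [normalize_to_reference()]).
#' @return list with `normalized` (data frame) and `fits` (one list per
#'   spacer length with intercept and slope results).
#' @export
invitro_report <- function(data, n_ref = 17, params = twist_params(),
                           sigma_tol = 0) {
  norm <- normalize_to_reference(data, n_ref = n_ref, sigma_tol = sigma_tol)
  lengths <- sort(setdiff(unique(norm$spacer_len), n_ref))
  fits <- lapply(lengths, function(n) {
    res <- list(spacer_len = n)
    res$intercept <- tryCatch(fit_intercept(norm, n, params),
                              twistspacer_error = function(e) conditionMessage(e))
    res$slope <- tryCatch(slope_consistency_test(norm, n, params),
                          twistspacer_error = function(e) conditionMessage(e))
    res
  })
  names(fits) <- paste0("n", lengths)
  list(normalized = norm, fits = fits, n_ref = n_ref)
}
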