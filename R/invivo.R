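#' Read a plate-reader reporter table
#'
#' Long-format TSV with columns `time_min`, `od`, `lum`, `promoter_id`,
#' `spacer_len`, `treatment`, `replicate`, `shock_time_min`.
#'
#' @param file path to a TSV file.
#' @return data frame of reporter time series.
#' @export
read_reporter_table <- function(file) {
  df <- read.delim(file, stringsAsFactors = FALSE)
  need <- c("time_min", "od", "lum", "promoter_id", "spacer_len",
            "treatment", "replicate", "shock_time_min")
  if (!all(need %in% names(df))) {
    stop_format("reporter table must have columns %s", paste(need, collapse = ", "))
  }
  if (any(df$lum < 0, na.rm = TRUE) || any(df$od < 0, na.rm = TRUE)) {
    stop_invalid("od and lum must be non-negative")
  }
  df
}

# Luminescence of each replicate of one arm at the evaluation time (nearest
# sample within half the sampling interval).
arm_values_at <- function(series, t_eval) {
  times <- sort(unique(series$time_min))
  if (length(times) < 2L) {
    stop_insufficient_data("need at least 2 time points per series")
  }
  dt <- median(diff(times))
  reps <- sort(unique(series$replicate))
  vapply(reps, function(r) {
    s <- series[series$replicate == r, , drop = FALSE]
    i <- which.min(abs(s$time_min - t_eval))
    if (abs(s$time_min[i] - t_eval) > dt / 2) {
      stop_out_of_range(
        "no measurement within half a sampling interval of t = %g min", t_eval)
    }
    s$lum[i]
  }, numeric(1L))
}

#' Shock fold-change from reporter time series
#'
#' Expression fold-change of a shocked culture relative to its vehicle
#' control, evaluated at a single time point `delay` minutes after the shock
#' (the nearest sample within half the sampling interval). The point estimate
#' is the ratio of mean luminescences (treated/vehicle); the 95% confidence
#' interval is a Student t interval on the log-ratios of replicate pairs
#' (paired by sorted replicate id).
#'
#' @param series long-format data frame for one promoter with columns
#'   `time_min`, `lum`, `treatment`, `replicate`, `shock_time_min` (and
#'   optionally `promoter_id`, `spacer_len`).
#' @param delay evaluation delay after the shock, minutes (presets: 60 for
#'   the relaxation drug, 5 for the overtwisting drug).
#' @param treated,vehicle labels of the two arms in the `treatment` column.
#' @param conf_level confidence level (default 0.95).
#' @return an object of class `fold_change_result`: list with `promoter_id`,
#'   `spacer_length`, `fold_change`, `ci95`, `n_replicates`,
#'   `evaluation_delay`, `log_ratios`.
#' @export
shock_fold_change <- function(series, delay, treated = "shock",
                              vehicle = "vehicle", conf_level = 0.95) {
  need <- c("time_min", "lum", "treatment", "replicate", "shock_time_min")
  if (!is.data.frame(series) || !all(need %in% names(series))) {
    stop_format("`series` must have columns %s", paste(need, collapse = ", "))
  }
  assert_number(delay, "delay", lower = 0)
  shock_time <- unique(series$shock_time_min)
  if (length(shock_time) != 1L) {
    stop_invalid("`series` must have a single shock_time_min")
  }
  t_eval <- shock_time + delay
  tr <- series[series$treatment == treated, , drop = FALSE]
  vh <- series[series$treatment == vehicle, , drop = FALSE]
  if (nrow(tr) == 0L || nrow(vh) == 0L) {
    stop_insufficient_data("both '%s' and '%s' arms must be present",
                           treated, vehicle)
  }
  tv <- arm_values_at(tr, t_eval)
  vv <- arm_values_at(vh, t_eval)
  if (any(vv == 0)) {
    ts_stop("twistspacer_undefined_ratio",
            "vehicle luminescence is zero at the evaluation time")
  }
  m <- min(length(tv), length(vv))
  if (length(tv) != length(vv)) {
    warning("unequal replicate counts; pairing the first ", m,
            " replicates of each arm", call. = FALSE)
  }
  lr <- log(tv[seq_len(m)] / vv[seq_len(m)])
  fc <- mean(tv) / mean(vv)
  ci <- if (m >= 2L) {
    half <- qt(1 - (1 - conf_level) / 2, df = m - 1L) * sd(lr) / sqrt(m)
    exp(mean(lr) + c(-1, 1) * half)
  } else c(NA_real_, NA_real_)
  structure(
    list(promoter_id = unique(series$promoter_id)[1L] %||% NA_character_,
         spacer_length = unique(series$spacer_len)[1L] %||% NA_real_,
         fold_change = fc, ci95 = setNames(ci, c("lower", "upper")),
         n_replicates = m, evaluation_delay = delay, log_ratios = lr),
    class = "fold_change_result")
}

#' @export
print.fold_change_result <- function(x, ...) {
  cat(sprintf("Fold-change %s (spacer %g nt): %.3f [%.3f, %.3f], %d replicates, %g' after shock\n",
              x$promoter_id, x$spacer_length, x$fold_change,
              x$ci95[1L], x$ci95[2L], x$n_replicates, x$evaluation_delay))
  invisible(x)
}

#' Fold-changes for every promoter of a reporter dataset
#'
#' Applies [shock_fold_change()] per `promoter_id`.
#'
#' @inheritParams shock_fold_change
#' @param data long-format reporter data frame covering several promoters.
#' @return data frame with one row per promoter: `promoter_id`,
#'   `spacer_length`, `fold_change`, `ci_lower`, `ci_upper`, `n_replicates`.
#' @export
panel_fold_changes <- function(data, delay, treated = "shock",
                               vehicle = "vehicle") {
  ids <- unique(data$promoter_id)
  rows <- lapply(ids, function(id) {
    r <- shock_fold_change(data[data$promoter_id == id, , drop = FALSE],
                           delay = delay, treated = treated, vehicle = vehicle)
    data.frame(promoter_id = id, spacer_length = r$spacer_length,
               fold_change = r$fold_change, ci_lower = r$ci95[1L],
               ci_upper = r$ci95[2L], n_replicates = r$n_replicates,
               row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Fit the effective shock parameters from a mutant panel
#'
#' Estimates the effective superhelical shift `delta_sigma` and the
#' spacer-independent term `r_sc` that reproduce the measured fold-changes of
#' a panel of spacer-length mutants of one promoter. Two variants:
#' * `"joint"` (default): least squares on log fold-changes over the whole
#'   panel, with `r_sc` profiled out analytically at each candidate
#'   `delta_sigma`;
#' * `"two_step"`: `r_sc` is pinned by the reference-spacer promoter alone and
#'   `delta_sigma` then fitted on the remaining lengths.
#' On noise-free model-generated panels the two agree exactly.
#'
#' @param panel data frame with columns `spacer_length` and `fold_change` (or
#'   `log_fc`); must contain the reference length.
#' @param sigma0 pre-shock superhelical density (default -0.06).
#' @param params a [twist_params()] object.
#' @param method `"joint"` or `"two_step"`.
#' @param interval search interval for `delta_sigma`.
#' @return list with `delta_sigma`, `r_sc`, `method`, `sse`, `fitted` (data
#'   frame of observed and predicted fold-changes) and `ref_fold_change`
#'   (model-predicted fold-change of the reference spacer, which includes the
#'   small orientational residual on top of `exp(-r_sc)`).
#' @export
fit_shock_model <- function(panel, sigma0 = -0.06, params = twist_params(),
                            method = c("joint", "two_step"),
                            interval = c(-0.12, 0.12)) {
  method <- match.arg(method)
  if (!is.data.frame(panel) || !("spacer_length" %in% names(panel))) {
    stop_format("`panel` must be a data frame with a `spacer_length` column")
  }
  lfc <- if ("log_fc" %in% names(panel)) panel$log_fc else {
    if (!("fold_change" %in% names(panel))) {
      stop_format("`panel` needs a `fold_change` or `log_fc` column")
    }
    if (any(panel$fold_change <= 0)) stop_invalid("fold-changes must be > 0")
    log(panel$fold_change)
  }
  n <- panel$spacer_length
  if (!(params$n_ref %in% n)) {
    stop_missing_reference("panel must contain the reference spacer length %g",
                           params$n_ref)
  }
  ddg <- function(ds, nn) {
    orientational_energy(sigma0 + ds, nn, params) -
      orientational_energy(sigma0, nn, params)
  }
  is_ref <- n == params$n_ref
  rsc_at <- function(ds) {
    switch(method,
      joint = -mean(lfc + ddg(ds, n)),
      two_step = -mean(lfc[is_ref]) - ddg(ds, params$n_ref))
  }
  sse_at <- function(ds) {
    r <- rsc_at(ds)
    pred <- -r - ddg(ds, n)
    use <- if (method == "two_step") !is_ref else rep(TRUE, length(n))
    if (!any(use)) use <- rep(TRUE, length(n))  # degenerate ref-only panel
    sum((lfc[use] - pred[use])^2)
  }
  grid <- seq(interval[1L], interval[2L], length.out = 241L)
  sse_grid <- vapply(grid, sse_at, numeric(1L))
  best <- grid[which.min(sse_grid)]
  step <- diff(grid[1:2])
  opt <- optimize(sse_at, lower = max(interval[1L], best - 2 * step),
                  upper = min(interval[2L], best + 2 * step), tol = 1e-12)
  ds_hat <- opt$minimum
  r_hat <- rsc_at(ds_hat)
  pred_lfc <- -r_hat - ddg(ds_hat, n)
  fitted <- data.frame(spacer_length = n, observed_fc = exp(lfc),
                       predicted_fc = exp(pred_lfc))
  list(delta_sigma = ds_hat, r_sc = r_hat, method = method, sse = opt$objective,
       fitted = fitted,
       ref_fold_change = exp(-r_hat - ddg(ds_hat, params$n_ref)))
}

#' Model-predicted fold-changes for a panel of spacer lengths
#'
#' `exp(logfc_under_shock())` for each length under a fitted or assumed
#' `(delta_sigma, r_sc)`.
#'
#' @param delta_sigma superhelical shift.
#' @param r_sc spacer-independent shock term, kBT.
#' @param spacer_lengths spacer lengths, nucleotides.
#' @param sigma0 pre-shock superhelical density.
#' @param params a [twist_params()] object.
#' @return named numeric vector of fold-changes.
#' @examples
#' predict_panel_foldchanges(-0.02, -0.97, c(15, 17, 19))  # ~0.95, 2.5, 6.2
#' @export
predict_panel_foldchanges <- function(delta_sigma, r_sc,
                                      spacer_lengths = 15:19,
                                      sigma0 = -0.06,
                                      params = twist_params()) {
  cond <- shock_condition(sigma0, delta_sigma)
  terms <- promoter_energy_terms(r_sc = r_sc)
  setNames(exp(logfc_under_shock(cond, spacer_lengths, terms, params)),
           spacer_lengths)
}
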