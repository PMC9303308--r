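# Independent oracles and fixture builders shared across test files.

# Constrained-quadratic oracle for the sequence energy: minimise
# sum_i k_i/2 (theta_i - alpha_i (1+sigma))^2 subject to sum_i theta_i =
# theta_P, by eliminating the last angle and solving the reduced linear
# system. Independent of the closed form under test.
qp_energy_oracle <- function(alpha, k, sigma, theta_P) {
  a <- alpha * (1 + sigma)
  m <- length(a)
  if (m == 1L) {
    return(k[1L] / 2 * (theta_P - a[1L])^2)
  }
  km <- k[m]
  H <- diag(k[-m], m - 1L) + km
  b <- k[-m] * a[-m] + km * (theta_P - a[m])
  x <- solve(H, b)
  theta <- c(x, theta_P - sum(x))
  sum(k / 2 * (theta - a)^2)
}

# Discrete-convolution oracle for the first-order reporter filter: the
# filtered signal at time t is the exponentially weighted history of the
# step activity, computed by brute-force quadrature.
convolution_reporter_oracle <- function(t, shock_time, a0, a1, tau,
                                        dt = 0.001) {
  s <- seq(-20 * tau, t, by = dt)
  act <- ifelse(s <= shock_time, a0, a1)
  sum(act * exp(-(t - s) / tau) / tau * dt)
}

random_spacer <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Minimal two-arm reporter fixture with given replicate luminescence values
# at the evaluation time.
make_fc_series <- function(treated_vals, vehicle_vals, t_eval = 10,
                           shock_time = 0) {
  rows <- list()
  add <- function(arm, vals) {
    for (j in seq_along(vals)) {
      rows[[length(rows) + 1L]] <<- data.frame(
        time_min = c(shock_time, t_eval), od = 0.5,
        lum = c(1, vals[j]), promoter_id = "p", spacer_len = 17,
        treatment = arm, replicate = j, shock_time_min = shock_time)
    }
  }
  add("shock", treated_vals)
  add("vehicle", vehicle_vals)
  do.call(rbind, rows)
}

# Promoter/response fixture with classes assigned independently of spacer
# length (null for the spacer-class association).
make_null_cohort <- function(n_per_class = 60) {
  probs <- c(`15` = 0.14, `16` = 0.14, `17` = 0.27, `18` = 0.25, `19` = 0.20)
  n <- 2 * n_per_class
  promoters <- data.frame(
    promoter_id = sprintf("n%03d", seq_len(n)),
    sigma_factor = "sigma70",
    spacer_len = as.numeric(sample(names(probs), n, TRUE, probs)))
  responses <- data.frame(
    promoter_id = promoters$promoter_id,
    logfc = rep(c(1, -1), each = n_per_class),
    padj = 1e-4)
  list(promoters = promoters, responses = responses)
}
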