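#' Optimal RNAP-imposed spacer twist angle
#'
#' Total spacer twist angle imposed by RNA polymerase, chosen such that a
#' spacer of length `n_opt` is at zero orientational deformation at the
#' superhelical density `sigma_opt`: `theta_P = n_opt * alpha0 * (1 + sigma_opt)`.
#' With the defaults (17 nt, sigma = -0.06, alpha0 = 34 deg) this is 543.32
#' degrees, conventionally rounded to 543; most downstream predictions
#' (all slopes and fold-change differences) are independent of its value.
#'
#' @param n_opt spacer length (nt) that is optimal at `sigma_opt`.
#' @param sigma_opt superhelical density at which `n_opt` is optimal.
#' @param alpha0 mean twist per basepair step, radians.
#' @return angle in radians.
#' @examples
#' rad2deg(default_theta_P())             # 543.32
#' rad2deg(default_theta_P(17, 0))        # 578
#' @export
default_theta_P <- function(n_opt = 17, sigma_opt = -0.06, alpha0 = deg2rad(34)) {
  if (!is.numeric(n_opt) || length(n_opt) != 1L || !is.finite(n_opt) || n_opt < 1) {
    stop_invalid("`n_opt` must be a single spacer length >= 1")
  }
  assert_number(sigma_opt, "sigma_opt", -0.3, 0.3)
  assert_number(alpha0, "alpha0", lower = .Machine$double.xmin)
  n_opt * alpha0 * (1 + sigma_opt)
}

#' Physical constants of the torsion model
#'
#' Bundles the DNA twist stiffness, mean twist per basepair step, the
#' RNAP-imposed total spacer angle and the reference spacer length. Angles are
#' taken in degrees at this boundary and stored in radians (the stiffness is
#' published per squared radian).
#'
#' @param k_theta sequence-averaged DNA twist stiffness, kBT per rad^2 per
#'   basepair step (default 71.4).
#' @param alpha0_deg mean twist angle between adjacent nucleotides, degrees
#'   (default 34).
#' @param theta_P_deg optimal total spacer twist angle for RNAP binding,
#'   degrees. Default `NULL` computes the unrounded value that makes the
#'   `n_ref` spacer optimal at `sigma_ref` (543.32 deg with defaults); the
#'   printed 543 is an output rounding convention only.
#' @param n_ref reference spacer length, nucleotides (default 17, the most
#'   frequent length among sigma70 promoters).
#' @param sigma_ref superhelical density at which the reference spacer is
#'   optimal (default -0.06, the standard level of exponentially growing
#'   E. coli).
#' @return an object of class `twist_params` with fields `k_theta`, `alpha0`
#'   (rad), `theta_P` (rad), `n_ref`, `sigma_ref`.
#' @examples
#' p <- twist_params()
#' round(rad2deg(p$theta_P))  # 543
#' @export
twist_params <- function(k_theta = 71.4, alpha0_deg = 34, theta_P_deg = NULL,
                         n_ref = 17, sigma_ref = -0.06) {
  assert_number(k_theta, "k_theta", lower = .Machine$double.xmin)
  assert_number(alpha0_deg, "alpha0_deg", lower = .Machine$double.xmin)
  if (!is.numeric(n_ref) || length(n_ref) != 1L || !is.finite(n_ref) || n_ref < 1) {
    stop_invalid("`n_ref` must be a single spacer length >= 1")
  }
  assert_number(sigma_ref, "sigma_ref", -0.3, 0.3)
  alpha0 <- deg2rad(alpha0_deg)
  theta_P <- if (is.null(theta_P_deg)) {
    default_theta_P(n_ref, sigma_ref, alpha0)
  } else {
    assert_number(theta_P_deg, "theta_P_deg", lower = .Machine$double.xmin)
    deg2rad(theta_P_deg)
  }
  structure(
    list(k_theta = k_theta, alpha0 = alpha0, theta_P = theta_P,
         n_ref = n_ref, sigma_ref = sigma_ref),
    class = "twist_params"
  )
}

#' @export
print.twist_params <- function(x, ...) {
  cat("Torsion model parameters\n")
  cat(sprintf("  k_theta : %.3f kBT/rad^2 per step\n", x$k_theta))
  cat(sprintf("  alpha0  : %.2f deg (%.5f rad)\n", rad2deg(x$alpha0), x$alpha0))
  cat(sprintf("  theta_P : %.2f deg (%.5f rad)\n", rad2deg(x$theta_P), x$theta_P))
  cat(sprintf("  n_ref   : %g nt, optimal at sigma = %g\n", x$n_ref, x$sigma_ref))
  invisible(x)
}

#' Promoter-specific non-orientational energy terms
#'
#' Promoter terms that the model does not predict: the basal rate `k0`
#' (set by the -10/-35 affinities), the sigma-independent spacer offset
#' `q_sp` (difference of spacer free energies between the reference and this
#' variant, kBT), and the spacer-independent supercoiling-shock term `r_sc`
#' (kBT; its fold-change contribution is `exp(-r_sc)`).
#'
#' @param k0 basal transcription rate, arbitrary activity units, > 0.
#' @param q_sp sigma-independent spacer intercept, kBT.
#' @param r_sc spacer-independent shock term, kBT.
#' @return an object of class `promoter_terms`.
#' @export
promoter_energy_terms <- function(k0 = 1, q_sp = 0, r_sc = 0) {
  if (!is.numeric(k0) || length(k0) != 1L || !is.finite(k0) || k0 <= 0) {
    stop_invalid("`k0` must be a single finite rate > 0")
  }
  assert_number(q_sp, "q_sp")
  assert_number(r_sc, "r_sc")
  structure(list(k0 = k0, q_sp = q_sp, r_sc = r_sc), class = "promoter_terms")
}

#' Superhelical shock condition
#'
#' A global superhelical shift `sigma0 -> sigma0 + delta_sigma`. Positive
#' `delta_sigma` is a DNA relaxation (e.g. gyrase inhibition by novobiocin),
#' negative an overtwisting (e.g. topoisomerase I inhibition by
#' seconeolitsine).
#'
#' @param sigma0 pre-shock superhelical density.
#' @param delta_sigma superhelical shift (dimensionless).
#' @return an object of class `shock_condition`.
#' @export
shock_condition <- function(sigma0 = -0.06, delta_sigma = 0) {
  assert_number(sigma0, "sigma0")
  assert_number(delta_sigma, "delta_sigma")
  if (abs(sigma0) >= 0.3 || abs(sigma0 + delta_sigma) >= 0.3) {
    stop_invalid("|sigma0| and |sigma0 + delta_sigma| must stay below 0.3")
  }
  structure(list(sigma0 = sigma0, delta_sigma = delta_sigma),
            class = "shock_condition")
}

#' Orientational free energy of the spacer
#'
#' Elastic cost of (un)twisting an `n`-nt spacer from its supercoiling-set
#' twist `alpha0 * (1 + sigma)` per step to the RNAP-imposed total angle
#' `theta_P`:
#' `(n/2) * k_theta * (theta_P/n - alpha0*(1+sigma))^2` (kBT).
#' Non-negative everywhere, zero exactly where `theta_P/n = alpha0*(1+sigma)`,
#' and quadratic (convex) in sigma at fixed n.
#'
#' @param sigma superhelical density (vectorised).
#' @param n spacer length, nucleotides (vectorised).
#' @param params a [twist_params()] object.
#' @return energy in kBT.
#' @examples
#' orientational_energy(-0.06, 17)  # 0 by construction of theta_P
#' orientational_energy(0, 17)      # ~0.769
#' @export
orientational_energy <- function(sigma, n, params = twist_params()) {
  if (!inherits(params, "twist_params")) {
    stop_invalid("`params` must be a `twist_params` object")
  }
  check_sigma(sigma)
  check_spacer_length(n)
  (n / 2) * params$k_theta * (params$theta_P / n - params$alpha0 * (1 + sigma))^2
}

#' Transcription rate under the thermodynamic framework
#'
#' `k = k0 * exp(-(DG_or - q_sp + sc_energy))`: the basal rate attenuated by
#' the orientational energy, optionally offset by the promoter-specific
#' sigma-independent spacer term `q_sp` and by an additional spacer-independent
#' supercoiling energy `sc_energy` (kBT, vectorised with `sigma`). Strictly
#' positive and monotone decreasing in the orientational energy.
#'
#' @inheritParams orientational_energy
#' @param terms a [promoter_energy_terms()] object.
#' @param sc_energy optional spacer-independent supercoiling free energy
#'   (kBT); cancels in all relative quantities.
#' @return activity in the units of `terms$k0`.
#' @export
transcription_rate <- function(sigma, n, terms = promoter_energy_terms(),
                               params = twist_params(), sc_energy = 0) {
  if (!inherits(terms, "promoter_terms")) {
    stop_invalid("`terms` must be a `promoter_terms` object")
  }
  terms$k0 * exp(-(orientational_energy(sigma, n, params) - terms$q_sp + sc_energy))
}

#' Log relative expression versus the reference spacer
#'
#' Natural-log ratio of the activity of an `n`-nt spacer variant to the
#' reference (`n_ref`) variant of the same promoter at the same sigma:
#' `DG_or(sigma, n_ref) - DG_or(sigma, n) + q_sp`. Independent of `k0` and of
#' any spacer-independent sigma term, which cancel in the normalisation.
#'
#' @inheritParams transcription_rate
#' @return dimensionless natural-log ratio.
#' @export
log_relative_expression <- function(sigma, n, terms = promoter_energy_terms(),
                                    params = twist_params()) {
  if (!inherits(terms, "promoter_terms")) {
    stop_invalid("`terms` must be a `promoter_terms` object")
  }
  orientational_energy(sigma, params$n_ref, params) -
    orientational_energy(sigma, n, params) + terms$q_sp
}

#' Slope of the log relative expression in sigma
#'
#' The parameter-free slope of [log_relative_expression()] with respect to
#' sigma. The linearised form is `-k_theta * alpha0^2 * (n - n_ref)`
#' (about -25.1 per nucleotide with the default constants), independent of
#' `theta_P` and `q_sp`; the exact analytic derivative at a given sigma
#' carries an additional factor `(1 + sigma)`.
#'
#' @inheritParams orientational_energy
#' @param linearized if `TRUE` (default) return the sigma-free linearised
#'   slope; otherwise the exact derivative at `sigma`.
#' @param sigma superhelical density at which the exact derivative is
#'   evaluated (ignored when `linearized = TRUE`).
#' @return d(log-ratio)/d(sigma), dimensionless.
#' @examples
#' relative_expression_slope(18)                       # ~ -25.1
#' relative_expression_slope(19) / relative_expression_slope(18)  # 2
#' @export
relative_expression_slope <- function(n, params = twist_params(),
                                      linearized = TRUE,
                                      sigma = params$sigma_ref) {
  if (!inherits(params, "twist_params")) {
    stop_invalid("`params` must be a `twist_params` object")
  }
  check_spacer_length(n)
  base <- -params$k_theta * params$alpha0^2 * (n - params$n_ref)
  if (linearized) base else {
    check_sigma(sigma)
    base * (1 + sigma)
  }
}

#' Log fold-change of a promoter under a superhelical shock
#'
#' Natural-log expression fold-change induced by `sigma0 -> sigma0 +
#' delta_sigma`:
#' `-r_sc - (DG_or(sigma0 + delta_sigma, n) - DG_or(sigma0, n))`.
#' The orientational part is evaluated exactly (not linearised), so the small
#' residual of the reference spacer after the shock is retained.
#'
#' @param cond a [shock_condition()] object.
#' @inheritParams transcription_rate
#' @return natural-log fold-change (use `exp()` for the fold-change,
#'   `/log(2)` for log2).
#' @examples
#' cond <- shock_condition(-0.06, -0.02)
#' exp(logfc_under_shock(cond, 19, promoter_energy_terms(r_sc = -0.97)))  # ~6.2
#' @export
logfc_under_shock <- function(cond, n, terms = promoter_energy_terms(),
                              params = twist_params()) {
  if (!inherits(cond, "shock_condition")) {
    stop_invalid("`cond` must be a `shock_condition` object")
  }
  if (!inherits(terms, "promoter_terms")) {
    stop_invalid("`terms` must be a `promoter_terms` object")
  }
  -terms$r_sc -
    (orientational_energy(cond$sigma0 + cond$delta_sigma, n, params) -
       orientational_energy(cond$sigma0, n, params))
}

#' Spacer-length dependence of the shock response
#'
#' Difference of log fold-changes between spacers `n_ref + delta_n` and
#' `n_ref` under the same shock. The linearised form is
#' `-k_theta * alpha0^2 * delta_n * delta_sigma` (about `-25 * dn * dsigma`),
#' independent of `sigma0`, `theta_P` and all promoter-specific terms; the
#' exact form evaluates [logfc_under_shock()] at both lengths (the `r_sc` term
#' cancels) and equals the linearised value times `(1 + sigma0 +
#' delta_sigma/2)` because the energy is quadratic in sigma.
#'
#' @param delta_sigma superhelical shift.
#' @param delta_n spacer length difference, nucleotides.
#' @param params a [twist_params()] object.
#' @param linearized if `TRUE` (default) return the parameter-free linearised
#'   form.
#' @param sigma0 pre-shock level for the exact form (ignored when
#'   `linearized = TRUE`).
#' @return natural-log fold-change difference.
#' @examples
#' spacer_logfc_difference(0.03, 1)        # ~ -0.754; exp(0.754) ~ 2.1
#' @export
spacer_logfc_difference <- function(delta_sigma, delta_n,
                                    params = twist_params(),
                                    linearized = TRUE,
                                    sigma0 = params$sigma_ref) {
  if (!inherits(params, "twist_params")) {
    stop_invalid("`params` must be a `twist_params` object")
  }
  assert_number(delta_sigma, "delta_sigma", allow_vector = TRUE)
  if (!is.numeric(delta_n) || any(!is.finite(delta_n))) {
    stop_invalid("`delta_n` must be finite numeric value(s)")
  }
  if (linearized) {
    return(-params$k_theta * params$alpha0^2 * delta_n * delta_sigma)
  }
  assert_number(sigma0, "sigma0", allow_vector = TRUE)
  ddg <- function(n) {
    orientational_energy(sigma0 + delta_sigma, n, params) -
      orientational_energy(sigma0, n, params)
  }
  # r_sc cancels between the two lengths
  out <- numeric(length(delta_n))
  zero <- delta_n == 0
  if (any(!zero)) {
    out[!zero] <- -(ddg(params$n_ref + delta_n[!zero]) - ddg(params$n_ref))
  }
  out
}
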