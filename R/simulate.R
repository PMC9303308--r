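random_dna <- function(n, gc = 0.5) {
  paste(sample(c("G", "C", "A", "T"), n, replace = TRUE,
               prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Simulate an in vitro supercoiling titration
#'
#' Model-generated activities on a grid of superhelical densities for a set
#' of spacer-length variants of one promoter, with multiplicative log-normal
#' measurement noise. The reference length is always included so the dataset
#' can be normalised. A common spacer-independent supercoiling energy
#' `sc_energy(sigma)` (e.g. facilitated promoter opening at negative sigma)
#' can be added; it cancels on normalisation.
#'
#' @param lengths spacer lengths to simulate (reference added if absent).
#' @param sigma_grid superhelical densities of the titration.
#' @param q_sp named numeric vector of sigma-independent offsets per length
#'   (kBT; names are lengths, missing lengths get 0).
#' @param k0 basal rate.
#' @param noise_sd log-scale measurement noise sd (0 = noise-free).
#' @param seed RNG seed; mandatory when `noise_sd > 0`.
#' @param params a [twist_params()] object.
#' @param sc_energy function of sigma giving the spacer-independent
#'   supercoiling free energy (kBT); default linear relaxation penalty.
#' @return data frame with columns `promoter_id`, `sigma`, `spacer_len`,
#'   `activity`.
#' @export
simulate_invitro <- function(lengths = c(15, 17, 18, 19),
                             sigma_grid = seq(-0.09, -0.01, by = 0.01),
                             q_sp = NULL, k0 = 1, noise_sd = 0, seed = NULL,
                             params = twist_params(),
                             sc_energy = function(sigma) 20 * (sigma + 0.06)) {
  assert_number(noise_sd, "noise_sd", lower = 0)
  check_sigma(sigma_grid, "sigma_grid")
  if (noise_sd > 0 && is.null(seed)) {
    stop_invalid("`seed` is mandatory for a stochastic simulation")
  }
  if (!is.null(seed)) set.seed(seed)
  lengths <- sort(unique(c(lengths, params$n_ref)))
  grid <- expand.grid(sigma = sigma_grid, spacer_len = lengths,
                      KEEP.OUT.ATTRS = FALSE)
  qs <- vapply(as.character(grid$spacer_len),
               function(L) unname(q_sp[L] %||% 0) %||% 0, numeric(1L))
  qs[is.na(qs)] <- 0
  mu <- vapply(seq_len(nrow(grid)), function(i) {
    transcription_rate(grid$sigma[i], grid$spacer_len[i],
                       promoter_energy_terms(k0 = k0, q_sp = qs[i]),
                       params, sc_energy = sc_energy(grid$sigma[i]))
  }, numeric(1L))
  act <- mu * exp(rnorm(nrow(grid), 0, noise_sd))
  data.frame(promoter_id = paste0("sp", grid$spacer_len),
             sigma = grid$sigma, spacer_len = grid$spacer_len,
             activity = act)
}

# First-order reporter response to a step change in promoter activity at the
# shock time: steady state a0 before, relaxing towards a1 with the reporter
# lifetime tau afterwards. tau = 0 gives the unbuffered step.
reporter_signal <- function(times, shock_time, a0, a1, tau) {
  post <- times > shock_time
  s <- rep(a0, length(times))
  if (tau <= 0) {
    s[post] <- a1
  } else {
    s[post] <- a0 + (a1 - a0) * (1 - exp(-(times[post] - shock_time) / tau))
  }
  s
}

#' Simulate plate-reader reporter time series under a superhelical shock
#'
#' Logistic growth plus a luciferase-like reporter whose per-cell signal
#' follows the promoter activity through a first-order filter with the
#' reporter lifetime (default 45 min), buffering rapid expression changes.
#' At the shock time the promoter activity of the treated arm switches by the
#' model fold-change for its spacer length; the vehicle arm sees no shift.
#' Luminescence is the filtered per-cell signal times the optical density
#' times multiplicative log-normal noise.
#'
#' @param spacer_lengths spacer lengths of the mutant panel.
#' @param cond a [shock_condition()] giving the pre-shock level and shift.
#' @param r_sc spacer-independent shock term, kBT.
#' @param shock_time shock time, minutes.
#' @param times sampling times, minutes (default every 5 min for 5 h).
#' @param reporter_lifetime reporter first-order lifetime, minutes
#'   (default 45; 0 disables buffering).
#' @param noise_sd log-scale multiplicative noise sd per sample.
#' @param n_replicates replicates per arm.
#' @param growth list with logistic parameters `od0`, `k` (carrying
#'   capacity), `r` (per-minute rate).
#' @param params a [twist_params()] object.
#' @param seed RNG seed; mandatory when `noise_sd > 0`.
#' @return long data frame with columns `time_min`, `od`, `lum`,
#'   `promoter_id`, `spacer_len`, `treatment` (`"shock"`/`"vehicle"`),
#'   `replicate`, `shock_time_min`.
#' @export
simulate_reporter <- function(spacer_lengths = c(15, 17, 19),
                              cond = shock_condition(-0.06, 0.005),
                              r_sc = 0, shock_time = 120,
                              times = seq(0, 300, by = 5),
                              reporter_lifetime = 45, noise_sd = 0,
                              n_replicates = 3,
                              growth = list(od0 = 0.05, k = 1.5, r = 0.03),
                              params = twist_params(), seed = NULL) {
  if (!inherits(cond, "shock_condition")) {
    stop_invalid("`cond` must be a `shock_condition` object")
  }
  assert_number(noise_sd, "noise_sd", lower = 0)
  assert_number(reporter_lifetime, "reporter_lifetime", lower = 0)
  if (shock_time < min(times) || shock_time > max(times)) {
    stop_invalid("`shock_time` must lie within the time range")
  }
  if (noise_sd > 0 && is.null(seed)) {
    stop_invalid("`seed` is mandatory for a stochastic simulation")
  }
  if (!is.null(seed)) set.seed(seed)
  od <- growth$k / (1 + ((growth$k - growth$od0) / growth$od0) *
                      exp(-growth$r * times))
  terms_of <- function(n) promoter_energy_terms(r_sc = r_sc)
  out <- list()
  for (n in spacer_lengths) {
    a0 <- transcription_rate(cond$sigma0, n, params = params)
    fc <- exp(logfc_under_shock(cond, n, terms_of(n), params))
    for (arm in c("shock", "vehicle")) {
      a1 <- if (arm == "shock") a0 * fc else a0
      sig <- reporter_signal(times, shock_time, a0, a1, reporter_lifetime)
      for (rep_i in seq_len(n_replicates)) {
        lum <- sig * od * 1e4 * exp(rnorm(length(times), 0, noise_sd))
        out[[length(out) + 1L]] <- data.frame(
          time_min = times, od = od, lum = lum,
          promoter_id = paste0("pheP_sp", n), spacer_len = n,
          treatment = arm, replicate = rep_i, shock_time_min = shock_time)
      }
    }
  }
  do.call(rbind, out)
}

#' Specification of a synthetic genome-wide promoter cohort
#'
#' Defaults emulate the structure of the genome-wide analyses: spacer lengths
#' 15-19 peaked at 17 nt (27% of promoters), a pre-shock level of -0.06, a
#' relaxation of magnitude 0.03, promoter-to-promoter spread of the
#' spacer-independent shock term, and replicate-level measurement noise. The
#' spacer-length distribution is a stand-in consistent with the 17-nt mode,
#' not a curated-database claim.
#'
#' @param n_promoters cohort size (default 300).
#' @param spacer_probs named probabilities over spacer lengths 15-19
#'   (must sum to 1).
#' @param sigma0 pre-shock superhelical density.
#' @param delta_sigma superhelical shift (positive = relaxation).
#' @param r_sc_mean,r_sc_sd mean and promoter-to-promoter sd of the
#'   spacer-independent shock term (kBT). The term is a response to the
#'   shift, so it is identically 0 when `delta_sigma = 0`.
#' @param replicate_noise_sd per-replicate log-scale measurement noise sd.
#' @param n_replicates replicates per promoter (>= 2).
#' @param gc_discriminator baseline discriminator G+C probability.
#' @param gc_shift_16 additive G+C shift for 16-nt-spacer discriminators.
#' @param discriminator_len discriminator length, nucleotides.
#' @param seed RNG seed (mandatory).
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_promoters = 300,
                        spacer_probs = c(`15` = 0.14, `16` = 0.14,
                                         `17` = 0.27, `18` = 0.25,
                                         `19` = 0.20),
                        sigma0 = -0.06, delta_sigma = 0.03,
                        r_sc_mean = 0, r_sc_sd = 0.5,
                        replicate_noise_sd = 0.2, n_replicates = 3,
                        gc_discriminator = 0.5, gc_shift_16 = 0,
                        discriminator_len = 7, seed) {
  if (missing(seed) || is.null(seed)) {
    stop_invalid("`seed` is mandatory for a stochastic simulation")
  }
  assert_number(n_promoters, "n_promoters", lower = 2)
  if (is.null(names(spacer_probs)) || abs(sum(spacer_probs) - 1) > 1e-8 ||
      any(spacer_probs < 0)) {
    stop_invalid("`spacer_probs` must be named non-negative probabilities summing to 1")
  }
  assert_number(r_sc_sd, "r_sc_sd", lower = 0)
  assert_number(replicate_noise_sd, "replicate_noise_sd", lower = 0)
  assert_number(n_replicates, "n_replicates", lower = 2)
  assert_number(gc_discriminator, "gc_discriminator", lower = 0, upper = 1)
  assert_number(gc_discriminator + gc_shift_16, "gc_discriminator + gc_shift_16",
                lower = 0, upper = 1)
  structure(
    list(n_promoters = as.integer(n_promoters), spacer_probs = spacer_probs,
         sigma0 = sigma0, delta_sigma = delta_sigma, r_sc_mean = r_sc_mean,
         r_sc_sd = r_sc_sd, replicate_noise_sd = replicate_noise_sd,
         n_replicates = as.integer(n_replicates),
         gc_discriminator = gc_discriminator, gc_shift_16 = gc_shift_16,
         discriminator_len = as.integer(discriminator_len),
         seed = as.integer(seed)),
    class = "cohort_spec")
}

#' Simulate a genome-wide promoter cohort and its shock response
#'
#' Draws a promoter map (ids, strands, hexamer coordinates and sequences,
#' spacer and discriminator sequences) plus a matched differential-response
#' table. Each promoter's true log fold-change is
#' `-R_sc_i - (DG_or(sigma0 + dsigma, n_i) - DG_or(sigma0, n_i))` with a
#' promoter-specific `R_sc_i`; observed log fold-changes are replicate means,
#' and p-values come from per-promoter t-tests of the replicates against
#' zero, Benjamini-Hochberg adjusted, so the classification threshold has the
#' same semantics as in the analysis pipeline.
#'
#' @param spec a [cohort_spec()].
#' @param params a [twist_params()] object.
#' @return list with `promoters` (promoter-map dialect data frame),
#'   `responses` (`promoter_id`, `logfc`, `padj`) and `truth`
#'   (`promoter_id`, `spacer_len`, `r_sc`, `true_logfc`).
#' @export
simulate_genome_cohort <- function(spec, params = twist_params()) {
  if (!inherits(spec, "cohort_spec")) {
    stop_invalid("`spec` must be a `cohort_spec` object")
  }
  set.seed(spec$seed)
  np <- spec$n_promoters
  lens <- as.numeric(sample(names(spec$spacer_probs), np, replace = TRUE,
                            prob = spec$spacer_probs))
  r_sc <- if (spec$delta_sigma == 0) rep(0, np) else
    rnorm(np, spec$r_sc_mean, spec$r_sc_sd)
  ddg <- orientational_energy(spec$sigma0 + spec$delta_sigma, lens, params) -
    orientational_energy(spec$sigma0, lens, params)
  true_lfc <- -r_sc - ddg

  m <- spec$n_replicates
  reps <- matrix(rnorm(np * m, mean = true_lfc, sd = spec$replicate_noise_sd),
                 nrow = np)
  obs <- rowMeans(reps)
  s <- sqrt(rowSums((reps - obs)^2) / (m - 1L))
  tstat <- obs / (s / sqrt(m))
  p <- 2 * pt(-abs(tstat), df = m - 1L)
  p[s == 0] <- ifelse(obs[s == 0] == 0, 1, 0)
  padj <- p.adjust(p, method = "BH")

  ids <- sprintf("P%04d", seq_len(np))
  strand <- sample(c("+", "-"), np, replace = TRUE)
  anchor <- 200L * seq_len(np)
  gc <- ifelse(lens == 16, spec$gc_discriminator + spec$gc_shift_16,
               spec$gc_discriminator)
  dlen <- spec$discriminator_len
  m35_seq <- vapply(seq_len(np), function(i) random_dna(6), character(1L))
  m10_seq <- vapply(seq_len(np), function(i) random_dna(6), character(1L))
  spacer_seq <- vapply(lens, random_dna, character(1L))
  disc_seq <- vapply(gc, function(g) random_dna(dlen, g), character(1L))

  plus <- strand == "+"
  m35_start <- m10_start <- integer(np)
  m35_start[plus] <- anchor[plus]
  m35_end <- m35_start + 5L
  m10_start[plus] <- m35_end[plus] + lens[plus] + 1L
  tss <- integer(np)
  # minus strand: mirror layout, tss at the low-coordinate end
  tss[!plus] <- anchor[!plus]
  m10_start[!plus] <- tss[!plus] + dlen + 1L
  m10_end <- m10_start + 5L
  m35_start[!plus] <- m10_end[!plus] + lens[!plus] + 1L
  m35_end <- m35_start + 5L
  tss[plus] <- m10_end[plus] + dlen + 1L

  promoters <- data.frame(
    promoter_id = ids, sigma_factor = "sigma70", tss = tss, strand = strand,
    m35_start = m35_start, m35_end = m35_end, m35_seq = m35_seq,
    m10_start = m10_start, m10_end = m10_end, m10_seq = m10_seq,
    spacer_len = lens, spacer_seq = spacer_seq,
    discriminator_seq = disc_seq, stringsAsFactors = FALSE)
  responses <- data.frame(promoter_id = ids, logfc = obs, padj = padj,
                          stringsAsFactors = FALSE)
  truth <- data.frame(promoter_id = ids, spacer_len = lens, r_sc = r_sc,
                      true_logfc = true_lfc, stringsAsFactors = FALSE)
  list(promoters = promoters, responses = responses, truth = truth)
}
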