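DINUC_STEPS <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                               paste0))

#' Dinucleotide twist table
#'
#' Per-dinucleotide intrinsic twist angles and torsional stiffnesses used by
#' the sequence-dependent extension of the orientational-energy model. All 16
#' steps over \{A,C,G,T\}^2 must be present.
#'
#' @param twist_deg named numeric vector of intrinsic twist angles in degrees,
#'   one per dinucleotide step (names like `"AA"`, `"AC"`, ...).
#' @param stiffness named numeric vector of torsional stiffnesses in
#'   kBT/rad^2 per step, same names.
#' @return an object of class `twist_table`: a data frame with columns
#'   `step`, `alpha` (radians) and `k`, one row per step.
#' @seealso [uniform_twist_table()], [default_twist_table()],
#'   [read_twist_table()]
#' @export
twist_table <- function(twist_deg, stiffness) {
  if (is.null(names(twist_deg)) || is.null(names(stiffness))) {
    stop_invalid("`twist_deg` and `stiffness` must be named by dinucleotide step")
  }
  stiffness <- stiffness[names(twist_deg)]
  if (!setequal(names(twist_deg), DINUC_STEPS) ||
      length(twist_deg) != 16L || anyNA(stiffness)) {
    stop_invalid("twist table must cover exactly the 16 dinucleotide steps")
  }
  if (any(!is.finite(twist_deg)) || any(twist_deg <= 0) ||
      any(!is.finite(stiffness)) || any(stiffness <= 0)) {
    stop_invalid("all twist angles and stiffnesses must be finite and > 0")
  }
  ord <- match(DINUC_STEPS, names(twist_deg))
  out <- data.frame(step = DINUC_STEPS,
                    alpha = deg2rad(unname(twist_deg[ord])),
                    k = unname(stiffness[ord]),
                    stringsAsFactors = FALSE)
  rownames(out) <- out$step
  class(out) <- c("twist_table", "data.frame")
  out
}

#' @describeIn twist_table table with every step set to the sequence-averaged
#'   constants of `params` (`alpha0`, `k_theta`); under it the sequence model
#'   reduces exactly to the homogeneous one.
#' @param params a [twist_params()] object.
#' @export
uniform_twist_table <- function(params = twist_params()) {
  twist_table(setNames(rep(rad2deg(params$alpha0), 16L), DINUC_STEPS),
              setNames(rep(params$k_theta, 16L), DINUC_STEPS))
}

#' @describeIn twist_table read a table from a TSV file with columns `step`,
#'   `twist_deg`, `stiffness`.
#' @param file path to a TSV file.
#' @export
read_twist_table <- function(file) {
  df <- read.delim(file, stringsAsFactors = FALSE)
  need <- c("step", "twist_deg", "stiffness")
  if (!all(need %in% names(df))) {
    stop_format("twist table file must have columns %s",
                paste(need, collapse = ", "))
  }
  twist_table(setNames(df$twist_deg, df$step), setNames(df$stiffness, df$step))
}

#' @describeIn twist_table the synthetic illustrative table shipped with the
#'   package (`inst/extdata/dinucleotide_twist_synthetic.tsv`). Its values are
#'   a constructed stand-in with realistic qualitative structure
#'   (complement-symmetric, mean twist 34 deg, about twofold stiffness
#'   variability), not measured crystallographic parameters.
#' @export
default_twist_table <- function() {
  read_twist_table(system.file("extdata", "dinucleotide_twist_synthetic.tsv",
                               package = "twistspacer", mustWork = TRUE))
}

#' Read spacer sequences from a FASTA file
#'
#' Sequence names are expected to match `promoter_id`s of a promoter map.
#' Requires the optional Biostrings package.
#'
#' @param file path to an (uncompressed) FASTA file.
#' @return named character vector of upper-case spacer sequences.
#' @export
read_spacer_fasta <- function(file) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop_invalid("reading FASTA spacer sequences requires the Biostrings package")
  }
  seqs <- Biostrings::readDNAStringSet(file)
  setNames(toupper(as.character(seqs)), names(seqs))
}

# Split a spacer (plus optional single-base flanks) into consecutive
# dinucleotide steps. n-nt spacers contribute n-1 steps unless flanks are
# supplied, in which case the two boundary steps into the hexamers are added.
spacer_steps <- function(seq, flank5 = NULL, flank3 = NULL) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    ts_stop("twistspacer_invalid_sequence", "`seq` must be a single string")
  }
  full <- paste0(flank5 %||% "", seq, flank3 %||% "")
  chars <- strsplit(toupper(full), "")[[1]]
  if (length(chars) < 2L) {
    ts_stop("twistspacer_invalid_sequence",
            "need at least 2 nucleotides for a step-wise computation")
  }
  if (!all(chars %in% c("A", "C", "G", "T"))) {
    ts_stop("twistspacer_invalid_sequence",
            "sequence contains characters outside ACGT (ambiguity codes are rejected)")
  }
  paste0(chars[-length(chars)], chars[-1L])
}

#' Total intrinsic twist of a spacer sequence
#'
#' Sum of the table's intrinsic twist angles over the consecutive dinucleotide
#' steps of the spacer. For a uniform table over `m` steps this equals
#' `m * alpha0`.
#'
#' @param seq spacer sequence, upper-case ACGT string.
#' @param table a [twist_table()].
#' @param flank5,flank3 optional flanking bases (last base of the -35 hexamer,
#'   first base of the -10 hexamer) to include the boundary steps.
#' @return total intrinsic twist in radians.
#' @export
sequence_mean_twist <- function(seq, table, flank5 = NULL, flank3 = NULL) {
  if (!inherits(table, "twist_table")) {
    stop_invalid("`table` must be a `twist_table` object")
  }
  sum(table[spacer_steps(seq, flank5, flank3), "alpha"])
}

#' Effective torsional stiffness of a spacer sequence
#'
#' Series-spring combination of the per-step stiffnesses,
#' `1 / sum(1/k_i)`: the stiffness governing the total-angle deformation when
#' each step relaxes to its elastic equilibrium under the RNAP constraint.
#' For a uniform table over `m` steps this is `k_theta / m`.
#'
#' @inheritParams sequence_mean_twist
#' @return stiffness in kBT/rad^2.
#' @export
effective_stiffness <- function(seq, table, flank5 = NULL, flank3 = NULL) {
  if (!inherits(table, "twist_table")) {
    stop_invalid("`table` must be a `twist_table` object")
  }
  1 / sum(1 / table[spacer_steps(seq, flank5, flank3), "k"])
}

#' Sequence-dependent orientational energy
#'
#' Generalises the homogeneous orientational energy to heterogeneous DNA: each
#' step is a torsional spring with its own intrinsic twist `alpha_i` and
#' stiffness `k_i`, and RNAP imposes the total angle `theta_P`. Minimising the
#' per-step elastic energy under that constraint gives the closed form
#' `(k_eff / 2) * (theta_P - A * (1 + sigma))^2`, with
#' `A = sum(alpha_i)` ([sequence_mean_twist()]) and
#' `k_eff = 1/sum(1/k_i)` ([effective_stiffness()]).
#' With a uniform table it reduces exactly to [orientational_energy()] at the
#' step count of the sequence.
#'
#' @inheritParams sequence_mean_twist
#' @param sigma superhelical density (vectorised).
#' @param theta_P RNAP-imposed total spacer twist angle, radians.
#' @return energy in kBT.
#' @export
sequence_orientational_energy <- function(seq, sigma,
                                          theta_P = twist_params()$theta_P,
                                          table = default_twist_table(),
                                          flank5 = NULL, flank3 = NULL) {
  check_sigma(sigma)
  assert_number(theta_P, "theta_P", lower = .Machine$double.xmin)
  a <- sequence_mean_twist(seq, table, flank5, flank3)
  k_eff <- effective_stiffness(seq, table, flank5, flank3)
  (k_eff / 2) * (theta_P - a * (1 + sigma))^2
}

# Ablated copies of a table: impose the table-averaged value on one parameter.
ablate_table <- function(table, mode) {
  mean_deg <- rad2deg(mean(table$alpha))
  mean_k <- mean(table$k)
  switch(mode,
    full = table,
    average_alpha = twist_table(setNames(rep(mean_deg, 16L), table$step),
                                setNames(table$k, table$step)),
    average_k = twist_table(setNames(rad2deg(table$alpha), table$step),
                            setNames(rep(mean_k, 16L), table$step)),
    stop_invalid("`mode` must be one of 'full', 'average_alpha', 'average_k'")
  )
}

#' Span of sequence-dependent energy adjustments over a promoter panel
#'
#' For each spacer sequence, the difference between the sequence-dependent
#' orientational energy and the uniform-model energy computed with the
#' table-averaged parameters (same step count). Two ablations isolate which
#' kind of heterogeneity matters: `average_alpha` imposes the
#' table-averaged intrinsic twist (leaving only stiffness heterogeneity) and
#' `average_k` the table-averaged stiffness (leaving only structural twist
#' heterogeneity). Applying both ablations removes all sequence dependence and
#' every adjustment is exactly zero.
#'
#' @param seqs character vector (or list) of spacer sequences.
#' @param sigma superhelical density.
#' @param theta_P RNAP-imposed total angle, radians.
#' @param table a [twist_table()].
#' @param mode `"full"` (default), `"average_alpha"` or `"average_k"`.
#' @return list with `adjustment` (named numeric, kBT per sequence) and
#'   `span` (max - min).
#' @export
sequence_adjustment_span <- function(seqs, sigma,
                                     theta_P = twist_params()$theta_P,
                                     table = default_twist_table(),
                                     mode = c("full", "average_alpha", "average_k")) {
  mode <- match.arg(mode)
  seqs <- as.character(unlist(seqs))
  if (length(seqs) == 0L) {
    stop_invalid("`seqs` must contain at least one spacer sequence")
  }
  used <- ablate_table(table, mode)
  unif <- ablate_table(ablate_table(table, "average_alpha"), "average_k")
  adj <- vapply(seqs, function(s) {
    sequence_orientational_energy(s, sigma, theta_P, used) -
      sequence_orientational_energy(s, sigma, theta_P, unif)
  }, numeric(1L))
  list(adjustment = adj, span = max(adj) - min(adj))
}
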