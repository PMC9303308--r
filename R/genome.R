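#' Read and validate a promoter map
#'
#' Reads an EcoCyc-style tabular promoter map (TSV). Required columns:
#' `promoter_id`, `sigma_factor`; coordinates/sequences are optional but
#' validated when present (`strand`, `m35_start`, `m35_end`, `m35_seq`,
#' `m10_start`, `m10_end`, `m10_seq`, `spacer_len`, `tss`,
#' `discriminator_seq`, `spacer_seq`).
#'
#' Validation rules: hexamer sequences must be 6 nt; `strand` must be `+` or
#' `-`; the spacer length is the gap between the two hexamers (1-based
#' inclusive coordinates, strand-symmetric: downstream-interval start minus
#' upstream-interval end minus 1). An explicit `spacer_len` column takes
#' precedence over the recomputed gap, with a consistency warning on
#' mismatch. Rows failing validation are dropped and counted; duplicated
#' `promoter_id`s keep the first occurrence.
#'
#' @param file path to a TSV file, or a data frame in the same dialect.
#' @return data frame of validated promoter records, with attribute
#'   `dropped` (named integer vector of drop reasons).
#' @export
read_promoter_map <- function(file) {
  df <- if (is.data.frame(file)) file else read.delim(file, stringsAsFactors = FALSE)
  need <- c("promoter_id", "sigma_factor")
  if (!all(need %in% names(df))) {
    stop_format("promoter map must have columns %s", paste(need, collapse = ", "))
  }
  drops <- c(bad_strand = 0L, bad_hexamer = 0L, no_spacer = 0L, duplicate = 0L)
  keep <- rep(TRUE, nrow(df))

  if ("strand" %in% names(df)) {
    bad <- !(df$strand %in% c("+", "-"))
    drops["bad_strand"] <- sum(bad & keep)
    keep <- keep & !bad
  }
  for (col in c("m35_seq", "m10_seq")) {
    if (col %in% names(df)) {
      has <- !is.na(df[[col]]) & df[[col]] != ""
      bad <- has & nchar(df[[col]]) != 6L
      drops["bad_hexamer"] <- drops["bad_hexamer"] + sum(bad & keep)
      keep <- keep & !bad
    }
  }

  coord_cols <- c("m35_start", "m35_end", "m10_start", "m10_end")
  has_coords <- all(coord_cols %in% names(df))
  gap <- rep(NA_real_, nrow(df))
  if (has_coords) {
    ok <- complete.cases(df[coord_cols])
    a_s <- df$m35_start; a_e <- df$m35_end; b_s <- df$m10_start; b_e <- df$m10_end
    gap[ok] <- ifelse(b_s[ok] > a_e[ok],
                      b_s[ok] - a_e[ok] - 1,   # -10 downstream in genome coords
                      a_s[ok] - b_e[ok] - 1)   # mirrored (minus strand)
  }
  if ("spacer_len" %in% names(df)) {
    have_len <- !is.na(df$spacer_len)
    mismatch <- have_len & !is.na(gap) & df$spacer_len != gap
    if (any(mismatch & keep)) {
      warning(sum(mismatch & keep),
              " promoter(s) with spacer_len inconsistent with hexamer ",
              "coordinates; keeping the curated spacer_len column",
              call. = FALSE)
    }
    df$spacer_len[!have_len] <- gap[!have_len]
  } else {
    df$spacer_len <- gap
  }
  no_len <- is.na(df$spacer_len) | df$spacer_len < 0
  drops["no_spacer"] <- sum(no_len & keep)
  keep <- keep & !no_len

  out <- df[keep, , drop = FALSE]
  dup <- duplicated(out$promoter_id)
  drops["duplicate"] <- sum(dup)
  out <- out[!dup, , drop = FALSE]
  rownames(out) <- NULL
  if (sum(drops) > 0L) {
    message("read_promoter_map: dropped ", sum(drops), " row(s) [",
            paste(names(drops)[drops > 0], drops[drops > 0],
                  sep = "=", collapse = ", "), "]")
  }
  attr(out, "dropped") <- drops
  out
}

#' Read a differential-response table
#'
#' TSV with columns `promoter_id`, `logfc`, `padj` (adjusted p-values in
#' `[0, 1]`).
#'
#' @param file path to a TSV file.
#' @return data frame of response records.
#' @export
read_response_table <- function(file) {
  df <- read.delim(file, stringsAsFactors = FALSE)
  need <- c("promoter_id", "logfc", "padj")
  if (!all(need %in% names(df))) {
    stop_format("response table must have columns %s", paste(need, collapse = ", "))
  }
  if (any(df$padj < 0 | df$padj > 1, na.rm = TRUE)) {
    stop_invalid("`padj` values must lie in [0, 1]")
  }
  df
}

#' Classify promoter responses
#'
#' `activated` if `padj < alpha` and `logfc > 0`; `repressed` if
#' `padj < alpha` and `logfc < 0`; otherwise `none`. The default threshold is
#' 0.05; a relaxed 0.1 is conventional for lower-powered datasets such as
#' evolved-strain transcriptomes.
#'
#' @param logfc log fold-changes (any base; only the sign is used).
#' @param padj adjusted p-values in `[0, 1]`.
#' @param alpha significance threshold.
#' @return factor with levels `activated`, `none`, `repressed`.
#' @export
classify_response <- function(logfc, padj, alpha = 0.05) {
  assert_number(alpha, "alpha", lower = 1e-12, upper = 1)
  if (!is.numeric(padj) || any(!is.finite(padj)) ||
      any(padj < 0) || any(padj > 1)) {
    stop_invalid("`padj` must be numeric in [0, 1]")
  }
  if (!is.numeric(logfc) || length(logfc) != length(padj)) {
    stop_invalid("`logfc` must be numeric and match `padj` in length")
  }
  cls <- ifelse(padj < alpha & logfc > 0, "activated",
                ifelse(padj < alpha & logfc < 0, "repressed", "none"))
  factor(cls, levels = c("activated", "none", "repressed"))
}

#' Filter a promoter map for analysis
#'
#' Retains promoters of one sigma factor within a spacer-length range,
#' optionally excluding 16-nt spacers (which empirically do not follow the
#' orientational model and are left out of the statistical comparisons, while
#' remaining available for the discriminator analysis).
#'
#' @param records promoter data frame (see [read_promoter_map()]).
#' @param sigma_factor sigma factor to retain (default `"sigma70"`); `NULL`
#'   retains all.
#' @param length_range inclusive spacer-length range (default `c(15, 19)`).
#' @param exclude_16 drop 16-nt spacers (default `TRUE`).
#' @return filtered data frame with attribute `removed` (counts per
#'   criterion).
#' @export
filter_promoters <- function(records, sigma_factor = "sigma70",
                             length_range = c(15, 19), exclude_16 = TRUE) {
  if (!is.data.frame(records) || !("spacer_len" %in% names(records))) {
    stop_format("`records` must be a data frame with a `spacer_len` column")
  }
  removed <- c(sigma_factor = 0L, length_range = 0L, spacer16 = 0L)
  keep <- rep(TRUE, nrow(records))
  if (!is.null(sigma_factor)) {
    bad <- records$sigma_factor != sigma_factor
    removed["sigma_factor"] <- sum(bad & keep)
    keep <- keep & !bad
  }
  bad <- records$spacer_len < length_range[1L] | records$spacer_len > length_range[2L]
  removed["length_range"] <- sum(bad & keep)
  keep <- keep & !bad
  if (exclude_16) {
    bad <- records$spacer_len == 16
    removed["spacer16"] <- sum(bad & keep)
    keep <- keep & !bad
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- removed
  out
}

group_ci <- function(x, conf_level = 0.95) {
  m <- length(x)
  mu <- mean(x)
  if (m < 2L) return(c(mean = mu, lower = NA_real_, upper = NA_real_, n = m))
  half <- qt(1 - (1 - conf_level) / 2, df = m - 1L) * sd(x) / sqrt(m)
  c(mean = mu, lower = mu - half, upper = mu + half, n = m)
}

#' Compare mean spacer lengths of activated and repressed promoters
#'
#' Joins a promoter map with a response table, classifies each promoter and
#' compares the mean spacer lengths of the activated and repressed classes
#' with a two-sample t-test. Both the Welch and the pooled-variance
#' ("Student's") variants are computed; `variant` selects which drives the
#' headline p-value.
#'
#' @param promoters promoter data frame (`promoter_id`, `spacer_len`).
#' @param responses response data frame (`promoter_id`, `logfc`, `padj`).
#' @param alpha classification threshold.
#' @param variant `"welch"` (default) or `"pooled"`.
#' @param conf_level confidence level for the group means.
#' @return list with `group_stats` (mean, 95% CI, n per class), `p_value`,
#'   `estimate` (mean difference activated - repressed), `t_welch`,
#'   `t_pooled`.
#' @export
spacer_mean_comparison <- function(promoters, responses, alpha = 0.05,
                                   variant = c("welch", "pooled"),
                                   conf_level = 0.95) {
  variant <- match.arg(variant)
  dat <- merge(promoters[, c("promoter_id", "spacer_len")], responses,
               by = "promoter_id")
  if (nrow(dat) == 0L) stop_insufficient_data("no promoter has a response record")
  dat$class <- classify_response(dat$logfc, dat$padj, alpha)
  for (g in c("activated", "repressed")) {
    if (sum(dat$class == g) < 2L) {
      stop_insufficient_data("fewer than 2 promoters in the '%s' group", g)
    }
  }
  stats <- t(vapply(levels(dat$class), function(g) {
    group_ci(dat$spacer_len[dat$class == g], conf_level)
  }, numeric(4L)))
  a <- dat$spacer_len[dat$class == "activated"]
  r <- dat$spacer_len[dat$class == "repressed"]
  welch <- t.test(a, r)
  pooled <- t.test(a, r, var.equal = TRUE)
  chosen <- if (variant == "welch") welch else pooled
  list(group_stats = data.frame(class = rownames(stats), stats,
                                row.names = NULL, check.names = FALSE),
       p_value = chosen$p.value, estimate = mean(a) - mean(r),
       variant = variant, t_welch = welch, t_pooled = pooled,
       classes = dat$class)
}

#' Proportion of activated promoters versus spacer length
#'
#' Among promoters responsive to the shift (`padj < alpha`, either sign), the
#' per-length proportion that is activated, with exact binomial 95%
#' confidence intervals, and an ordinary least-squares regression of the
#' proportion on spacer length (unweighted by default; `weighted = TRUE`
#' weights by group size).
#'
#' @inheritParams spacer_mean_comparison
#' @param weighted weight the regression by per-length responsive counts.
#' @param conf_level confidence level for the binomial CIs.
#' @return list with `proportions` (per-length data frame), `slope`,
#'   `p_value`, `fit` (the `lm` object).
#' @export
activation_proportion_regression <- function(promoters, responses,
                                             alpha = 0.05, weighted = FALSE,
                                             conf_level = 0.95) {
  dat <- merge(promoters[, c("promoter_id", "spacer_len")], responses,
               by = "promoter_id")
  dat$class <- classify_response(dat$logfc, dat$padj, alpha)
  resp <- dat[dat$class != "none", , drop = FALSE]
  lens <- sort(unique(resp$spacer_len))
  if (length(lens) < 2L) {
    stop_insufficient_data(
      "need responsive promoters at >= 2 distinct spacer lengths (got %d)",
      length(lens))
  }
  tab <- do.call(rbind, lapply(lens, function(L) {
    sub <- resp[resp$spacer_len == L, , drop = FALSE]
    k <- sum(sub$class == "activated")
    m <- nrow(sub)
    ci <- binom.test(k, m, conf.level = conf_level)$conf.int
    data.frame(spacer_len = L, n_responsive = m, n_activated = k,
               proportion = k / m, ci_lower = ci[1L], ci_upper = ci[2L])
  }))
  fit <- if (weighted) {
    lm(proportion ~ spacer_len, data = tab, weights = tab$n_responsive)
  } else {
    lm(proportion ~ spacer_len, data = tab)
  }
  # summary() warns on zero-residual fits; the p-value is reported as NA there
  sm <- suppressWarnings(summary(fit))$coefficients
  slope <- unname(coef(fit)["spacer_len"])
  p <- if ("spacer_len" %in% rownames(sm) && nrow(tab) > 2L &&
           is.finite(sm["spacer_len", "Std. Error"]) &&
           sm["spacer_len", "Std. Error"] > 0) {
    sm["spacer_len", "Pr(>|t|)"]
  } else NA_real_
  list(proportions = tab, slope = slope, p_value = p, fit = fit)
}

#' GC fraction of sequences
#'
#' @param seq character vector of ACGT sequences.
#' @return numeric vector of G+C fractions.
#' @export
gc_fraction <- function(seq) {
  vapply(strsplit(toupper(as.character(seq)), ""), function(ch) {
    if (length(ch) == 0L) return(NA_real_)
    mean(ch %in% c("G", "C"))
  }, numeric(1L))
}

#' Discriminator G/C content of 16-nt-spacer promoters versus the rest
#'
#' Compares the GC fraction of the discriminator (sequence between the 3' end
#' of the -10 hexamer and the TSS, both exclusive) between promoters with a
#' given spacer length (default 16 nt) and all other promoters, with a
#' two-sample t-test.
#'
#' @param promoters promoter data frame with `spacer_len` and
#'   `discriminator_seq` columns.
#' @param group_length spacer length defining the focal group (default 16).
#' @param variant `"welch"` (default) or `"pooled"`.
#' @return list with `mean_group`, `mean_other`, `difference`, `p_value`,
#'   `n_group`, `n_other`, `t_welch`, `t_pooled`.
#' @export
discriminator_gc_comparison <- function(promoters, group_length = 16,
                                        variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  if (!all(c("spacer_len", "discriminator_seq") %in% names(promoters))) {
    stop_format("`promoters` must have spacer_len and discriminator_seq columns")
  }
  ok <- !is.na(promoters$discriminator_seq) & promoters$discriminator_seq != ""
  gc <- gc_fraction(promoters$discriminator_seq[ok])
  grp <- promoters$spacer_len[ok] == group_length
  if (sum(grp) < 2L || sum(!grp) < 2L) {
    stop_insufficient_data(
      "need >= 2 promoters with discriminator sequences in each group")
  }
  diff <- mean(gc[grp]) - mean(gc[!grp])
  if (sd(gc[grp]) == 0 && sd(gc[!grp]) == 0) {
    # degenerate constant groups: separation is certain (or absent)
    welch <- pooled <- NULL
    p <- if (diff == 0) 1 else 0
  } else {
    welch <- t.test(gc[grp], gc[!grp])
    pooled <- t.test(gc[grp], gc[!grp], var.equal = TRUE)
    p <- if (variant == "welch") welch$p.value else pooled$p.value
  }
  list(mean_group = mean(gc[grp]), mean_other = mean(gc[!grp]),
       difference = diff,
       p_value = p, n_group = sum(grp), n_other = sum(!grp),
       variant = variant, t_welch = welch, t_pooled = pooled)
}

#' Genome-scale spacer-response report
#'
#' Runs the full genome pipeline: promoter filtering, response
#' classification, mean-spacer comparison, activation-proportion regression
#' and (when discriminator sequences are present) the 16-nt discriminator
#' G/C comparison.
#'
#' @param promoters promoter data frame (see [read_promoter_map()]).
#' @param responses response data frame (see [read_response_table()]).
#' @param alpha classification threshold.
#' @param exclude_16 exclude 16-nt spacers from the statistical comparisons.
#' @param sigma_factor sigma factor to retain (`NULL` keeps all).
#' @return list of results; components that cannot be computed carry the
#'   error message instead.
#' @export
genome_report <- function(promoters, responses, alpha = 0.05,
                          exclude_16 = TRUE, sigma_factor = "sigma70") {
  filtered <- filter_promoters(promoters, sigma_factor = sigma_factor,
                               exclude_16 = exclude_16)
  try_part <- function(expr) {
    tryCatch(expr, twistspacer_error = function(e) conditionMessage(e))
  }
  merged <- merge(filtered[, c("promoter_id", "spacer_len")], responses,
                  by = "promoter_id")
  cls <- classify_response(merged$logfc, merged$padj, alpha)
  disc <- if ("discriminator_seq" %in% names(promoters)) {
    try_part(discriminator_gc_comparison(
      filter_promoters(promoters, sigma_factor = sigma_factor,
                       exclude_16 = FALSE)))
  } else NULL
  list(
    n_promoters = nrow(filtered),
    removed = attr(filtered, "removed"),
    class_counts = table(cls),
    spacer_means = try_part(spacer_mean_comparison(filtered, responses, alpha)),
    proportion_regression =
      try_part(activation_proportion_regression(filtered, responses, alpha)),
    discriminator = disc,
    alpha = alpha
  )
}
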