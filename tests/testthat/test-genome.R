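make_map_fixture <- function() {
  # plus-strand promoter, its minus-strand mirror, and a third with a curated
  # spacer_len only
  data.frame(
    promoter_id = c("pA", "pB", "pC"),
    sigma_factor = c("sigma70", "sigma70", "sigma38"),
    tss = c(140, 100, 260),
    strand = c("+", "-", "+"),
    m35_start = c(100, 131, NA), m35_end = c(105, 136, NA),
    m35_seq = c("TTGACA", "TGTCAA", ""),
    m10_start = c(123, 108, NA), m10_end = c(128, 113, NA),
    m10_seq = c("TATAAT", "ATTATA", "TATAAT"),
    spacer_len = c(NA, NA, 18),
    discriminator_seq = c("GCGCGCG", "ATATATA", "GCATGCA"),
    stringsAsFactors = FALSE)
}

test_that("promoter map parsing computes strand-symmetric spacer lengths", {
  suppressMessages(rec <- read_promoter_map(make_map_fixture()))
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$spacer_len, c(17, 17, 18))
  expect_equal(rec$spacer_len[rec$promoter_id == "pA"],
               rec$spacer_len[rec$promoter_id == "pB"])
})

test_that("invalid rows are dropped with counted reasons", {
  bad <- make_map_fixture()
  bad$m10_seq[1] <- "TATAA"        # 5-nt "hexamer"
  bad$strand[3] <- "x"
  bad <- rbind(bad, bad[2, ])      # duplicated promoter id
  suppressMessages(rec <- read_promoter_map(bad))
  drops <- attr(rec, "dropped")
  expect_equal(unname(drops["bad_hexamer"]), 1L)
  expect_equal(unname(drops["bad_strand"]), 1L)
  expect_equal(unname(drops["duplicate"]), 1L)
  expect_equal(rec$promoter_id, "pB")
  # curated spacer_len wins over inconsistent coordinates, with a warning
  inc <- make_map_fixture()
  inc$spacer_len[1] <- 12
  expect_warning(read_promoter_map(inc), "inconsistent")
  suppressWarnings(suppressMessages(rec2 <- read_promoter_map(inc)))
  expect_equal(rec2$spacer_len[rec2$promoter_id == "pA"], 12)
  expect_error(read_promoter_map(data.frame(x = 1)),
               class = "twistspacer_format_error")
})

test_that("response classification partitions promoters at the threshold", {
  expect_equal(as.character(classify_response(1.2, 0.01, 0.05)), "activated")
  expect_equal(as.character(classify_response(-0.8, 0.2, 0.05)), "none")
  expect_equal(as.character(classify_response(-0.8, 0.07, 0.1)), "repressed")
  cls <- classify_response(c(1, -1, 0.5, -2), c(0.01, 0.2, 0.04, 0.001), 0.05)
  expect_equal(sum(table(cls)), 4)
  expect_error(classify_response(1, 1.2), class = "twistspacer_invalid_argument")
  expect_error(classify_response(1, 0.5, alpha = 1.5),
               class = "twistspacer_invalid_argument")
})

test_that("promoter filtering applies the sigma70, length-range and 16-nt rules", {
  rec <- data.frame(promoter_id = sprintf("p%d", 1:8),
                    sigma_factor = c(rep("sigma70", 7), "sigma38"),
                    spacer_len = c(14:20, 17))
  f <- filter_promoters(rec)
  expect_equal(sort(f$spacer_len), c(15, 17, 18, 19))
  f16 <- filter_promoters(rec, exclude_16 = FALSE)
  expect_true(16 %in% f16$spacer_len)
  expect_equal(unname(attr(f, "removed")["sigma_factor"]), 1L)
  expect_equal(unname(attr(f, "removed")["length_range"]), 2L)
  expect_equal(unname(attr(f, "removed")["spacer16"]), 1L)
})

test_that("spacer mean comparison matches the textbook two-sample t-test", {
  promoters <- data.frame(promoter_id = sprintf("p%d", 1:6),
                          sigma_factor = "sigma70",
                          spacer_len = c(15, 15, 17, 18, 19, 19))
  responses <- data.frame(promoter_id = promoters$promoter_id,
                          logfc = c(1, 1, 1, -1, -1, -1),
                          padj = 0.001)
  res <- spacer_mean_comparison(promoters, responses, variant = "pooled")
  # hand computation: x = {15,15,17}, y = {18,19,19}
  x <- c(15, 15, 17); y <- c(18, 19, 19)
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / 4
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  p_hand <- 2 * pt(-abs(t_hand), df = 4)
  expect_equal(res$p_value, p_hand, tolerance = 1e-12)
  expect_equal(res$estimate, mean(x) - mean(y))
  expect_equal(res$group_stats$n[res$group_stats$class == "activated"], 3)
  # empty group is an error naming the group
  resp_none <- responses; resp_none$logfc <- abs(resp_none$logfc)
  expect_error(spacer_mean_comparison(promoters, resp_none),
               regexp = "repressed", class = "twistspacer_insufficient_data")
})

test_that("null cohorts give approximately uniform comparison p-values", {
  set.seed(31)
  pvals <- replicate(400, {
    d <- make_null_cohort(60)
    spacer_mean_comparison(d$promoters, d$responses)$p_value
  })
  # discrete spacer lengths can tie the statistic; the KS tie warning is benign
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.001)
  expect_gt(mean(pvals > 0.05), 0.90)
})

test_that("activation proportions and their regression behave on constructed fixtures", {
  promoters <- data.frame(promoter_id = sprintf("p%02d", 1:40),
                          sigma_factor = "sigma70",
                          spacer_len = rep(c(15, 17, 18, 19), each = 10))
  # proportions exactly linear in length: 0.9, 0.7, 0.6, 0.5
  k_act <- c(9, 7, 6, 5)
  logfc <- unlist(lapply(k_act, function(k) c(rep(1, k), rep(-1, 10 - k))))
  responses <- data.frame(promoter_id = promoters$promoter_id,
                          logfc = logfc, padj = 0.001)
  res <- activation_proportion_regression(promoters, responses)
  expect_equal(res$proportions$proportion, c(0.9, 0.7, 0.6, 0.5))
  expect_equal(res$slope, -0.1, tolerance = 1e-10)
  expect_true(all(res$proportions$ci_lower <= res$proportions$proportion &
                    res$proportions$proportion <= res$proportions$ci_upper))
  # all promoters activated: proportions 1 and slope 0
  resp_all <- responses; resp_all$logfc <- 1
  res_all <- activation_proportion_regression(promoters, resp_all)
  expect_true(all(res_all$proportions$proportion == 1))
  expect_equal(res_all$slope, 0)
  expect_error(
    activation_proportion_regression(promoters[promoters$spacer_len == 17, ],
                                     responses),
    class = "twistspacer_insufficient_data")
})

test_that("discriminator GC comparison separates constructed extremes", {
  promoters <- data.frame(
    promoter_id = sprintf("p%d", 1:8),
    sigma_factor = "sigma70",
    spacer_len = c(16, 16, 16, 17, 17, 18, 18, 19),
    discriminator_seq = c("GCGCGCG", "GGCCGGC", "GCGGCCG",
                          "ATATATA", "AATTAAT", "TTAATTA", "ATTAATA", "TATATAT"))
  res <- discriminator_gc_comparison(promoters)
  expect_equal(res$mean_group, 1)
  expect_equal(res$mean_other, 0)
  expect_lt(res$p_value, 1e-6)
  expect_error(discriminator_gc_comparison(promoters[3:8, ]),
               class = "twistspacer_insufficient_data")
  expect_equal(gc_fraction(c("GCGC", "ATAT", "GCAT")), c(1, 0, 0.5))
})

test_that("GC comparison has calibrated size and power on simulated cohorts", {
  set.seed(55)
  null_sig <- 0L
  power_hits <- 0L
  n_seeds <- 100L
  for (i in seq_len(n_seeds)) {
    # null: identical GC distributions
    pn <- data.frame(promoter_id = sprintf("p%d", 1:120),
                     spacer_len = rep(c(16, 17), times = c(30, 90)))
    pn$discriminator_seq <- vapply(rep(0.5, 120), function(g)
      paste(sample(c("G", "C", "A", "T"), 7, TRUE,
                   c(g / 2, g / 2, (1 - g) / 2, (1 - g) / 2)), collapse = ""),
      character(1))
    if (discriminator_gc_comparison(pn)$p_value < 0.05) null_sig <- null_sig + 1L
    # shifted: +0.15 GC for the 16-nt group, n = 50 vs 200
    ps <- data.frame(promoter_id = sprintf("q%d", 1:250),
                     spacer_len = rep(c(16, 17), times = c(50, 200)))
    gcs <- ifelse(ps$spacer_len == 16, 0.65, 0.5)
    ps$discriminator_seq <- vapply(gcs, function(g)
      paste(sample(c("G", "C", "A", "T"), 7, TRUE,
                   c(g / 2, g / 2, (1 - g) / 2, (1 - g) / 2)), collapse = ""),
      character(1))
    if (discriminator_gc_comparison(ps)$p_value < 0.001) power_hits <- power_hits + 1L
  }
  expect_gte((n_seeds - null_sig) / n_seeds, 0.93)
  expect_gte(power_hits / n_seeds, 0.90)
})

test_that("relaxation cohorts show shorter spacers among activated promoters", {
  p <- twist_params()
  hits_t <- 0L
  hits_slope <- 0L
  n_seeds <- 50L
  for (i in seq_len(n_seeds)) {
    cohort <- simulate_genome_cohort(cohort_spec(seed = 7000L + i), p)
    filt <- filter_promoters(cohort$promoters)
    cmp <- spacer_mean_comparison(filt, cohort$responses)
    if (cmp$estimate < 0 && cmp$p_value < 0.05) hits_t <- hits_t + 1L
    reg <- activation_proportion_regression(filt, cohort$responses)
    if (reg$slope < 0) hits_slope <- hits_slope + 1L
  }
  expect_gte(hits_t / n_seeds, 0.80)
  expect_gte(hits_slope / n_seeds, 0.90)
})

test_that("reversing the shift direction reverses the genome-scale signal", {
  p <- twist_params()
  cohort <- simulate_genome_cohort(
    cohort_spec(n_promoters = 400, delta_sigma = -0.03, seed = 1234), p)
  filt <- filter_promoters(cohort$promoters)
  cmp <- spacer_mean_comparison(filt, cohort$responses)
  expect_gt(cmp$estimate, 0)   # activated promoters now have longer spacers
  reg <- activation_proportion_regression(filt, cohort$responses)
  expect_gt(reg$slope, 0)
})

test_that("the genome report ties the pieces together", {
  p <- twist_params()
  cohort <- simulate_genome_cohort(cohort_spec(seed = 99), p)
  suppressMessages(
    rep_out <- genome_report(read_promoter_map(cohort$promoters),
                             cohort$responses))
  expect_true(is.list(rep_out$spacer_means))
  expect_true(is.list(rep_out$proportion_regression))
  expect_true(is.list(rep_out$discriminator))
  expect_equal(sum(rep_out$class_counts), rep_out$n_promoters)
})
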