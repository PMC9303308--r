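test_that("twist tables are validated and the uniform constructor reduces to the constants", {
  p <- twist_params()
  u <- uniform_twist_table(p)
  expect_s3_class(u, "twist_table")
  expect_equal(nrow(u), 16L)
  expect_true(all(abs(u$alpha - p$alpha0) < 1e-15))
  bad <- setNames(rep(34, 15), head(u$step, 15))
  expect_error(twist_table(bad, setNames(rep(70, 15), names(bad))),
               class = "twistspacer_invalid_argument")
  neg <- setNames(rep(34, 16), u$step); neg[1] <- -1
  expect_error(twist_table(neg, setNames(rep(70, 16), u$step)),
               class = "twistspacer_invalid_argument")
})

test_that("mean twist sums steps in order and rejects invalid sequences", {
  p <- twist_params()
  u <- uniform_twist_table(p)
  expect_equal(rad2deg(sequence_mean_twist(strrep("A", 18), u)), 17 * 34)
  # order dependence with asymmetric AT/TA values
  tw <- setNames(rep(34, 16), u$step)
  tw["AT"] <- 40; tw["TA"] <- 28
  tab <- twist_table(tw, setNames(rep(70, 16), u$step))
  expect_equal(rad2deg(sequence_mean_twist("ATAT", tab)), 40 + 28 + 40)
  expect_equal(rad2deg(sequence_mean_twist("TATA", tab)), 28 + 40 + 28)
  expect_error(sequence_mean_twist("A", u), class = "twistspacer_invalid_sequence")
  expect_error(sequence_mean_twist("", u), class = "twistspacer_invalid_sequence")
  expect_error(sequence_mean_twist("ACGN", u), class = "twistspacer_invalid_sequence")
  # flanking bases add the boundary steps
  expect_equal(rad2deg(sequence_mean_twist("AA", u, flank5 = "G", flank3 = "C")),
               3 * 34)
})

test_that("effective stiffness is the series-spring combination", {
  p <- twist_params()
  u <- uniform_twist_table(p)
  expect_equal(effective_stiffness(strrep("A", 18), u), 71.4 / 17)
  expect_equal(effective_stiffness("AC", u), 71.4)
  st <- setNames(c(2, rep(1, 15)), u$step)  # AA soft... actually AA = 2
  tab <- twist_table(setNames(rep(34, 16), u$step), st)
  expect_equal(effective_stiffness("AAC", tab), 1 / (1 / 2 + 1 / 1))
})

test_that("closed-form sequence energy equals the constrained quadratic minimum", {
  set.seed(42)
  tab_steps <- uniform_twist_table()$step
  for (i in 1:20) {
    twist <- setNames(runif(16, 25, 45), tab_steps)
    stiff <- setNames(runif(16, 40, 110), tab_steps)
    tab <- twist_table(twist, stiff)
    seq5 <- random_spacer(6)   # 5 steps
    sigma <- runif(1, -0.1, 0.02)
    theta_P <- runif(1, 2.5, 3.5)
    closed <- sequence_orientational_energy(seq5, sigma, theta_P, tab)
    steps <- substring(seq5, 1:5, 2:6)
    oracle <- qp_energy_oracle(tab[steps, "alpha"], tab[steps, "k"],
                               sigma, theta_P)
    expect_equal(closed, oracle, tolerance = 1e-9)
    # effective stiffness itself against the oracle's curvature in theta_P
    h <- 1e-4
    curv <- (qp_energy_oracle(tab[steps, "alpha"], tab[steps, "k"], sigma, theta_P + h) +
               qp_energy_oracle(tab[steps, "alpha"], tab[steps, "k"], sigma, theta_P - h) -
               2 * oracle) / h^2
    expect_equal(effective_stiffness(seq5, tab), curv, tolerance = 1e-5)
  }
})

test_that("a uniform table reproduces the homogeneous model exactly", {
  p <- twist_params()
  u <- uniform_twist_table(p)
  for (n in 15:19) {
    s <- strrep("AC", 20)
    s <- substr(s, 1, n + 1)  # n steps
    for (sig in seq(-0.1, 0.02, by = 0.02)) {
      expect_equal(sequence_orientational_energy(s, sig, p$theta_P, u),
                   orientational_energy(sig, n, p), tolerance = 1e-12)
    }
  }
  # zero where the sequence mean twist matches the imposed angle
  s <- strrep("A", 18)
  tp <- sequence_mean_twist(s, u) * (1 - 0.06)
  expect_equal(sequence_orientational_energy(s, -0.06, tp, u), 0)
})

test_that("ablations: structure dominates, stiffness alone has almost no effect", {
  set.seed(7)
  tab <- default_twist_table()
  seqs <- replicate(60, random_spacer(18))  # 17 steps, as for a 17-nt spacer
  p <- twist_params()
  sp_full <- sequence_adjustment_span(seqs, -0.04, p$theta_P, tab, mode = "full")
  sp_a <- sequence_adjustment_span(seqs, -0.04, p$theta_P, tab, mode = "average_alpha")
  sp_k <- sequence_adjustment_span(seqs, -0.04, p$theta_P, tab, mode = "average_k")
  expect_lt(sp_a$span, 0.25 * sp_full$span)
  expect_gt(sp_k$span, 0.5 * sp_full$span)
  expect_lt(sp_k$span, 1.5 * sp_full$span)
  # double ablation: averaged-stiffness table + alpha ablation has no sequence
  # dependence left
  unif_k <- twist_table(setNames(rad2deg(tab$alpha), tab$step),
                        setNames(rep(mean(tab$k), 16), tab$step))
  sp0 <- sequence_adjustment_span(seqs, -0.04, p$theta_P, unif_k,
                                  mode = "average_alpha")
  expect_equal(unname(sp0$adjustment), rep(0, length(seqs)))
  expect_equal(sp0$span, 0)
  expect_error(sequence_adjustment_span(character(0), -0.04, p$theta_P, tab),
               class = "twistspacer_invalid_argument")
})

test_that("the sequence contribution to the shock response is weaker than one nucleotide", {
  set.seed(11)
  tab <- default_twist_table()
  p <- twist_params()
  seqs <- replicate(80, random_spacer(18))
  adj0 <- sequence_adjustment_span(seqs, -0.06, p$theta_P, tab)$adjustment
  adj1 <- sequence_adjustment_span(seqs, -0.03, p$theta_P, tab)$adjustment
  contrib <- adj1 - adj0  # per-promoter sequence term in the relaxation logFC
  one_nt <- abs(spacer_logfc_difference(0.03, 1, p))
  expect_lt(max(contrib) - min(contrib), one_nt)
})

test_that("FASTA spacer sequences feed the sequence energy by promoter id", {
  skip_if_not_installed("Biostrings")
  tmp <- tempfile(fileext = ".fa")
  writeLines(c(">P0001", "acgtacgtacgtacgtac", ">P0002", "ATATATATATATATATAT"), tmp)
  seqs <- read_spacer_fasta(tmp)
  expect_named(seqs, c("P0001", "P0002"))
  expect_equal(unname(nchar(seqs)), c(18L, 18L))
  e <- sequence_orientational_energy(seqs[["P0001"]], -0.06,
                                     table = default_twist_table())
  expect_gte(e, 0)
})

test_that("the shipped synthetic table round-trips through the TSV reader", {
  tab <- default_twist_table()
  expect_s3_class(tab, "twist_table")
  expect_equal(mean(rad2deg(tab$alpha)), 34, tolerance = 1e-12)
  # complement symmetry of the synthetic values
  comp <- function(s) chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  for (s in tab$step) {
    expect_equal(tab[s, "alpha"], tab[comp(s), "alpha"])
    expect_equal(tab[s, "k"], tab[comp(s), "k"])
  }
  tmp <- tempfile(fileext = ".tsv")
  write.table(data.frame(step = tab$step, twist_deg = rad2deg(tab$alpha),
                         stiffness = tab$k),
              tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_twist_table(tmp), tab)
})
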