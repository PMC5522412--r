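test_that("LRT statistic and p-value follow the chi-square tail", {
  # printed worked examples: statistic fed as 2*(lnl_alt - lnl_null)
  r <- lrt_pvalue(-1000, -1000 + 4.683 / 2, df = 1)
  expect_equal(r$stat, 4.683)
  expect_equal(r$p_raw, 3.047e-2, tolerance = 1e-3)
  r2 <- lrt_pvalue(-500, -500 + 18.374 / 2, df = 2)
  expect_equal(r2$p_raw, 1.023e-4, tolerance = 1e-3)
  # clamping: a better-fitting null gives stat 0, p exactly 1
  r3 <- lrt_pvalue(-100, -103, df = 1)
  expect_equal(r3$stat, 0)
  expect_equal(r3$p_raw, 1)
  expect_error(lrt_pvalue(0, 1, df = 3), "df")
  # monotone decreasing in the statistic
  s <- seq(0, 50, by = 0.5)
  expect_true(all(diff(chisq_tail(s, 1)) < 0))
  expect_equal(chisq_tail(0, 1), 1)
})

test_that("BH adjustment equals the step-up definition and respects families", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(1)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
  # family-wise: adjustment independent within keys, order preserved
  p <- c(0.01, 0.04, 0.01, 0.04)
  fam <- c("a", "a", "b", "b")
  expect_equal(bh_adjust(p, fam), c(0.02, 0.04, 0.02, 0.04))
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("branch declarations require both codon-frequency arms", {
  both <- data.frame(codon_freq = c("F3X4", "F61"), p_adj = c(0.001, 0.003))
  expect_true(declare_branch_selection(both))
  one_arm <- data.frame(codon_freq = c("F3X4", "F61"), p_adj = c(0.003, 0.5))
  expect_false(declare_branch_selection(one_arm))
  null_case <- data.frame(codon_freq = c("F3X4", "F61"), p_adj = c(1, 1))
  expect_false(declare_branch_selection(null_case))
  expect_error(declare_branch_selection(
    data.frame(codon_freq = "F3X4", p_adj = 0.01)), "exactly one")
})

test_that("site-model declarations require all four arms significant", {
  grid <- expand.grid(test_id = c("M7_vs_M8", "M8a_vs_M8"),
                      codon_freq = c("F3X4", "F61"),
                      stringsAsFactors = FALSE)
  grid$p_adj <- c(1e-5, 1e-4, 1e-3, 1e-2)
  expect_true(declare_site_model_selection(grid))
  grid2 <- grid
  grid2$p_adj[grid2$test_id == "M8a_vs_M8" & grid2$codon_freq == "F61"] <- 0.2
  expect_false(declare_site_model_selection(grid2))
  grid3 <- grid
  grid3$p_adj[1] <- 1
  expect_false(declare_site_model_selection(grid3))
  expect_error(declare_site_model_selection(grid[-1, ]), "four")
})

test_that("branch-site consensus is the BEB x MEME intersection", {
  beb <- data.frame(gene_id = "g", codon_index = c(329L, 500L),
                    score = c(0.96, 0.95))
  meme <- data.frame(gene_id = "g", codon_index = 329L, score = 0.02)
  out <- consensus_branch_sites(beb, meme)
  expect_identical(out$codon_index, 329L)
  empty <- consensus_branch_sites(beb, meme[0, ])
  expect_equal(nrow(empty), 0)
  # boundary semantics: BEB >= 0.90 passes, MEME <= 0.1 passes
  out2 <- consensus_branch_sites(
    data.frame(gene_id = "g", codon_index = 1L, score = 0.90),
    data.frame(gene_id = "g", codon_index = 1L, score = 0.1))
  expect_equal(nrow(out2), 1)
  expect_error(consensus_branch_sites(
    beb, data.frame(gene_id = "h", codon_index = 1L, score = 0.01)), "mix")
})

test_that("phylogeny consensus equals brute-force pass-pattern enumeration", {
  # all 2^3 pass/fail patterns at one codon
  cuts <- list(BEB_M8 = c(fail = 0.5, pass = 0.95),
               FUBAR = c(fail = 0.5, pass = 0.95),
               REL = c(fail = 10, pass = 80))
  for (mask in 0:7) {
    bits <- as.logical(bitwAnd(mask, c(1L, 2L, 4L)))
    ev <- data.frame(
      gene_id = "g", codon_index = 7L,
      method = c("BEB_M8", "FUBAR", "REL"),
      score = mapply(function(m, b) cuts[[m]][[if (b) "pass" else "fail"]],
                     c("BEB_M8", "FUBAR", "REL"), bits))
    out <- consensus_phylogeny_sites(ev)
    expect_equal(nrow(out), as.integer(sum(bits) >= 2),
                 info = paste("mask", mask))
    if (nrow(out)) expect_gte(out$n_methods, 2)
  }
  expect_error(consensus_phylogeny_sites(
    data.frame(gene_id = "g", codon_index = 1L, method = "SLAC",
               score = 1)), "unknown")
})

test_that("lineage site filter is strict at the posterior cutoff", {
  d <- data.frame(pr_gamma_ge_1 = c(0.901, 0.752, 0.75))
  kept <- lineage_selected_sites(d)
  expect_equal(kept$pr_gamma_ge_1, c(0.901, 0.752))
  expect_error(lineage_selected_sites(data.frame(pr_gamma_ge_1 = 1.2)),
               "\\[0, 1\\]")
})

test_that("module fractions come out in printed one-decimal form", {
  expect_equal(module_selection_fraction(8L, 47L), 17.0)
  expect_equal(module_selection_fraction(6L, 21L), 28.6)
  expect_equal(module_selection_fraction(logical(5), 5L), 0.0)
  expect_error(module_selection_fraction(1L, 0L), "module_size")
})

test_that("null LRT simulation declares at no more than the nominal rate", {
  for (df in c(1L, 2L)) {
    x <- simulate_lrt_inputs(2000, fraction_alt = 0, ncp = 0, df = df,
                             seed = 100 + df)
    p <- lrt_pvalue(x$lnl_null, x$lnl_alt, df = df)$p_raw
    rate <- mean(bh_adjust(p) < 0.05)
    se <- sqrt(0.05 * 0.95 / 2000)
    expect_lte(rate, 0.05 + 3 * se)
  }
})
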