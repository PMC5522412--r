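test_that("gene scores average ancestry probabilities over member SNPs", {
  g <- data.frame(gene_id = "g", chrom = "chr1", start = 0, end = 100)
  s <- data.frame(chrom = "chr1", pos = c(10, 20, 30),
                  np_EUR = c(0.2, 0.4, 0.6), np_ASN = c(0, 0, 0))
  expect_equal(gene_introgression_score(g, s, "EUR")$score, 0.4)
  expect_equal(gene_introgression_score(g, s, "ASN")$score, 0)
  # permutation invariance
  expect_equal(gene_introgression_score(g, s[c(3, 1, 2), ], "EUR")$score, 0.4)
  # no qualifying SNP: missing score, never zero
  far <- data.frame(chrom = "chr1", pos = 500, np_EUR = 0.9, np_ASN = 0.9)
  out <- gene_introgression_score(g, far, "EUR")
  expect_true(is.na(out$score))
  expect_equal(out$n_snps, 0)
  # half-open membership: SNP at end is outside
  edge <- data.frame(chrom = "chr1", pos = c(0, 100), np_EUR = c(1, 0),
                     np_ASN = 0)
  expect_equal(gene_introgression_score(g, edge, "EUR")$n_snps, 1)
})

test_that("percentile threshold uses linear interpolation", {
  expect_equal(percentile_threshold(1:100, 95), 95.05)
  expect_equal(percentile_threshold(1:100, 5), 5.95)
  expect_equal(percentile_threshold(rep(7, 10), 95), 7)
  expect_error(percentile_threshold(numeric(0), 95), "empty")
})

test_that("outlier calling is strict above the background percentile", {
  m <- data.frame(gene_id = c("a", "b"), score = c(94, 96))
  expect_identical(call_outlier_genes(m, 1:100), "b")
  expect_length(call_outlier_genes(
    data.frame(gene_id = "a", score = 1), 1:100), 0)
  expect_error(call_outlier_genes(m, numeric(0)), "empty")
  # background against itself flags about (100 - q)% of genes
  set.seed(5)
  bg <- runif(2000)
  self <- data.frame(gene_id = as.character(seq_along(bg)), score = bg)
  rate <- length(call_outlier_genes(self, bg)) / length(bg)
  se <- sqrt(0.05 * 0.95 / 2000)
  expect_lt(abs(rate - 0.05), 3 * se + 1 / 2000)
})

test_that("archaic-SNP rule requires homozygosity and African absence", {
  base <- data.frame(snp_id = c("s1", "s2", "s3", "s4"),
                     ancestral = "A", derived = "G",
                     altai_a1 = c("G", "G", "A", NA),
                     altai_a2 = c("G", "G", "G", NA),
                     af_AFR = c(0, 0.01, 0, 0),
                     af_EUR = c(0.02, 0.02, 0.02, 0.02),
                     af_ASN = c(0, 0, 0, 0),
                     stringsAsFactors = FALSE)
  out <- identify_archaic_snps(base)
  expect_identical(out$is_archaic, c(TRUE, FALSE, FALSE, NA))
  expect_identical(out$archaic_allele, c("G", NA, NA, NA))
})

test_that("region building equals the brute-force run oracle", {
  set.seed(6)
  for (rep in 1:40) {
    n <- sample(5:40, 1)
    snps <- data.frame(
      snp_id = sprintf("s%02d", 1:n),
      chrom = sort(sample(c("chr1", "chr2"), n, replace = TRUE)),
      pos = NA_integer_,
      is_archaic = sample(c(TRUE, FALSE), n, replace = TRUE,
                          prob = c(0.6, 0.4)),
      score = runif(n),
      stringsAsFactors = FALSE)
    for (ch in unique(snps$chrom)) {
      k <- sum(snps$chrom == ch)
      snps$pos[snps$chrom == ch] <- sort(sample.int(5e4, k))
    }
    gap <- sample(c(Inf, 5000, 20000), 1)
    got <- define_introgressed_regions(snps, 0.5, max_gap_bp = gap)
    want <- region_oracle(transform(snps, score = score), 0.5, gap)
    got <- got[order(got$chrom, got$start), c("chrom", "start", "end",
                                              "n_snps")]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want[, c("chrom", "start", "end", "n_snps")])
  }
})

test_that("region builder rejects unsorted input and handles singletons", {
  snps <- data.frame(snp_id = c("a", "b"), chrom = "chr1",
                     pos = c(100, 50), is_archaic = TRUE, score = 1)
  expect_error(define_introgressed_regions(snps, 0.5), "sorted")
  single <- data.frame(snp_id = "a", chrom = "chr1", pos = 100,
                       is_archaic = TRUE, score = 1)
  reg <- define_introgressed_regions(single, 0.5)
  expect_equal(reg$start, 100)
  expect_equal(reg$end, 101)
  expect_equal(reg$n_snps, 1)
})

test_that("planted introgressed gene is flagged and its region exact", {
  for (seed in c(1, 2, 3)) {
    cohort <- simulate_cohort(small_config(seed = seed))
    genes <- cohort$genes
    scores <- gene_introgression_scores(genes, cohort$snps, "EUR")
    lab <- genes$module_label[match(scores$gene_id, genes$gene_id)]
    bg <- scores$score[lab == "background"]
    outliers <- call_outlier_genes(scores[lab != "background", ], bg)
    expect_true(cohort$truth$introgressed_gene %in% outliers)
    # region recovery with exact SNP membership
    arch <- identify_archaic_snps(cohort$snps)
    reg_in <- cohort$snps[, c("snp_id", "gene_id", "chrom", "pos")]
    reg_in$is_archaic <- arch$is_archaic
    reg_in$score <- cohort$snps$np_EUR
    thr <- percentile_threshold(bg[!is.na(bg)], 95)
    regions <- define_introgressed_regions(reg_in, thr)
    planted <- paste(sort(cohort$truth$haplotype_snps), collapse = ",")
    members <- vapply(strsplit(regions$snp_ids, ","), function(x) {
      paste(sort(x), collapse = ",")
    }, "")
    expect_true(planted %in% members)
  }
})
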