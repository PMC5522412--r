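make_pool <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(gene_id = sprintf("B%03d", seq_len(n)),
             gc_fraction = runif(n, 0.3, 0.7),
             cds_length = round(runif(n, 500, 5000)),
             gerp_score = runif(n, 0.5, 4),
             stringsAsFactors = FALSE)
}

test_that("matching applies the joint +/-10% relative rule", {
  focal <- data.frame(gene_id = "f", gc_fraction = 0.45, cds_length = 1000,
                      gerp_score = 2)
  cand <- data.frame(gene_id = c("a", "b", "c"),
                     gc_fraction = c(0.46, 0.40, 0.46),
                     cds_length = c(1080, 1000, 1101),
                     gerp_score = c(2, 2, 2),
                     stringsAsFactors = FALSE)
  # a: deviations 0.0222 and 0.08 both inside; b: GC off by 0.111;
  # c: length off by 0.101
  expect_identical(match_genes(focal, cand, "gc_length"), "a")
  # reflexivity
  expect_true("f" %in% match_genes(focal, rbind(cand, focal), "gc_length"))
  # zero focal feature is a signalled error, not a silent skip
  focal0 <- focal
  focal0$gerp_score <- 0
  expect_error(match_genes(focal0, cand, "gerp"), "zero")
})

test_that("matched sets equal the brute-force all-pairs filter", {
  pool <- make_pool(300, seed = 2)
  focal_set <- make_pool(10, seed = 3)
  focal_set$gene_id <- sprintf("F%02d", 1:10)
  for (mode in c("gc_length", "gerp")) {
    cols <- if (mode == "gc_length") c("gc_fraction", "cds_length") else
      "gerp_score"
    for (i in seq_len(nrow(focal_set))) {
      expect_identical(match_genes(focal_set[i, ], pool, mode),
                       match_oracle(focal_set[i, ], pool, cols))
    }
  }
})

test_that("tolerance shrinkage never grows a matched set", {
  pool <- make_pool(200, seed = 4)
  focal <- make_pool(1, seed = 5)
  sets <- lapply(c(0.20, 0.10, 0.05, 0.01), function(tol) {
    match_genes(focal, pool, "gc_length", tolerance = tol)
  })
  for (i in 2:length(sets)) {
    expect_true(all(sets[[i]] %in% sets[[i - 1]]))
  }
})

test_that("reference-set construction dedups and reports unmatched genes", {
  pool <- make_pool(100, seed = 6)
  focal <- pool[1:2, ]
  focal$gene_id <- c("F1", "F2")
  ref <- build_reference_set(focal, pool, "gc_length")
  expect_false(anyDuplicated(ref$reference_ids) > 0)
  expect_true(all(ref$pairs$matched_id %in% pool$gene_id))
  # every reference gene is within tolerance of at least one focal gene
  for (id in ref$reference_ids) {
    devs <- vapply(seq_len(nrow(focal)), function(i) {
      cand <- pool[pool$gene_id == id, ]
      max(abs(cand$gc_fraction - focal$gc_fraction[i]) / focal$gc_fraction[i],
          abs(cand$cds_length - focal$cds_length[i]) / focal$cds_length[i])
    }, 0)
    expect_lte(min(devs), 0.10)
  }
  # disjoint feature ranges leave focal genes unmatched, with a warning
  far <- focal
  far$gc_fraction <- 0.99
  far$cds_length <- 1e6
  expect_warning(ref2 <- build_reference_set(far, pool, "gc_length"),
                 "no matched")
  expect_length(ref2$reference_ids, 0)
  expect_error(build_reference_set(focal, focal, "gc_length"), "empty")
})

test_that("focal-vs-matched comparison detects planted shifts", {
  cfg <- sim_config(seed = 9, n_genes = 200, n_background_genes = 200,
                    module_split = c(100, 100))
  genes <- simulate_genes(cfg)
  cv <- simulate_constraint_values(genes, shift = 0.2, seed = 9)
  fm <- cv$f[cv$module_label != "background"]
  fb <- cv$f[cv$module_label == "background"]
  expect_lt(compare_focal_vs_matched(fm, fb, "t_test")$p_value, 0.01)
  expect_lt(compare_focal_vs_matched(fm, fb, "rank_sum")$p_value, 0.01)
  # identical groups: p ~ 1
  same <- compare_focal_vs_matched(fb, fb, "t_test")
  expect_equal(same$statistic, 0)
  expect_gt(same$p_value, 0.99)
  expect_error(compare_focal_vs_matched(1, fb), "at least 2")
})

test_that("shift-free comparisons reject at about the nominal rate", {
  set.seed(21)
  p <- replicate(200, {
    compare_focal_vs_matched(rbeta(40, 12, 8), rbeta(40, 12, 8),
                             "t_test")$p_value
  })
  rate <- mean(p < 0.05)
  se <- sqrt(0.05 * 0.95 / 200)
  expect_lte(rate, 0.05 + 3 * se)
})

test_that("three-group comparisons run both omnibus/post-hoc families", {
  set.seed(10)
  vals <- c(rnorm(50, 0), rnorm(50, 0), rnorm(50, 1.2))
  grp <- rep(c("M1", "M2", "background"), each = 50)
  for (m in c("anova_tukey", "kruskal_nemenyi")) {
    res <- three_group_compare(vals, grp, m)
    expect_lt(res$omnibus_p, 1e-4)
    pw <- res$pairwise
    shifted <- pw[pw$group1 == "background" | pw$group2 == "background", ]
    other <- pw[!(pw$group1 == "background" | pw$group2 == "background"), ]
    expect_true(all(shifted$p_adj < 0.01))
    expect_true(all(other$p_adj > 0.05))
  }
  # null case: omnibus p well away from significance
  null_res <- three_group_compare(rnorm(150), grp, "anova_tukey")
  expect_gt(null_res$omnibus_p, 0.05)
  expect_error(three_group_compare(vals[1:100], grp[1:100]), "three")
})
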