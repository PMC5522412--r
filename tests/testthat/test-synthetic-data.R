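test_that("gene generation is seeded, disjoint and validated", {
  cfg <- sim_config(seed = 1, n_genes = 5, n_background_genes = 0)
  g1 <- simulate_genes(cfg)
  g2 <- simulate_genes(cfg)
  expect_identical(g1, g2)
  expect_equal(nrow(g1), 5)
  # non-overlap within chromosome, half-open intervals
  for (ch in unique(g1$chrom)) {
    gg <- g1[g1$chrom == ch, ]
    gg <- gg[order(gg$start), ]
    expect_true(all(gg$start < gg$end))
    if (nrow(gg) > 1) {
      expect_true(all(gg$start[-1] >= gg$end[-nrow(gg)]))
    }
  }
  expect_true(all(g1$gc_fraction >= 0 & g1$gc_fraction <= 1))
  g3 <- simulate_genes(sim_config(seed = 2, n_genes = 5,
                                  n_background_genes = 0))
  expect_false(identical(g1$start, g3$start))
  expect_error(sim_config(n_genes = 0), "n_genes")
})

test_that("SNP generation covers all fields and respects planted structure", {
  cfg <- small_config()
  genes <- simulate_genes(cfg)
  snps <- simulate_snps(genes, cfg)
  expect_true(all(c("af_AFR", "af_EUR", "af_ASN") %in% names(snps)))
  for (cl in c("af_AFR", "af_EUR", "af_ASN", "np_EUR", "np_ASN")) {
    expect_true(all(snps[[cl]] >= 0 & snps[[cl]] <= 1))
  }
  # background ancestry probabilities concentrate near the configured mean
  expect_lt(mean(snps$np_EUR), 3 * cfg$ancestry_background_prob)
  # missing archaic genotypes are explicit NA pairs
  miss <- is.na(snps$altai_a1)
  expect_identical(miss, is.na(snps$altai_a2))
  expect_error(simulate_snps(genes[0, ], cfg), "non-empty")
})

test_that("planted haplotype is archaic-specific and in full LD", {
  cfg <- small_config()
  genes <- simulate_genes(cfg)
  snps <- simulate_snps(genes, cfg)
  counts <- table(snps$gene_id)
  target <- names(counts)[counts >= cfg$n_haplotype_snps][1]
  hap <- plant_introgressed_haplotype(snps, target, cfg)
  expect_length(hap$snp_ids, 20)
  planted <- hap$snps[hap$snps$snp_id %in% hap$snp_ids, ]
  expect_true(all(planted$af_AFR == 0))
  expect_true(all(planted$af_EUR > 0 | planted$af_ASN > 0))
  expect_true(all(planted$altai_a1 == planted$derived &
                    planted$altai_a2 == planted$derived))
  # full pairwise LD among modern chromosomes: r^2 = 1 for every SNP pair
  modern <- hap$matrix[!rownames(hap$matrix) %in% c("ALTAI", "DENISOVA"), ]
  r2 <- suppressWarnings(cor(modern))
  expect_true(all(abs(r2) == 1))
  expect_true(all(hap$matrix["ALTAI", ] == 1))
  # carrier frequency 0 leaves no modern carrier and breaks the archaic rule
  hap0 <- plant_introgressed_haplotype(snps, target, cfg, carrier_freq = 0)
  planted0 <- hap0$snps[hap0$snps$snp_id %in% hap0$snp_ids, ]
  arch0 <- identify_archaic_snps(planted0)
  expect_true(all(arch0$is_archaic == FALSE))
  # too-small gene rejected
  small <- names(counts)[which.min(counts)]
  cfg_big <- small_config(n_haplotype_snps = max(counts) + 1)
  expect_error(plant_introgressed_haplotype(snps, small, cfg_big), "fewer")
})

test_that("planted sweep region spans the configured width and is recoverable", {
  cfg <- small_config(sweep_span_bp = 30000)
  genes <- simulate_genes(cfg)
  snps <- simulate_snps(genes, cfg)
  sw <- plant_sweep_region(snps, cfg)
  expect_gte(sw$region$end - 1 - sw$region$start, 30000)
  thr <- genome_s_threshold(sw$snps$s_score, 5)
  found <- sweep_scan(sw$snps, thr, min_span = 25000)
  hit <- found[found$chrom == sw$region$chrom &
                 found$start == sw$region$start, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$end, sw$region$end)
  expect_equal(hit$n_snps, sw$region$n_snps)
  expect_error(sim_config(sweep_span_bp = 10000), "minimum")
})

test_that("simulated LRT inputs follow the asymptotic null", {
  x <- simulate_lrt_inputs(2000, fraction_alt = 0, ncp = 0, df = 1, seed = 7)
  p <- lrt_pvalue(x$lnl_null, x$lnl_alt, df = 1)$p_raw
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
  # strong alternatives are nearly all detected after FDR
  y <- simulate_lrt_inputs(500, fraction_alt = 1, ncp = 50, df = 1, seed = 8)
  py <- lrt_pvalue(y$lnl_null, y$lnl_alt, df = 1)$p_raw
  expect_gt(mean(bh_adjust(py) < 0.05), 0.95)
  expect_error(simulate_lrt_inputs(10, 0, 0, df = 3, seed = 1), "df")
})

test_that("site evidence construction matches its planted truth", {
  ev <- simulate_site_evidence("g1", 300, c(10L, 50L), seed = 3,
                               family = "branch")
  beb <- ev[ev$method == "BEB_branch", ]
  meme <- ev[ev$method == "MEME", ]
  called <- consensus_branch_sites(beb, meme)
  expect_identical(called$codon_index, c(10L, 50L))
  evp <- simulate_site_evidence("g1", 300, c(10L, 50L), seed = 3,
                                family = "phylogeny")
  calledp <- consensus_phylogeny_sites(evp)
  expect_identical(calledp$codon_index, c(10L, 50L))
  expect_true(all(calledp$n_methods >= 2))
  expect_error(simulate_site_evidence("g1", 100, 200L, seed = 1), "within")
})

test_that("constraint values carry the planted module shift", {
  cfg <- small_config()
  genes <- simulate_genes(cfg)
  cv0 <- simulate_constraint_values(genes, shift = 0, seed = 5)
  expect_true(all(cv0$f >= 0 & cv0$f <= 1))
  expect_error(simulate_constraint_values(genes, shift = 0.7, seed = 5),
               "inside")
})

test_that("a full cohort is byte-identical under a fixed seed", {
  cfg <- small_config(seed = 11)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(serialize(c1, NULL), serialize(c2, NULL))
  expect_true(c1$truth$introgressed_gene %in% c1$genes$gene_id)
  expect_true(all(c1$truth$sweep_snps %in% c1$snps$snp_id))
})
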