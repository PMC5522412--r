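#' Simulation configuration for synthetic cohorts
#'
#' Bundles every tunable of the synthetic-cohort generator. The defaults
#' emulate the study design the package targets: two focal modules of 47
#' (M1-like) and 21 (M2-like) genes against a large coding background, rare
#' high-probability Neanderthal-ancestry haplotypes on an otherwise
#' near-zero ancestry map, a 20-SNP archaic haplotype in full linkage
#' disequilibrium, plantable low-S sweep runs of at least 25 kb, and a
#' constraint (f) shift between module and background genes.
#'
#' @param seed single integer; root seed. Every stage derives its own child
#'   stream from it via [derive_seed()], so the cohort is byte-identical
#'   across runs for a fixed seed.
#' @param n_genes number of focal module genes (split between M1-like and
#'   M2-like labels according to `module_split`).
#' @param n_background_genes number of background genes.
#' @param module_split integer vector of length 2, sizes of the M1-like and
#'   M2-like modules; must sum to `n_genes`.
#' @param snps_per_gene mean number of SNPs generated per gene (Poisson,
#'   floored at 2).
#' @param ancestry_high_prob Neanderthal-ancestry probability given to SNPs
#'   of the planted introgressed haplotype.
#' @param ancestry_background_prob mean ancestry probability of unplanted
#'   SNPs (the background mixture component is concentrated near 0).
#' @param sweep_span_bp span of the planted low-S region, in bp; must be at
#'   least `min_sweep_span`.
#' @param min_sweep_span minimum admissible sweep span (default 25000, the
#'   scan rule's window floor).
#' @param n_haplotype_snps number of SNPs in the planted archaic haplotype.
#' @param hap_carrier_freq fraction of non-African chromosomes carrying the
#'   planted haplotype.
#' @param n_chrom_per_pop number of phased chromosomes simulated per
#'   population for the haplotype matrix.
#' @param pop_labels population labels; the first is treated as African.
#' @param effect_sizes named list of planted shifts; `f_shift` is the mean
#'   constraint difference between module and background genes.
#' @return an object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 10, n_background_genes = 50)
#' cfg$sweep_span_bp
sim_config <- function(seed = 1L,
                       n_genes = 68L,
                       n_background_genes = 2000L,
                       module_split = NULL,
                       snps_per_gene = 30,
                       ancestry_high_prob = 0.9,
                       ancestry_background_prob = 0.02,
                       sweep_span_bp = 30000L,
                       min_sweep_span = 25000L,
                       n_haplotype_snps = 20L,
                       hap_carrier_freq = 0.05,
                       n_chrom_per_pop = 100L,
                       pop_labels = c("AFR", "EUR", "ASN"),
                       effect_sizes = list(f_shift = 0.2)) {
  if (n_genes < 1L) stop("n_genes must be >= 1", call. = FALSE)
  if (n_background_genes < 0L) {
    stop("n_background_genes must be >= 0", call. = FALSE)
  }
  if (snps_per_gene <= 0) stop("snps_per_gene must be positive", call. = FALSE)
  assert_prob(ancestry_high_prob, "ancestry_high_prob")
  assert_prob(ancestry_background_prob, "ancestry_background_prob")
  assert_prob(hap_carrier_freq, "hap_carrier_freq")
  if (sweep_span_bp <= 0) stop("sweep_span_bp must be > 0", call. = FALSE)
  if (sweep_span_bp < min_sweep_span) {
    stop(sprintf("sweep_span_bp (%d) is below the minimum admissible span (%d)",
                 as.integer(sweep_span_bp), as.integer(min_sweep_span)),
         call. = FALSE)
  }
  if (n_haplotype_snps < 2L) {
    stop("n_haplotype_snps must be >= 2", call. = FALSE)
  }
  if (length(pop_labels) < 2L) {
    stop("need at least an African and one non-African population",
         call. = FALSE)
  }
  if (is.null(module_split)) {
    n1 <- ceiling(n_genes * 47 / 68)  # study module proportions
    module_split <- c(n1, n_genes - n1)
  }
  if (sum(module_split) != n_genes || any(module_split < 0)) {
    stop("module_split must be non-negative and sum to n_genes", call. = FALSE)
  }
  structure(list(
    seed = as.integer(seed),
    n_genes = as.integer(n_genes),
    n_background_genes = as.integer(n_background_genes),
    module_split = as.integer(module_split),
    snps_per_gene = snps_per_gene,
    ancestry_high_prob = ancestry_high_prob,
    ancestry_background_prob = ancestry_background_prob,
    sweep_span_bp = as.integer(sweep_span_bp),
    min_sweep_span = as.integer(min_sweep_span),
    n_haplotype_snps = as.integer(n_haplotype_snps),
    hap_carrier_freq = hap_carrier_freq,
    n_chrom_per_pop = as.integer(n_chrom_per_pop),
    pop_labels = pop_labels,
    effect_sizes = effect_sizes
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  seed %d; %d module genes (%s) + %d background genes\n",
              x$seed, x$n_genes,
              paste(x$module_split, collapse = " + "),
              x$n_background_genes))
  cat(sprintf("  ~%g SNPs/gene; planted haplotype %d SNPs; sweep span %d bp\n",
              x$snps_per_gene, x$n_haplotype_snps, x$sweep_span_bp))
  invisible(x)
}
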