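#' Filter modern-human-specific candidate alleles
#'
#' A SNP passes when (i) both the Altai Neanderthal and the Denisova
#' genotypes are homozygous for the ancestral allele, (ii) the derived
#' allele frequency reaches `freq_threshold` in every modern population,
#' and (iii) the variant is a brain eQTL or carries at least one regulatory
#' annotation (open chromatin, enhancer-type histone marks, or DNase
#' hypersensitivity). SNPs with a missing archaic genotype are not callable
#' (`passes = NA`).
#'
#' @param snps SNP records with `ancestral`, archaic allele columns,
#'   `af_AFR`, `af_EUR`, `af_ASN` and the four regulatory flags.
#' @param freq_threshold minimum derived frequency in each modern
#'   population (default 0.90).
#' @param pops modern population suffixes (default `c("AFR","EUR","ASN")`).
#' @return `data.frame` with `snp_id`, per-criterion booleans
#'   (`archaic_ancestral_ok`, `frequency_ok`, `regulatory_ok`), `passes`
#'   (their conjunction) and `in_sweep_region` (initialised `NA`, see
#'   [annotate_in_sweep()]).
#' @export
filter_modern_specific <- function(snps, freq_threshold = 0.90,
                                   pops = c("AFR", "EUR", "ASN")) {
  assert_prob(freq_threshold, "freq_threshold")
  gt_present <- !is.na(snps$altai_a1) & !is.na(snps$altai_a2) &
    !is.na(snps$denisova_a1) & !is.na(snps$denisova_a2)
  anc_ok <- gt_present &
    snps$altai_a1 == snps$ancestral & snps$altai_a2 == snps$ancestral &
    snps$denisova_a1 == snps$ancestral & snps$denisova_a2 == snps$ancestral
  freq_ok <- Reduce(`&`, lapply(pops, function(p) {
    snps[[paste0("af_", p)]] >= freq_threshold
  }))
  reg_ok <- snps$brain_eqtl | snps$open_chromatin |
    snps$histone_enhancer | snps$dnase
  passes <- ifelse(gt_present, anc_ok & freq_ok & reg_ok, NA)
  data.frame(snp_id = snps$snp_id,
             archaic_ancestral_ok = ifelse(gt_present, anc_ok, NA),
             frequency_ok = freq_ok,
             regulatory_ok = reg_ok,
             passes = passes,
             in_sweep_region = NA,
             stringsAsFactors = FALSE)
}

#' Genome-wide percentile threshold of selective-sweep S scores
#'
#' @param s_scores numeric vector of S scores (`NA`s dropped).
#' @param q percentile, default 5 (the low tail consistent with selection
#'   in early modern humans).
#' @return the linear-interpolation percentile.
#' @export
#' @examples
#' genome_s_threshold(1:100)  # 5.95
genome_s_threshold <- function(s_scores, q = 5) {
  quantile_linear(s_scores, q)
}

#' Scan for candidate sweep regions of consistently low S scores
#'
#' Builds maximal runs of consecutive SNPs (per chromosome, in positional
#' order) whose S scores are all strictly below `threshold`, and emits a
#' region for each run whose span (`last_pos - first_pos`) is at least
#' `min_span`. Region coordinates are half-open
#' `[first_pos, last_pos + 1)`. A single above-threshold SNP interrupts a
#' run. SNPs with missing S are treated as interrupting (score evidence
#' absent).
#'
#' @param snps SNP records with `chrom`, `pos` (sorted within chromosome),
#'   `s_score`. Unsorted input is rejected.
#' @param threshold S-score threshold (exclusive), typically
#'   [genome_s_threshold()] of the genome-wide distribution.
#' @param min_span minimum region span in bp (default 25000).
#' @return `data.frame` with `chrom`, `start`, `end`, `n_snps`,
#'   `max_s_inside`.
#' @export
#' @examples
#' s <- data.frame(chrom = "chr1", pos = c(0, 10000, 26000),
#'                 s_score = c(-9, -9, -9))
#' sweep_scan(s, threshold = 0)$end  # 26001
sweep_scan <- function(snps, threshold, min_span = 25000) {
  assert_sorted(snps)
  below <- !is.na(snps$s_score) & snps$s_score < threshold
  if (!any(below)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_snps = integer(0),
                      max_s_inside = numeric(0), stringsAsFactors = FALSE))
  }
  # run = maximal block of consecutive below-threshold SNPs on one chrom
  brk <- c(TRUE, snps$chrom[-1] != snps$chrom[-nrow(snps)])
  block <- cumsum(brk | c(TRUE, diff(below) != 0))
  out <- lapply(split(which(below), block[below]), function(i) {
    span <- snps$pos[i[length(i)]] - snps$pos[i[1]]
    if (span < min_span) return(NULL)
    data.frame(chrom = snps$chrom[i[1]],
               start = snps$pos[i[1]],
               end = snps$pos[i[length(i)]] + 1L,
               n_snps = length(i),
               max_s_inside = max(snps$s_score[i]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_snps = integer(0),
                      max_s_inside = numeric(0), stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Annotate modern-allele calls with sweep-region membership
#'
#' Sets `in_sweep_region` to `TRUE` for calls whose SNP position lies in
#' any region interval (half-open: a SNP at `start` is inside, a SNP at
#' `end` is outside).
#'
#' @param calls output of [filter_modern_specific()] augmented with `chrom`
#'   and `pos` columns (or any `data.frame` carrying them).
#' @param regions output of [sweep_scan()].
#' @return `calls` with `in_sweep_region` filled in.
#' @export
annotate_in_sweep <- function(calls, regions) {
  if (!all(c("chrom", "pos") %in% names(calls))) {
    stop("calls must carry chrom and pos columns", call. = FALSE)
  }
  inside <- rep(FALSE, nrow(calls))
  for (i in seq_len(nrow(regions))) {
    inside <- inside | (calls$chrom == regions$chrom[i] &
                          calls$pos >= regions$start[i] &
                          calls$pos < regions$end[i])
  }
  calls$in_sweep_region <- inside
  calls
}
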