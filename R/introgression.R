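#' Per-gene Neanderthal introgression score
#'
#' The gene's score in a population is the arithmetic mean of the marginal
#' probabilities of Neanderthal ancestry over all its SNPs (positions in
#' `[start, end)`, half-open) with a non-missing probability. A gene with no
#' qualifying SNP yields a missing score (`NA`), which downstream callers
#' exclude — it is never imputed as zero.
#'
#' @param gene single-row `data.frame` (or list) with `gene_id`, `chrom`,
#'   `start`, `end`.
#' @param snps SNP records with `chrom`, `pos` and per-population ancestry
#'   probability columns `np_EUR`, `np_ASN`.
#' @param population `"EUR"` or `"ASN"`.
#' @return list with `gene_id`, `population`, `score` (`NA` if no
#'   qualifying SNP), `n_snps`.
#' @export
#' @examples
#' g <- data.frame(gene_id = "g", chrom = "chr1", start = 0, end = 100)
#' s <- data.frame(chrom = "chr1", pos = c(10, 20, 30),
#'                 np_EUR = c(0.2, 0.4, 0.6), np_ASN = 0)
#' gene_introgression_score(g, s, "EUR")$score  # 0.4
gene_introgression_score <- function(gene, snps, population = c("EUR", "ASN")) {
  population <- match.arg(population)
  np <- snps[[paste0("np_", population)]]
  assert_prob(np, "ancestry probability")
  in_gene <- snps$chrom == gene$chrom &
    snps$pos >= gene$start & snps$pos < gene$end & !is.na(np)
  n <- sum(in_gene)
  list(gene_id = gene$gene_id,
       population = population,
       score = if (n == 0L) NA_real_ else mean(np[in_gene]),
       n_snps = n)
}

#' Introgression scores for a table of genes
#'
#' Vectorized wrapper around [gene_introgression_score()].
#'
#' @param genes gene table with `gene_id`, `chrom`, `start`, `end`.
#' @param snps SNP records (see [gene_introgression_score()]).
#' @param population `"EUR"` or `"ASN"`.
#' @return `data.frame` with `gene_id`, `population`, `score`, `n_snps`;
#'   genes with no qualifying SNP carry `NA` scores.
#' @export
gene_introgression_scores <- function(genes, snps,
                                      population = c("EUR", "ASN")) {
  population <- match.arg(population)
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    as.data.frame(gene_introgression_score(genes[i, ], snps, population),
                  stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Linear-interpolation percentile of an empirical score distribution
#'
#' @param scores non-empty numeric vector (`NA`s dropped).
#' @param q percentile in `(0, 100)`.
#' @return the q-th percentile under linear interpolation between order
#'   statistics.
#' @export
#' @examples
#' percentile_threshold(1:100, 95)  # 95.05
percentile_threshold <- function(scores, q = 95) {
  quantile_linear(scores, q)
}

#' Call introgression-outlier genes against a background distribution
#'
#' Flags focal genes whose score is strictly greater than the q-th
#' percentile of the background score distribution.
#'
#' @param module_scores `data.frame` with `gene_id` and `score` (`NA`
#'   scores are excluded, not imputed).
#' @param background_scores numeric vector of background gene scores.
#' @param q percentile (default 95).
#' @return character vector of outlier `gene_id`s.
#' @export
#' @examples
#' m <- data.frame(gene_id = c("a", "b"), score = c(94, 96))
#' call_outlier_genes(m, 1:100)  # "b"
call_outlier_genes <- function(module_scores, background_scores, q = 95) {
  background_scores <- background_scores[!is.na(background_scores)]
  if (length(background_scores) == 0L) {
    stop("background score distribution is empty", call. = FALSE)
  }
  thr <- percentile_threshold(background_scores, q)
  keep <- !is.na(module_scores$score) & module_scores$score > thr
  module_scores$gene_id[keep]
}

#' Identify archaic-specific SNPs
#'
#' A SNP is archaic-specific when the Altai Neanderthal genotype is
#' homozygous for an allele whose frequency is exactly 0 in the African
#' population and greater than 0 in at least one non-African population.
#' SNPs with a missing Altai genotype are not callable (`NA`), which is
#' distinct from a negative call. The Denisova genotype is reported
#' alongside but does not gate the call.
#'
#' @param snps SNP records with `ancestral`, `derived`, `altai_a1`,
#'   `altai_a2`, `af_AFR` and at least one other `af_*` column.
#' @param nonafr_pops non-African population suffixes (default
#'   `c("EUR", "ASN")`).
#' @return `data.frame` with `snp_id`, `is_archaic` (logical, `NA` when not
#'   callable) and `archaic_allele` (the Altai-homozygous allele, or `NA`).
#' @export
identify_archaic_snps <- function(snps, nonafr_pops = c("EUR", "ASN")) {
  hom <- !is.na(snps$altai_a1) & !is.na(snps$altai_a2) &
    snps$altai_a1 == snps$altai_a2
  allele <- ifelse(hom, snps$altai_a1, NA_character_)
  allele_freq <- function(pop) {
    af <- snps[[paste0("af_", pop)]]
    ifelse(allele == snps$derived, af,
           ifelse(allele == snps$ancestral, 1 - af, 0))
  }
  afr <- allele_freq("AFR")
  nonafr <- Reduce(pmax, lapply(nonafr_pops, allele_freq))
  is_archaic <- ifelse(is.na(snps$altai_a1) | is.na(snps$altai_a2),
                       NA, hom & !is.na(afr) & afr == 0 & nonafr > 0)
  data.frame(snp_id = snps$snp_id,
             is_archaic = is_archaic,
             archaic_allele = ifelse(is_archaic %in% TRUE, allele,
                                     NA_character_),
             stringsAsFactors = FALSE)
}

#' Delineate introgressed regions from archaic SNPs
#'
#' Builds maximal runs of archaic-specific SNPs whose introgression score
#' exceeds `score_threshold`, splitting a run wherever the distance between
#' consecutive qualifying SNPs exceeds `max_gap_bp`. Region coordinates are
#' 0-based half-open over the member SNP positions; a single qualifying SNP
#' yields a degenerate region of span 0 (`end = start + 1` in half-open
#' output, span counted as `last - first`).
#'
#' @param snps SNP records sorted by position within chromosome, carrying
#'   `snp_id`, `chrom`, `pos`, a logical `is_archaic` column and a numeric
#'   `score` column (e.g. the per-SNP ancestry probability). When a
#'   `gene_id` column is present, runs are additionally split at gene
#'   boundaries, so the unlimited-gap default yields one contiguous
#'   haplotype block per gene. Unsorted input is rejected.
#' @param score_threshold minimum (exclusive) score for a SNP to qualify.
#' @param max_gap_bp maximum distance between consecutive qualifying SNPs
#'   in one region (default `Inf`: no distance-based splitting within a
#'   gene's SNP run).
#' @return `data.frame` with `chrom`, `start`, `end` (half-open), `n_snps`,
#'   `snp_ids` (comma-joined, in positional order).
#' @export
define_introgressed_regions <- function(snps, score_threshold,
                                        max_gap_bp = Inf) {
  assert_sorted(snps)
  qual <- which(!is.na(snps$is_archaic) & snps$is_archaic &
                  !is.na(snps$score) & snps$score > score_threshold)
  if (length(qual) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_snps = integer(0),
                      snp_ids = character(0), stringsAsFactors = FALSE))
  }
  q <- snps[qual, , drop = FALSE]
  new_run <- c(TRUE, q$chrom[-1] != q$chrom[-nrow(q)] |
                 diff(q$pos) > max_gap_bp)
  if (!is.null(q$gene_id)) {
    new_run <- new_run | c(FALSE, q$gene_id[-1] != q$gene_id[-nrow(q)])
  }
  run_id <- cumsum(new_run)
  regions <- lapply(split(seq_len(nrow(q)), run_id), function(i) {
    data.frame(chrom = q$chrom[i[1]],
               start = q$pos[i[1]],
               end = q$pos[i[length(i)]] + 1L,
               n_snps = length(i),
               snp_ids = paste(q$snp_id[i], collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, regions)
  rownames(out) <- NULL
  out
}
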