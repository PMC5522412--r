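#' Generate synthetic gene models
#'
#' Lays out non-overlapping gene intervals (0-based, half-open) across 22
#' autosomes with per-gene GC content, CDS length and mean GERP score, and
#' assigns module labels: the first `module_split[1]` genes are `M1`, the
#' next `module_split[2]` are `M2`, the rest `background`.
#'
#' @param config a [sim_config()] object.
#' @return `data.frame` with columns `gene_id`, `module_label`, `chrom`,
#'   `start`, `end`, `gc_fraction`, `cds_length`, `gerp_score`.
#' @export
#' @examples
#' genes <- simulate_genes(sim_config(seed = 1, n_genes = 5,
#'                                    n_background_genes = 0))
#' nrow(genes)
simulate_genes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_total <- config$n_genes + config$n_background_genes
  with_seed(derive_seed(config$seed, "genes"), {
    chrom <- paste0("chr", rep_len(1:22, n_total))
    span <- pmax(5000L, as.integer(round(rlnorm(n_total, log(4e4), 0.7))))
    # sequential placement per chromosome with random intergenic gaps keeps
    # intervals disjoint by construction
    start <- integer(n_total)
    for (ch in unique(chrom)) {
      i <- which(chrom == ch)
      gaps <- as.integer(round(runif(length(i), 1e4, 2e5)))
      start[i] <- cumsum(gaps) + cumsum(c(0L, span[i][-length(i)]))
    }
    genes <- data.frame(
      gene_id = sprintf("G%04d", seq_len(n_total)),
      module_label = rep(c("M1", "M2", "background"),
                         times = c(config$module_split[1],
                                   config$module_split[2],
                                   config$n_background_genes)),
      chrom = chrom,
      start = start,
      end = start + span,
      gc_fraction = rbeta(n_total, 0.46 * 40, 0.54 * 40),
      cds_length = pmax(300L, as.integer(round(rlnorm(n_total, log(1800), 0.6)))),
      gerp_score = rnorm(n_total, 2, 1),
      stringsAsFactors = FALSE
    )
    genes
  })
}

#' Generate synthetic SNP records for a set of genes
#'
#' Draws per-gene SNPs with per-population derived-allele frequencies,
#' Neanderthal-ancestry probabilities (a background Beta mixture component
#' concentrated near zero), selective-sweep S scores, archaic (Altai,
#' Denisova) genotypes and regulatory annotation flags.
#'
#' @param genes output of [simulate_genes()].
#' @param config a [sim_config()] object.
#' @return `data.frame` of SNP records sorted by chromosome and position,
#'   with columns `snp_id`, `gene_id`, `chrom`, `pos`, `ancestral`,
#'   `derived`, `af_AFR`, `af_EUR`, `af_ASN`, `np_EUR`, `np_ASN`, `s_score`,
#'   `altai_a1`, `altai_a2`, `denisova_a1`, `denisova_a2`, and logical flags
#'   `brain_eqtl`, `open_chromatin`, `histone_enhancer`, `dnase`.
#'   Missing archaic genotypes are encoded as `NA` allele pairs, never as a
#'   frequency of zero.
#' @export
simulate_snps <- function(genes, config) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(genes) == 0L) stop("genes must be non-empty", call. = FALSE)
  bases <- c("A", "C", "G", "T")
  m <- config$ancestry_background_prob
  with_seed(derive_seed(config$seed, "snps"), {
    n_per_gene <- pmax(2L, rpois(nrow(genes), config$snps_per_gene))
    idx <- rep(seq_len(nrow(genes)), n_per_gene)
    n <- length(idx)
    pos <- integer(n)
    for (g in seq_len(nrow(genes))) {
      k <- which(idx == g)
      pos[k] <- sort(sample(seq.int(genes$start[g], genes$end[g] - 1L),
                            length(k)))
    }
    anc <- sample(bases, n, replace = TRUE)
    der <- vapply(anc, function(a) sample(setdiff(bases, a), 1L), "")
    base_af <- rbeta(n, 0.7, 0.7)
    jitter_af <- function(p) {
      pmin(1, pmax(0, p + rnorm(n, 0, 0.05)))
    }
    # background ancestry probabilities: Beta concentrated near 0 with the
    # configured mean
    np_shape1 <- 0.5
    np_shape2 <- np_shape1 * (1 - m) / max(m, 1e-6)
    draw_np <- function() rbeta(n, np_shape1, np_shape2)
    af_eur <- jitter_af(base_af)
    af_asn <- jitter_af(base_af)
    # archaic genotypes drawn near the ancestral state; ~2% missing
    draw_gt <- function() {
      g1 <- ifelse(runif(n) < 0.15, der, anc)
      g2 <- ifelse(runif(n) < 0.15, der, anc)
      miss <- runif(n) < 0.02
      g1[miss] <- NA_character_
      g2[miss] <- NA_character_
      list(g1, g2)
    }
    altai <- draw_gt()
    deni <- draw_gt()
    snps <- data.frame(
      snp_id = sprintf("snp%06d", seq_len(n)),
      gene_id = genes$gene_id[idx],
      chrom = genes$chrom[idx],
      pos = pos,
      ancestral = unname(anc),
      derived = unname(der),
      af_AFR = jitter_af(base_af),
      af_EUR = af_eur,
      af_ASN = af_asn,
      np_EUR = draw_np(),
      np_ASN = draw_np(),
      s_score = rnorm(n, 0, 1.5),
      altai_a1 = altai[[1]], altai_a2 = altai[[2]],
      denisova_a1 = deni[[1]], denisova_a2 = deni[[2]],
      brain_eqtl = runif(n) < 0.08,
      open_chromatin = runif(n) < 0.10,
      histone_enhancer = runif(n) < 0.10,
      dnase = runif(n) < 0.10,
      stringsAsFactors = FALSE
    )
    snps <- snps[order(match(snps$chrom, paste0("chr", 1:22)), snps$pos), ]
    rownames(snps) <- NULL
    snps
  })
}

#' Plant an introgressed archaic haplotype into a gene
#'
#' Marks `n_haplotype_snps` SNPs of the target gene as archaic-specific
#' (Altai and Denisova homozygous for the derived allele, African frequency
#' exactly 0, non-African frequency equal to the carrier fraction) with a
#' high Neanderthal-ancestry probability, and builds the phased 0/1
#' haplotype matrix: a minority of non-African chromosomes carry the full
#' haplotype in complete linkage disequilibrium, and the archaic samples
#' (`ALTAI`, `DENISOVA`) carry it too.
#'
#' @param snps output of [simulate_snps()].
#' @param gene_id gene to plant into; must contain at least
#'   `config$n_haplotype_snps` SNPs.
#' @param config a [sim_config()] object.
#' @param carrier_freq fraction of non-African chromosomes carrying the
#'   haplotype; `0` produces no modern carrier (the SNPs then fail the
#'   archaic-SNP rule because their non-African frequency is 0).
#' @return list with elements `snps` (modified records), `matrix` (phased
#'   chromosomes x planted SNPs, rows labelled `POP_i` plus `ALTAI` and
#'   `DENISOVA`), `snp_ids`, `gene_id` and `carriers`.
#' @export
plant_introgressed_haplotype <- function(snps, gene_id, config,
                                         carrier_freq = config$hap_carrier_freq) {
  stopifnot(inherits(config, "sim_config"))
  assert_prob(carrier_freq, "carrier_freq")
  in_gene <- which(snps$gene_id == gene_id)
  k <- config$n_haplotype_snps
  if (length(in_gene) < k) {
    stop(sprintf("gene %s has %d SNPs, fewer than the %d needed for the haplotype",
                 gene_id, length(in_gene), k), call. = FALSE)
  }
  with_seed(derive_seed(config$seed, paste0("hap:", gene_id)), {
    # spread planted SNPs evenly across the gene body
    pick <- in_gene[unique(round(seq(1, length(in_gene), length.out = k)))]
    pick <- pick[seq_len(min(k, length(pick)))]
    pops <- config$pop_labels
    afr <- pops[1]
    nonafr <- pops[-1]
    rows <- c(unlist(lapply(pops, function(p) {
      sprintf("%s_%03d", p, seq_len(config$n_chrom_per_pop))
    })), "ALTAI", "DENISOVA")
    nonafr_rows <- grep(paste0("^(", paste(nonafr, collapse = "|"), ")_"), rows)
    n_car <- round(carrier_freq * length(nonafr_rows))
    carriers <- if (n_car > 0) sort(sample(nonafr_rows, n_car)) else integer(0)
    mat <- matrix(0L, nrow = length(rows), ncol = length(pick),
                  dimnames = list(rows, snps$snp_id[pick]))
    mat[carriers, ] <- 1L
    mat[c("ALTAI", "DENISOVA"), ] <- 1L
    # observed non-African carrier frequency, per population
    obs_freq <- vapply(nonafr, function(p) {
      pr <- grep(paste0("^", p, "_"), rows)
      mean(mat[pr, 1])
    }, 0)
    snps$af_AFR[pick] <- 0
    for (p in nonafr) snps[[paste0("af_", p)]][pick] <- obs_freq[[p]]
    snps$np_EUR[pick] <- config$ancestry_high_prob
    snps$np_ASN[pick] <- config$ancestry_high_prob
    snps$altai_a1[pick] <- snps$derived[pick]
    snps$altai_a2[pick] <- snps$derived[pick]
    snps$denisova_a1[pick] <- snps$derived[pick]
    snps$denisova_a2[pick] <- snps$derived[pick]
    list(snps = snps,
         matrix = mat,
         snp_ids = snps$snp_id[pick],
         gene_id = gene_id,
         carriers = rows[carriers])
  })
}

#' Plant a low-S selective-sweep region
#'
#' Chooses a window of consecutive SNPs spanning at least
#' `config$sweep_span_bp` on one chromosome and rewrites their S scores to
#' values below the genome-wide 5th percentile of the generated
#' distribution; the nearest flanking SNP on each side is pushed above the
#' threshold so the planted run has exact boundaries.
#'
#' @param snps output of [simulate_snps()] (sorted by position).
#' @param config a [sim_config()] object; `sweep_span_bp` below
#'   `min_sweep_span` (default 25 kb) is rejected at configuration time.
#' @param span_bp span to plant; defaults to `config$sweep_span_bp`.
#' @return list with elements `snps` (modified) and `region`, a one-row
#'   `data.frame` (`chrom`, `start`, `end`, `n_snps`, half-open coordinates)
#'   recording the planted truth.
#' @export
plant_sweep_region <- function(snps, config, span_bp = config$sweep_span_bp) {
  stopifnot(inherits(config, "sim_config"))
  if (span_bp < config$min_sweep_span) {
    stop(sprintf("sweep span %d bp is below the %d bp minimum",
                 as.integer(span_bp), config$min_sweep_span), call. = FALSE)
  }
  assert_sorted(snps)
  with_seed(derive_seed(config$seed, "sweep"), {
    q5 <- quantile_linear(snps$s_score, 5)
    lo <- min(snps$s_score, na.rm = TRUE)
    # choose the chromosome with the widest SNP span, anchor at a random SNP
    spans <- tapply(snps$pos, snps$chrom, function(p) max(p) - min(p))
    ch <- names(which.max(spans))
    on_ch <- which(snps$chrom == ch)
    pos <- snps$pos[on_ch]
    anchors <- which(pos + span_bp <= max(pos))
    if (length(anchors) == 0L) {
      stop("no chromosome offers enough span for the sweep region",
           call. = FALSE)
    }
    i0 <- sample(anchors, 1L)
    j0 <- which(pos - pos[i0] >= span_bp)[1]
    inside <- on_ch[i0:j0]
    if (length(inside) < 2L) {
      stop("sweep interval contains fewer than 2 SNPs", call. = FALSE)
    }
    snps$s_score[inside] <- runif(length(inside), lo - 2, lo - 0.5)
    # sharpen boundaries: flanking SNPs must sit above the threshold
    flank <- c(on_ch[i0 - 1L][i0 > 1L], on_ch[j0 + 1L][j0 < length(on_ch)])
    flank <- flank[!is.na(flank)]
    snps$s_score[flank] <- pmax(snps$s_score[flank], q5 + 1)
    new_thr <- quantile_linear(snps$s_score, 5)
    if (any(snps$s_score[inside] >= new_thr)) {
      stop("planted sweep scores failed to stay below the 5th percentile",
           call. = FALSE)
    }
    region <- data.frame(chrom = ch,
                         start = snps$pos[inside[1]],
                         end = snps$pos[inside[length(inside)]] + 1L,
                         n_snps = length(inside),
                         stringsAsFactors = FALSE)
    list(snps = snps, region = region,
         snp_ids = snps$snp_id[inside])
  })
}

#' Simulate paired null/alternative log-likelihoods for LRTs
#'
#' For null genes the statistic `2(lnL_alt - lnL_null)` follows a central
#' chi-square with `df` degrees of freedom (the asymptotic null of the
#' likelihood-ratio test); for alternative genes it is noncentral with
#' noncentrality `ncp`.
#'
#' @param n_genes number of genes.
#' @param fraction_alt fraction of genes drawn from the alternative.
#' @param ncp noncentrality parameter of the alternative.
#' @param df degrees of freedom, 1 or 2.
#' @param seed integer seed.
#' @return `data.frame` with `gene_id`, `lnl_null`, `lnl_alt`, `df` and the
#'   truth flag `is_alt`.
#' @export
#' @examples
#' x <- simulate_lrt_inputs(10, fraction_alt = 0.5, ncp = 20, df = 1, seed = 1)
#' table(x$is_alt)
simulate_lrt_inputs <- function(n_genes, fraction_alt, ncp, df, seed) {
  if (!df %in% c(1L, 2L)) stop("df must be 1 or 2", call. = FALSE)
  if (fraction_alt < 0 || fraction_alt > 1) {
    stop("fraction_alt must be in [0, 1]", call. = FALSE)
  }
  with_seed(seed, {
    n_alt <- round(fraction_alt * n_genes)
    is_alt <- seq_len(n_genes) <= n_alt
    stat <- numeric(n_genes)
    stat[!is_alt] <- rchisq(sum(!is_alt), df)
    stat[is_alt] <- rchisq(sum(is_alt), df, ncp = ncp)
    lnl_null <- rnorm(n_genes, -5000, 200)
    data.frame(gene_id = sprintf("G%04d", seq_len(n_genes)),
               lnl_null = lnl_null,
               lnl_alt = lnl_null + stat / 2,
               df = df,
               is_alt = is_alt,
               stringsAsFactors = FALSE)
  })
}

#' Simulate per-site selection evidence for consensus calling
#'
#' Emulates the per-codon outputs of site-level selection methods. Planted
#' sites receive scores passing the cutoffs of at least two methods;
#' background sites pass at most one.
#'
#' @param gene_id gene identifier attached to the records.
#' @param n_codons number of codons in the (human-numbered) protein.
#' @param planted_sites integer codon indices to plant as positively
#'   selected; must lie in `1:n_codons`.
#' @param seed integer seed.
#' @param family `"branch"` emits `BEB_branch` posteriors and `MEME`
#'   p-values (both passing at planted sites); `"phylogeny"` emits `BEB_M8`
#'   and `FUBAR` posteriors and `REL` Bayes factors with at least two
#'   passing at planted sites.
#' @return long `data.frame` with `gene_id`, `codon_index`, `method`,
#'   `score`.
#' @export
simulate_site_evidence <- function(gene_id, n_codons, planted_sites, seed,
                                   family = c("branch", "phylogeny")) {
  family <- match.arg(family)
  planted_sites <- as.integer(planted_sites)
  if (length(planted_sites) &&
      (min(planted_sites) < 1L || max(planted_sites) > n_codons)) {
    stop("planted_sites must lie within 1..n_codons", call. = FALSE)
  }
  with_seed(seed, {
    codon <- seq_len(n_codons)
    planted <- codon %in% planted_sites
    if (family == "branch") {
      beb <- runif(n_codons, 0, 0.85)
      meme <- runif(n_codons, 0.15, 1)
      # a sprinkle of single-method background hits (never both)
      lone <- runif(n_codons) < 0.05 & !planted
      which_m <- runif(n_codons) < 0.5
      beb[lone & which_m] <- runif(sum(lone & which_m), 0.91, 0.99)
      meme[lone & !which_m] <- runif(sum(lone & !which_m), 0.001, 0.09)
      beb[planted] <- runif(sum(planted), 0.92, 0.99)
      meme[planted] <- runif(sum(planted), 0.001, 0.08)
      out <- rbind(
        data.frame(gene_id = gene_id, codon_index = codon,
                   method = "BEB_branch", score = beb),
        data.frame(gene_id = gene_id, codon_index = codon,
                   method = "MEME", score = meme)
      )
    } else {
      beb <- runif(n_codons, 0, 0.85)
      fubar <- runif(n_codons, 0, 0.85)
      rel <- runif(n_codons, 0, 40)
      lone <- runif(n_codons) < 0.05 & !planted
      pickm <- sample(3L, n_codons, replace = TRUE)
      beb[lone & pickm == 1L] <- runif(sum(lone & pickm == 1L), 0.91, 0.99)
      fubar[lone & pickm == 2L] <- runif(sum(lone & pickm == 2L), 0.91, 0.99)
      rel[lone & pickm == 3L] <- runif(sum(lone & pickm == 3L), 55, 200)
      beb[planted] <- runif(sum(planted), 0.92, 0.99)
      fubar[planted] <- runif(sum(planted), 0.92, 0.99)
      rel[planted] <- runif(sum(planted), 60, 300)
      out <- rbind(
        data.frame(gene_id = gene_id, codon_index = codon,
                   method = "BEB_M8", score = beb),
        data.frame(gene_id = gene_id, codon_index = codon,
                   method = "FUBAR", score = fubar),
        data.frame(gene_id = gene_id, codon_index = codon,
                   method = "REL", score = rel)
      )
    }
    rownames(out) <- NULL
    out
  })
}

#' Simulate per-gene constraint (f) values
#'
#' Draws the constraint parameter f (the proportion of non-synonymous
#' mutations that are not deleterious) from Beta distributions whose mean is
#' lower by `shift` for module genes than for background genes, emulating
#' stronger purifying selection on the modules.
#'
#' @param genes output of [simulate_genes()].
#' @param shift mean reduction in f for module genes; the shifted mean must
#'   stay inside `[0, 1]`.
#' @param seed integer seed.
#' @param base_mean background mean of f.
#' @param concentration Beta concentration (higher = less spread).
#' @return `data.frame` with `gene_id`, `module_label`, `f`.
#' @export
simulate_constraint_values <- function(genes, shift, seed,
                                       base_mean = 0.6, concentration = 30) {
  mu_mod <- base_mean - shift
  if (mu_mod <= 0 || mu_mod >= 1 || base_mean <= 0 || base_mean >= 1) {
    stop("shift must leave the module mean of f inside (0, 1)", call. = FALSE)
  }
  with_seed(seed, {
    is_mod <- genes$module_label != "background"
    mu <- ifelse(is_mod, mu_mod, base_mean)
    f <- rbeta(nrow(genes), mu * concentration, (1 - mu) * concentration)
    data.frame(gene_id = genes$gene_id,
               module_label = genes$module_label,
               f = f,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a full synthetic cohort with planted truth
#'
#' Runs every generator in sequence: gene models, SNP records, one planted
#' introgressed haplotype (in the first M2-like gene with enough SNPs, as in
#' the motivating locus), one planted low-S sweep region, paired LRT
#' log-likelihoods, per-site selection evidence for one planted gene, and
#' per-gene constraint values. Each stage draws from its own child stream of
#' `config$seed`, so the whole cohort is reproducible.
#'
#' @param config a [sim_config()] object.
#' @return list of class `sim_cohort` with elements `genes`, `snps`,
#'   `haplotype` (planted haplotype bundle), `lrt`, `site_evidence`
#'   (list with `branch` and `phylogeny` tables), `constraint`, `config`
#'   and `truth` (planted gene id, sweep region, selected sites, f shift).
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(seed = 1, n_genes = 6,
#'   n_background_genes = 40, n_chrom_per_pop = 20))
#' cohort$truth$introgressed_gene
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  genes <- simulate_genes(config)
  snps <- simulate_snps(genes, config)

  # plant the archaic haplotype in the first module gene large enough
  counts <- table(snps$gene_id)
  mod_ids <- genes$gene_id[genes$module_label != "background"]
  big <- mod_ids[counts[mod_ids] >= config$n_haplotype_snps]
  if (length(big) == 0L) {
    stop("no module gene has enough SNPs for the planted haplotype; ",
         "increase snps_per_gene", call. = FALSE)
  }
  hap <- plant_introgressed_haplotype(snps, big[1], config)
  snps <- hap$snps

  swept <- plant_sweep_region(snps, config)
  snps <- swept$snps

  lrt <- simulate_lrt_inputs(nrow(genes), fraction_alt = 0.1, ncp = 25,
                             df = 1, seed = derive_seed(config$seed, "lrt"))
  planted_sites <- c(101L, 250L, 329L)
  ev_gene <- genes$gene_id[1]
  evidence <- list(
    branch = simulate_site_evidence(ev_gene, 500L, planted_sites,
                                    derive_seed(config$seed, "sites-branch"),
                                    family = "branch"),
    phylogeny = simulate_site_evidence(ev_gene, 500L, planted_sites,
                                       derive_seed(config$seed, "sites-phylo"),
                                       family = "phylogeny")
  )
  constraint <- simulate_constraint_values(
    genes, shift = config$effect_sizes$f_shift,
    seed = derive_seed(config$seed, "constraint"))

  structure(list(
    genes = genes,
    snps = snps,
    haplotype = hap,
    lrt = lrt,
    site_evidence = evidence,
    constraint = constraint,
    config = config,
    truth = list(
      introgressed_gene = hap$gene_id,
      haplotype_snps = hap$snp_ids,
      sweep_region = swept$region,
      sweep_snps = swept$snp_ids,
      selected_sites = planted_sites,
      evidence_gene = ev_gene,
      f_shift = config$effect_sizes$f_shift
    )
  ), class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d genes, %d SNPs (seed %d)\n",
              nrow(x$genes), nrow(x$snps), x$config$seed))
  cat(sprintf("  planted: haplotype in %s (%d SNPs), sweep %s:%d-%d\n",
              x$truth$introgressed_gene, length(x$truth$haplotype_snps),
              x$truth$sweep_region$chrom, x$truth$sweep_region$start,
              x$truth$sweep_region$end))
  invisible(x)
}
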