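# Stage orchestration: each stage consumes the shared state list, checks
# its upstream dependencies, computes, optionally writes its outputs, and
# appends a StageReport.

stage_dependencies <- list(
  simulate = character(0),
  lrt = "simulate",
  sites = "simulate",
  constraint = "simulate",
  introgression = "simulate",
  network = "simulate",
  modern = c("simulate", "introgression")
)

#' Default pipeline thresholds
#'
#' @return named list of the tunables used by [run_pipeline()]: `alpha`
#'   (LRT significance after FDR), `beb_cutoff`, `meme_cutoff`,
#'   `fubar_cutoff`, `rel_cutoff` (site-consensus cutoffs), `tolerance`
#'   (matching, relative), `q_outlier` (introgression percentile),
#'   `q_sweep` (S-score percentile), `min_span` (sweep window floor, bp),
#'   `freq_threshold` (modern-allele frequency floor).
#' @export
pipeline_defaults <- function() {
  list(alpha = 0.05,
       beb_cutoff = 0.90, meme_cutoff = 0.1,
       fubar_cutoff = 0.90, rel_cutoff = 50,
       tolerance = 0.10,
       q_outlier = 95, q_sweep = 5,
       min_span = 25000,
       freq_threshold = 0.90)
}

new_report <- function(stage, n_in, n_out, warnings, elapsed) {
  list(stage = stage, n_in = n_in, n_out = n_out,
       warnings = warnings, elapsed = elapsed)
}

#' Run a single pipeline stage
#'
#' Stages: `simulate` (build the synthetic cohort), `lrt` (p-values, FDR,
#' per-gene declarations), `sites` (consensus site calls), `constraint`
#' (matched reference sets and group comparisons), `introgression`
#' (scores, outliers, archaic SNPs, regions), `network` (median-joining
#' haplotype network), `modern` (modern-allele filter and sweep scan).
#' A stage whose upstream outputs are absent fails with an error naming
#' the missing stage.
#'
#' @param name stage name.
#' @param state pipeline state list; pass the result of the previous call.
#'   A fresh state needs `config` (a [sim_config()]) and optionally
#'   `params` (see [pipeline_defaults()]) and `out_dir`.
#' @return updated state, with the stage's outputs under `state[[name]]`
#'   and its report appended to `state$reports`.
#' @export
run_stage <- function(name, state) {
  if (!name %in% names(stage_dependencies)) {
    stop("unknown stage: ", name, call. = FALSE)
  }
  missing_dep <- setdiff(stage_dependencies[[name]], names(state$done))
  if (length(missing_dep)) {
    stop(sprintf("stage '%s' requires upstream stage '%s' to run first",
                 name, missing_dep[1]), call. = FALSE)
  }
  if (is.null(state$params)) state$params <- pipeline_defaults()
  t0 <- proc.time()[["elapsed"]]
  warns <- character(0)
  state <- withCallingHandlers(
    switch(name,
           simulate = stage_simulate(state),
           lrt = stage_lrt(state),
           sites = stage_sites(state),
           constraint = stage_constraint(state),
           introgression = stage_introgression(state),
           network = stage_network(state),
           modern = stage_modern(state)),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  elapsed <- proc.time()[["elapsed"]] - t0
  state$done[[name]] <- TRUE
  state$reports[[name]] <- new_report(name,
                                      state$counts$n_in %||% NA_integer_,
                                      state$counts$n_out %||% NA_integer_,
                                      warns, elapsed)
  state$counts <- NULL
  state
}

`%||%` <- function(a, b) if (is.null(a)) b else a

out_path <- function(state, file) {
  if (is.null(state$out_dir)) return(NULL)
  dir.create(state$out_dir, recursive = TRUE, showWarnings = FALSE)
  file.path(state$out_dir, file)
}

stage_simulate <- function(state) {
  if (is.null(state$config)) {
    stop("state$config (a sim_config) is required", call. = FALSE)
  }
  cohort <- simulate_cohort(state$config)
  state$cohort <- cohort
  state$counts <- list(n_in = state$config$n_genes,
                       n_out = nrow(cohort$snps))
  if (!is.null(state$out_dir)) {
    write_genes(cohort$genes,
                bed_path = out_path(state, "genes.bed"),
                tsv_path = out_path(state, "genes.tsv"))
    write_variants_vcf(cohort$snps, out_path(state, "variants.vcf"))
    write_hap_matrix(cohort$haplotype$matrix,
                     out_path(state, "haplotypes.tsv"))
    write_truth_json(cohort$truth, out_path(state, "truth.json"))
  }
  state
}

stage_lrt <- function(state) {
  p <- state$params
  lrt <- state$cohort$lrt
  res <- lrt_pvalue(lrt$lnl_null, lrt$lnl_alt, df = lrt$df[1])
  tab <- data.frame(gene_id = lrt$gene_id,
                    stat = res$stat, p_raw = res$p_raw,
                    stringsAsFactors = FALSE)
  tab$p_adj <- bh_adjust(tab$p_raw)
  tab$declared <- tab$p_adj < p$alpha
  state$lrt <- tab
  state$counts <- list(n_in = nrow(lrt), n_out = sum(tab$declared))
  if (!is.null(state$out_dir)) {
    write.table(tab, out_path(state, "lrt.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  state
}

stage_sites <- function(state) {
  p <- state$params
  ev <- state$cohort$site_evidence
  beb <- ev$branch[ev$branch$method == "BEB_branch", ]
  meme <- ev$branch[ev$branch$method == "MEME", ]
  branch_sites <- consensus_branch_sites(beb, meme,
                                         p$beb_cutoff, p$meme_cutoff)
  phylo_sites <- consensus_phylogeny_sites(ev$phylogeny,
                                           p$beb_cutoff, p$fubar_cutoff,
                                           p$rel_cutoff)
  state$sites <- list(branch = branch_sites, phylogeny = phylo_sites)
  state$counts <- list(n_in = nrow(ev$branch) + nrow(ev$phylogeny),
                       n_out = nrow(branch_sites) + nrow(phylo_sites))
  if (!is.null(state$out_dir)) {
    write.table(branch_sites, out_path(state, "sites_branch.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(phylo_sites, out_path(state, "sites_phylogeny.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  state
}

stage_constraint <- function(state) {
  p <- state$params
  genes <- state$cohort$genes
  constraint <- state$cohort$constraint
  modules <- genes[genes$module_label != "background", ]
  background <- genes[genes$module_label == "background", ]
  ref <- build_reference_set(modules, background, "gc_length", p$tolerance)
  f <- setNames(constraint$f, constraint$gene_id)
  cmp <- compare_focal_vs_matched(f[modules$gene_id], f[ref$reference_ids],
                                  method = "t_test")
  grp <- three_group_compare(constraint$f, constraint$module_label,
                             method = "anova_tukey")
  state$constraint <- list(reference = ref, matched_test = cmp,
                           three_group = grp)
  state$counts <- list(n_in = nrow(genes),
                       n_out = length(ref$reference_ids))
  if (!is.null(state$out_dir)) {
    write.table(ref$pairs, out_path(state, "matched_sets.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  state
}

stage_introgression <- function(state) {
  p <- state$params
  genes <- state$cohort$genes
  snps <- state$cohort$snps
  scores <- gene_introgression_scores(genes, snps, "EUR")
  scores$module_label <- genes$module_label[match(scores$gene_id,
                                                  genes$gene_id)]
  bg <- scores$score[scores$module_label == "background"]
  mod <- scores[scores$module_label != "background", ]
  outliers <- call_outlier_genes(mod, bg, p$q_outlier)
  archaic <- identify_archaic_snps(snps)
  thr <- percentile_threshold(bg[!is.na(bg)], p$q_outlier)
  reg_in <- snps[, c("snp_id", "gene_id", "chrom", "pos")]
  reg_in$is_archaic <- archaic$is_archaic
  reg_in$score <- snps$np_EUR
  regions <- define_introgressed_regions(reg_in, thr)
  state$introgression <- list(scores = scores, outliers = outliers,
                              archaic = archaic, regions = regions,
                              threshold = thr)
  state$counts <- list(n_in = nrow(snps), n_out = length(outliers))
  if (!is.null(state$out_dir)) {
    write.table(scores, out_path(state, "introgression_scores.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_regions_bed(regions, out_path(state, "introgressed_regions.bed"))
  }
  state
}

stage_network <- function(state) {
  haps <- collapse_haplotypes(state$cohort$haplotype$matrix)
  net <- build_mj_network(haps)
  state$network <- net
  state$counts <- list(n_in = nrow(state$cohort$haplotype$matrix),
                       n_out = nrow(net$nodes))
  if (!is.null(state$out_dir)) {
    export_network(net, out_path(state, "haplotype_network"))
  }
  state
}

stage_modern <- function(state) {
  p <- state$params
  snps <- state$cohort$snps
  calls <- filter_modern_specific(snps, p$freq_threshold)
  calls$chrom <- snps$chrom
  calls$pos <- snps$pos
  thr <- genome_s_threshold(snps$s_score, p$q_sweep)
  regions <- sweep_scan(snps, thr, p$min_span)
  calls <- annotate_in_sweep(calls, regions)
  state$modern <- list(calls = calls, regions = regions, s_threshold = thr)
  state$counts <- list(n_in = nrow(snps),
                       n_out = sum(calls$passes, na.rm = TRUE))
  if (!is.null(state$out_dir)) {
    write.table(calls, out_path(state, "modern_allele_calls.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_regions_bed(regions, out_path(state, "sweep_regions.bed"))
  }
  state
}

#' Run the full pipeline on a synthetic cohort
#'
#' Executes every stage in dependency order. All randomness flows from
#' `config$seed`; rerunning with the same configuration reproduces the
#' outputs byte for byte.
#'
#' @param config a [sim_config()].
#' @param out_dir optional output directory; when given, every stage
#'   writes its tables (TSV/BED/VCF/JSON).
#' @param params threshold list, see [pipeline_defaults()]; partial lists
#'   are completed with the defaults, unknown keys are rejected.
#' @param stages stages to run, in order (default: all).
#' @return final state list with per-stage outputs and `reports`.
#' @export
#' @examples
#' st <- run_pipeline(sim_config(seed = 1, n_genes = 6,
#'   n_background_genes = 60, n_chrom_per_pop = 20))
#' st$introgression$outliers
run_pipeline <- function(config = sim_config(), out_dir = NULL,
                         params = list(),
                         stages = names(stage_dependencies)) {
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown)) {
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  full <- utils::modifyList(defaults, params)
  state <- list(config = config, params = full, out_dir = out_dir,
                done = list(), reports = list())
  for (s in stages) state <- run_stage(s, state)
  state
}

#' Summarize stage reports as a data frame
#'
#' @param state pipeline state from [run_pipeline()].
#' @return `data.frame` with one row per executed stage.
#' @export
stage_report_table <- function(state) {
  do.call(rbind, lapply(state$reports, function(r) {
    data.frame(stage = r$stage, n_in = r$n_in, n_out = r$n_out,
               n_warnings = length(r$warnings), elapsed = r$elapsed,
               stringsAsFactors = FALSE)
  }))
}
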