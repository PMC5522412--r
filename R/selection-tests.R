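#' Likelihood-ratio test statistic and p-value for nested codon models
#'
#' Computes the statistic `2(lnL_alt - lnL_null)` (clamped at zero: a
#' better-fitting null yields a statistic of 0 and p = 1) and its upper-tail
#' probability under the central chi-square with `df` degrees of freedom.
#' Following the convention under which the published worked examples were
#' produced, the one-degree comparison of the neutral-boundary model against
#' the selection model uses a plain chi-square(1) tail, not a 50:50 mixture.
#'
#' @param lnl_null,lnl_alt log-likelihoods of the null and alternative
#'   model fits (vectorized).
#' @param df degrees of freedom of the comparison, 1 or 2.
#' @return `data.frame` with columns `stat` and `p_raw`.
#' @seealso [chisq_tail()] when the statistic itself is already in hand.
#' @export
#' @examples
#' lrt_pvalue(-1000, -997.6585, df = 1)  # stat 4.683, p ~ 3.05e-2
lrt_pvalue <- function(lnl_null, lnl_alt, df) {
  if (!all(df %in% c(1L, 2L))) stop("df must be 1 or 2", call. = FALSE)
  stat <- pmax(0, 2 * (lnl_alt - lnl_null))
  data.frame(stat = stat, p_raw = chisq_tail(stat, df))
}

#' Chi-square upper-tail probability of an LRT statistic
#'
#' @param stat statistic `2ΔlnL`, clamped below at 0.
#' @param df degrees of freedom, 1 or 2.
#' @return upper-tail probability; `stat = 0` gives exactly 1.
#' @export
#' @examples
#' chisq_tail(18.374, 2)  # ~ 1.02e-4
chisq_tail <- function(stat, df) {
  if (!all(df %in% c(1L, 2L))) stop("df must be 1 or 2", call. = FALSE)
  if (any(stat < 0)) stop("stat must be >= 0", call. = FALSE)
  pchisq(stat, df, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment within declared test families
#'
#' Step-up FDR adjustment. Because the grouping of tests into families is a
#' reporting decision, the family membership is explicit configuration: when
#' `family` is supplied, the adjustment is performed independently within
#' each family key, and input order is preserved.
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @param family optional vector (same length) of family keys.
#' @return adjusted p-values, same order as input; always `>=` the raw
#'   values and capped at 1.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
bh_adjust <- function(p, family = NULL) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(family)) {
    return(p.adjust(p, method = "BH"))
  }
  if (length(family) != length(p)) {
    stop("family must have the same length as p", call. = FALSE)
  }
  out <- numeric(length(p))
  for (key in unique(family)) {
    i <- which(family == key)
    out[i] <- p.adjust(p[i], method = "BH")
  }
  out
}

#' Declare branch-level positive selection for one gene and branch
#'
#' A branch test is declared positive only if the adjusted p-value falls
#' below `alpha` under BOTH codon-frequency parameterizations (F3X4 and
#' F61) — a single significant arm is not sufficient.
#'
#' @param results `data.frame` with columns `codon_freq`
#'   (values `"F3X4"` and `"F61"`, exactly one row each) and `p_adj`.
#' @param alpha significance level.
#' @return single logical.
#' @export
declare_branch_selection <- function(results, alpha = 0.05) {
  need <- c("F3X4", "F61")
  if (!all(need %in% results$codon_freq) ||
      any(table(results$codon_freq[results$codon_freq %in% need]) != 1L)) {
    stop("need exactly one F3X4 and one F61 result", call. = FALSE)
  }
  all(results$p_adj[match(need, results$codon_freq)] < alpha)
}

#' Declare site-model positive selection for one gene
#'
#' Requires rejection of both neutral site models (M7 and the
#' neutral-boundary model M8a) in favour of the selection model M8 under
#' both codon-frequency parameterizations: all four adjusted p-values must
#' fall below `alpha`.
#'
#' @param results `data.frame` with columns `test_id` (values `"M7_vs_M8"`,
#'   `"M8a_vs_M8"`), `codon_freq` (`"F3X4"`, `"F61"`) and `p_adj`; all four
#'   combinations must be present exactly once.
#' @param alpha significance level.
#' @return single logical.
#' @export
declare_site_model_selection <- function(results, alpha = 0.05) {
  key <- paste(results$test_id, results$codon_freq)
  need <- c("M7_vs_M8 F3X4", "M7_vs_M8 F61", "M8a_vs_M8 F3X4", "M8a_vs_M8 F61")
  if (!all(need %in% key) || anyDuplicated(key[key %in% need])) {
    stop("need all four test x codon-frequency arms exactly once",
         call. = FALSE)
  }
  all(results$p_adj[match(need, key)] < alpha)
}

#' Consensus positively selected sites on a branch (BEB x MEME)
#'
#' A codon is reported only when the Bayes-Empirical-Bayes posterior from
#' the branch-site model reaches `beb_cutoff` AND the MEME p-value at the
#' same codon is at most `meme_cutoff`. Codon indices are 1-based positions
#' in the human protein sequence.
#'
#' @param beb `data.frame` with `gene_id`, `codon_index`, `score`
#'   (posterior probability).
#' @param meme `data.frame` with `gene_id`, `codon_index`, `score`
#'   (p-value).
#' @param beb_cutoff posterior cutoff (default 0.90).
#' @param meme_cutoff p-value cutoff (default 0.1).
#' @return `data.frame` with `gene_id`, `codon_index`,
#'   `supporting_methods` (comma-joined).
#' @export
#' @examples
#' beb <- data.frame(gene_id = "g", codon_index = c(329, 500),
#'                   score = c(0.96, 0.95))
#' meme <- data.frame(gene_id = "g", codon_index = 329, score = 0.02)
#' consensus_branch_sites(beb, meme)$codon_index  # 329
consensus_branch_sites <- function(beb, meme, beb_cutoff = 0.90,
                                   meme_cutoff = 0.1) {
  gid <- unique(c(beb$gene_id, meme$gene_id))
  if (length(gid) > 1L) {
    stop("evidence tables mix gene ids: ", paste(gid, collapse = ", "),
         call. = FALSE)
  }
  assert_prob(beb$score, "BEB posterior")
  assert_prob(meme$score, "MEME p-value")
  hit_beb <- beb$codon_index[beb$score >= beb_cutoff]
  hit_meme <- meme$codon_index[meme$score <= meme_cutoff]
  codons <- sort(intersect(hit_beb, hit_meme))
  data.frame(gene_id = rep(gid, length(codons)),
             codon_index = codons,
             supporting_methods = rep("BEB_branch,MEME", length(codons)),
             stringsAsFactors = FALSE)
}

#' Consensus positively selected sites across a phylogeny (>= 2 methods)
#'
#' Evaluates per-codon evidence from the site-model BEB posterior
#' (`BEB_M8`, cutoff 0.90), FUBAR posterior (cutoff 0.90) and REL Bayes
#' factor (cutoff 50), and reports codons detected by at least two methods.
#'
#' @param evidence long `data.frame` with `gene_id`, `codon_index`,
#'   `method` (one of `"BEB_M8"`, `"FUBAR"`, `"REL"`), `score`.
#' @param beb_cutoff,fubar_cutoff posterior cutoffs (default 0.90).
#' @param rel_cutoff Bayes-factor cutoff (default 50).
#' @return `data.frame` with `gene_id`, `codon_index`, `n_methods`,
#'   `supporting_methods` (comma-joined, alphabetical).
#' @export
consensus_phylogeny_sites <- function(evidence, beb_cutoff = 0.90,
                                      fubar_cutoff = 0.90, rel_cutoff = 50) {
  known <- c("BEB_M8", "FUBAR", "REL")
  bad <- setdiff(unique(evidence$method), known)
  if (length(bad)) {
    stop("unknown method label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  gid <- unique(evidence$gene_id)
  if (length(gid) > 1L) {
    stop("evidence table mixes gene ids", call. = FALSE)
  }
  cutoff <- c(BEB_M8 = beb_cutoff, FUBAR = fubar_cutoff, REL = rel_cutoff)
  pass <- evidence[evidence$score >= cutoff[evidence$method], ,
                   drop = FALSE]
  if (nrow(pass) == 0L) {
    return(data.frame(gene_id = character(0), codon_index = integer(0),
                      n_methods = integer(0),
                      supporting_methods = character(0),
                      stringsAsFactors = FALSE))
  }
  by_codon <- split(pass$method, pass$codon_index)
  supp <- lapply(by_codon, function(m) sort(unique(m)))
  keep <- vapply(supp, length, 0L) >= 2L
  codons <- as.integer(names(by_codon))[keep]
  o <- order(codons)
  data.frame(gene_id = rep(gid, sum(keep)),
             codon_index = codons[o],
             n_methods = vapply(supp[keep], length, 0L)[o],
             supporting_methods = vapply(supp[keep], paste,
                                         collapse = ",", "")[o],
             stringsAsFactors = FALSE)
}

#' Filter lineage-specific positively selected sites
#'
#' Keeps sites whose posterior probability of a population-scaled selection
#' coefficient of at least 1 is strictly greater than `cutoff` — a site at
#' exactly the cutoff is dropped.
#'
#' @param records `data.frame` with at least `pr_gamma_ge_1` in `[0, 1]`.
#' @param cutoff posterior cutoff (default 0.75).
#' @return the filtered `data.frame`.
#' @export
#' @examples
#' d <- data.frame(pr_gamma_ge_1 = c(0.901, 0.752, 0.75))
#' nrow(lineage_selected_sites(d))  # 2
lineage_selected_sites <- function(records, cutoff = 0.75) {
  assert_prob(records$pr_gamma_ge_1, "pr_gamma_ge_1")
  records[!is.na(records$pr_gamma_ge_1) & records$pr_gamma_ge_1 > cutoff, ,
          drop = FALSE]
}

#' Fraction of a module's genes with declared positive selection
#'
#' A gene counts once if declared on at least one branch. The result is a
#' percentage reported to one decimal, as in module summaries such as
#' "8/47 (17.0%)".
#'
#' @param declared logical vector of per-gene declarations (or a single
#'   integer count).
#' @param module_size number of genes in the module, `>= 1`.
#' @return percentage rounded to one decimal.
#' @export
#' @examples
#' module_selection_fraction(8L, 47L)   # 17.0
#' module_selection_fraction(6L, 21L)   # 28.6
module_selection_fraction <- function(declared, module_size) {
  if (module_size < 1L) stop("module_size must be >= 1", call. = FALSE)
  n <- if (is.logical(declared)) sum(declared) else as.integer(declared)
  round(100 * n / module_size, 1)
}

#' Per-gene, per-branch declarations from a table of branch LRT outcomes
#'
#' Convenience wrapper applying [declare_branch_selection()] to every
#' gene x branch group of a long results table.
#'
#' @param results `data.frame` with columns `gene_id`, `branch`,
#'   `codon_freq`, `p_adj`.
#' @param alpha significance level.
#' @return `data.frame` with `gene_id`, `branch`, `declared`.
#' @export
declare_branch_table <- function(results, alpha = 0.05) {
  key <- interaction(results$gene_id, results$branch, drop = TRUE)
  groups <- split(results, key)
  out <- do.call(rbind, lapply(groups, function(g) {
    data.frame(gene_id = g$gene_id[1], branch = g$branch[1],
               declared = declare_branch_selection(g, alpha),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$gene_id, out$branch), , drop = FALSE]
}
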