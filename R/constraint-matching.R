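#' Find background genes matched to a focal gene within a relative tolerance
#'
#' A candidate matches when, for EVERY feature of the chosen mode, its
#' relative deviation from the focal gene is at most `tolerance` (default
#' +/-10%). `"gc_length"` matches jointly on GC fraction and CDS length;
#' `"gerp"` matches on the mean GERP conservation score. Matching is
#' reflexive: a gene always matches itself.
#'
#' @param focal single-row `data.frame` (or list) with the feature columns
#'   `gc_fraction`, `cds_length`, `gerp_score`.
#' @param candidates `data.frame` of candidate genes with the same columns
#'   plus `gene_id`.
#' @param features matching mode, `"gc_length"` or `"gerp"`.
#' @param tolerance maximum relative deviation per feature.
#' @return character vector of matched `gene_id`s.
#' @export
#' @examples
#' focal <- data.frame(gene_id = "f", gc_fraction = 0.45, cds_length = 1000,
#'                     gerp_score = 2)
#' cand <- data.frame(gene_id = c("a", "b"),
#'                    gc_fraction = c(0.46, 0.40), cds_length = c(1080, 1000),
#'                    gerp_score = c(2, 2))
#' match_genes(focal, cand, "gc_length")  # "a"
match_genes <- function(focal, candidates, features = c("gc_length", "gerp"),
                        tolerance = 0.10) {
  features <- match.arg(features)
  cols <- switch(features,
                 gc_length = c("gc_fraction", "cds_length"),
                 gerp = "gerp_score")
  ok <- rep(TRUE, nrow(candidates))
  for (cl in cols) {
    fv <- as.numeric(focal[[cl]])
    if (length(fv) != 1L || is.na(fv)) {
      stop("focal gene must carry a single non-missing value for ", cl,
           call. = FALSE)
    }
    if (fv == 0) {
      stop("focal feature ", cl, " is zero; relative tolerance is undefined",
           call. = FALSE)
    }
    ok <- ok & abs(candidates[[cl]] - fv) / abs(fv) <= tolerance
  }
  candidates$gene_id[ok]
}

#' Build the matched reference set for a module
#'
#' For each focal (module) gene, collects all candidate genes within the
#' feature tolerance and returns the deduplicated union, with per-focal
#' provenance and the list of focal genes that found no match.
#'
#' @param module_genes `data.frame` of focal genes (feature columns as in
#'   [match_genes()]).
#' @param candidates `data.frame` of candidate background genes; module
#'   genes present in the pool are removed before matching.
#' @param features,tolerance passed to [match_genes()].
#' @return list with `reference_ids` (character union), `pairs`
#'   (`data.frame` `focal_id`, `matched_id`) and `unmatched` (focal ids with
#'   zero matches; also raised as a warning).
#' @export
build_reference_set <- function(module_genes, candidates,
                                features = c("gc_length", "gerp"),
                                tolerance = 0.10) {
  features <- match.arg(features)
  candidates <- candidates[!candidates$gene_id %in% module_genes$gene_id, ,
                           drop = FALSE]
  if (nrow(candidates) == 0L) {
    stop("candidate pool is empty after excluding module genes",
         call. = FALSE)
  }
  pairs <- vector("list", nrow(module_genes))
  for (i in seq_len(nrow(module_genes))) {
    m <- match_genes(module_genes[i, ], candidates, features, tolerance)
    if (length(m)) {
      pairs[[i]] <- data.frame(focal_id = module_genes$gene_id[i],
                               matched_id = m, stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs)) {
    pairs <- data.frame(focal_id = character(0), matched_id = character(0),
                        stringsAsFactors = FALSE)
  }
  unmatched <- setdiff(module_genes$gene_id, pairs$focal_id)
  if (length(unmatched)) {
    warning("no matched background gene for: ",
            paste(unmatched, collapse = ", "), call. = FALSE)
  }
  list(reference_ids = unique(pairs$matched_id),
       pairs = pairs,
       unmatched = unmatched)
}

#' Compare constraint between a focal group and its matched reference set
#'
#' Two-sided two-sample location test of f values, by Student's t test or
#' the Wilcoxon rank-sum test (the two conventions used for matched-set
#' comparisons).
#'
#' @param f_focal,f_matched numeric vectors of f values, each of length
#'   `>= 2`.
#' @param method `"t_test"` or `"rank_sum"`.
#' @return list with `statistic`, `p_value`, `method`, group sizes.
#' @export
compare_focal_vs_matched <- function(f_focal, f_matched,
                                     method = c("t_test", "rank_sum")) {
  method <- match.arg(method)
  if (length(f_focal) < 2L || length(f_matched) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  ht <- switch(method,
               t_test = t.test(f_focal, f_matched),
               rank_sum = wilcox.test(f_focal, f_matched, exact = FALSE))
  list(statistic = unname(ht$statistic),
       p_value = ht$p.value,
       method = method,
       n_focal = length(f_focal),
       n_matched = length(f_matched))
}

#' Omnibus and post-hoc comparison of three gene groups
#'
#' Compares a value (f or an introgression score) across three groups by
#' either one-way ANOVA with Tukey's post-hoc test, or a Kruskal-Wallis
#' test with Nemenyi's post-hoc test on mean ranks (studentized-range
#' approximation with infinite degrees of freedom, appropriate for
#' continuous scores without heavy ties).
#'
#' @param values numeric vector.
#' @param groups factor or character vector of group labels (exactly three
#'   non-empty groups).
#' @param method `"anova_tukey"` or `"kruskal_nemenyi"`.
#' @return list with `omnibus_statistic`, `omnibus_p`, `pairwise`
#'   (`data.frame` `group1`, `group2`, `p_adj`) and `method`.
#' @export
three_group_compare <- function(values, groups,
                                method = c("anova_tukey", "kruskal_nemenyi")) {
  method <- match.arg(method)
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) != 3L || any(table(groups) == 0L)) {
    stop("exactly three non-empty groups are required", call. = FALSE)
  }
  if (method == "anova_tukey") {
    fit <- aov(values ~ groups)
    s <- summary(fit)[[1]]
    tk <- TukeyHSD(fit)$groups
    cmp <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
    pairwise <- data.frame(group1 = cmp[, 1], group2 = cmp[, 2],
                           p_adj = unname(tk[, "p adj"]),
                           stringsAsFactors = FALSE)
    list(omnibus_statistic = s[["F value"]][1],
         omnibus_p = s[["Pr(>F)"]][1],
         pairwise = pairwise, method = method)
  } else {
    kw <- kruskal.test(values, groups)
    r <- rank(values)
    n_i <- tapply(values, groups, length)
    rbar <- tapply(r, groups, mean)
    N <- length(values)
    lev <- levels(groups)
    combs <- utils::combn(lev, 2)
    p_adj <- numeric(ncol(combs))
    for (j in seq_len(ncol(combs))) {
      a <- combs[1, j]; b <- combs[2, j]
      se <- sqrt(N * (N + 1) / 12 * (1 / n_i[[a]] + 1 / n_i[[b]]))
      q <- abs(rbar[[a]] - rbar[[b]]) / se * sqrt(2)
      p_adj[j] <- ptukey(q, nmeans = 3, df = Inf, lower.tail = FALSE)
    }
    list(omnibus_statistic = unname(kw$statistic),
         omnibus_p = kw$p.value,
         pairwise = data.frame(group1 = combs[1, ], group2 = combs[2, ],
                               p_adj = p_adj, stringsAsFactors = FALSE),
         method = method)
  }
}
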