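# Independent oracles used to cross-check package implementations.
# Each is a direct transcription of the defining rule, kept deliberately
# naive (loops, exhaustive enumeration) and separate from package code.

# Benjamini-Hochberg by definition: adj_i = min over j with rank_j >= rank_i
# of p_(j) * n / j, capped at 1
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj_sorted <- numeric(n)
  for (i in seq_len(n)) {
    adj_sorted[i] <- min(1, min(p[o][i:n] * n / (i:n)))
  }
  adj <- numeric(n)
  adj[o] <- adj_sorted
  adj
}

# sweep regions by exhaustive sub-interval enumeration: a region is a run
# [i, j] of consecutive SNPs on one chromosome, all below threshold,
# maximal, with pos_j - pos_i >= min_span
sweep_oracle <- function(snps, threshold, min_span) {
  out <- NULL
  for (ch in unique(snps$chrom)) {
    s <- snps[snps$chrom == ch, , drop = FALSE]
    n <- nrow(s)
    below <- !is.na(s$s_score) & s$s_score < threshold
    for (i in seq_len(n)) {
      for (j in i:n) {
        if (!all(below[i:j])) next
        left_ok <- i == 1 || !below[i - 1]
        right_ok <- j == n || !below[j + 1]
        if (left_ok && right_ok && s$pos[j] - s$pos[i] >= min_span) {
          out <- rbind(out, data.frame(chrom = ch, start = s$pos[i],
                                       end = s$pos[j] + 1L,
                                       n_snps = j - i + 1L))
        }
      }
    }
  }
  if (is.null(out)) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_snps = integer(0))
  }
  rownames(out) <- NULL
  out
}

# introgressed regions by enumeration of maximal qualifying runs
region_oracle <- function(snps, threshold, max_gap = Inf) {
  qual <- !is.na(snps$is_archaic) & snps$is_archaic & snps$score > threshold
  out <- NULL
  groups <- if (!is.null(snps$gene_id)) {
    paste(snps$chrom, snps$gene_id)
  } else {
    snps$chrom
  }
  for (g in unique(groups)) {
    s <- snps[groups == g & qual, , drop = FALSE]
    if (nrow(s) == 0) next
    run_start <- 1
    for (k in seq_len(nrow(s))) {
      close_run <- k == nrow(s) ||
        s$pos[k + 1] - s$pos[k] > max_gap
      if (close_run) {
        idx <- run_start:k
        out <- rbind(out, data.frame(chrom = s$chrom[1],
                                     start = s$pos[idx[1]],
                                     end = s$pos[idx[length(idx)]] + 1L,
                                     n_snps = length(idx)))
        run_start <- k + 1
      }
    }
  }
  if (is.null(out)) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_snps = integer(0))
  }
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

# naive Prim MST total weight over binary sequences (independent of the
# package's Kruskal implementation)
prim_cost <- function(seqs) {
  n <- nrow(seqs)
  if (n <= 1) return(0)
  d <- as.matrix(dist(seqs, method = "manhattan"))
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  cost <- 0
  while (!all(in_tree)) {
    best <- Inf
    bj <- NA
    for (j in which(!in_tree)) {
      w <- min(d[in_tree, j])
      if (w < best) { best <- w; bj <- j }
    }
    in_tree[bj] <- TRUE
    cost <- cost + best
  }
  cost
}

# exhaustive Steiner search: minimal MST cost over observed sequences plus
# any subset of at most `max_extra` auxiliary binary vectors
steiner_oracle <- function(obs, max_extra = 2) {
  L <- ncol(obs)
  all_vec <- as.matrix(expand.grid(rep(list(0:1), L)))
  colnames(all_vec) <- NULL
  best <- prim_cost(obs)
  if (max_extra >= 1) {
    for (i in seq_len(nrow(all_vec))) {
      best <- min(best, prim_cost(rbind(obs, all_vec[i, ])))
    }
  }
  if (max_extra >= 2) {
    for (i in seq_len(nrow(all_vec) - 1)) {
      for (j in (i + 1):nrow(all_vec)) {
        best <- min(best, prim_cost(rbind(obs, all_vec[i, ],
                                          all_vec[j, ])))
      }
    }
  }
  best
}

# all-pairs matched-set filter by direct arithmetic
match_oracle <- function(focal, candidates, cols, tol = 0.10) {
  ok <- rep(TRUE, nrow(candidates))
  for (cl in cols) {
    ok <- ok & abs(candidates[[cl]] - focal[[cl]]) / abs(focal[[cl]]) <= tol
  }
  candidates$gene_id[ok]
}

# a small cohort configuration shared across tests (kept modest so the
# default suite stays fast)
small_config <- function(seed = 1, ...) {
  sim_config(seed = seed, n_genes = 8, n_background_genes = 80,
             n_chrom_per_pop = 30, ...)
}
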