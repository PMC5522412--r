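#' Collapse a phased haplotype matrix into distinct haplotypes
#'
#' Rows (chromosomes, including archaic samples such as `ALTAI` and
#' `DENISOVA`) with identical 0/1 site states are merged; carriers and
#' counts are recorded. Rows containing missing sites are excluded rather
#' than imputed, and the exclusions are reported.
#'
#' @param mat matrix of site states (rows = chromosomes, columns = SNPs)
#'   with entries 0, 1 or `NA`; rows must be labelled.
#' @param labels optional row labels (defaults to `rownames(mat)`).
#' @return object of class `hap_set`: list with `seqs` (haplotypes x sites
#'   0/1 matrix), `count`, `carriers` (list of chromosome labels),
#'   `is_median` (all `FALSE` for observed haplotypes) and `excluded`
#'   (labels of dropped rows).
#' @export
#' @examples
#' m <- rbind(a = c(0, 0), b = c(0, 0), c = c(1, 1))
#' h <- collapse_haplotypes(m)
#' h$count  # 2 1
collapse_haplotypes <- function(mat, labels = rownames(mat)) {
  mat <- as.matrix(mat)
  if (is.null(labels)) stop("rows must be labelled", call. = FALSE)
  if (!all(mat %in% c(0L, 1L, NA))) {
    stop("matrix entries must be 0, 1 or NA", call. = FALSE)
  }
  complete <- rowSums(is.na(mat)) == 0L
  excluded <- labels[!complete]
  if (length(excluded)) {
    message(length(excluded), " chromosome(s) with missing sites excluded: ",
            paste(utils::head(excluded, 5), collapse = ", "))
  }
  mat <- mat[complete, , drop = FALSE]
  labels <- labels[complete]
  if (nrow(mat) == 0L) stop("no complete haplotype rows", call. = FALSE)
  key <- apply(mat, 1, paste, collapse = "")
  ord <- sort(unique(key))
  seqs <- do.call(rbind, lapply(ord, function(k) {
    mat[match(k, key), , drop = TRUE]
  }))
  if (is.null(dim(seqs))) seqs <- matrix(seqs, nrow = length(ord))
  rownames(seqs) <- paste0("H", seq_along(ord))
  carriers <- lapply(ord, function(k) labels[key == k])
  structure(list(seqs = seqs,
                 count = vapply(carriers, length, 0L),
                 carriers = carriers,
                 is_median = rep(FALSE, length(ord)),
                 excluded = excluded),
            class = "hap_set")
}

#' @export
print.hap_set <- function(x, ...) {
  cat(sprintf("%d haplotype(s) over %d site(s); counts: %s\n",
              nrow(x$seqs), ncol(x$seqs),
              paste(x$count, collapse = ", ")))
  invisible(x)
}

hamming <- function(a, b) sum(a != b)

hamming_matrix <- function(seqs) {
  n <- nrow(seqs)
  d <- matrix(0L, n, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        d[i, j] <- d[j, i] <- hamming(seqs[i, ], seqs[j, ])
      }
    }
  }
  d
}

seq_key <- function(seqs) apply(seqs, 1, paste, collapse = "")

# deterministic Kruskal MST: edges sorted by (weight, lexicographic node
# keys) so the returned tree is canonical for a given node set
mst_edges <- function(d, keys) {
  n <- nrow(d)
  if (n == 1L) {
    return(data.frame(from = integer(0), to = integer(0),
                      weight = integer(0)))
  }
  idx <- which(upper.tri(d), arr.ind = TRUE)
  e <- data.frame(from = idx[, 1], to = idx[, 2],
                  weight = d[idx])
  ka <- pmin(keys[e$from], keys[e$to])
  kb <- pmax(keys[e$from], keys[e$to])
  e <- e[order(e$weight, ka, kb), , drop = FALSE]
  comp <- seq_len(n)
  keep <- logical(nrow(e))
  for (i in seq_len(nrow(e))) {
    ca <- comp[e$from[i]]; cb <- comp[e$to[i]]
    if (ca != cb) {
      keep[i] <- TRUE
      comp[comp == cb] <- ca
    }
  }
  out <- e[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

mst_cost <- function(seqs) {
  sum(mst_edges(hamming_matrix(seqs), seq_key(seqs))$weight)
}

# feasible links of the minimum spanning network at tolerance epsilon:
# edge (u, v) is feasible iff u and v lie in different components of the
# graph restricted to edges strictly cheaper than d(u, v) - epsilon
msn_links <- function(d, epsilon = 0) {
  n <- nrow(d)
  feas <- matrix(FALSE, n, n)
  if (n < 2L) return(feas)
  ws <- sort(unique(d[upper.tri(d)]))
  for (w in ws) {
    comp <- seq_len(n)
    sub <- which(d < w - epsilon & upper.tri(d), arr.ind = TRUE)
    if (nrow(sub)) {
      for (i in seq_len(nrow(sub))) {
        ca <- comp[sub[i, 1]]; cb <- comp[sub[i, 2]]
        if (ca != cb) comp[comp == cb] <- ca
      }
    }
    at_w <- which(d == w & upper.tri(d), arr.ind = TRUE)
    for (i in seq_len(nrow(at_w))) {
      u <- at_w[i, 1]; v <- at_w[i, 2]
      if (comp[u] != comp[v]) feas[u, v] <- feas[v, u] <- TRUE
    }
  }
  feas
}

#' Build a median-joining haplotype network
#'
#' Reconstructs the haplotype genealogy of binary (ancestral/derived)
#' sequences in the median-joining spirit: starting from the observed
#' haplotypes, median (consensus) vectors of triplets linked in the minimum
#' spanning network are added greedily whenever they reduce the total
#' connection cost, obsolete medians are pruned, and the emitted edge set is
#' the canonical minimum spanning tree over the final node set (with
#' `epsilon = 0` this is the sparsest connected network; tie-breaking is
#' lexicographic on sequence strings, so the output is deterministic and
#' independent of input order).
#'
#' @param haps a `hap_set` from [collapse_haplotypes()], or a 0/1 matrix of
#'   haplotypes (rows) by sites (columns).
#' @param epsilon tolerance of the minimum-spanning-network feasibility
#'   rule (default 0).
#' @return object of class `hap_network`: list with `nodes` (`data.frame`
#'   `node_id`, `seq`, `count`, `is_median` plus a `carriers` list column)
#'   and `edges` (`data.frame` `from`, `to`, `weight`, node ids; weights are
#'   Hamming distances `>= 1`).
#' @export
#' @examples
#' m <- rbind(a = c(0, 0, 0), b = c(0, 1, 1), c = c(1, 0, 1))
#' net <- build_mj_network(collapse_haplotypes(m))
#' sum(net$edges$weight)  # 3, via the inferred median 001
build_mj_network <- function(haps, epsilon = 0) {
  if (is.matrix(haps)) {
    obs <- haps
    count <- rep(1L, nrow(obs))
    carriers <- lapply(rownames(obs), function(x) x)
  } else if (inherits(haps, "hap_set")) {
    obs <- haps$seqs
    count <- haps$count
    carriers <- haps$carriers
  } else {
    stop("haps must be a hap_set or a 0/1 matrix", call. = FALSE)
  }
  if (nrow(obs) == 0L) stop("need at least one haplotype", call. = FALSE)
  storage.mode(obs) <- "integer"
  n_obs <- nrow(obs)
  seqs <- obs
  is_median <- rep(FALSE, n_obs)

  repeat {
    d <- hamming_matrix(seqs)
    keys <- seq_key(seqs)
    cur_cost <- sum(mst_edges(d, keys)$weight)
    feas <- msn_links(d, epsilon)
    n <- nrow(seqs)
    cand <- character(0)
    if (n >= 3L) {
      trip <- utils::combn(n, 3)
      for (j in seq_len(ncol(trip))) {
        u <- trip[1, j]; v <- trip[2, j]; w <- trip[3, j]
        n_links <- feas[u, v] + feas[u, w] + feas[v, w]
        if (n_links >= 2L) {
          med <- as.integer((seqs[u, ] + seqs[v, ] + seqs[w, ]) >= 2L)
          cand <- c(cand, paste(med, collapse = ""))
        }
      }
    }
    cand <- sort(setdiff(unique(cand), keys))
    if (length(cand) == 0L) break
    # candidates are pre-sorted, so the first minimum wins ties
    # lexicographically and the construction is deterministic
    best_key <- NULL
    best_cost <- cur_cost
    for (k in cand) {
      med <- as.integer(strsplit(k, "")[[1]])
      new_cost <- mst_cost(rbind(seqs, med))
      if (new_cost < best_cost) {
        best_cost <- new_cost
        best_key <- k
      }
    }
    if (is.null(best_key)) break
    seqs <- rbind(seqs, as.integer(strsplit(best_key, "")[[1]]))
    is_median <- c(is_median, TRUE)
  }

  # prune obsolete medians: a median whose removal does not raise the cost
  repeat {
    removed <- FALSE
    med_idx <- which(is_median)
    keys <- seq_key(seqs)
    for (i in med_idx[order(keys[med_idx])]) {
      cost_with <- mst_cost(seqs)
      cost_without <- mst_cost(seqs[-i, , drop = FALSE])
      if (cost_without <= cost_with) {
        seqs <- seqs[-i, , drop = FALSE]
        is_median <- is_median[-i]
        removed <- TRUE
        break
      }
    }
    if (!removed) break
  }

  # canonical node order: observed first (by sequence string), then medians
  keys <- seq_key(seqs)
  obs_keys <- seq_key(obs)
  ord <- c(order(keys)[!is_median[order(keys)]],
           order(keys)[is_median[order(keys)]])
  seqs <- seqs[ord, , drop = FALSE]
  is_median <- is_median[ord]
  keys <- keys[ord]
  node_count <- integer(length(keys))
  node_carriers <- vector("list", length(keys))
  for (i in seq_along(keys)) {
    if (is_median[i]) {
      node_count[i] <- 0L
      node_carriers[[i]] <- character(0)
    } else {
      j <- match(keys[i], obs_keys)
      node_count[i] <- count[j]
      node_carriers[[i]] <- carriers[[j]]
    }
  }
  nodes <- data.frame(node_id = paste0("N", seq_along(keys)),
                      seq = keys,
                      count = node_count,
                      is_median = is_median,
                      stringsAsFactors = FALSE)
  nodes$carriers <- node_carriers
  ed <- mst_edges(hamming_matrix(seqs), keys)
  edges <- data.frame(from = nodes$node_id[ed$from],
                      to = nodes$node_id[ed$to],
                      weight = ed$weight,
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges), class = "hap_network")
}

#' @export
print.hap_network <- function(x, ...) {
  cat(sprintf("Haplotype network: %d node(s) (%d median), %d edge(s), total cost %d\n",
              nrow(x$nodes), sum(x$nodes$is_median), nrow(x$edges),
              sum(x$edges$weight)))
  invisible(x)
}

#' Export a haplotype network to plain-text files
#'
#' Writes a node table (`node_id`, `seq`, `count`, `is_median`, carriers
#' semicolon-joined) and an edge-list table (`from`, `to`, `weight`), both
#' TSV. The pair round-trips losslessly through [read_network()].
#'
#' @param network a `hap_network`.
#' @param path output path prefix; `<path>.nodes.tsv` and
#'   `<path>.edges.tsv` are written.
#' @return invisibly, the two file paths.
#' @export
export_network <- function(network, path) {
  stopifnot(inherits(network, "hap_network"))
  bad <- !network$nodes$is_median &
    vapply(network$nodes$carriers, length, 0L) == 0L
  if (any(bad)) {
    stop("observed node(s) without carriers violate the network invariant",
         call. = FALSE)
  }
  nodes <- network$nodes
  nodes$carriers <- vapply(nodes$carriers, paste, collapse = ";", "")
  nf <- paste0(path, ".nodes.tsv")
  ef <- paste0(path, ".edges.tsv")
  write.table(nodes, nf, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(network$edges, ef, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(nodes = nf, edges = ef))
}

#' Read a haplotype network written by [export_network()]
#'
#' @param path the path prefix used at export time.
#' @return a `hap_network`.
#' @export
read_network <- function(path) {
  nodes <- read.delim(paste0(path, ".nodes.tsv"), sep = "\t",
                      colClasses = c(seq = "character"))
  edges <- read.delim(paste0(path, ".edges.tsv"), sep = "\t")
  carriers <- strsplit(ifelse(is.na(nodes$carriers), "", nodes$carriers), ";",
                       fixed = TRUE)
  nodes$carriers <- lapply(carriers, function(x) x[nzchar(x)])
  nodes$is_median <- as.logical(nodes$is_median)
  structure(list(nodes = nodes, edges = edges), class = "hap_network")
}
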