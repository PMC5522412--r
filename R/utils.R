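#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `expr` and restores the previous
#' RNG state afterwards, so library code never clobbers the caller's stream.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Derive a deterministic child seed from a root seed and a stage label
#'
#' One root seed drives the whole simulation; each stage mixes its label into
#' the root so adding a stage never perturbs the draws of earlier stages.
#' The result is always a valid positive 32-bit integer seed.
#'
#' @param seed root integer seed.
#' @param label character stage label.
#' @return single integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "genes") != derive_seed(1, "snps")
derive_seed <- function(seed, label) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(label))
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- as.numeric(seed) %% m
  for (k in utf8ToInt(label)) {
    h <- (h * 31 + k) %% m
  }
  as.integer(h %% (m - 1)) + 1L
}

# shared linear-interpolation quantile (R type 7), the convention used for
# every percentile threshold in the package
quantile_linear <- function(x, q) {
  if (length(x) == 0L || all(is.na(x))) {
    stop("cannot take a percentile of an empty score list", call. = FALSE)
  }
  if (q <= 0 || q >= 100) stop("percentile must be in (0, 100)", call. = FALSE)
  unname(stats::quantile(x, probs = q / 100, na.rm = TRUE, type = 7))
}

assert_prob <- function(x, what) {
  bad <- !is.na(x) & (x < 0 | x > 1)
  if (any(bad)) {
    stop(sprintf("%s must lie in [0, 1]; offending value(s): %s",
                 what, paste(utils::head(x[bad], 3), collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

# rows of `snps` with positions sorted within chromosome, error otherwise
assert_sorted <- function(snps) {
  for (ch in unique(snps$chrom)) {
    p <- snps$pos[snps$chrom == ch]
    if (is.unsorted(p)) {
      stop("SNPs must be sorted by position within each chromosome",
           call. = FALSE)
    }
  }
  invisible(snps)
}
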