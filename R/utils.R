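# Internal helpers shared across modules.

#' Derive a reproducible child seed from a master seed and a string key
#'
#' A stable polynomial hash over the key is folded into the master seed so
#' that per-(condition, replicate) random streams are independent of the
#' order in which they are drawn: adding a replicate never perturbs the
#' fragments of an existing one.
#'
#' @param seed master integer seed
#' @param key character key, e.g. "AcG2:2"
#' @return an integer in [0, 2^31 - 2]
#' @keywords internal
stream_seed <- function(seed, key) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  m <- 2147483647  # 2^31 - 1, keeps derived seeds valid R integers
  h <- as.numeric(seed) %% m
  for (c in utf8ToInt(as.character(key))) {
    h <- (h * 31 + c) %% m
  }
  as.integer(h)
}

#' Evaluate an expression under a local RNG state
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Convert a 0-based half-open interval data.frame (chrom, start, end) to
# GRanges (1-based closed) and back. All package-internal coordinates are
# 0-based half-open; GRanges is used only as an overlap engine.
df_to_gr <- function(df, seqlengths = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
  if (!is.null(seqlengths)) {
    GenomicRanges::seqlengths(gr) <- seqlengths[as.character(GenomicRanges::seqlevels(gr))]
  }
  gr
}

gr_to_df <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Thin wrapper over [stats::p.adjust()] so the step-up procedure used for
#' every q-value in the pipeline has a single, testable entry point.
#'
#' @param p numeric vector of p-values
#' @return adjusted p-values (q-values), same length
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' Upper-tail Fisher/hypergeometric enrichment test on a 2x2 table
#'
#' Tests over-representation of a gene set intersection: given `k` successes
#' in a draw of `n` from a universe of `N` containing `K` successes, returns
#' the exact upper tail P(X >= k) and the sample odds ratio of the implied
#' 2x2 table `[[k, n-k], [K-k, N-K-n+k]]`.
#'
#' @param k overlap count
#' @param n drawn set size
#' @param K number of successes in the universe
#' @param N universe size
#' @return list with `p` (exact upper-tail probability), `odds_ratio`
#'   (sample odds ratio; `Inf` when a complementary cell is zero) and
#'   `odds_ratio_haldane` (Haldane-Anscombe corrected: +0.5 per cell,
#'   always finite)
#' @export
fisher_enrichment <- function(k, n, K, N) {
  stopifnot(k >= 0, k <= n, k <= K, n <= N, K <= N)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  a <- k; b <- n - k; c <- K - k; d <- N - K - n + k
  or <- (a * d) / (b * c)
  or_h <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  list(p = p, odds_ratio = or, odds_ratio_haldane = or_h,
       table = matrix(c(a, c, b, d), 2, 2))
}

# stop() with the calling function's name stripped, for cleaner errors
abort <- function(...) stop(..., call. = FALSE)
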