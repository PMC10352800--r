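# Fragment filtering, binned coverage, and Poisson local-background peak
# calling of DNase I hypersensitive sites with Benjamini-Hochberg q-value
# control, plus coverage QC (metaprofiles, replicate correlation) and
# peak-overlap statistics.

#' Filter fragments by maximum length
#'
#' Retains exactly the records with `end - start <= max_len` (125 bp by
#' default: the sub-nucleosomal fraction used for DHS peak calling),
#' preserving input order.
#'
#' @param frags fragment data.frame (chrom, start, end)
#' @param max_len maximum fragment length in bp
#' @return filtered fragment data.frame
#' @export
filter_fragments <- function(frags, max_len = 125) {
  keep <- (frags$end - frags$start) <= max_len
  out <- frags[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Binned fragment-midpoint coverage
#'
#' Counts fragment midpoints per fixed-width bin (10 bp by default). The sum
#' over all bins equals the number of fragments.
#'
#' @param frags fragment data.frame (chrom, start, end)
#' @param seqlengths named vector of chromosome lengths (bp)
#' @param bin bin width in bp
#' @return list chrom -> integer vector of per-bin counts, with attributes
#'   `bin` and `n_fragments`
#' @export
fragment_coverage <- function(frags, seqlengths, bin = 10) {
  if (bin <= 0) abort("bin size must be > 0")
  unknown <- setdiff(unique(frags$chrom), names(seqlengths))
  if (length(unknown))
    abort("fragments on unknown chromosomes: ", paste(unknown, collapse = ", "))
  track <- lapply(stats::setNames(names(seqlengths), names(seqlengths)), function(ch) {
    nb <- ceiling(seqlengths[[ch]] / bin)
    f <- frags[frags$chrom == ch, , drop = FALSE]
    if (nrow(f) == 0) return(integer(nb))
    mid <- floor((f$start + f$end) / 2)
    idx <- pmin(nb, floor(mid / bin) + 1L)
    tabulate(idx, nbins = nb)
  })
  attr(track, "bin") <- as.integer(bin)
  attr(track, "n_fragments") <- nrow(frags)
  class(track) <- "coverage_track"
  track
}

#' Upper-tail Poisson probability P(X >= count)
#'
#' The significance measure of the peak-calling scan: the probability of
#' observing at least `count` fragment midpoints in a window under a local
#' Poisson background with mean `lambda`.
#'
#' @param count observed window count
#' @param lambda background mean
#' @return upper-tail probability
#' @export
poisson_tail <- function(count, lambda) {
  stats::ppois(count - 1, lambda, lower.tail = FALSE)
}

# running sum of x over centered windows of k bins (truncated at the edges),
# returned together with the number of bins actually covered
running_stats <- function(x, k) {
  n <- length(x)
  cs <- c(0, cumsum(as.numeric(x)))
  half <- floor(k / 2)
  lo <- pmax(0L, seq_len(n) - 1L - half)
  hi <- pmin(n, seq_len(n) - 1L + (k - half))
  list(sum = cs[hi + 1L] - cs[lo + 1L], nbin = hi - lo)
}

#' Call DHS peaks with a Poisson local-background scan
#'
#' Slides a window (default 150 bp, step = bin) over binned midpoint
#' coverage; each window count is tested against
#' `lambda_local = max(lambda_genome, lambda over each local background
#' span)` with an upper-tail Poisson p-value. BH adjustment is applied over
#' all tested windows genome-wide; windows with `q <= q_max` are merged when
#' the gap between them is at most `merge_gap`, peaks shorter than `min_len`
#' are dropped. The summit is the maximum-coverage bin and `fold` is the
#' summit window count over its local lambda.
#'
#' @param frags fragment data.frame (filtered; midpoints are counted)
#' @param seqlengths named vector of chromosome lengths
#' @param q_max BH-adjusted p-value threshold
#' @param relaxed_p when set, windows are selected by raw p <= `relaxed_p`
#'   instead of q <= `q_max`. Used to build deliberately permissive per-
#'   replicate peak lists for IDR reconciliation, which needs a genuine
#'   irreproducible component to anchor its noise model; q-values are still
#'   reported so the reconciled set can be re-filtered at `q_max`
#' @param window scan window (bp)
#' @param local_bgs local background spans (bp) for the local lambda
#' @param min_len minimum peak length (bp)
#' @param merge_gap maximum gap for merging significant windows (bp)
#' @param bin coverage bin (bp)
#' @return peak data.frame (chrom, start, end, name, summit, score, p, q,
#'   fold), non-overlapping, sorted
#' @export
call_peaks <- function(frags, seqlengths, q_max = 0.05, relaxed_p = NULL,
                       window = 150, local_bgs = c(1000, 5000, 10000),
                       min_len = 50, merge_gap = 50, bin = 10) {
  if (nrow(frags) == 0) {
    warning("empty fragment set; returning empty peak set")
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), summit = integer(), score = numeric(),
                      p = numeric(), q = numeric(), fold = numeric()))
  }
  track <- fragment_coverage(frags, seqlengths, bin = bin)
  wbins <- max(1L, round(window / bin))
  lambda_genome <- nrow(frags) * (wbins * bin) / sum(as.numeric(seqlengths))

  per_chrom <- lapply(names(track), function(ch) {
    x <- track[[ch]]
    n <- length(x)
    if (n < wbins) return(NULL)
    cs <- c(0, cumsum(as.numeric(x)))
    starts <- seq_len(n - wbins + 1L)
    cnt <- cs[starts + wbins] - cs[starts]
    lam <- rep(lambda_genome, length(starts))
    centre <- starts + floor(wbins / 2) - 1L
    for (bg in local_bgs) {
      kb <- round(bg / bin)
      if (kb <= wbins) next
      rs <- running_stats(x, kb)
      # flanking background: the scanned window itself is excluded so a
      # strong site does not inflate its own local lambda
      bg_sum <- pmax(0, rs$sum[centre + 1L] - cnt)
      bg_bins <- pmax(1L, rs$nbin[centre + 1L] - wbins)
      lam <- pmax(lam, bg_sum / bg_bins * wbins)
    }
    p <- poisson_tail(cnt, lam)
    # continuous -log10 p from the log-scale tail: survives underflow of p,
    # so downstream rank-based steps (IDR) never see tied saturated scores
    mlog10p <- -stats::ppois(cnt - 1, lam, lower.tail = FALSE, log.p = TRUE) / log(10)
    data.frame(chrom = ch, wstart = (starts - 1L) * bin, cnt = cnt,
               lam = lam, p = p, mlog10p = mlog10p, stringsAsFactors = FALSE)
  })
  win <- do.call(rbind, per_chrom)
  if (is.null(win) || nrow(win) == 0) {
    warning("no windows tested; returning empty peak set")
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), summit = integer(), score = numeric(),
                      p = numeric(), q = numeric(), fold = numeric()))
  }
  win$q <- bh_adjust(win$p)
  sig <- if (is.null(relaxed_p)) win[win$q <= q_max, , drop = FALSE]
         else win[win$p <= relaxed_p, , drop = FALSE]
  if (nrow(sig) == 0)
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), summit = integer(), score = numeric(),
                      p = numeric(), q = numeric(), fold = numeric()))

  gr <- GenomicRanges::GRanges(sig$chrom,
                               IRanges::IRanges(sig$wstart + 1L, sig$wstart + wbins * bin))
  merged <- GenomicRanges::reduce(gr, min.gapwidth = merge_gap + 1L)
  hits <- GenomicRanges::findOverlaps(merged, gr)
  mdf <- gr_to_df(merged)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)

  peaks <- lapply(seq_len(nrow(mdf)), function(i) {
    rows <- sig[sh[qh == i], , drop = FALSE]
    ch <- mdf$chrom[i]; s <- mdf$start[i]; e <- min(mdf$end[i], seqlengths[[ch]])
    if (e - s < min_len) return(NULL)
    # summit: max-coverage bin inside the peak
    b0 <- floor(s / bin) + 1L; b1 <- min(length(track[[ch]]), ceiling(e / bin))
    cov <- track[[ch]][b0:b1]
    smax <- which.max(cov)
    summit <- as.integer(min((b0 + smax - 1L - 1L) * bin + floor(bin / 2), e - 1L) - s)
    best <- which.max(rows$mlog10p)
    data.frame(chrom = ch, start = s, end = e, summit = summit,
               p = rows$p[best], q = min(rows$q), mlog10p = rows$mlog10p[best],
               fold = rows$cnt[best] / rows$lam[best], stringsAsFactors = FALSE)
  })
  peaks <- do.call(rbind, peaks)
  if (is.null(peaks) || nrow(peaks) == 0)
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), summit = integer(), score = numeric(),
                      p = numeric(), q = numeric(), fold = numeric()))
  peaks <- peaks[order(peaks$chrom, peaks$start), , drop = FALSE]
  rownames(peaks) <- NULL
  peaks$name <- sprintf("peak%d", seq_len(nrow(peaks)))
  # ranking score: the continuous -log10 p of the best window
  peaks$score <- peaks$mlog10p
  peaks[, c("chrom", "start", "end", "name", "summit", "score", "p", "q", "fold")]
}

#' Strand-oriented TSS-body-TES metaprofile
#'
#' Averages binned coverage density over `[TSS - flank, TSS + flank]`, a
#' length-scaled gene body, and `[TES - flank, TES + flank]`; minus-strand
#' genes are reversed so the profile always reads 5' to 3'.
#'
#' @param track coverage track from [fragment_coverage()]
#' @param genes gene table
#' @param flank flank size in bp
#' @param body_bins number of bins the gene body is scaled to
#' @return numeric profile vector with attribute `n_skipped` (genes shorter
#'   than 2 coverage bins)
#' @export
metaprofile <- function(track, genes, flank = 1000, body_bins = 50) {
  bin <- attr(track, "bin")
  fb <- max(1L, round(flank / bin))
  skipped <- 0L
  profs <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    x <- track[[g$chrom]]
    if (is.null(x)) next
    gb0 <- floor(g$start / bin) + 1L; gb1 <- ceiling(g$end / bin)
    if (gb1 - gb0 + 1L < 2L) { skipped <- skipped + 1L; next }
    up <- x[pmax(1L, pmin(length(x), (gb0 - fb):(gb0 - 1L)))]
    body <- x[pmax(1L, pmin(length(x), gb0:gb1))]
    down <- x[pmax(1L, pmin(length(x), (gb1 + 1L):(gb1 + fb)))]
    body_scaled <- stats::approx(seq_along(body), body,
                                 xout = seq(1, length(body), length.out = body_bins))$y
    prof <- c(up, body_scaled, down)
    if (g$strand == "-") prof <- rev(prof)
    profs[[length(profs) + 1]] <- prof
  }
  if (!length(profs)) abort("no usable genes for metaprofile")
  out <- colMeans(do.call(rbind, profs))
  attr(out, "n_skipped") <- skipped
  attr(out, "flank_bins") <- fb
  attr(out, "body_bins") <- body_bins
  out
}

#' Pearson correlation of two replicate coverage tracks
#'
#' @param track1,track2 coverage tracks with identical binning
#' @return Pearson r, or `NA` with a warning when either track has zero
#'   variance
#' @export
replicate_correlation <- function(track1, track2) {
  if (attr(track1, "bin") != attr(track2, "bin"))
    abort("tracks have different bin sizes")
  x <- unlist(track1, use.names = FALSE)
  y <- unlist(track2, use.names = FALSE)
  if (length(x) != length(y)) abort("tracks cover different genomes")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero-variance track: correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Recall and base-pair coverage of a reference peak set by a query set
#'
#' `recall` is the fraction of reference peaks with at least 1 bp of overlap
#' in the query; `bp_coverage` is overlapping bp over total reference bp.
#'
#' @param query,reference peak data.frames (chrom, start, end)
#' @return list(recall, bp_coverage)
#' @export
peak_overlap_stats <- function(query, reference) {
  if (nrow(reference) == 0) return(list(recall = NA_real_, bp_coverage = NA_real_))
  if (nrow(query) == 0) return(list(recall = 0, bp_coverage = 0))
  qr <- df_to_gr(query); rf <- df_to_gr(reference)
  hit <- GenomicRanges::countOverlaps(rf, qr) > 0
  inter <- GenomicRanges::intersect(rf, GenomicRanges::reduce(qr))
  list(recall = mean(hit),
       bp_coverage = sum(GenomicRanges::width(inter)) / sum(GenomicRanges::width(rf)))
}
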