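# Fragment filtering, coverage, Poisson peak calling, metaprofiles,
# replicate correlation and overlap statistics.

test_that("fragment filtering keeps exactly the sub-threshold records in order", {
  fr <- data.frame(chrom = "chr1", start = c(0L, 10L, 20L),
                   end = c(100L, 135L, 146L))  # lengths 100, 125, 126
  out <- filter_fragments(fr)
  expect_equal(out$end - out$start, c(100L, 125L))
  expect_equal(filter_fragments(fr[0, ]), fr[0, ])
  expect_equal(nrow(filter_fragments(fr, max_len = Inf)), 3)
})

test_that("coverage bins midpoints, conserves counts, and validates chroms", {
  sl <- c(chr1 = 1000L)
  fr <- data.frame(chrom = "chr1", start = 100L, end = 120L)  # midpoint 110
  tr <- fragment_coverage(fr, sl, bin = 10)
  expect_equal(tr$chr1[12], 1L)  # bin covering [110, 120)
  expect_equal(sum(tr$chr1), 1L)

  set.seed(1)
  fr2 <- data.frame(chrom = "chr1", start = sample(0:950, 500, TRUE))
  fr2$end <- fr2$start + 40L
  tr2 <- fragment_coverage(fr2, sl, bin = 1)
  expect_equal(sum(unlist(tr2)), 500L)

  expect_error(fragment_coverage(data.frame(chrom = "chrX", start = 1L, end = 2L), sl),
               "unknown chromosome")
})

test_that("uniform fragments give Poisson-dispersed bin counts", {
  set.seed(42)
  sl <- c(chr1 = 200000L)
  n <- 20000
  fr <- data.frame(chrom = "chr1", start = sample(0:(200000 - 50), n, TRUE))
  fr$end <- fr$start + 50L
  tr <- fragment_coverage(fr, sl, bin = 10)
  x <- tr$chr1
  disp_index <- var(x) / mean(x)
  expect_gt(disp_index, 0.9); expect_lt(disp_index, 1.1)
})

test_that("Poisson tail matches pmf summation to 1e-12 for counts <= 50", {
  for (lambda in c(0.1, 1, 5, 20)) {
    for (cnt in c(0, 1, 8, 25, 50)) {
      oracle <- sum(dpois(cnt:(cnt + 400), lambda))
      expect_lt(abs(poisson_tail(cnt, lambda) - oracle), 1e-12)
    }
  }
  expect_equal(poisson_tail(0, 5), 1)  # count 0 never significant
  expect_equal(poisson_tail(8, 1), sum(dpois(8:300, 1)), tolerance = 1e-14)
})

test_that("empty fragment sets yield an empty peak set with a warning", {
  fr <- data.frame(chrom = character(), start = integer(), end = integer())
  expect_warning(pk <- call_peaks(fr, c(chr1 = 1000L)), "empty")
  expect_equal(nrow(pk), 0)
})

test_that("peak calling recovers planted DHSs and is translation-equivariant", {
  cfg <- small_sim_config(seed = 21, fragment_count = 80000L)
  g <- generate_genome(cfg)
  tr <- plant_truth(g$genome, g$genes, list(), cfg)$truth
  fr <- filter_fragments(simulate_fragments(tr, "AcG2", 1, cfg))
  pk <- call_peaks(fr, tr$seqlengths)
  st <- peak_overlap_stats(pk, tr$dhs)
  expect_gte(st$recall, 0.9)
  prec <- peak_overlap_stats(tr$dhs, pk)$recall
  expect_gte(prec, 0.9)

  # translation by a bin multiple shifts every peak identically
  shift <- 130L
  fr_shift <- fr; fr_shift$start <- fr$start + shift; fr_shift$end <- fr$end + shift
  sl2 <- tr$seqlengths + shift + 10L
  pk2 <- call_peaks(fr_shift, sl2)
  expect_equal(nrow(pk2), nrow(pk))
  expect_equal(pk2$start, pk$start + shift)
  expect_equal(pk2$end, pk$end + shift)
})

test_that("background-only fragments call at most 1% of the genome", {
  set.seed(3)
  sl <- c(chr1 = 500000L)
  n <- 100000
  fr <- data.frame(chrom = "chr1", start = sample(0:(500000 - 80), n, TRUE))
  fr$end <- fr$start + sample(40:125, n, TRUE)
  pk <- call_peaks(fr, sl)
  called_bp <- if (nrow(pk)) sum(pk$end - pk$start) else 0
  expect_lte(called_bp / 500000, 0.01)
})

test_that("metaprofile is flat on uniform coverage and peaked where planted", {
  genes <- random_gene_table(120, chrom_len = 1e6, n_chrom = 1, seed = 8)
  genes$end <- genes$start + 2000L  # regular bodies
  track <- list(chr1 = rep(5L, 1e5))
  attr(track, "bin") <- 10L
  prof <- metaprofile(track, genes, flank = 500, body_bins = 20)
  expect_lte(max(prof) / min(prof), 1.05)

  # concentrate coverage at -500..0 of each TSS
  x <- rep(0L, 1e5)
  for (i in seq_len(nrow(genes))) {
    tss <- if (genes$strand[i] == "+") genes$start[i] else genes$end[i] - 1L
    dirn <- if (genes$strand[i] == "+") -1 else 1
    b <- sort(floor((tss + dirn * (1:500)) / 10) + 1)
    b <- b[b >= 1 & b <= 1e5]
    x[b] <- x[b] + 10L
  }
  track2 <- list(chr1 = x); attr(track2, "bin") <- 10L
  prof2 <- metaprofile(track2, genes, flank = 1000, body_bins = 20)
  fb <- attr(prof2, "flank_bins")
  expect_lt(which.max(prof2), fb + 1)  # maximum strictly inside the upstream flank
})

test_that("synthetic coverage is TSS-enriched relative to gene bodies", {
  cfg <- small_sim_config(seed = 31)
  g <- generate_genome(cfg)
  tr <- plant_truth(g$genome, g$genes, list(), cfg)$truth
  fr <- filter_fragments(simulate_fragments(tr, "AcG2", 1, cfg))
  track <- fragment_coverage(fr, tr$seqlengths)
  prof <- metaprofile(track, g$genes, flank = 1000, body_bins = 40)
  fb <- attr(prof, "flank_bins")
  tss_region <- prof[(fb - 20):(fb + 5)]
  body_region <- prof[(fb + 10):(fb + 30)]
  expect_gt(mean(tss_region), mean(body_region))
})

test_that("replicate correlation behaves at the identity, independence and replicate cases", {
  sl <- c(chr1 = 1e6)
  set.seed(5)
  fr <- data.frame(chrom = "chr1", start = sample(0:(1e6 - 50), 50000, TRUE))
  fr$end <- fr$start + 50L
  t1 <- fragment_coverage(fr, sl)
  expect_equal(replicate_correlation(t1, t1), 1)

  t_a <- list(chr1 = rpois(1e5, 2)); attr(t_a, "bin") <- 10L
  t_b <- list(chr1 = rpois(1e5, 2)); attr(t_b, "bin") <- 10L
  expect_lt(abs(replicate_correlation(t_a, t_b)), 0.05)

  t_flat <- list(chr1 = rep(1L, 1e5)); attr(t_flat, "bin") <- 10L
  expect_warning(r <- replicate_correlation(t_a, t_flat), "zero-variance")
  expect_true(is.na(r))

  cfg <- small_sim_config(seed = 41, fragment_count = 300000L)
  g <- generate_genome(cfg)
  tr <- plant_truth(g$genome, g$genes, list(), cfg)$truth
  r1 <- fragment_coverage(filter_fragments(simulate_fragments(tr, "AcG2", 1, cfg)),
                          tr$seqlengths)
  r2 <- fragment_coverage(filter_fragments(simulate_fragments(tr, "AcG2", 2, cfg)),
                          tr$seqlengths)
  expect_gte(replicate_correlation(r1, r2), 0.9)
})

test_that("peak overlap statistics handle identity, disjoint and partial cases", {
  a <- data.frame(chrom = "chr1", start = 0L, end = 100L)
  expect_equal(peak_overlap_stats(a, a), list(recall = 1, bp_coverage = 1))
  b <- data.frame(chrom = "chr1", start = 200L, end = 300L)
  expect_equal(peak_overlap_stats(b, a), list(recall = 0, bp_coverage = 0))
  q <- data.frame(chrom = "chr1", start = 50L, end = 150L)
  st <- peak_overlap_stats(q, a)
  expect_equal(st$recall, 1)
  expect_equal(st$bp_coverage, 0.5)
})
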