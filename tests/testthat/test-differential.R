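# Union building, region counting, size factors, the NB Wald engine,
# DDHS/DEG calling, CCG identification, partition and term enrichment.

test_that("union merges overlapping and book-ended intervals idempotently", {
  a <- data.frame(chrom = "chr1", start = 0L, end = 100L)
  b <- data.frame(chrom = "chr1", start = 50L, end = 150L)
  u <- build_union(list(a, b))
  expect_equal(u[, c("start", "end")], data.frame(start = 0L, end = 150L))

  d1 <- data.frame(chrom = "chr1", start = c(0L, 300L), end = c(100L, 400L))
  d2 <- data.frame(chrom = "chr2", start = 10L, end = 20L)
  u2 <- build_union(list(d1, d2))
  expect_equal(nrow(u2), 3)

  u3 <- build_union(list(u2))
  expect_equal(u3[, c("chrom", "start", "end")], u2[, c("chrom", "start", "end")])
})

test_that("fragments are counted once, at their midpoint region", {
  u <- data.frame(chrom = "chr1", start = c(0L, 100L), end = c(100L, 200L),
                  name = c("r1", "r2"))
  frags <- list(s1 = data.frame(chrom = "chr1",
                                start = c(10L, 90L, 95L), end = c(50L, 180L, 104L)))
  # midpoints 30, 135, 99 -> r1, r2, r1
  m <- count_in_regions(u, frags)
  expect_equal(unname(m[, 1]), c(2L, 1L))

  # conservation when regions tile the genome
  u_tile <- data.frame(chrom = "chr1", start = seq(0L, 900L, 100L),
                       end = seq(100L, 1000L, 100L),
                       name = sprintf("t%d", 1:10))
  set.seed(2)
  fr <- data.frame(chrom = "chr1", start = sample(0:950, 200, TRUE))
  fr$end <- pmin(1000L, fr$start + 40L)
  expect_warning(m2 <- count_in_regions(u_tile, list(s = fr)), "unsorted")
  expect_equal(sum(m2), 200L)
})

test_that("size factors follow the median-of-ratios definition", {
  set.seed(4)
  base <- matrix(rnbinom(2000, mu = 50, size = 10), ncol = 2)
  m <- cbind(base[, 1], base[, 1] * 2L)
  rownames(m) <- sprintf("r%d", seq_len(nrow(m)))
  colnames(m) <- c("a", "b")
  sf <- size_factors(m)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  ident <- cbind(base[, 1], base[, 1], base[, 1])
  rownames(ident) <- rownames(m)
  expect_equal(unname(size_factors(ident)), rep(1, 3))

  # independent oracle: direct formula implementation
  m3 <- matrix(rnbinom(600, mu = 80, size = 5), ncol = 3,
               dimnames = list(sprintf("g%d", 1:200), c("s1", "s2", "s3")))
  sf3 <- size_factors(m3)
  pos <- rowSums(m3 == 0) == 0
  geo <- exp(rowMeans(log(m3[pos, ])))
  raw <- apply(m3[pos, ], 2, function(col) median(col / geo))
  oracle <- raw / exp(mean(log(raw)))
  expect_equal(unname(sf3), unname(oracle), tolerance = 1e-12)

  expect_error(size_factors(matrix(c(0L, 1L, 1L, 0L), 2)), "all-positive")
})

test_that("the NB Wald engine is calibrated under the null and recovers planted folds", {
  set.seed(11)
  n <- 3000
  mu <- rlnorm(n, log(80), 1)
  m <- sapply(1:6, function(j) rnbinom(n, size = 1 / 0.05, mu = mu))
  rownames(m) <- sprintf("r%04d", 1:n)
  res <- nb_test(m, 1:3, 4:6)
  rate <- mean(res$p <= 0.05)
  expect_gte(rate, 0.03); expect_lte(rate, 0.07)
  # BH keeps the all-null DDHS count essentially zero
  expect_lte(sum(call_ddhs(res)$call != "none"), 2)

  idx <- sample(n, 300)
  m2 <- m
  m2[idx, 1:3] <- sapply(1:3, function(j) rnbinom(300, size = 1 / 0.05, mu = mu[idx] * 4))
  res2 <- call_ddhs(nb_test(m2, 1:3, 4:6))
  expect_gte(mean(res2$call[idx] == "A-preferential"), 0.8)

  # symmetry: swapping groups negates log2FC and preserves p
  res_sw <- nb_test(m2, 4:6, 1:3)
  expect_equal(res_sw$log2fc, -res2$log2fc, tolerance = 1e-12)
  expect_equal(res_sw$p, res2$p, tolerance = 1e-12)

  # all-zero feature: p = 1, no call
  m3 <- rbind(m[1:50, ], zero = 0L)
  res3 <- call_ddhs(nb_test(m3, 1:3, 4:6))
  expect_equal(res3$p[res3$feature == "zero"], 1)
  expect_equal(res3$call[res3$feature == "zero"], "none")
})

test_that("DDHS/DEG thresholds are boundary-inclusive on the printed scales", {
  res <- data.frame(feature = c("a", "b", "c"),
                    base_mean = 10, log2fc = c(1.0, 0.9, -1.2), se = 1,
                    stat = 1, p = c(0.04, 0.001, 0.2), padj = c(0.05, 0.001, 0.04))
  called <- call_ddhs(res)
  expect_equal(called$call, c("A-preferential", "none", "B-preferential"))
  deg <- call_degs(res)  # raw p by default
  expect_equal(deg$call, c("A-preferential", "none", "none"))
  deg_adj <- call_degs(res, use_adjusted = TRUE)
  expect_equal(deg_adj$call, c("A-preferential", "none", "B-preferential"))
})

test_that("BH equals the brute-force step-up definition exactly", {
  set.seed(13)
  for (rep in 1:5) {
    p <- runif(sample(50:1000, 1))
    expect_equal(bh_adjust(p), bh_bruteforce(p), tolerance = 1e-12)
  }
})

test_that("Fisher enrichment matches hypergeometric enumeration and fisher.test", {
  # sample odds ratio example
  fe <- fisher_enrichment(10, 30, 40, 300)  # table [[10,20],[30,240]]
  expect_equal(fe$odds_ratio, 4.0)

  set.seed(14)
  for (rep in 1:50) {
    N <- sample(5:30, 1)
    K <- sample(0:N, 1); n <- sample(0:N, 1)
    k_lo <- max(0, n + K - N); k_hi <- min(n, K)
    supp_k <- k_lo:k_hi
    k <- supp_k[sample.int(length(supp_k), 1)]
    fe <- fisher_enrichment(k, n, K, N)
    # enumeration oracle over the full support
    supp <- k_lo:k_hi
    probs <- dhyper(supp, K, N - K, n)
    expect_lt(abs(fe$p - sum(probs[supp >= k])), 1e-10)
    # cross-check against the one-sided exact test
    ft <- fisher.test(matrix(c(k, n - k, K - k, N - K - n + k), 2),
                      alternative = "greater")
    expect_equal(fe$p, ft$p.value, tolerance = 1e-9)
  }
})

test_that("CCG identification intersects DHS genes with DEGs over the universe", {
  out <- ccg_identify(c("A", "B", "C"), c("B", "C", "D"), LETTERS[1:10])
  expect_equal(out$ccg, c("B", "C"))
  expect_equal(out$overlap_ratio, 2 / 3)
  expect_error(ccg_identify("A", "B", character()), "empty")
})

test_that("specific/common partition labels follow the within-condition calls", {
  res <- data.frame(feature = sprintf("u%d", 1:6),
                    call = c("A-preferential", "none", "B-preferential",
                             "none", "A-preferential", "none"))
  part <- partition_specific_common(res$feature, res)
  expect_equal(as.integer(attr(part, "counts")), c(2L, 1L, 3L))
  expect_equal(part$label[2], "common")

  res_none <- res; res_none$call <- "none"
  part0 <- partition_specific_common(res$feature, res_none)
  expect_true(all(part0$label == "common"))

  expect_error(partition_specific_common(c("u1", "zz"), res), "mismatch")
})

test_that("partition proportions recover a planted specific/common mixture", {
  set.seed(15)
  n <- 2000
  mu <- rlnorm(n, log(100), 0.8)
  idxA <- sample(n, 200); idxB <- sample(setdiff(1:n, idxA), 200)
  mk <- function(mult) sapply(1:3, function(j) rnbinom(n, size = 20, mu = mu * mult))
  multA <- rep(1, n); multA[idxA] <- 4
  multB <- rep(1, n); multB[idxB] <- 4
  m <- cbind(sapply(1:3, function(j) rnbinom(n, size = 20, mu = mu * multA)),
             sapply(1:3, function(j) rnbinom(n, size = 20, mu = mu * multB)))
  rownames(m) <- sprintf("u%04d", 1:n)
  res <- call_ddhs(nb_test(m, 1:3, 4:6))
  part <- partition_specific_common(rownames(m), res)
  props <- prop.table(table(part$label))
  expect_lt(abs(props[["A-specific"]] - 0.1), 0.05)
  expect_lt(abs(props[["B-specific"]] - 0.1), 0.05)
})

test_that("hypergeometric term enrichment flags planted terms and controls nulls", {
  universe <- sprintf("g%03d", 1:300)
  term_map <- data.frame(gene_id = c(universe[1:10], sample(universe, 60, replace = FALSE)),
                         term = c(rep("T001", 10), rep(sprintf("T%03d", 2:7), each = 10)))
  out <- term_enrichment(universe[1:10], term_map, universe)
  top <- out[out$term == "T001", ]
  expect_true(top$significant)
  expect_lt(top$p, 1e-8)

  # k = 0 can never be significant
  out0 <- term_enrichment(setdiff(universe, term_map$gene_id)[1:5], term_map, universe)
  expect_true(all(out0$p[out0$k == 0] == 1))

  # random sets: essentially nothing significant across repeats
  set.seed(16)
  n_sig <- sum(vapply(1:20, function(i) {
    sum(term_enrichment(sample(universe, 15), term_map, universe)$significant)
  }, numeric(1)))
  expect_lte(n_sig, 2)
})
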