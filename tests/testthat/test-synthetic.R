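# Synthetic-data generator: determinism, planted-signal calibration, and
# the statistical properties the downstream stages rely on.

test_that("genome generation is deterministic and handles degenerate configs", {
  cfg <- small_sim_config()
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(g1$genes, g2$genes)

  f1 <- tempfile(); f2 <- tempfile()
  write_genome_fasta(g1$genome, f1); write_genome_fasta(g2$genome, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  cfg0 <- sim_config(seed = 1, n_genes = 0, n_chromosomes = 1,
                     chrom_length = 50000L, n_dhs = 5)
  g0 <- generate_genome(cfg0)
  expect_equal(nrow(g0$genes), 0)
  expect_equal(length(g0$genome), 1)
})

test_that("intergenic gaps average near the configured mean over seeds", {
  gaps <- c()
  for (s in 1:10) {
    cfg <- sim_config(seed = s, n_chromosomes = 1, chrom_length = 700000L,
                      n_genes = 50, mean_intergenic_gap = 9546, n_dhs = 10)
    gff <- tempfile(fileext = ".gff3")
    g <- generate_genome(cfg)
    write_genes_gff3(g$genes, g$exons, gff)
    gg <- read_genes_gff3(gff)$genes
    gg <- gg[order(gg$start), ]
    gaps <- c(gaps, gg$start[-1] - gg$end[-nrow(gg)])
  }
  expect_gt(mean(gaps), 9546 * 0.8)
  expect_lt(mean(gaps), 9546 * 1.2)
})

test_that("gene placement overflow produces an explicit capacity error", {
  cfg <- sim_config(seed = 1, n_chromosomes = 1, chrom_length = 30000L,
                    n_genes = 40, n_dhs = 5)
  expect_error(suppressWarnings(generate_genome(cfg)), "placement failure")
})

test_that("condition multipliers are flat when no DHS is condition-specific", {
  cfg <- small_sim_config(frac_condition_specific = 0)
  g <- generate_genome(cfg)
  tr <- plant_truth(g$genome, g$genes, list(), cfg)$truth
  mult <- as.matrix(tr$dhs[, paste0("mult_", cfg$conditions)])
  expect_true(all(mult == 1))
})

test_that("motif planting at rate 1 writes the consensus into every DHS", {
  cfg <- small_sim_config(motif_plant_rate = 1)
  g <- generate_genome(cfg)
  pw <- random_pwms(1, w = 10, seed = 3)
  pt <- plant_truth(g$genome, g$genes, pw, cfg)
  tr <- pt$truth
  expect_equal(nrow(tr$planted_motifs), nrow(tr$dhs))
  cons <- pwm_consensus(pw[[1]])
  for (i in sample(nrow(tr$planted_motifs), 10)) {
    pm <- tr$planted_motifs[i, ]
    d <- tr$dhs[tr$dhs$dhs_id == pm$dhs_id, ]
    s <- as.character(Biostrings::subseq(pt$genome[[d$chrom]],
                                         d$start + pm$offset + 1L,
                                         d$start + pm$offset + nchar(cons)))
    expected <- if (pm$strand == "+") cons else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(cons)))
    expect_identical(s, expected)
  }
})

test_that("CCG planting selects about frac_ccg of specific DHSs and is coordinated", {
  cfg <- sim_config(seed = 5, n_chromosomes = 2, chrom_length = 400000L,
                    n_genes = 60, n_dhs = 200, frac_condition_specific = 0.2,
                    frac_ccg = 0.5)
  g <- generate_genome(cfg)
  tr <- plant_truth(g$genome, g$genes, list(), cfg)$truth
  n_spec <- sum(tr$dhs$mult_AcG2 > 1)
  expect_equal(n_spec, round(0.2 * nrow(tr$dhs)))
  n_ccg <- length(tr$ccg_genes$AcG2)
  # the first condition draws round(frac_ccg * n_spec) specific DHSs; the CCG
  # gene count is that minus collisions of DHSs sharing a nearest gene
  expect_lte(n_ccg, round(0.5 * n_spec))
  expect_gte(n_ccg, round(0.6 * round(0.5 * n_spec)))
  # coordination: every CCG gene is nearest to a same-condition specific DHS,
  # and its planted expression mean is shifted in that condition
  for (cd in cfg$conditions) {
    for (gene in tr$ccg_genes[[cd]]) {
      own <- tr$dhs[!is.na(tr$dhs$nearest_gene) & tr$dhs$nearest_gene == gene, ]
      expect_true(any(own[[paste0("mult_", cd)]] > 1))
      # expression shifted by the planted fold over the gene's baseline
      # (baseline = conditions where the gene is not itself a CCG)
      base_conds <- cfg$conditions[!vapply(cfg$conditions, function(x)
        gene %in% tr$ccg_genes[[x]], logical(1))]
      if (length(base_conds)) {
        baseline <- min(tr$expression_means[gene, base_conds])
        expect_gte(tr$expression_means[gene, cd],
                   baseline * cfg$ccg_expr_fold * 0.999)
      }
    }
  }
})

test_that("fragment simulation is deterministic and respects the length mixture", {
  cfg <- small_sim_config(seed = 7)
  cfg$fragment_length_mix$sub125_fraction <- 0.6
  g <- generate_genome(cfg)
  tr <- plant_truth(g$genome, g$genes, list(), cfg)$truth
  f1 <- simulate_fragments(tr, "AcG2", 1, cfg)
  f2 <- simulate_fragments(tr, "AcG2", 1, cfg)
  expect_identical(f1, f2)
  f_other <- simulate_fragments(tr, "AcG2", 2, cfg)
  expect_false(identical(f1, f_other))
  expect_error(simulate_fragments(tr, "NoSuch", 1, cfg), "unknown condition")

  frac125 <- mean(f1$end - f1$start <= 125)
  expect_gte(frac125, 0.55)
  expect_lte(frac125, 0.65)
  expect_false(is.unsorted(f1$start[f1$chrom == f1$chrom[1]]))
})

test_that("fold_enrichment = 1 gives indistinguishable DHS vs background density", {
  cfg <- small_sim_config(seed = 2, fold_enrichment = 1,
                          frac_condition_specific = 0)
  g <- generate_genome(cfg)
  tr <- plant_truth(g$genome, g$genes, list(), cfg)$truth
  fr <- simulate_fragments(tr, "AcG2", 1, cfg)
  mid <- floor((fr$start + fr$end) / 2)
  dhs_bp <- sum(tr$dhs$end - tr$dhs$start)
  genome_bp <- sum(as.numeric(tr$seqlengths))
  in_dhs <- GenomicRanges::countOverlaps(
    GenomicRanges::GRanges(fr$chrom, IRanges::IRanges(mid + 1, mid + 1)),
    GenomicRanges::GRanges(tr$dhs$chrom,
                           IRanges::IRanges(tr$dhs$start + 1, tr$dhs$end))) > 0
  rate_in <- sum(in_dhs) / dhs_bp
  rate_out <- sum(!in_dhs) / (genome_bp - dhs_bp)
  expect_gt(rate_in / rate_out, 0.9)
  expect_lt(rate_in / rate_out, 1.1)
})

test_that("planted fold enrichment is recovered empirically within 15%", {
  cfg <- small_sim_config(seed = 4, fold_enrichment = 8, fragment_count = 100000L)
  g <- generate_genome(cfg)
  tr <- plant_truth(g$genome, g$genes, list(), cfg)$truth
  fr <- simulate_fragments(tr, "AcW10", 1, cfg)
  mid <- floor((fr$start + fr$end) / 2)
  # restrict to non-specific DHSs (multiplier 1) in this condition
  d <- tr$dhs[tr$dhs$mult_AcW10 == 1, ]
  in_dhs <- GenomicRanges::countOverlaps(
    GenomicRanges::GRanges(fr$chrom, IRanges::IRanges(mid + 1, mid + 1)),
    GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$start + 1, d$end))) > 0
  dhs_bp <- sum(d$end - d$start)
  all_dhs_bp <- sum(tr$dhs$end - tr$dhs$start)
  genome_bp <- sum(as.numeric(tr$seqlengths))
  out_bp <- genome_bp - all_dhs_bp
  in_other <- GenomicRanges::countOverlaps(
    GenomicRanges::GRanges(fr$chrom, IRanges::IRanges(mid + 1, mid + 1)),
    GenomicRanges::GRanges(tr$dhs$chrom,
                           IRanges::IRanges(tr$dhs$start + 1, tr$dhs$end))) > 0
  rate_in <- sum(in_dhs) / dhs_bp
  rate_out <- sum(!in_other) / out_bp
  fold_hat <- rate_in / rate_out
  expect_gt(fold_hat, 8 * 0.85)
  expect_lt(fold_hat, 8 * 1.15)
})

test_that("expression simulation is deterministic, coordinated, and Poisson-limited", {
  cfg <- small_sim_config(seed = 9, nb_dispersion = 1e-10, n_replicates = 40,
                          libsize_sd = 0)
  g <- generate_genome(cfg)
  tr <- plant_truth(g$genome, g$genes, list(), cfg)$truth
  m1 <- simulate_expression(tr, cfg)
  m2 <- simulate_expression(tr, cfg)
  expect_identical(m1, m2)

  # Poisson limit: replicate variance ~ mean for high-count genes
  info <- attr(m1, "sample_info")
  sub <- m1[, info$condition == "AcG2", drop = FALSE]
  mu <- rowMeans(sub); v <- apply(sub, 1, var)
  hi <- mu > 50
  expect_gt(sum(hi), 5)
  idx <- median(v[hi] / mu[hi])
  expect_gt(idx, 0.7); expect_lt(idx, 1.4)

  # non-CCG genes: two-group mean ratio centred at 1
  cfg2 <- small_sim_config(seed = 10, n_replicates = 6, libsize_sd = 0)
  g2 <- generate_genome(cfg2)
  tr2 <- plant_truth(g2$genome, g2$genes, list(), cfg2)$truth
  m <- simulate_expression(tr2, cfg2)
  info2 <- attr(m, "sample_info")
  nonccg <- setdiff(rownames(m), unlist(tr2$ccg_genes))
  rat <- rowMeans(m[nonccg, info2$condition == "AcG2"]) /
    pmax(1e-9, rowMeans(m[nonccg, info2$condition == "AcW2"]))
  gm <- exp(mean(log(rat[rat > 0])))
  expect_gt(gm, 0.9); expect_lt(gm, 1.1)
})
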