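# Location classification, nearest-TSS assignment, per-gene DHS statistics
# and the TF/TC vs other-gene comparison.

test_that("anchor positions fall into the documented strand-aware bins", {
  fx <- tiny_genes()
  # gA: + strand, TSS 10000, TES 11999; gB: - strand, TSS 32999, TES 30000
  cases <- list(
    list(a = 9500L,  cat = "Promoter<=1kb"),    # TSS-500 on +
    list(a = 8500L,  cat = "Promoter1-2kb"),    # TSS-1500 on +
    list(a = 13500L, cat = "Downstream1-2kb"),  # TES+1500 on +
    list(a = 12500L, cat = "Downstream<=1kb"),
    list(a = 10200L, cat = "Exon"),
    list(a = 11000L, cat = "Intron"),
    list(a = 33400L, cat = "Promoter<=1kb"),    # upstream of - gene
    list(a = 34500L, cat = "Promoter1-2kb"),
    list(a = 29500L, cat = "Downstream<=1kb"),  # downstream of - gene TES
    list(a = 200000L, cat = "DistalIntergenic") # >2 kb from every gene
  )
  for (cs in cases) {
    got <- as.character(classify_location(peak_at(cs$a), fx$genes, fx$exons))
    expect_identical(got, cs$cat)
  }
  expect_error(classify_location(peak_at(100L, chrom = "chrZ"), fx$genes, fx$exons),
               "absent")
})

test_that("categories always partition the peak set", {
  fx <- tiny_genes()
  set.seed(7)
  anchors <- sample(0:40000, 300)
  peaks <- data.frame(chrom = "chr1", start = anchors - 50L, end = anchors + 50L,
                      summit = 50L)
  cats <- classify_location(peaks, fx$genes, fx$exons)
  expect_equal(sum(table(cats)), nrow(peaks))
  expect_false(anyNA(cats))
})

test_that("nearest-TSS matches brute-force minimization and breaks ties leftward", {
  genes <- random_gene_table(800, seed = 5)
  set.seed(6)
  anchors <- data.frame(chrom = sample(unique(genes$chrom), 400, TRUE),
                        anchor = sample(0:3e6, 400))
  got <- nearest_tss(anchors, genes)
  oracle <- nearest_tss_bruteforce(anchors, genes)
  expect_identical(got$gene_id, oracle$gene_id)
  expect_equal(got$distance, oracle$distance)

  # tie: anchor exactly 1 kb from two TSSs
  tg <- data.frame(gene_id = c("gR", "gL"), chrom = "chr1",
                   start = c(12000L, 8000L), end = c(13000L, 10000L),
                   strand = c("+", "-"), stringsAsFactors = FALSE)
  # gL TSS = 9999 (- strand), gR TSS = 12000; midpoint anchor
  a <- data.frame(chrom = "chr1", anchor = 10999.5)
  # distances 1000.5 each; leftmost start (gL, start 8000) wins
  nt <- nearest_tss(a, tg)
  expect_identical(nt$gene_id, "gL")
})

test_that("strand flip maps promoter bins to downstream bins on a symmetric fixture", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 10000L, end = 12000L,
                      strand = "+", stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = "g1", start = 10000L, end = 12000L)
  flipped <- genes; flipped$strand <- "-"
  p_up <- peak_at(9500L)   # Promoter<=1kb on +, Downstream<=1kb on -
  expect_identical(as.character(classify_location(p_up, genes, exons)),
                   "Promoter<=1kb")
  expect_identical(as.character(classify_location(p_up, flipped, exons)),
                   "Downstream<=1kb")
  p_down <- peak_at(12500L)
  expect_identical(as.character(classify_location(p_down, genes, exons)),
                   "Downstream<=1kb")
  expect_identical(as.character(classify_location(p_down, flipped, exons)),
                   "Promoter<=1kb")
})

test_that("per-gene DHS statistics aggregate counts, lengths and zero classes", {
  fx <- tiny_genes()
  peaks <- data.frame(chrom = "chr1",
                      start = c(9500L, 9000L), end = c(9800L, 9400L),
                      name = c("d1", "d2"), summit = c(150L, 200L))
  ann <- annotate_peaks(peaks, fx$genes, fx$exons)
  st <- per_gene_dhs_stats(ann, fx$genes)
  expect_equal(st$per_gene$n_dhs[st$per_gene$gene_id == "gA"], 2L)
  expect_equal(st$per_gene$total_bp[st$per_gene$gene_id == "gA"], 700)
  expect_equal(st$frac_genes_with_dhs, 0.5)  # gB has none
  expect_equal(sum(st$count_hist), 1)        # one gene with DHSs

  # histogram equals a brute-force recount from the assignment table
  genes <- random_gene_table(100, seed = 9)
  set.seed(10)
  anchors <- sample(0:3e6, 300)
  pk <- data.frame(chrom = sample(unique(genes$chrom), 300, TRUE),
                   start = anchors, end = anchors + sample(100:1500, 300, TRUE),
                   name = sprintf("d%03d", 1:300))
  ann2 <- annotate_peaks(pk, genes, data.frame(gene_id = character(),
                                               start = integer(), end = integer()))
  st2 <- per_gene_dhs_stats(ann2, genes)
  recount <- table(table(ann2$gene_id[!is.na(ann2$gene_id)]))
  expect_equal(unname(st2$count_hist[["1"]]), sum(recount[names(recount) == "1"]))
  expect_equal(unname(st2$count_hist[[">=4"]]),
               sum(recount[as.integer(names(recount)) >= 4]))
})

test_that("TF/TC vs other comparison flags planted differences and handles nulls", {
  genes <- random_gene_table(200, seed = 12)
  labels <- setNames(rep("other", 200), genes$gene_id)
  labels[seq_len(40)] <- "TF"
  # plant: TF genes get 3 DHSs each, others 1
  mk_peaks <- function(gene_rows, per_gene) {
    do.call(rbind, lapply(gene_rows, function(i) {
      g <- genes[i, ]
      tss <- if (g$strand == "+") g$start else g$end - 1
      data.frame(chrom = g$chrom, start = tss - 600 - (0:(per_gene - 1)) * 70,
                 end = tss - 500 - (0:(per_gene - 1)) * 70)
    }))
  }
  pk <- rbind(mk_peaks(1:40, 3), mk_peaks(41:200, 1))
  pk$name <- sprintf("d%04d", seq_len(nrow(pk)))
  ann <- annotate_peaks(pk, genes, data.frame(gene_id = character(),
                                              start = integer(), end = integer()))
  cmp <- class_feature_comparison(ann, genes, labels)
  expect_true(cmp$TFTC$defined && cmp$other$defined)
  expect_gt(cmp$TFTC$prop_multi_dhs, cmp$other$prop_multi_dhs)

  # identical planting: proportions approximately equal
  pk0 <- mk_peaks(1:200, 2)
  pk0$name <- sprintf("e%04d", seq_len(nrow(pk0)))
  ann0 <- annotate_peaks(pk0, genes, data.frame(gene_id = character(),
                                                start = integer(), end = integer()))
  cmp0 <- class_feature_comparison(ann0, genes, labels)
  expect_lt(abs(cmp0$TFTC$prop_multi_dhs - cmp0$other$prop_multi_dhs), 0.15)

  # empty class: comparison undefined
  cmp_na <- class_feature_comparison(ann, genes,
                                     setNames(rep("other", 200), genes$gene_id))
  expect_false(cmp_na$TFTC$defined)
})
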