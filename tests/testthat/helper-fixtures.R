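# Shared fixture builders. Everything is generated in code at test time.

# two genes on one chromosome, one per strand, with known exon structure
tiny_genes <- function() {
  list(
    genes = data.frame(
      gene_id = c("gA", "gB"), chrom = "chr1",
      start = c(10000L, 30000L), end = c(12000L, 33000L),
      strand = c("+", "-"), stringsAsFactors = FALSE),
    exons = data.frame(
      gene_id = c("gA", "gA", "gB"),
      start = c(10000L, 11500L, 30000L),
      end = c(10500L, 12000L, 33000L))
  )
}

# a one-peak data.frame centred at an anchor position (summit at centre)
peak_at <- function(anchor, width = 100L, chrom = "chr1") {
  data.frame(chrom = chrom, start = anchor - width %/% 2L,
             end = anchor + width %/% 2L, summit = width %/% 2L)
}

# random gene table (no sequence needed) for annotation stress tests
random_gene_table <- function(n_genes, chrom_len = 3e6, n_chrom = 2, seed = 1) {
  set.seed(seed)
  chrom <- sample(sprintf("chr%d", seq_len(n_chrom)), n_genes, replace = TRUE)
  start <- sort(sample(seq(0, chrom_len - 5000), n_genes))
  len <- sample(500:4000, n_genes, replace = TRUE)
  genes <- data.frame(gene_id = sprintf("g%04d", seq_len(n_genes)),
                      chrom = chrom, start = start, end = start + len,
                      strand = sample(c("+", "-"), n_genes, replace = TRUE),
                      stringsAsFactors = FALSE)
  genes[order(genes$chrom, genes$start), ]
}

# small simulation config used by several integration tests; named arguments
# override the small-scale defaults
small_sim_config <- function(seed = 1, ...) {
  args <- list(seed = seed, n_chromosomes = 1, chrom_length = 400000L,
               n_genes = 22, n_dhs = 60, fragment_count = 50000L)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

# brute-force nearest-TSS oracle: plain loop over all genes
nearest_tss_bruteforce <- function(anchors, genes) {
  out <- data.frame(gene_id = rep(NA_character_, nrow(anchors)),
                    distance = rep(NA_real_, nrow(anchors)))
  for (i in seq_len(nrow(anchors))) {
    cand <- genes[genes$chrom == anchors$chrom[i], , drop = FALSE]
    if (nrow(cand) == 0) next
    tss <- ifelse(cand$strand == "+", cand$start, cand$end - 1L)
    d <- abs(anchors$anchor[i] - tss)
    best <- which(d == min(d))
    if (length(best) > 1) {
      best <- best[order(cand$start[best], cand$gene_id[best])][1]
    }
    out$gene_id[i] <- cand$gene_id[best]
    out$distance[i] <- ifelse(cand$strand[best] == "+",
                              anchors$anchor[i] - tss[best],
                              tss[best] - anchors$anchor[i])
  }
  out
}

# brute-force BH step-up
bh_bruteforce <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(1, adj)
  out
}
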