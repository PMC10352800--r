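# Genomic annotation of DHS peaks: strand-aware location categories with the
# promoter and downstream regions split at 1 kb, nearest-TSS gene assignment
# with a signed distance, per-gene DHS feature statistics, and the TF/TC vs
# other-gene feature comparison.

#' Location categories, in priority order
#' @export
location_categories <- function() {
  c("Promoter<=1kb", "Promoter1-2kb", "Exon", "Intron",
    "Downstream<=1kb", "Downstream1-2kb", "DistalIntergenic")
}

# signed distance from anchor to a gene's TSS: negative when the anchor lies
# on the gene's upstream side, regardless of strand
signed_tss_distance <- function(anchor, tss, strand) {
  ifelse(strand == "+", anchor - tss, tss - anchor)
}

#' Nearest-TSS gene for anchor points
#'
#' For each anchor, the gene minimizing `|anchor - TSS|` on the same
#' chromosome; ties are broken by smaller gene start, then lexicographic
#' gene id. The returned distance is signed: negative upstream of the TSS
#' (strand-aware).
#'
#' @param anchors data.frame (chrom, anchor) of 0-based anchor positions
#' @param genes gene table (gene_id, chrom, start, end, strand)
#' @return data.frame (gene_id, distance); `gene_id` is `NA` for anchors on
#'   chromosomes without genes
#' @export
nearest_tss <- function(anchors, genes) {
  out <- data.frame(gene_id = rep(NA_character_, nrow(anchors)),
                    distance = rep(NA_real_, nrow(anchors)),
                    stringsAsFactors = FALSE)
  if (nrow(genes) == 0 || nrow(anchors) == 0) return(out)
  tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  ord <- order(genes$start, genes$gene_id)  # tie-break order
  for (ch in unique(anchors$chrom)) {
    gi <- ord[genes$chrom[ord] == ch]
    ai <- which(anchors$chrom == ch)
    if (!length(gi)) next
    a <- anchors$anchor[ai]
    d <- abs(outer(a, tss[gi], "-"))
    best <- gi[apply(d, 1, which.min)]  # which.min takes the first = tie-break
    out$gene_id[ai] <- genes$gene_id[best]
    out$distance[ai] <- signed_tss_distance(a, tss[best], genes$strand[best])
  }
  out
}

#' Classify peak anchor points into location categories
#'
#' The anchor (summit when present, midpoint otherwise) is tested against
#' strand-aware bins in fixed priority:
#' Promoter<=1kb > Promoter1-2kb > Exon > Intron > Downstream<=1kb >
#' Downstream1-2kb > DistalIntergenic. Promoter bins cover signed TSS
#' distances [-1000, 0) and [-2000, -1000); downstream bins cover [0, 1000)
#' and [1000, 2000) past the TES. Anchors with no gene within the 2 kb
#' flanks and outside every gene body are distal intergenic.
#'
#' @param peaks peak data.frame (chrom, start, end, optional summit)
#' @param genes gene table
#' @param exons exon table (gene_id, start, end)
#' @param promoter_bp,downstream_bp outer extents of the promoter /
#'   downstream bins (bp); the 1 kb split point is half of each
#' @param anchor "summit" (default, midpoint fallback) or "midpoint"
#' @return factor of categories, one per peak
#' @export
classify_location <- function(peaks, genes, exons,
                              promoter_bp = 2000, downstream_bp = 2000,
                              anchor = c("summit", "midpoint")) {
  anchor <- match.arg(anchor)
  bad <- setdiff(unique(peaks$chrom), unique(genes$chrom))
  if (nrow(genes) > 0 && length(bad))
    abort("peak chromosomes absent from gene annotation: ",
          paste(bad, collapse = ", "))
  a <- peak_anchors(peaks, anchor)
  cats <- location_categories()
  assigned <- rep(7L, nrow(peaks))  # default DistalIntergenic
  if (nrow(genes) == 0) return(factor(cats[assigned], levels = cats))

  half_p <- promoter_bp / 2; half_d <- downstream_bp / 2
  agr <- GenomicRanges::GRanges(peaks$chrom, IRanges::IRanges(a + 1L, a + 1L))

  region_hit <- function(df) {
    if (nrow(df) == 0) return(logical(length(a)))
    df <- df[df$end > df$start, , drop = FALSE]
    if (nrow(df) == 0) return(logical(length(a)))
    GenomicRanges::countOverlaps(agr, df_to_gr(df)) > 0
  }
  plus <- genes$strand == "+"
  tss <- ifelse(plus, genes$start, genes$end - 1L)
  # promoter / downstream windows as genomic intervals (0-based half-open)
  prom1 <- data.frame(chrom = genes$chrom,
                      start = ifelse(plus, tss - half_p, tss + 1),
                      end = ifelse(plus, tss, tss + 1 + half_p))
  prom2 <- data.frame(chrom = genes$chrom,
                      start = ifelse(plus, tss - promoter_bp, tss + 1 + half_p),
                      end = ifelse(plus, tss - half_p, tss + 1 + promoter_bp))
  tes <- ifelse(plus, genes$end - 1L, genes$start)
  down1 <- data.frame(chrom = genes$chrom,
                      start = ifelse(plus, tes + 1, tes - half_d),
                      end = ifelse(plus, tes + 1 + half_d, tes))
  down2 <- data.frame(chrom = genes$chrom,
                      start = ifelse(plus, tes + 1 + half_d, tes - downstream_bp),
                      end = ifelse(plus, tes + 1 + downstream_bp, tes - half_d))
  prom1$start <- pmax(0, prom1$start); prom2$start <- pmax(0, prom2$start)
  down1$start <- pmax(0, down1$start); down2$start <- pmax(0, down2$start)
  exon_df <- data.frame(chrom = genes$chrom[match(exons$gene_id, genes$gene_id)],
                        start = exons$start, end = exons$end)
  body <- data.frame(chrom = genes$chrom, start = genes$start, end = genes$end)

  tests <- list(region_hit(prom1), region_hit(prom2), region_hit(exon_df),
                region_hit(body), region_hit(down1), region_hit(down2))
  # Intron = gene body minus exon: replace slot 4 accordingly
  tests[[4]] <- tests[[4]] & !tests[[3]]
  for (k in 6:1) assigned[tests[[k]]] <- k
  factor(cats[assigned], levels = cats)
}

# anchor position of each peak: absolute summit if present, else midpoint
peak_anchors <- function(peaks, anchor = "summit") {
  if (anchor == "summit" && !is.null(peaks$summit) && !anyNA(peaks$summit))
    peaks$start + peaks$summit
  else floor((peaks$start + peaks$end) / 2)
}

#' Annotate a peak set: category + nearest-TSS gene + signed distance
#'
#' @inheritParams classify_location
#' @return data.frame (peak_id, chrom, start, end, category, gene_id,
#'   distance)
#' @export
annotate_peaks <- function(peaks, genes, exons,
                           promoter_bp = 2000, downstream_bp = 2000,
                           anchor = c("summit", "midpoint")) {
  anchor <- match.arg(anchor)
  a <- peak_anchors(peaks, anchor)
  cat <- classify_location(peaks, genes, exons, promoter_bp, downstream_bp, anchor)
  nt <- nearest_tss(data.frame(chrom = peaks$chrom, anchor = a), genes)
  data.frame(peak_id = if (!is.null(peaks$name)) peaks$name
             else sprintf("peak%d", seq_len(nrow(peaks))),
             chrom = peaks$chrom, start = peaks$start, end = peaks$end,
             category = as.character(cat), gene_id = nt$gene_id,
             distance = nt$distance, stringsAsFactors = FALSE)
}

#' Per-gene DHS count and total length statistics
#'
#' Counts and summed lengths of the DHSs assigned (by nearest TSS) to each
#' gene, with the count histogram binned {1, 2, 3, >=4} and the length
#' histogram binned {<1 kb, 1-2 kb, >=2 kb}; genes with zero DHSs are
#' reported via `frac_genes_with_dhs`.
#'
#' @param annotation output of [annotate_peaks()]
#' @param genes gene table
#' @return list(per_gene, count_hist, length_hist, frac_genes_with_dhs)
#' @export
per_gene_dhs_stats <- function(annotation, genes) {
  asg <- annotation[!is.na(annotation$gene_id), , drop = FALSE]
  len <- asg$end - asg$start
  n_dhs <- table(asg$gene_id)
  tot_len <- tapply(len, asg$gene_id, sum)
  per_gene <- data.frame(gene_id = names(n_dhs),
                         n_dhs = as.integer(n_dhs),
                         total_bp = as.numeric(tot_len[names(n_dhs)]),
                         stringsAsFactors = FALSE)
  count_bin <- cut(per_gene$n_dhs, breaks = c(0.5, 1.5, 2.5, 3.5, Inf),
                   labels = c("1", "2", "3", ">=4"))
  length_bin <- cut(per_gene$total_bp, breaks = c(-Inf, 1000, 2000, Inf),
                    labels = c("<1kb", "1-2kb", ">=2kb"), right = FALSE)
  list(per_gene = per_gene,
       count_hist = table(count_bin),
       length_hist = table(length_bin),
       frac_genes_with_dhs = if (nrow(genes)) nrow(per_gene) / nrow(genes) else NA_real_)
}

#' Compare DHS features of TF/TC genes against other genes
#'
#' For the TF/TC class versus all other genes: the proportion of genes with
#' more than one DHS, the proportion whose assigned DHSs total more than
#' 1 kb, the location-category distribution of their DHSs, and the
#' intergenic fraction of the top-50%-by-DHS-count TF/TC subset.
#'
#' @param annotation output of [annotate_peaks()]
#' @param genes gene table
#' @param tf_labels named character vector gene_id -> {TF, TC, other}
#' @return list of per-class summaries; `defined` is FALSE when a class is
#'   empty
#' @export
class_feature_comparison <- function(annotation, genes, tf_labels) {
  stats_all <- per_gene_dhs_stats(annotation, genes)$per_gene
  cls <- ifelse(tf_labels[stats_all$gene_id] %in% c("TF", "TC"), "TFTC", "other")
  summarize <- function(sub, ann_sub) {
    if (nrow(sub) == 0) return(list(defined = FALSE))
    list(defined = TRUE,
         n_genes = nrow(sub),
         prop_multi_dhs = mean(sub$n_dhs > 1),
         prop_len_gt1kb = mean(sub$total_bp > 1000),
         category_dist = prop.table(table(factor(ann_sub$category,
                                                 levels = location_categories()))))
  }
  ann <- annotation[!is.na(annotation$gene_id), , drop = FALSE]
  ann_cls <- ifelse(tf_labels[ann$gene_id] %in% c("TF", "TC"), "TFTC", "other")
  tf_stats <- stats_all[cls == "TFTC", , drop = FALSE]
  other_stats <- stats_all[cls == "other", , drop = FALSE]
  out <- list(TFTC = summarize(tf_stats, ann[ann_cls == "TFTC", , drop = FALSE]),
              other = summarize(other_stats, ann[ann_cls == "other", , drop = FALSE]))
  # top 50% of TF/TC genes by DHS count: intergenic fraction of their DHSs
  if (nrow(tf_stats) >= 2) {
    topn <- ceiling(nrow(tf_stats) / 2)
    top_genes <- tf_stats$gene_id[order(-tf_stats$n_dhs)][seq_len(topn)]
    top_ann <- ann[ann$gene_id %in% top_genes, , drop = FALSE]
    out$top50_tf_intergenic_frac <-
      mean(top_ann$category == "DistalIntergenic")
  } else out$top50_tf_intergenic_frac <- NA_real_
  out
}
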