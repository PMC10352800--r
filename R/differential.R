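# Union DHS construction, fragment counting in regions, and a transparent
# negative-binomial differential engine: median-of-ratios size factors,
# method-of-moments dispersion shrunk toward a mean-dispersion trend, and a
# Wald test on log2 fold changes. DDHS/DEG calling, coordinately changed
# gene (CCG) identification with Fisher statistics, specific/common DHS
# partition, and hypergeometric term enrichment.

#' Merge peak sets into a union set
#'
#' Overlapping or book-ended intervals are merged; the result is sorted,
#' disjoint and idempotent under re-application.
#'
#' @param peak_sets list of peak data.frames (chrom, start, end)
#' @return union peak data.frame (chrom, start, end, name)
#' @export
build_union <- function(peak_sets) {
  all <- do.call(rbind, lapply(peak_sets, function(p) p[, c("chrom", "start", "end")]))
  if (is.null(all) || nrow(all) == 0)
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character()))
  merged <- GenomicRanges::reduce(df_to_gr(all))
  out <- gr_to_df(GenomicRanges::sort(merged))
  out$name <- sprintf("u%05d", seq_len(nrow(out)))
  out
}

#' Count fragments in regions by midpoint
#'
#' A fragment is counted in the region containing its midpoint, so each
#' fragment is counted at most once even across adjacent regions.
#'
#' @param union union region data.frame (chrom, start, end, name)
#' @param frag_list named list of fragment data.frames, one per sample
#' @return integer matrix regions x samples (rownames = region names)
#' @export
count_in_regions <- function(union, frag_list) {
  ugr <- df_to_gr(union)
  m <- matrix(0L, nrow(union), length(frag_list),
              dimnames = list(union$name, names(frag_list)))
  for (j in seq_along(frag_list)) {
    f <- frag_list[[j]]
    if (is.unsorted(order(f$chrom, f$start))) {
      warning("unsorted fragment input; sorting internally")
      f <- f[order(f$chrom, f$start), , drop = FALSE]
    }
    mid <- floor((f$start + f$end) / 2)
    mgr <- GenomicRanges::GRanges(f$chrom, IRanges::IRanges(mid + 1L, mid + 1L))
    h <- GenomicRanges::findOverlaps(mgr, ugr, select = "first")
    tab <- tabulate(h[!is.na(h)], nbins = nrow(union))
    m[, j] <- tab
  }
  m
}

#' Median-of-ratios size factors
#'
#' `factor_j = median over regions of count_ij / geometric mean_i`, computed
#' over regions with no zero count, then normalized to geometric mean 1.
#'
#' @param m count matrix (features x samples)
#' @return named numeric vector of size factors
#' @export
size_factors <- function(m) {
  logm <- log(m)
  ok <- rowSums(is.finite(logm)) == ncol(m)
  if (!any(ok))
    abort("no region with all-positive counts; cannot compute ",
          "median-of-ratios size factors (consider a pseudo-reference)")
  geo <- exp(rowMeans(logm[ok, , drop = FALSE]))
  sf <- apply(m[ok, , drop = FALSE], 2, function(col) stats::median(col / geo))
  sf <- sf / exp(mean(log(sf)))
  sf
}

#' Negative-binomial Wald test for two groups
#'
#' Counts are normalized by [size_factors()]; per-feature dispersion is
#' estimated by method of moments from within-group variability, shrunk
#' toward a mean-dispersion trend `a0 + a1/mean` fitted across features; the
#' log2 fold change of shrunk group means (pseudocount 1/2) is tested with a
#' Wald statistic whose standard error comes from the NB delta method, with
#' a two-sided normal p-value and BH adjustment over all tested features.
#'
#' @param m count matrix (features x samples)
#' @param groupA,groupB column names (or indices) of the two groups (>= 2
#'   replicates each)
#' @param shrink_weight weight of the trend in the shrunk dispersion
#' @return data.frame (feature, base_mean, log2fc, se, stat, p, padj); rows
#'   with all-zero counts get p = 1
#' @export
nb_test <- function(m, groupA, groupB, shrink_weight = 0.5) {
  A <- m[, groupA, drop = FALSE]; B <- m[, groupB, drop = FALSE]
  if (ncol(A) < 2 || ncol(B) < 2) abort("each group needs >= 2 replicates")
  sub <- cbind(A, B)
  sf <- size_factors(sub)
  norm <- sweep(sub, 2, sf, "/")
  nA <- ncol(A); nB <- ncol(B)
  xA <- norm[, seq_len(nA), drop = FALSE]
  xB <- norm[, nA + seq_len(nB), drop = FALSE]
  mA <- rowMeans(xA); mB <- rowMeans(xB)
  base_mean <- rowMeans(norm)

  # method-of-moments dispersion from pooled within-group variance
  vA <- apply(xA, 1, stats::var); vB <- apply(xB, 1, stats::var)
  vpool <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
  mpool <- (nA * mA + nB * mB) / (nA + nB)
  disp_mm <- pmax(1e-8, (vpool - mpool) / mpool^2)

  # mean-dispersion trend a0 + a1/mean, fitted on moderately expressed rows
  use <- is.finite(disp_mm) & mpool > 1
  if (sum(use) >= 10) {
    fit <- stats::lm(disp_mm[use] ~ I(1 / mpool[use]))
    co <- stats::coef(fit)
    trend <- pmax(1e-8, co[1] + co[2] / mpool)
  } else {
    trend <- rep(stats::median(disp_mm[is.finite(disp_mm)], na.rm = TRUE), length(mpool))
  }
  disp <- shrink_weight * trend + (1 - shrink_weight) * disp_mm
  disp <- pmax(disp, 1e-8)

  log2fc <- log2((mA + 0.5) / (mB + 0.5))
  # delta method: var(log mean) ~ (1/mu + alpha) / n per group
  se <- sqrt((1 / (mA + 0.5) + disp) / nA + (1 / (mB + 0.5) + disp) / nB) / log(2)
  stat <- log2fc / se
  p <- 2 * stats::pnorm(-abs(stat))
  zero <- rowSums(sub) == 0
  p[zero] <- 1; log2fc[zero] <- 0; stat[zero] <- 0
  padj <- bh_adjust(p)
  data.frame(feature = rownames(m), base_mean = base_mean, log2fc = log2fc,
             se = se, stat = stat, p = p, padj = padj,
             stringsAsFactors = FALSE)
}

#' Call differentially accessible DHSs (DDHSs)
#'
#' Boundary-inclusive: `|log2FC| >= log2(fc_min)` and adjusted p `<=
#' padj_max`. Returns the directional calls (A-preferential when log2FC is
#' positive).
#'
#' @param result output of [nb_test()]
#' @param fc_min linear fold-change threshold
#' @param padj_max adjusted-p threshold
#' @return result with an added `call` column in
#'   {A-preferential, B-preferential, none}
#' @export
call_ddhs <- function(result, fc_min = 2, padj_max = 0.05) {
  lfc <- log2(fc_min)
  call <- rep("none", nrow(result))
  sig <- result$padj <= padj_max & abs(result$log2fc) >= lfc
  call[sig & result$log2fc > 0] <- "A-preferential"
  call[sig & result$log2fc < 0] <- "B-preferential"
  result$call <- call
  result
}

#' Call differentially expressed genes (DEGs)
#'
#' Same rule as [call_ddhs()] but thresholded on the raw p-value by default,
#' as DEGs are reported with unadjusted p.
#'
#' @param result output of [nb_test()]
#' @param fc_min linear fold-change threshold
#' @param p_max raw-p threshold
#' @param use_adjusted threshold the BH-adjusted p instead
#' @return result with an added `call` column
#' @export
call_degs <- function(result, fc_min = 2, p_max = 0.05, use_adjusted = FALSE) {
  lfc <- log2(fc_min)
  pv <- if (use_adjusted) result$padj else result$p
  call <- rep("none", nrow(result))
  sig <- pv <= p_max & abs(result$log2fc) >= lfc
  call[sig & result$log2fc > 0] <- "A-preferential"
  call[sig & result$log2fc < 0] <- "B-preferential"
  result$call <- call
  result
}

#' Identify coordinately changed genes (CCGs)
#'
#' CCGs are the genes nearest to at least one condition-preferential DHS
#' that are also differentially expressed in the same condition. Enrichment
#' of the overlap over the gene universe (by default all genes assigned any
#' DHS) is quantified with an exact upper-tail Fisher test and the sample
#' odds ratio.
#'
#' @param ddhs_gene_ids gene ids nearest to the condition-preferential DHSs
#' @param deg_gene_ids gene ids called differentially expressed in the same
#'   condition
#' @param universe gene-id universe
#' @return list(ccg, overlap_ratio, fisher_p, odds_ratio, table)
#' @export
ccg_identify <- function(ddhs_gene_ids, deg_gene_ids, universe) {
  if (length(universe) == 0) abort("empty gene universe")
  ddhs_gene_ids <- intersect(unique(ddhs_gene_ids), universe)
  deg_gene_ids <- intersect(unique(deg_gene_ids), universe)
  ccg <- intersect(ddhs_gene_ids, deg_gene_ids)
  fe <- fisher_enrichment(k = length(ccg), n = length(ddhs_gene_ids),
                          K = length(deg_gene_ids), N = length(universe))
  list(ccg = sort(ccg),
       overlap_ratio = if (length(ddhs_gene_ids)) length(ccg) / length(ddhs_gene_ids) else NA_real_,
       fisher_p = fe$p, odds_ratio = fe$odds_ratio,
       odds_ratio_haldane = fe$odds_ratio_haldane, table = fe$table)
}

#' Partition DHSs into A-specific / B-specific / common
#'
#' Given a within-condition differential result on the same coordinates,
#' each DHS is labelled by its call; DHSs not called at the thresholds are
#' "common".
#'
#' @param dhs_ids DHS/region ids to partition
#' @param within_result called result ([call_ddhs()]) of the
#'   within-condition comparison on the same union coordinates
#' @param labels names for the two specific classes, in (A, B) order
#' @return data.frame (feature, label) plus a `counts` attribute
#' @export
partition_specific_common <- function(dhs_ids, within_result,
                                      labels = c("A-specific", "B-specific")) {
  missing <- setdiff(dhs_ids, within_result$feature)
  if (length(missing))
    abort("coordinate mismatch: ", length(missing),
          " DHS ids absent from the within-condition result")
  idx <- match(dhs_ids, within_result$feature)
  call <- within_result$call[idx]
  lab <- ifelse(call == "A-preferential", labels[1],
                ifelse(call == "B-preferential", labels[2], "common"))
  out <- data.frame(feature = dhs_ids, label = lab, stringsAsFactors = FALSE)
  attr(out, "counts") <- table(factor(lab, levels = c(labels, "common")))
  out
}

#' Hypergeometric term enrichment
#'
#' Upper-tail hypergeometric p per term with BH FDR across terms;
#' significant at `FDR <= 0.05` by convention.
#'
#' @param gene_set gene ids of interest (must be within the universe)
#' @param term_map data.frame (gene_id, term)
#' @param universe gene-id universe
#' @return data.frame (term, k, n, K, N, p, fdr, significant), ordered by p;
#'   attribute `n_skipped_terms` counts terms with no universe gene
#' @export
term_enrichment <- function(gene_set, term_map, universe) {
  gene_set <- intersect(unique(gene_set), universe)
  all_terms <- unique(term_map$term)
  term_map <- term_map[term_map$gene_id %in% universe, , drop = FALSE]
  terms <- split(term_map$gene_id, term_map$term)
  skipped <- length(setdiff(all_terms, names(terms)))
  N <- length(universe); n <- length(gene_set)
  rows <- lapply(names(terms), function(t) {
    K <- length(unique(terms[[t]]))
    k <- length(intersect(gene_set, terms[[t]]))
    data.frame(term = t, k = k, n = n, K = K, N = N,
               p = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame(term = character(), k = integer(),
                                      n = integer(), K = integer(), N = integer(),
                                      p = numeric(), fdr = numeric(),
                                      significant = logical()))
  out$fdr <- bh_adjust(out$p)
  out$significant <- out$fdr <= 0.05
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped_terms") <- skipped
  out
}
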