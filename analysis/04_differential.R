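# Differential accessibility (DDHS: fold >= 2, adjusted p <= 0.05) and
# expression (DEG: fold >= 2, p <= 0.05) between tissues at each timepoint,
# coordinately changed genes (CCGs) with Fisher statistics, the
# AcG2-specific / AcG10-specific / common partition of photosynthetic
# DHSs, and term enrichment of the CCGs.

source(file.path("analysis", "00_settings.R"))

cfg <- demo_sim_config()
bundle <- demo_bundle()

union <- utils::read.table(file.path(RESULTS, "union_dhs.tsv"), header = TRUE,
                           stringsAsFactors = FALSE)
ann <- utils::read.table(file.path(RESULTS, "annotation.tsv"), header = TRUE,
                         stringsAsFactors = FALSE)

frag_list <- list()
for (cd in cfg$conditions)
  for (r in seq_len(cfg$n_replicates))
    frag_list[[paste0(cd, "_r", r)]] <-
      filter_fragments(bundle$fragments[[cd]][[r]])
counts <- count_in_regions(union, frag_list)
write_counts_tsv(counts, file.path(RESULTS, "union_counts.tsv"))
sample_cond <- sub("_r\\d+$", "", colnames(counts))

expr <- bundle$expression
expr_info <- attr(expr, "sample_info")
universe <- unique(ann$gene_id[!is.na(ann$gene_id)])
truth_ccg <- bundle$truth$ccg_genes

for (ct in list(c("AcG2", "AcW2"), c("AcG10", "AcW10"))) {
  lab <- paste(ct, collapse = "_vs_")
  dres <- call_ddhs(nb_test(counts, which(sample_cond == ct[1]),
                            which(sample_cond == ct[2])))
  tsv(dres, sprintf("ddhs_%s.tsv", lab))
  eres <- call_degs(nb_test(expr, which(expr_info$condition == ct[1]),
                            which(expr_info$condition == ct[2])))
  tsv(eres, sprintf("deg_%s.tsv", lab))
  pref <- dres$feature[dres$call == "A-preferential"]
  pref_genes <- ann$gene_id[match(pref, ann$peak_id)]
  degs_up <- eres$feature[eres$call == "A-preferential"]
  ccg <- ccg_identify(pref_genes[!is.na(pref_genes)], degs_up, universe)
  tsv(data.frame(gene_id = ccg$ccg), sprintf("ccg_%s.tsv", ct[1]))
  jac <- length(intersect(ccg$ccg, truth_ccg[[ct[1]]])) /
    max(1, length(union(ccg$ccg, truth_ccg[[ct[1]]])))
  message(sprintf("%s: %d DDHSs, %d DEGs, %d CCGs (overlap %.1f%%, OR = %.2f, p = %.2g, truth Jaccard %.2f)",
                  lab, sum(dres$call != "none"), sum(eres$call != "none"),
                  length(ccg$ccg), 100 * ccg$overlap_ratio,
                  if (is.finite(ccg$odds_ratio)) ccg$odds_ratio else ccg$odds_ratio_haldane,
                  ccg$fisher_p, jac))
}

# within-tissue partition: AcG2 vs AcG10 on the same union coordinates
wres <- call_ddhs(nb_test(counts, which(sample_cond == "AcG2"),
                          which(sample_cond == "AcG10")))
part <- partition_specific_common(union$name, wres,
                                  labels = c("AcG2-specific", "AcG10-specific"))
tsv(part, "partition_AcG2_AcG10.tsv")
cnt <- attr(part, "counts")
message(sprintf("partition: %d AcG2-specific, %d AcG10-specific, %d common",
                cnt[[1]], cnt[[2]], cnt[[3]]))

# term enrichment of the AcG2 CCGs over a synthetic gene->term map
term_map <- simulate_term_map(bundle$genes, seed = SEED)
ccg_g2 <- utils::read.table(file.path(RESULTS, "ccg_AcG2.tsv"), header = TRUE,
                            stringsAsFactors = FALSE)$gene_id
enr <- term_enrichment(ccg_g2, term_map, universe)
tsv(enr, "enrichment_ccg_AcG2.tsv")
message(sprintf("enrichment: %d terms tested, %d significant at FDR <= 0.05",
                nrow(enr), sum(enr$significant)))
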