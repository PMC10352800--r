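# Union DHS set, genomic annotation (promoter/gene-body/downstream/distal
# bins with the 1 kb split), per-gene DHS statistics, and the TF/TC vs
# other-gene feature comparison.

source(file.path("analysis", "00_settings.R"))

cfg <- demo_sim_config()
bundle <- demo_bundle()

peak_sets <- lapply(cfg$conditions, function(cd)
  read_narrowpeak(file.path(RESULTS, sprintf("peaks_%s.narrowPeak", cd))))
union <- build_union(peak_sets)
tsv(union, "union_dhs.tsv")

ann <- annotate_peaks(union, bundle$genes, bundle$exons)
tsv(ann, "annotation.tsv")

cat_dist <- prop.table(table(factor(ann$category, levels = location_categories())))
tsv(data.frame(category = names(cat_dist), fraction = round(as.numeric(cat_dist), 4)),
    "category_distribution.tsv")
prom <- ann$category %in% c("Promoter<=1kb", "Promoter1-2kb")
message(sprintf("union DHSs: %d; promoter fraction %.1f%%, of which within 1 kb: %.1f%%",
                nrow(union), 100 * mean(prom),
                100 * sum(ann$category == "Promoter<=1kb") / max(1, sum(prom))))

st <- per_gene_dhs_stats(ann, bundle$genes)
tsv(st$per_gene, "per_gene_dhs.tsv")
message(sprintf("genes with >= 1 DHS: %.1f%%; DHS-count histogram: %s",
                100 * st$frac_genes_with_dhs,
                paste(names(st$count_hist), as.integer(st$count_hist),
                      sep = "=", collapse = ", ")))

cmp <- class_feature_comparison(ann, bundle$genes, bundle$truth$tf_labels)
if (cmp$TFTC$defined && cmp$other$defined) {
  message(sprintf("TF/TC >1-DHS proportion %.2f vs other %.2f; intergenic DHS fraction %.2f vs %.2f",
                  cmp$TFTC$prop_multi_dhs, cmp$other$prop_multi_dhs,
                  cmp$TFTC$category_dist[["DistalIntergenic"]],
                  cmp$other$category_dist[["DistalIntergenic"]]))
  tsv(data.frame(class = c("TFTC", "other"),
                 n_genes = c(cmp$TFTC$n_genes, cmp$other$n_genes),
                 prop_multi_dhs = c(cmp$TFTC$prop_multi_dhs, cmp$other$prop_multi_dhs),
                 prop_len_gt1kb = c(cmp$TFTC$prop_len_gt1kb, cmp$other$prop_len_gt1kb)),
      "tf_vs_other.tsv")
}
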