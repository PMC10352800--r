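# Simulate the study bundle: a compact two-chromosome genome with 60 genes,
# 220 planted DHSs (promoter-biased), condition-specific accessibility for
# ~10% of DHSs per condition, coordinated expression for ~40% of those, and
# synthetic clock-like motif instances written into DHS sequence.
# Writes the raw inputs every later stage consumes.

source(file.path("analysis", "00_settings.R"))

cfg <- demo_sim_config()
bundle <- demo_bundle()

write_genome_fasta(bundle$genome, file.path(RESULTS, "genome.fa"))
write_genes_gff3(bundle$genes, bundle$exons, file.path(RESULTS, "genes.gff3"))
for (cd in cfg$conditions)
  for (r in seq_len(cfg$n_replicates))
    write_fragments_bed(bundle$fragments[[cd]][[r]],
                        file.path(RESULTS, sprintf("fragments_%s_r%d.bed", cd, r)))
write_counts_tsv(bundle$expression, file.path(RESULTS, "expression_counts.tsv"))
tsv(bundle$truth$dhs, "truth_dhs.tsv")
tsv(bundle$truth$planted_motifs, "truth_planted_motifs.tsv")
tsv(data.frame(gene_id = names(bundle$truth$tf_labels),
               class = unname(bundle$truth$tf_labels)), "gene_classes.tsv")
ccg_tab <- do.call(rbind, lapply(names(bundle$truth$ccg_genes), function(cd)
  if (length(bundle$truth$ccg_genes[[cd]]))
    data.frame(condition = cd, gene_id = bundle$truth$ccg_genes[[cd]])))
tsv(ccg_tab, "truth_ccg_genes.tsv")

message(sprintf("simulated %d genes, %d DHSs, %d x %d fragment sets, %d CCG genes",
                nrow(bundle$genes), nrow(bundle$truth$dhs),
                length(cfg$conditions), cfg$n_replicates, nrow(ccg_tab)))
frac125 <- mean(with(bundle$fragments$AcG2[[1]], end - start) <= 125)
message(sprintf("sub-125 bp fragment fraction (AcG2 r1): %.3f", frac125))
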