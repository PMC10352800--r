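# Shared settings for the analysis scripts: one master seed, one simulation
# design (4 conditions x 3 replicates on a compact 2-chromosome genome), and
# the output layout. Every script regenerates what it needs from the seed --
# all artifacts are pure functions of (config, seed) -- and writes its
# tables under results/.

library(dieldhs)

SEED <- 20230704L
RESULTS <- file.path("results")
dir.create(RESULTS, showWarnings = FALSE, recursive = TRUE)

demo_sim_config <- function() {
  sim_config(seed = SEED,
             n_chromosomes = 2, chrom_length = 400000L,
             n_genes = 60, mean_intergenic_gap = 5000,
             n_dhs = 220, fragment_count = 150000L,
             fold_enrichment = 8,
             frac_condition_specific = 0.1, frac_ccg = 0.4,
             conditions = c("AcG2", "AcG10", "AcW2", "AcW10"),
             n_replicates = 3)
}

demo_pwms <- function() {
  meme <- system.file("extdata", "synthetic_clock_motifs.meme",
                      package = "dieldhs")
  read_meme(meme)
}

demo_bundle <- function() {
  simulate_bundle(demo_sim_config(), demo_pwms())
}

tsv <- function(df, name) {
  path <- file.path(RESULTS, name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path, " (", nrow(df), " rows)")
  invisible(path)
}
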