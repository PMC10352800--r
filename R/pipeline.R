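# End-to-end orchestration: one configuration drives simulate -> filter ->
# peaks -> IDR -> annotate -> union/count -> differential -> CCG ->
# partition -> motif scan -> network -> enrichment, with a file manifest
# recording hashes, row counts and stage parameters.

#' Build a pipeline configuration
#'
#' Thresholds default to the study's printed values: fragment length
#' <= 125 bp, peak q <= 0.05, IDR <= 0.05, DDHS fold >= 2 with adjusted
#' p <= 0.05, DEG fold >= 2 with raw p <= 0.05, motif p < 1e-4, a 2 kb
#' TSS-distance window for network edges, and enrichment FDR <= 0.05.
#'
#' @param seed master seed
#' @param out_dir output directory
#' @param sim a [sim_config()] for the synthetic inputs
#' @param fragment_max_len,peak_q,idr,ddhs_fc,ddhs_padj,deg_fc,deg_p,motif_p,window,enrich_fdr
#'   stage thresholds (see description)
#' @param contrasts list of two-condition contrasts to test, each a
#'   character pair; the first contrast drives the CCG / partition / network
#'   stages together with `within_contrast`
#' @param within_contrast character pair: the within-tissue comparison used
#'   to partition specific vs common DHSs
#' @return a validated `pipeline_config`
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("dieldhs_run"),
                            sim = sim_config(seed = seed),
                            fragment_max_len = 125, peak_q = 0.05, idr = 0.05,
                            ddhs_fc = 2, ddhs_padj = 0.05,
                            deg_fc = 2, deg_p = 0.05,
                            motif_p = 1e-4, window = 2000, enrich_fdr = 0.05,
                            contrasts = list(c("AcG2", "AcW2"), c("AcG10", "AcW10")),
                            within_contrast = c("AcG2", "AcG10")) {
  cfg <- list(seed = as.integer(seed), out_dir = out_dir, sim = sim,
              fragment_max_len = fragment_max_len, peak_q = peak_q, idr = idr,
              ddhs_fc = ddhs_fc, ddhs_padj = ddhs_padj, deg_fc = deg_fc,
              deg_p = deg_p, motif_p = motif_p, window = window,
              enrich_fdr = enrich_fdr, contrasts = contrasts,
              within_contrast = within_contrast)
  class(cfg) <- "pipeline_config"
  errs <- validate_config(cfg)
  if (length(errs)) abort("invalid pipeline config:\n  ",
                          paste(errs, collapse = "\n  "))
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks every threshold invariant; returns a character vector of
#' human-readable errors (empty when the config is valid). Unknown fields
#' are rejected.
#'
#' @param config a `pipeline_config` (or plain list with the same fields)
#' @return character vector of errors (length 0 when ok)
#' @export
validate_config <- function(config) {
  errs <- character()
  known <- c("seed", "out_dir", "sim", "fragment_max_len", "peak_q", "idr",
             "ddhs_fc", "ddhs_padj", "deg_fc", "deg_p", "motif_p", "window",
             "enrich_fdr", "contrasts", "within_contrast")
  extra <- setdiff(names(config), known)
  if (length(extra)) errs <- c(errs, paste0("unknown field(s): ",
                                            paste(extra, collapse = ", ")))
  probfields <- c("peak_q", "idr", "ddhs_padj", "deg_p", "motif_p", "enrich_fdr")
  for (f in probfields) {
    v <- config[[f]]
    if (is.null(v) || !is.numeric(v) || v <= 0 || v > 1)
      errs <- c(errs, paste0(f, " must be in (0, 1]"))
  }
  for (f in c("ddhs_fc", "deg_fc"))
    if (is.null(config[[f]]) || config[[f]] < 1)
      errs <- c(errs, paste0(f, " must be >= 1"))
  if (is.null(config$window) || config$window <= 0)
    errs <- c(errs, "window must be > 0")
  if (is.null(config$fragment_max_len) || config$fragment_max_len <= 0)
    errs <- c(errs, "fragment_max_len must be > 0")
  errs
}

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full pipeline on synthetic data
#'
#' Executes every stage on a freshly simulated bundle and writes all outputs
#' plus a manifest (file, md5, n_rows, stage) under `config$out_dir`.
#' Deterministic: identical configs give byte-identical manifests.
#'
#' @param config a [pipeline_config()]
#' @param pwms PWM list to plant and scan; defaults to 7 synthetic
#'   information-rich motifs assigned to 7 simulated TF genes
#' @return invisible list with all in-memory stage results and the manifest
#' @export
run_pipeline <- function(config, pwms = NULL) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outfile <- function(...) file.path(config$out_dir, paste0(...))
  manifest <- list()
  note <- function(path, stage, n) {
    manifest[[length(manifest) + 1]] <<- data.frame(
      file = basename(path), md5 = unname(tools::md5sum(path)),
      n_rows = n, stage = stage, stringsAsFactors = FALSE)
  }

  # --- simulate ------------------------------------------------------------
  scfg <- config$sim
  if (is.null(pwms)) pwms <- random_pwms(7, w = 10, seed = scfg$seed)
  bundle <- simulate_bundle(scfg, pwms)
  genes <- bundle$genes; truth <- bundle$truth
  # map each motif to a simulated TF gene (cycling over labelled TFs)
  tf_genes <- names(truth$tf_labels)[truth$tf_labels == "TF"]
  if (length(tf_genes) == 0) tf_genes <- genes$gene_id[seq_len(min(7, nrow(genes)))]
  tf_map <- data.frame(pwm_id = vapply(pwms, `[[`, "", "id"),
                       tf_gene = rep_len(tf_genes, length(pwms)),
                       stringsAsFactors = FALSE)
  write_genome_fasta(bundle$genome, outfile("genome.fa"))
  note(outfile("genome.fa"), "simulate", length(bundle$genome))
  write_genes_gff3(genes, bundle$exons, outfile("genes.gff3"))
  note(outfile("genes.gff3"), "simulate", nrow(genes))
  utils::write.table(truth$dhs, outfile("truth_dhs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  note(outfile("truth_dhs.tsv"), "simulate", nrow(truth$dhs))
  log_stage("simulate", nrow(genes), " genes, ", nrow(truth$dhs), " planted DHSs")

  seqlens <- truth$seqlengths
  conds <- scfg$conditions

  # --- filter + peaks + IDR per condition ---------------------------------
  idr_sets <- list()
  tracks <- list()
  for (cd in conds) {
    rep_sets <- list()
    for (r in seq_len(scfg$n_replicates)) {
      fr <- filter_fragments(bundle$fragments[[cd]][[r]], config$fragment_max_len)
      path <- outfile(sprintf("fragments_%s_r%d.bed", cd, r))
      write_fragments_bed(fr, path)
      note(path, "fragments", nrow(fr))
      rep_sets[[r]] <- call_peaks(fr, seqlens, q_max = config$peak_q)
      if (r <= 2) tracks[[paste0(cd, "_r", r)]] <- fragment_coverage(fr, seqlens)
      bundle$fragments[[cd]][[r]] <- fr
    }
    idr_sets[[cd]] <- idr_reconcile(rep_sets, idr_max = config$idr)
    path <- outfile(sprintf("peaks_%s.narrowPeak", cd))
    write_narrowpeak(idr_sets[[cd]], path)
    note(path, "peaks", nrow(idr_sets[[cd]]))
    log_stage("peaks", cd, ": ", nrow(rep_sets[[1]]), " rep1 peaks -> ",
              nrow(idr_sets[[cd]]), " reproducible")
  }

  # --- QC: replicate correlation ------------------------------------------
  qc <- data.frame(condition = conds,
                   replicate_r = vapply(conds, function(cd)
                     replicate_correlation(tracks[[paste0(cd, "_r1")]],
                                           tracks[[paste0(cd, "_r2")]]),
                     numeric(1)))
  utils::write.table(qc, outfile("qc_replicate_correlation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  note(outfile("qc_replicate_correlation.tsv"), "qc", nrow(qc))

  # --- union + counts ------------------------------------------------------
  union <- build_union(idr_sets)
  frag_list <- list()
  for (cd in conds)
    for (r in seq_len(scfg$n_replicates))
      frag_list[[paste0(cd, "_r", r)]] <- bundle$fragments[[cd]][[r]]
  counts <- count_in_regions(union, frag_list)
  write_counts_tsv(counts, outfile("union_counts.tsv"))
  note(outfile("union_counts.tsv"), "counts", nrow(counts))
  log_stage("union", nrow(union), " union DHSs")

  # --- annotation of the union set ----------------------------------------
  ann <- annotate_peaks(union, genes, bundle$exons)
  utils::write.table(ann, outfile("annotation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  note(outfile("annotation.tsv"), "annotate", nrow(ann))

  # --- differential accessibility & expression ----------------------------
  sample_cond <- sub("_r\\d+$", "", colnames(counts))
  expr_info <- attr(bundle$expression, "sample_info")
  ddhs <- list(); degs <- list(); ccg <- list()
  universe <- unique(ann$gene_id[!is.na(ann$gene_id)])
  for (ct in config$contrasts) {
    lab <- paste(ct, collapse = "_vs_")
    res <- nb_test(counts, which(sample_cond == ct[1]), which(sample_cond == ct[2]))
    res <- call_ddhs(res, fc_min = config$ddhs_fc, padj_max = config$ddhs_padj)
    ddhs[[lab]] <- res
    utils::write.table(res, outfile(sprintf("ddhs_%s.tsv", lab)), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    note(outfile(sprintf("ddhs_%s.tsv", lab)), "differential", nrow(res))

    eres <- nb_test(bundle$expression,
                    which(expr_info$condition == ct[1]),
                    which(expr_info$condition == ct[2]))
    eres <- call_degs(eres, fc_min = config$deg_fc, p_max = config$deg_p)
    degs[[lab]] <- eres
    utils::write.table(eres, outfile(sprintf("deg_%s.tsv", lab)), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    note(outfile(sprintf("deg_%s.tsv", lab)), "differential", nrow(eres))

    # CCGs for the first condition of the contrast
    pref <- res$feature[res$call == "A-preferential"]
    pref_genes <- ann$gene_id[match(pref, ann$peak_id)]
    deg_up <- eres$feature[eres$call == "A-preferential"]
    ccg[[ct[1]]] <- ccg_identify(pref_genes[!is.na(pref_genes)], deg_up, universe)
    log_stage("ccg", ct[1], ": ", length(ccg[[ct[1]]]$ccg), " CCGs (OR=",
              round(ccg[[ct[1]]]$odds_ratio, 2), ")")
  }

  # --- specific / common partition within tissue --------------------------
  wc <- config$within_contrast
  wres <- nb_test(counts, which(sample_cond == wc[1]), which(sample_cond == wc[2]))
  wres <- call_ddhs(wres, fc_min = config$ddhs_fc, padj_max = config$ddhs_padj)
  part <- partition_specific_common(union$name, wres,
                                    labels = paste0(wc, "-specific"))
  utils::write.table(part, outfile("partition.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  note(outfile("partition.tsv"), "partition", nrow(part))

  # --- motif scan over union DHS sequences --------------------------------
  seqs <- peak_sequences(bundle$genome, union)
  bg <- background_frequencies(seqs)
  hit_list <- lapply(pwms, function(pw) {
    pw$bg <- bg
    h <- scan_motif(seqs, pw, p_max = config$motif_p)
    if (nrow(h)) h$pwm_id <- pw$id
    h
  })
  hits <- do.call(rbind, hit_list[vapply(hit_list, nrow, 1L) > 0])
  if (is.null(hits)) hits <- data.frame(seq_id = character(), offset = integer(),
                                        strand = character(), score = numeric(),
                                        p = numeric(), pwm_id = character())
  utils::write.table(hits, outfile("motif_hits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  note(outfile("motif_hits.tsv"), "motif", nrow(hits))
  log_stage("motif", nrow(hits), " significant occurrences")

  # --- regulatory network --------------------------------------------------
  net <- build_network(hits, ann, tf_map, window = config$window,
                       specificity = part)
  utils::write.table(net$edges, outfile("network_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  note(outfile("network_edges.tsv"), "network", nrow(net$edges))
  utils::write.table(net$nodes, outfile("network_nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  note(outfile("network_nodes.tsv"), "network", nrow(net$nodes))
  log_stage("network", nrow(net$edges), " edges, ", nrow(net$nodes), " nodes")

  # --- term enrichment of the first contrast's CCGs ------------------------
  term_map <- simulate_term_map(genes, seed = scfg$seed)
  first_ccg <- ccg[[config$contrasts[[1]][1]]]$ccg
  enr <- term_enrichment(first_ccg, term_map, universe)
  utils::write.table(enr, outfile("enrichment.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  note(outfile("enrichment.tsv"), "enrichment", nrow(enr))

  manifest <- do.call(rbind, manifest)
  utils::write.table(manifest, outfile("manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(bundle = bundle, peaks = idr_sets, union = union,
                 counts = counts, annotation = ann, ddhs = ddhs, degs = degs,
                 ccg = ccg, partition = part, hits = hits, network = net,
                 enrichment = enr, qc = qc, manifest = manifest,
                 tf_map = tf_map, pwms = pwms))
}
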