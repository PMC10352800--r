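# TF -> target regulatory networks from motif occurrences in open chromatin:
# an edge is created when a TF's binding motif occurs in a DHS that is the
# nearest-TSS DHS of the target gene, within a distance window.

#' Build a TF -> target regulatory network
#'
#' Joins motif hits (per DHS) with the DHS annotation (nearest gene, signed
#' TSS distance) and a motif -> TF gene map. One edge per
#' (TF, target, DHS, motif) with hit multiplicity recorded; edges are
#' restricted to DHSs with `|distance| <= window`. Self-regulation (a TF's
#' motif in its own nearest DHS) is allowed. Optionally restrict targets to
#' a gene set and DHSs to a specificity class.
#'
#' @param hits motif hit table from [scan_motif()] runs, with a `pwm_id`
#'   column and `seq_id` naming DHS/peak ids
#' @param annotation DHS annotation ([annotate_peaks()]: peak_id, gene_id,
#'   distance)
#' @param tf_map data.frame (pwm_id, tf_gene)
#' @param window maximum |signed TSS distance| of the DHS (bp)
#' @param nearest_only when TRUE, edges are restricted to each target gene's
#'   single nearest DHS (smallest |distance|); by default every DHS whose
#'   nearest gene is the target contributes edges
#' @param specificity optional data.frame (feature, label) from
#'   [partition_specific_common()]; adds a `specificity` column to edges
#' @param target_set optional gene-id set to restrict targets to
#' @param specificity_class optional label to restrict edges to
#' @return list with `edges` (tf_gene, target, dhs_id, pwm_id, n_hits,
#'   specificity), `nodes` (gene, kind), and `n_unmapped_hits` (hits whose
#'   motif had no TF mapping)
#' @export
build_network <- function(hits, annotation, tf_map, window = 2000,
                          nearest_only = FALSE, specificity = NULL,
                          target_set = NULL, specificity_class = NULL) {
  if (nrow(hits) == 0) {
    return(list(edges = data.frame(tf_gene = character(), target = character(),
                                   dhs_id = character(), pwm_id = character(),
                                   n_hits = integer(), specificity = character()),
                nodes = data.frame(gene = character(), kind = character()),
                n_unmapped_hits = 0L))
  }
  mapped <- hits$pwm_id %in% tf_map$pwm_id
  n_unmapped <- sum(!mapped)
  h <- hits[mapped, , drop = FALSE]
  h$tf_gene <- tf_map$tf_gene[match(h$pwm_id, tf_map$pwm_id)]
  ann <- annotation[!is.na(annotation$gene_id) &
                      abs(annotation$distance) <= window, , drop = FALSE]
  if (nearest_only) {
    ann <- ann[order(ann$gene_id, abs(ann$distance)), , drop = FALSE]
    ann <- ann[!duplicated(ann$gene_id), , drop = FALSE]
  }
  h <- h[h$seq_id %in% ann$peak_id, , drop = FALSE]
  h$target <- ann$gene_id[match(h$seq_id, ann$peak_id)]
  if (!is.null(target_set)) h <- h[h$target %in% target_set, , drop = FALSE]
  if (!is.null(specificity)) {
    h$specificity <- specificity$label[match(h$seq_id, specificity$feature)]
    if (!is.null(specificity_class))
      h <- h[!is.na(h$specificity) & h$specificity == specificity_class, , drop = FALSE]
  } else h$specificity <- NA_character_

  if (nrow(h) == 0) {
    return(list(edges = data.frame(tf_gene = character(), target = character(),
                                   dhs_id = character(), pwm_id = character(),
                                   n_hits = integer(), specificity = character()),
                nodes = data.frame(gene = character(), kind = character()),
                n_unmapped_hits = n_unmapped))
  }
  key <- paste(h$tf_gene, h$target, h$seq_id, h$pwm_id, sep = "\r")
  first <- !duplicated(key)
  cnt <- table(key)
  edges <- data.frame(tf_gene = h$tf_gene[first], target = h$target[first],
                      dhs_id = h$seq_id[first], pwm_id = h$pwm_id[first],
                      n_hits = as.integer(cnt[key[first]]),
                      specificity = h$specificity[first],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$tf_gene, edges$target, edges$dhs_id, edges$pwm_id), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  tf_genes <- unique(edges$tf_gene)
  targets <- setdiff(unique(edges$target), tf_genes)
  target_tf <- intersect(targets, tf_map$tf_gene)
  nodes <- data.frame(
    gene = c(tf_genes, targets),
    kind = c(rep("TF", length(tf_genes)),
             ifelse(targets %in% target_tf, "target-TF", "other")),
    stringsAsFactors = FALSE)
  list(edges = edges, nodes = nodes, n_unmapped_hits = n_unmapped)
}

#' Per-gene report of motifs present in each nearby DHS
#'
#' For each listed gene: its nearby DHSs (nearest-TSS assignment within
#' `window`), each DHS's specificity label, and the motif ids hitting it.
#' Genes absent from the annotation are reported missing.
#'
#' @param gene_ids genes to report on
#' @param hits motif hit table with `pwm_id` and `seq_id` columns
#' @param annotation DHS annotation ([annotate_peaks()])
#' @param specificity optional (feature, label) table
#' @param window maximum |signed TSS distance| (bp)
#' @return list with `report` (gene_id, dhs_id, distance, specificity,
#'   motifs) and `missing_genes`
#' @export
motif_cooccurrence_report <- function(gene_ids, hits, annotation,
                                      specificity = NULL, window = 2000) {
  ann <- annotation[!is.na(annotation$gene_id) &
                      abs(annotation$distance) <= window, , drop = FALSE]
  missing <- setdiff(gene_ids, ann$gene_id)
  rows <- list()
  for (g in gene_ids) {
    dhss <- ann[ann$gene_id == g, , drop = FALSE]
    if (nrow(dhss) == 0) {
      rows[[length(rows) + 1]] <- data.frame(
        gene_id = g, dhs_id = NA_character_, distance = NA_real_,
        specificity = NA_character_, motifs = "", stringsAsFactors = FALSE)
      next
    }
    for (i in seq_len(nrow(dhss))) {
      did <- dhss$peak_id[i]
      motifs <- sort(unique(hits$pwm_id[hits$seq_id == did]))
      lab <- if (!is.null(specificity))
        specificity$label[match(did, specificity$feature)] else NA_character_
      rows[[length(rows) + 1]] <- data.frame(
        gene_id = g, dhs_id = did, distance = dhss$distance[i],
        specificity = lab, motifs = paste(motifs, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  list(report = do.call(rbind, rows), missing_genes = missing)
}
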