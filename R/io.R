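# Readers and writers for the plain-text formats the pipeline exchanges.
# All interval tables are 0-based half-open in memory; 1-based coordinates
# appear only at the GFF3 boundary.

#' Write a genome to FASTA
#' @param genome a named [Biostrings::DNAStringSet]
#' @param path output file
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, filepath = path, width = 70L)
  invisible(path)
}

#' Read a genome from FASTA
#' @param path FASTA file
#' @return a named [Biostrings::DNAStringSet]
#' @export
read_genome_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' Write gene models to GFF3
#'
#' Emits gene/mRNA/exon features (one mRNA per gene). Internal 0-based
#' half-open coordinates are converted to GFF3 1-based closed.
#'
#' @param genes gene table as returned by [generate_genome()]
#' @param exons exon table (gene_id, start, end)
#' @param path output file
#' @export
write_genes_gff3 <- function(genes, exons, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    ex <- exons[exons$gene_id == g$gene_id, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    writeLines(sprintf("%s\tdieldhs\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$chrom, g$start + 1L, g$end, g$strand, g$gene_id), con)
    writeLines(sprintf("%s\tdieldhs\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.1;Parent=%s",
                       g$chrom, g$start + 1L, g$end, g$strand, g$gene_id, g$gene_id), con)
    if (nrow(ex))
      writeLines(sprintf("%s\tdieldhs\texon\t%d\t%d\t.\t%s\t.\tParent=%s.1",
                         g$chrom, ex$start + 1L, ex$end, g$strand, g$gene_id), con)
  }
  invisible(path)
}

#' Read gene models from GFF3
#'
#' @param path GFF3 file with gene and exon features
#' @return list with `genes` (gene_id, chrom, start, end, strand; 0-based
#'   half-open) and `exons` (gene_id, start, end)
#' @export
read_genes_gff3 <- function(path) {
  gff <- rtracklayer::import(path, format = "gff3")
  gg <- gff[gff$type == "gene"]
  genes <- data.frame(
    gene_id = as.character(gg$ID),
    chrom = as.character(GenomicRanges::seqnames(gg)),
    start = GenomicRanges::start(gg) - 1L,
    end = GenomicRanges::end(gg),
    strand = as.character(GenomicRanges::strand(gg)),
    stringsAsFactors = FALSE
  )
  ee <- gff[gff$type == "exon"]
  parent <- sub("\\.1$", "", vapply(ee$Parent, function(x) x[[1]], character(1)))
  exons <- data.frame(
    gene_id = parent,
    start = GenomicRanges::start(ee) - 1L,
    end = GenomicRanges::end(ee),
    stringsAsFactors = FALSE
  )
  list(genes = genes, exons = exons)
}

#' Write a fragment set to BED
#'
#' Columns: chrom, start, end, name, length (0-based half-open).
#' @param frags fragment data.frame (chrom, start, end)
#' @param path output file
#' @export
write_fragments_bed <- function(frags, path) {
  out <- data.frame(frags$chrom, frags$start, frags$end,
                    name = sprintf("frag%d", seq_len(nrow(frags))),
                    len = frags$end - frags$start)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a fragment BED file
#' @param path BED file (first three columns used)
#' @return data.frame (chrom, start, end)
#' @export
read_fragments_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  data.frame(chrom = as.character(df[[1]]), start = as.integer(df[[2]]),
             end = as.integer(df[[3]]), stringsAsFactors = FALSE)
}

#' Write a peak set in narrowPeak (BED6+4) format
#'
#' score = int(-10 * log10 q), capped at 1000; strand "."; then fold,
#' -log10 p, -log10 q, and summit offset from peak start.
#'
#' @param peaks peak data.frame as produced by [call_peaks()]
#' @param path output file
#' @export
write_narrowpeak <- function(peaks, path) {
  n <- nrow(peaks)
  if (n == 0) { file.create(path); return(invisible(path)) }
  q <- pmax(peaks$q, 1e-300)
  p <- pmax(peaks$p, 1e-300)
  out <- data.frame(
    peaks$chrom, peaks$start, peaks$end,
    name = if (!is.null(peaks$name)) peaks$name else sprintf("peak%d", seq_len(n)),
    score = pmin(1000L, as.integer(round(-10 * log10(q)))),
    strand = ".",
    fold = round(peaks$fold, 5),
    mlog10p = round(-log10(p), 5),
    mlog10q = round(-log10(q), 5),
    summit = peaks$summit
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a narrowPeak file
#' @param path narrowPeak file
#' @return peak data.frame (chrom, start, end, name, score, fold, p, q, summit)
#' @export
read_narrowpeak <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), score = numeric(), fold = numeric(),
                      p = numeric(), q = numeric(), summit = integer()))
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  data.frame(chrom = as.character(df[[1]]), start = as.integer(df[[2]]),
             end = as.integer(df[[3]]), name = as.character(df[[4]]),
             score = as.numeric(df[[5]]), fold = as.numeric(df[[7]]),
             p = 10^(-df[[8]]), q = 10^(-df[[9]]),
             summit = as.integer(df[[10]]), stringsAsFactors = FALSE)
}

#' Write a coverage track to bedGraph
#' @param track coverage track from [fragment_coverage()]
#' @param path output file
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  bin <- attr(track, "bin")
  for (chrom in names(track)) {
    v <- track[[chrom]]
    nz <- which(v != 0)
    if (length(nz))
      writeLines(sprintf("%s\t%d\t%d\t%g", chrom, (nz - 1L) * bin, nz * bin, v[nz]), con)
  }
  invisible(path)
}

#' Write a count matrix to TSV (regions/genes in rows, samples in columns)
#' @param m count matrix with rownames (features) and colnames (samples)
#' @param path output file
#' @export
write_counts_tsv <- function(m, path) {
  df <- data.frame(feature = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count matrix from TSV
#' @param path TSV written by [write_counts_tsv()]
#' @return integer matrix with feature rownames
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
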