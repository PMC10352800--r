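# Synthetic-data generator: a miniature genome with planted regulatory truth.
#
# The generator emulates a four-condition (two tissues x two timepoints),
# three-replicate diel DNase-seq design: DNase I hypersensitive sites (DHSs)
# are planted with a promoter-proximal bias, a subset is made preferentially
# accessible in one condition, a subset of those is coordinated with the
# expression of its nearest gene (the planted CCGs), and motif consensus
# sequences are written into DHS sequence at recorded offsets. Every artifact
# is a pure function of (config, seed).

#' Build a simulation configuration
#'
#' Defaults describe the emulated study design: 4 conditions x 3 replicates,
#' a compact gene-dense genome (mean intergenic gap 9546 bp), fragment
#' libraries dominated by sub-125 bp fragments, 8-fold fragment enrichment
#' inside DHSs, ~10% of DHSs preferentially accessible per condition, and
#' ~40% of those coordinated with nearest-gene expression.
#'
#' @param seed master integer seed; all stage streams derive from it
#' @param n_chromosomes,chrom_length genome shape (bp)
#' @param n_genes genes to place (non-overlapping, strand uniform)
#' @param mean_intergenic_gap mean gap between adjacent genes (bp)
#' @param gc genomic GC content
#' @param n_dhs DHSs to plant
#' @param dhs_length_range min/max DHS length (bp); min must be >= 50
#' @param dhs_min_gap minimum separation between planted DHSs (bp), so that
#'   adjacent called peaks remain resolvable after window extension
#' @param dhs_placement named probabilities over placement classes
#'   (promoter1kb, promoter2kb, genebody, downstream1kb, downstream2kb,
#'   distal); promoter-heavy by default so that a majority of promoter DHSs
#'   fall within 1 kb of the TSS
#' @param fold_enrichment mean fragment density in a DHS over background
#' @param dhs_intensity_sd lognormal sd of the per-DHS intensity multiplier
#'   (normalized to mean 1), emulating the wide dynamic range of real DHS
#'   strengths; 0 makes every DHS equally strong
#' @param frac_condition_specific fraction of DHSs preferentially accessible
#'   per condition (disjoint across conditions)
#' @param specific_fold accessibility multiplier of a specific DHS in its
#'   target condition (>= 2)
#' @param frac_ccg fraction of condition-specific DHSs whose nearest gene's
#'   expression is coordinated (fold `ccg_expr_fold` in the same condition)
#' @param ccg_expr_fold expression fold change planted for CCG genes
#' @param frac_tf,frac_tc fractions of genes labelled TF / TC
#' @param fragment_count fragments per replicate
#' @param fragment_length_mix list(sub125_fraction, short_meanlog,
#'   short_sdlog, long_meanlog, long_sdlog): a lognormal body for each of the
#'   short (<= 125 bp) and long (125-200 bp) components, mixed at
#'   `sub125_fraction`
#' @param nb_dispersion negative-binomial dispersion of expression counts
#' @param libsize_sd lognormal sd of the per-sample library size factor
#' @param motif_plant_rate probability each DHS receives an instance of each
#'   supplied PWM
#' @param conditions condition labels
#' @param n_replicates replicates per condition
#' @return a validated `sim_config` list
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chrom_length = 400000L,
                       n_genes = 60L,
                       mean_intergenic_gap = 9546,
                       gc = 0.4,
                       n_dhs = 150L,
                       dhs_length_range = c(150L, 400L),
                       dhs_min_gap = 300L,
                       dhs_placement = c(promoter1kb = 0.32, promoter2kb = 0.08,
                                         genebody = 0.18, downstream1kb = 0.07,
                                         downstream2kb = 0.03, distal = 0.32),
                       fold_enrichment = 8,
                       dhs_intensity_sd = 0.6,
                       frac_condition_specific = 0.1,
                       specific_fold = 4,
                       frac_ccg = 0.4,
                       ccg_expr_fold = 4,
                       frac_tf = 0.05,
                       frac_tc = 0.01,
                       fragment_count = 150000L,
                       fragment_length_mix = list(sub125_fraction = 0.7,
                                                  short_meanlog = log(85),
                                                  short_sdlog = 0.25,
                                                  long_meanlog = log(160),
                                                  long_sdlog = 0.2),
                       nb_dispersion = 0.05,
                       libsize_sd = 0.1,
                       motif_plant_rate = 0.15,
                       conditions = c("AcG2", "AcG10", "AcW2", "AcW10"),
                       n_replicates = 3L) {
  cfg <- list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
              chrom_length = as.integer(chrom_length), n_genes = as.integer(n_genes),
              mean_intergenic_gap = mean_intergenic_gap, gc = gc,
              n_dhs = as.integer(n_dhs), dhs_length_range = as.integer(dhs_length_range),
              dhs_min_gap = as.integer(dhs_min_gap),
              dhs_placement = dhs_placement, fold_enrichment = fold_enrichment,
              dhs_intensity_sd = dhs_intensity_sd,
              frac_condition_specific = frac_condition_specific,
              specific_fold = specific_fold, frac_ccg = frac_ccg,
              ccg_expr_fold = ccg_expr_fold, frac_tf = frac_tf, frac_tc = frac_tc,
              fragment_count = as.integer(fragment_count),
              fragment_length_mix = fragment_length_mix,
              nb_dispersion = nb_dispersion, libsize_sd = libsize_sd,
              motif_plant_rate = motif_plant_rate,
              conditions = conditions, n_replicates = as.integer(n_replicates))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  props <- c(gc = cfg$gc, frac_condition_specific = cfg$frac_condition_specific,
             frac_ccg = cfg$frac_ccg, frac_tf = cfg$frac_tf, frac_tc = cfg$frac_tc,
             motif_plant_rate = cfg$motif_plant_rate,
             sub125_fraction = cfg$fragment_length_mix$sub125_fraction)
  bad <- names(props)[props < 0 | props > 1]
  if (length(bad)) abort("proportions outside [0,1]: ", paste(bad, collapse = ", "))
  if (cfg$dhs_length_range[1] < 50) abort("dhs_length_range min must be >= 50 bp")
  if (cfg$dhs_length_range[1] > cfg$dhs_length_range[2])
    abort("dhs_length_range must be (min, max) with min <= max")
  if (cfg$specific_fold < 2) abort("specific_fold must be >= 2")
  if (cfg$n_replicates < 1) abort("n_replicates must be >= 1")
  if (abs(sum(cfg$dhs_placement) - 1) > 1e-8)
    abort("dhs_placement probabilities must sum to 1")
  invisible(cfg)
}

#' Generate a random genome and non-overlapping gene models
#'
#' Chromosome sequences are i.i.d. nucleotides at the configured GC. Genes
#' (1-4 exons, uniform) are laid down left to right with exponential
#' intergenic gaps around `mean_intergenic_gap`; strand is uniform.
#'
#' @param config a [sim_config()]
#' @return list with `genome` ([Biostrings::DNAStringSet]), `genes`
#'   (gene_id, chrom, start, end, strand; 0-based half-open) and `exons`
#'   (gene_id, start, end)
#' @export
generate_genome <- function(config) {
  validate_sim_config(config)
  with_seed(stream_seed(config$seed, "genome"), {
    chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))
    probs <- c(A = (1 - config$gc) / 2, C = config$gc / 2,
               G = config$gc / 2, T = (1 - config$gc) / 2)
    genome <- Biostrings::DNAStringSet(vapply(chroms, function(ch) {
      paste(sample(names(probs), config$chrom_length, replace = TRUE, prob = probs),
            collapse = "")
    }, character(1)))
    names(genome) <- chroms

    # capacity heuristic: expected footprint vs available bp
    mean_span <- 4 * 300 + 3 * 200  # upper-ish bound on expected gene span
    need <- config$n_genes * (mean_span + config$mean_intergenic_gap)
    avail <- config$n_chromosomes * as.numeric(config$chrom_length)
    if (config$n_genes > 0 && need > avail)
      warning(sprintf(paste0("expected gene footprint (%.0f bp) exceeds genome ",
                             "size (%.0f bp); genes may fail to place"), need, avail))

    genes <- list(); exons <- list()
    if (config$n_genes > 0) {
      chrom_of <- chroms[rep(seq_along(chroms), length.out = config$n_genes)]
      pos <- stats::setNames(rep(0, length(chroms)), chroms)
      for (i in seq_len(config$n_genes)) {
        ch <- chrom_of[i]
        gap <- max(1, round(stats::rexp(1, rate = 1 / config$mean_intergenic_gap)))
        n_ex <- sample(1:4, 1)
        ex_len <- pmax(30, round(stats::rlnorm(n_ex, log(300), 0.35)))
        in_len <- if (n_ex > 1) pmax(30, round(stats::rlnorm(n_ex - 1, log(200), 0.4))) else integer(0)
        span <- sum(ex_len) + sum(in_len)
        start <- pos[ch] + gap
        if (start + span > config$chrom_length)
          abort(sprintf(paste0("gene placement failure: gene %d does not fit on %s ",
                               "(needs %d bp past position %.0f, chrom_length %d); ",
                               "increase chrom_length or reduce n_genes/mean_intergenic_gap"),
                        i, ch, span, pos[ch], config$chrom_length))
        gid <- sprintf("g%04d", i)
        off <- start
        ex <- matrix(0, n_ex, 2)
        for (e in seq_len(n_ex)) {
          ex[e, ] <- c(off, off + ex_len[e])
          off <- off + ex_len[e] + if (e < n_ex) in_len[e] else 0
        }
        genes[[i]] <- data.frame(gene_id = gid, chrom = ch, start = start,
                                 end = start + span,
                                 strand = sample(c("+", "-"), 1),
                                 stringsAsFactors = FALSE)
        exons[[i]] <- data.frame(gene_id = gid, start = ex[, 1], end = ex[, 2])
        pos[ch] <- start + span
      }
    }
    genes <- if (length(genes)) do.call(rbind, genes) else
      data.frame(gene_id = character(), chrom = character(), start = integer(),
                 end = integer(), strand = character(), stringsAsFactors = FALSE)
    exons <- if (length(exons)) do.call(rbind, exons) else
      data.frame(gene_id = character(), start = integer(), end = integer())
    rownames(genes) <- NULL; rownames(exons) <- NULL
    list(genome = genome, genes = genes, exons = exons)
  })
}

#' Plant regulatory ground truth into a genome
#'
#' Places non-overlapping DHSs with a configurable bias toward the 1 kb
#' upstream of TSSs, assigns condition-specific accessibility multipliers,
#' selects coordinated (CCG) genes per condition as the nearest-TSS genes of
#' a fraction of the specific DHSs, labels genes TF/TC/other, writes motif
#' consensus sequences into DHS sequence at recorded offsets, and builds the
#' planted gene x condition expression mean matrix.
#'
#' @param genome [Biostrings::DNAStringSet] from [generate_genome()]
#' @param genes gene table from [generate_genome()]
#' @param pwms optional list of PWMs (see [read_meme()]); may be empty
#' @param config a [sim_config()]
#' @return list with the (possibly motif-edited) `genome` and `truth`, a list
#'   holding `dhs` (intervals + per-condition multiplier columns),
#'   `ccg_genes` (per-condition gene-id sets), `planted_motifs`,
#'   `tf_labels`, `expression_means`, and `seqlengths`
#' @export
plant_truth <- function(genome, genes, pwms = list(), config) {
  validate_sim_config(config)
  with_seed(stream_seed(config$seed, "truth"), {
    chroms <- names(genome)
    seqlens <- stats::setNames(Biostrings::width(genome), chroms)
    n <- config$n_dhs
    classes <- names(config$dhs_placement)
    placed <- data.frame(chrom = character(), start = numeric(), end = numeric())
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      len <- sample(config$dhs_length_range[1]:config$dhs_length_range[2], 1)
      ok <- FALSE
      for (try in 1:200) {
        cls <- sample(classes, 1, prob = config$dhs_placement)
        if (cls != "distal" && nrow(genes) > 0) {
          g <- genes[sample(nrow(genes), 1), ]
          tss <- if (g$strand == "+") g$start else g$end - 1L
          tes <- if (g$strand == "+") g$end - 1L else g$start
          dirn <- if (g$strand == "+") 1 else -1
          anchor <- switch(cls,
            promoter1kb  = tss + dirn * stats::runif(1, -1000, -1),
            promoter2kb  = tss + dirn * stats::runif(1, -2000, -1001),
            genebody     = stats::runif(1, g$start, g$end - 1),
            downstream1kb = tes + dirn * stats::runif(1, 1, 1000),
            downstream2kb = tes + dirn * stats::runif(1, 1001, 2000))
          ch <- g$chrom
        } else {
          ch <- sample(chroms, 1, prob = seqlens)
          anchor <- stats::runif(1, 0, seqlens[[ch]] - 1)
        }
        start <- round(anchor - len / 2)
        if (start < 0 || start + len > seqlens[[ch]]) next
        same <- placed[placed$chrom == ch, , drop = FALSE]
        # keep planted DHSs separated so called peaks stay resolvable
        gap <- config$dhs_min_gap
        if (nrow(same) == 0 ||
            all(start + len + gap <= same$start | start >= same$end + gap)) {
          ok <- TRUE; break
        }
      }
      if (!ok)
        abort(sprintf("DHS overflow: could not place DHS %d of %d without overlap", i, n))
      placed <- rbind(placed, data.frame(chrom = ch, start = start, end = start + len))
      rows[[i]] <- data.frame(chrom = ch, start = as.integer(start),
                              end = as.integer(start + len),
                              placement = cls, stringsAsFactors = FALSE)
    }
    dhs <- do.call(rbind, rows)
    dhs <- dhs[order(dhs$chrom, dhs$start), , drop = FALSE]
    rownames(dhs) <- NULL
    dhs$dhs_id <- sprintf("dhs%04d", seq_len(nrow(dhs)))
    # per-DHS intensity: real DHSs span a wide dynamic range; normalized to
    # mean 1 so the aggregate fold enrichment stays at fold_enrichment
    intensity <- stats::rlnorm(nrow(dhs), 0, config$dhs_intensity_sd)
    dhs$intensity <- intensity / mean(intensity)

    # condition-specific accessibility multipliers, disjoint across conditions
    conds <- config$conditions
    mult <- matrix(1, nrow(dhs), length(conds), dimnames = list(dhs$dhs_id, conds))
    n_spec <- round(config$frac_condition_specific * nrow(dhs))
    pool <- sample(seq_len(nrow(dhs)))
    spec_idx <- stats::setNames(vector("list", length(conds)), conds)
    off <- 0
    for (cd in conds) {
      take <- pool[seq_len(n_spec) + off]
      take <- take[!is.na(take)]
      spec_idx[[cd]] <- take
      mult[take, cd] <- config$specific_fold
      off <- off + n_spec
    }

    # nearest-TSS gene of every DHS (midpoint anchor), reused for CCG planting
    anchors <- floor((dhs$start + dhs$end) / 2)
    nearest <- nearest_tss(data.frame(chrom = dhs$chrom, anchor = anchors), genes)
    dhs$nearest_gene <- nearest$gene_id
    dhs$tss_distance <- nearest$distance
    for (cd in conds) dhs[[paste0("mult_", cd)]] <- mult[, cd]

    # coordinated genes: a fraction of each condition's specific DHSs.
    # Selections are disjoint across conditions: a gene coordinated in two
    # conditions would cancel its own expression contrast.
    ccg_genes <- stats::setNames(vector("list", length(conds)), conds)
    taken <- character(0)
    for (cd in conds) {
      idx <- spec_idx[[cd]]
      idx <- idx[!is.na(dhs$nearest_gene[idx]) &
                   !(dhs$nearest_gene[idx] %in% taken)]
      k <- round(config$frac_ccg * length(idx))
      pick <- if (k > 0) sample(idx, k) else integer(0)
      ccg_genes[[cd]] <- unique(dhs$nearest_gene[pick])
      taken <- c(taken, ccg_genes[[cd]])
    }

    # TF / TC / other labels
    cls_lab <- rep("other", nrow(genes))
    if (nrow(genes) > 0) {
      n_tf <- round(config$frac_tf * nrow(genes))
      n_tc <- round(config$frac_tc * nrow(genes))
      lab_idx <- sample(nrow(genes), min(nrow(genes), n_tf + n_tc))
      cls_lab[lab_idx[seq_len(min(n_tf, length(lab_idx)))]] <- "TF"
      if (n_tc > 0 && length(lab_idx) > n_tf)
        cls_lab[lab_idx[(n_tf + 1):length(lab_idx)]] <- "TC"
    }
    tf_labels <- stats::setNames(cls_lab, genes$gene_id)

    # expression means: lognormal baseline, CCG genes shifted in their condition
    base <- stats::rlnorm(nrow(genes), log(100), 0.7)
    expr <- matrix(rep(base, length(conds)), ncol = length(conds),
                   dimnames = list(genes$gene_id, conds))
    for (cd in conds)
      expr[rownames(expr) %in% ccg_genes[[cd]], cd] <-
        expr[rownames(expr) %in% ccg_genes[[cd]], cd] * config$ccg_expr_fold

    # plant motif consensus sequences inside DHSs (non-overlapping within a DHS)
    planted <- list()
    if (length(pwms) > 0 && config$motif_plant_rate > 0) {
      genome <- as.list(genome)  # mutable copy
      occupied <- stats::setNames(vector("list", nrow(dhs)), dhs$dhs_id)
      for (pw in pwms) {
        cons <- pwm_consensus(pw)
        w <- nchar(cons)
        for (i in seq_len(nrow(dhs))) {
          if (stats::runif(1) > config$motif_plant_rate) next
          len <- dhs$end[i] - dhs$start[i]
          if (len < w) next
          done <- FALSE
          for (try in 1:20) {
            offv <- sample(0:(len - w), 1)
            occ <- occupied[[i]]
            if (!is.null(occ) && any(offv < occ[, 2] & offv + w > occ[, 1])) next
            strand <- sample(c("+", "-"), 1)
            ins <- if (strand == "+") cons else
              as.character(Biostrings::reverseComplement(Biostrings::DNAString(cons)))
            ch <- dhs$chrom[i]
            s0 <- dhs$start[i] + offv
            genome[[ch]] <- Biostrings::replaceAt(
              genome[[ch]], IRanges::IRanges(s0 + 1L, s0 + w), ins)
            occupied[[i]] <- rbind(occ, c(offv, offv + w))
            planted[[length(planted) + 1]] <-
              data.frame(pwm_id = pw$id, dhs_id = dhs$dhs_id[i],
                         offset = offv, strand = strand, stringsAsFactors = FALSE)
            done <- TRUE; break
          }
        }
      }
      genome <- Biostrings::DNAStringSet(genome)
    }
    planted <- if (length(planted)) do.call(rbind, planted) else
      data.frame(pwm_id = character(), dhs_id = character(),
                 offset = integer(), strand = character(), stringsAsFactors = FALSE)

    list(genome = genome,
         truth = list(dhs = dhs, ccg_genes = ccg_genes, planted_motifs = planted,
                      tf_labels = tf_labels, expression_means = expr,
                      seqlengths = seqlens, conditions = conds))
  })
}

#' Simulate a replicate's DNase fragments
#'
#' Fragment midpoints are drawn from a mixture of a uniform background and
#' DHS-concentrated components weighted by
#' `fold_enrichment * condition multiplier`; lengths come from the two-part
#' lognormal mixture whose short component is truncated to <= 125 bp. The
#' replicate stream seed is a stable hash of (seed, condition, replicate).
#'
#' @param truth `truth` list from [plant_truth()]
#' @param condition condition label (must be one of the configured conditions)
#' @param replicate replicate index (1-based)
#' @param config a [sim_config()]
#' @return fragment data.frame (chrom, start, end), sorted by coordinate
#' @export
simulate_fragments <- function(truth, condition, replicate, config) {
  if (!condition %in% truth$conditions)
    abort("unknown condition label: ", condition,
          " (expected one of ", paste(truth$conditions, collapse = ", "), ")")
  with_seed(stream_seed(config$seed, paste0("frags:", condition, ":", replicate)), {
    dhs <- truth$dhs
    seqlens <- truth$seqlengths
    n <- config$fragment_count
    mult <- dhs[[paste0("mult_", condition)]]
    dhs_len <- dhs$end - dhs$start
    intensity <- if (!is.null(dhs$intensity)) dhs$intensity else 1
    w_dhs <- dhs_len * config$fold_enrichment * intensity * mult
    total_len <- sum(as.numeric(seqlens))
    w_bg <- total_len - sum(dhs_len)
    comp <- sample.int(nrow(dhs) + 1L, n, replace = TRUE,
                       prob = c(w_bg, w_dhs)) - 1L  # 0 = background

    mid <- numeric(n); chrom <- character(n)
    in_dhs <- comp > 0
    if (any(in_dhs)) {
      i <- comp[in_dhs]
      mid[in_dhs] <- dhs$start[i] + floor(stats::runif(sum(in_dhs)) * dhs_len[i])
      chrom[in_dhs] <- dhs$chrom[i]
    }
    if (any(!in_dhs)) {
      # background = complement of DHS intervals, sampled length-proportionally
      gaps <- list()
      for (ch in names(seqlens)) {
        d <- dhs[dhs$chrom == ch, , drop = FALSE]
        bounds <- c(0, as.vector(rbind(d$start, d$end)), seqlens[[ch]])
        gs <- matrix(bounds, ncol = 2, byrow = TRUE)
        gs <- gs[gs[, 2] > gs[, 1], , drop = FALSE]
        if (nrow(gs)) gaps[[ch]] <- data.frame(chrom = ch, start = gs[, 1], end = gs[, 2])
      }
      gaps <- do.call(rbind, gaps)
      glen <- gaps$end - gaps$start
      j <- sample.int(nrow(gaps), sum(!in_dhs), replace = TRUE, prob = glen)
      mid[!in_dhs] <- gaps$start[j] + floor(stats::runif(sum(!in_dhs)) * glen[j])
      chrom[!in_dhs] <- gaps$chrom[j]
    }

    mix <- config$fragment_length_mix
    short <- stats::runif(n) < mix$sub125_fraction
    len <- integer(n)
    rtrunc_lnorm <- function(k, meanlog, sdlog, lo, hi) {
      u <- stats::runif(k, stats::plnorm(lo, meanlog, sdlog),
                        stats::plnorm(hi, meanlog, sdlog))
      pmin(hi, pmax(lo, round(stats::qlnorm(u, meanlog, sdlog))))
    }
    if (any(short))
      len[short] <- rtrunc_lnorm(sum(short), mix$short_meanlog, mix$short_sdlog, 30, 125)
    if (any(!short))
      len[!short] <- rtrunc_lnorm(sum(!short), mix$long_meanlog, mix$long_sdlog, 126, 200)

    start <- as.integer(pmax(0, round(mid - len / 2)))
    end <- pmin(as.integer(start + len), seqlens[chrom])
    frags <- data.frame(chrom = chrom, start = start, end = as.integer(end),
                        stringsAsFactors = FALSE)
    frags <- frags[order(frags$chrom, frags$start, frags$end), , drop = FALSE]
    rownames(frags) <- NULL
    frags
  })
}

#' Simulate the gene expression count matrix
#'
#' Per-gene negative-binomial counts with mean
#' `expression_means[gene, condition] * library size factor`; CCG genes thus
#' inherit the planted fold change in their condition. Library size factors
#   lognormal around 1 with sd `libsize_sd`.
#'
#' @param truth `truth` list from [plant_truth()]
#' @param config a [sim_config()]
#' @return integer matrix genes x samples with a `sample_info` attribute
#'   (data.frame sample, condition, replicate)
#' @export
simulate_expression <- function(truth, config) {
  with_seed(stream_seed(config$seed, "expr"), {
    conds <- truth$conditions
    reps <- seq_len(config$n_replicates)
    samples <- as.vector(outer(reps, conds, function(r, cd) paste0(cd, "_r", r)))
    info <- data.frame(sample = samples,
                       condition = rep(conds, each = length(reps)),
                       replicate = rep(reps, times = length(conds)),
                       stringsAsFactors = FALSE)
    sf <- exp(stats::rnorm(length(samples), 0, config$libsize_sd))
    em <- truth$expression_means
    m <- matrix(0L, nrow(em), length(samples), dimnames = list(rownames(em), samples))
    for (j in seq_along(samples)) {
      mu <- em[, info$condition[j]] * sf[j]
      m[, j] <- if (config$nb_dispersion < 1e-8) stats::rpois(nrow(em), mu)
                else stats::rnbinom(nrow(em), size = 1 / config$nb_dispersion, mu = mu)
    }
    attr(m, "sample_info") <- info
    m
  })
}

#' Generate a random gene-to-term functional map
#'
#' A synthetic stand-in for a GO-style annotation: terms are assigned to
#' random gene subsets, giving the enrichment stage a universe to operate on.
#'
#' @param genes gene table
#' @param n_terms number of terms
#' @param mean_term_size mean genes per term (Poisson)
#' @param seed integer seed
#' @return data.frame (gene_id, term)
#' @export
simulate_term_map <- function(genes, n_terms = 20, mean_term_size = 8, seed = 1L) {
  with_seed(stream_seed(seed, "terms"), {
    out <- lapply(seq_len(n_terms), function(t) {
      k <- max(2, stats::rpois(1, mean_term_size))
      k <- min(k, nrow(genes))
      data.frame(gene_id = sample(genes$gene_id, k),
                 term = sprintf("T%03d", t), stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

#' Generate random PWMs (synthetic, non-biological)
#'
#' With `method = "dominant"` each column has one dominant nucleotide
#' (probability `dominance`), giving high-information motifs whose consensus
#' is recoverable by scanning. With `method = "dirichlet"` columns are
#' Dirichlet draws, producing heterogeneous, moderately informative motifs
#' with a near-continuous score distribution (useful for p-value
#' calibration studies).
#'
#' @param n number of motifs
#' @param w motif width (recycled)
#' @param seed integer seed
#' @param dominance probability of the preferred letter per column
#' @param method column model, "dominant" or "dirichlet"
#' @param alpha Dirichlet concentration for `method = "dirichlet"`
#' @return list of PWM objects (id, w, mat, bg, pseudocount)
#' @export
random_pwms <- function(n = 7, w = 10, seed = 1L, dominance = 0.85,
                        method = c("dominant", "dirichlet"), alpha = 0.8) {
  method <- match.arg(method)
  w <- rep_len(w, n)
  with_seed(stream_seed(seed, "pwms"), {
    lapply(seq_len(n), function(i) {
      mat <- sapply(seq_len(w[i]), function(j) {
        if (method == "dominant") {
          p <- rep((1 - dominance) / 3, 4)
          p[sample(4, 1)] <- dominance
          p
        } else {
          x <- stats::rgamma(4, alpha)
          x / sum(x)
        }
      })
      rownames(mat) <- c("A", "C", "G", "T")
      new_pwm(id = sprintf("M%02d", i), mat = mat)
    })
  })
}

#' Simulate the full study bundle
#'
#' Convenience wrapper running genome generation, truth planting, fragment
#' simulation for every condition x replicate, and expression simulation.
#'
#' @param config a [sim_config()]
#' @param pwms optional PWM list to plant
#' @return list (genome, genes, exons, truth, fragments, expression);
#'   `fragments` is a nested list `fragments[[condition]][[replicate]]`
#' @export
simulate_bundle <- function(config, pwms = list()) {
  gen <- generate_genome(config)
  pt <- plant_truth(gen$genome, gen$genes, pwms, config)
  frags <- lapply(stats::setNames(config$conditions, config$conditions), function(cd) {
    lapply(seq_len(config$n_replicates), function(r)
      simulate_fragments(pt$truth, cd, r, config))
  })
  expr <- simulate_expression(pt$truth, config)
  list(genome = pt$genome, genes = gen$genes, exons = gen$exons,
       truth = pt$truth, fragments = frags, expression = expr)
}
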