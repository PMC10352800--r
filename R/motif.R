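# Position weight matrices: MEME minimal format I/O, exact p-values of
# integer-discretized log-odds scores by positional convolution, and
# strand-aware scanning of DHS sequences.

NUCS <- c("A", "C", "G", "T")

#' Construct a PWM object
#'
#' @param id motif identifier
#' @param mat 4 x w probability matrix (rows A, C, G, T; columns sum to 1)
#' @param bg background nucleotide frequencies (length 4, sums to 1)
#' @param pseudocount total pseudocount distributed by background before
#'   log-odds scoring
#' @param tf optional TF gene id the motif belongs to
#' @return a `pwm` list (id, tf, w, mat, bg, pseudocount)
#' @export
new_pwm <- function(id, mat, bg = rep(0.25, 4), pseudocount = 0.1, tf = NA_character_) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4) abort("PWM matrix must have 4 rows (A, C, G, T)")
  rownames(mat) <- NUCS
  if (any(abs(colSums(mat) - 1) > 1e-6))
    abort("PWM columns must sum to 1")
  if (abs(sum(bg) - 1) > 1e-9) abort("background must sum to 1")
  structure(list(id = id, tf = tf, w = ncol(mat), mat = mat,
                 bg = stats::setNames(bg, NUCS), pseudocount = pseudocount),
            class = "pwm")
}

#' Consensus sequence of a PWM (most probable letter per column)
#' @param pwm a `pwm` object
#' @return character consensus
#' @export
pwm_consensus <- function(pwm) {
  paste(NUCS[apply(pwm$mat, 2, which.max)], collapse = "")
}

# regularized log-odds matrix (natural log by default)
pwm_logodds <- function(pwm, log_base = exp(1)) {
  reg <- sweep(pwm$mat + pwm$pseudocount * pwm$bg, 2,
               1 + pwm$pseudocount, "/")
  log(sweep(reg, 1, pwm$bg, "/")) / log(log_base)
}

#' Read PWMs from a MEME minimal-format motif file
#'
#' Parses `MOTIF` blocks with their letter-probability matrices; validates
#' the alphabet and that matrix rows sum to 1 (tolerance 1e-3), reporting
#' the offending line number otherwise. Background frequencies are taken
#' from the file when present.
#'
#' @param path MEME motif file
#' @return list of `pwm` objects (order preserved)
#' @export
read_meme <- function(path) {
  if (!nzchar(path) || !file.exists(path)) abort("motif file not found: '", path, "'")
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bgl <- grep("^Background letter frequencies", lines)
  if (length(bgl)) {
    tok <- strsplit(trimws(lines[bgl[1] + 1]), "\\s+")[[1]]
    freq <- as.numeric(tok[seq(2, length(tok), by = 2)])
    names(freq) <- tok[seq(1, length(tok), by = 2)]
    if (!all(NUCS %in% names(freq)))
      abort("malformed background line at line ", bgl[1] + 1,
            ": expected A C G T frequencies")
    bg <- unname(freq[NUCS])
  }
  starts <- grep("^MOTIF\\b", lines)
  pwms <- list()
  for (s in starts) {
    hdr <- strsplit(trimws(lines[s]), "\\s+")[[1]]
    id <- hdr[2]; alt <- if (length(hdr) >= 3) hdr[3] else NA_character_
    ml <- grep("letter-probability matrix", lines[s:length(lines)])[1] + s - 1
    wtok <- regmatches(lines[ml], regexec("w=\\s*(\\d+)", lines[ml]))[[1]]
    w <- as.integer(wtok[2])
    rows <- matrix(0, 4, w)
    for (j in seq_len(w)) {
      ln <- ml + j
      vals <- suppressWarnings(as.numeric(strsplit(trimws(lines[ln]), "\\s+")[[1]]))
      if (length(vals) != 4 || anyNA(vals))
        abort("malformed matrix row at line ", ln, ": expected 4 numeric values")
      if (abs(sum(vals) - 1) > 1e-3)
        abort("malformed matrix row at line ", ln, ": probabilities sum to ",
              format(sum(vals)), ", not 1")
      rows[, j] <- vals
    }
    pwms[[length(pwms) + 1]] <- new_pwm(id = id, mat = rows, bg = bg, tf = alt)
  }
  pwms
}

#' Write PWMs to a MEME minimal-format motif file
#' @param pwms list of `pwm` objects
#' @param path output file
#' @param bg background written to the header (taken from the first PWM)
#' @export
write_meme <- function(pwms, path, bg = NULL) {
  if (is.null(bg)) bg <- if (length(pwms)) pwms[[1]]$bg else rep(0.25, 4)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "", "Background letter frequencies"), con)
  writeLines(sprintf("A %.5f C %.5f G %.5f T %.5f", bg[1], bg[2], bg[3], bg[4]), con)
  for (pw in pwms) {
    writeLines("", con)
    tfpart <- if (!is.na(pw$tf)) paste0(" ", pw$tf) else ""
    writeLines(sprintf("MOTIF %s%s", pw$id, tfpart), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       pw$w), con)
    for (j in seq_len(pw$w))
      writeLines(paste(sprintf("%.6f", pw$mat[, j]), collapse = " "), con)
  }
  invisible(path)
}

#' Exact distribution of discretized PWM log-odds scores
#'
#' Per-position log-odds are shifted to non-negative integers at a common
#' scale chosen so the total score range spans `granularity` steps; the
#' distribution of the integer score sum under the background model is
#' computed by positional convolution, giving exact upper-tail p-values at
#' the discretization resolution.
#'
#' @param pwm a `pwm` object
#' @param granularity number of discretization steps across the score range
#'   (>= 1000)
#' @return list with `int_scores` (4 x w integer matrix), `scale`,
#'   `offset` (per-column integer shifts), `pdf`, `tail`
#'   (`tail[s + 1] = P(S_int >= s)`), `score_of` helper mapping an integer
#'   score to the real log-odds scale
#' @export
score_distribution <- function(pwm, granularity = 10000) {
  if (granularity < 1000) abort("granularity must be >= 1000")
  lo <- pwm_logodds(pwm)
  col_min <- apply(lo, 2, min)
  range_total <- sum(apply(lo, 2, max) - col_min)
  scale <- if (range_total > 0) granularity / range_total else 1
  int_scores <- round(sweep(lo, 2, col_min, "-") * scale)
  max_total <- sum(apply(int_scores, 2, max))
  pdf <- c(1, numeric(max_total))  # distribution over 0..max_total
  for (j in seq_len(pwm$w)) {
    newpdf <- numeric(max_total + 1)
    for (a in 1:4) {
      s <- int_scores[a, j]
      nz <- which(pdf > 0)
      newpdf[nz + s] <- newpdf[nz + s] + pdf[nz] * pwm$bg[a]
    }
    pdf <- newpdf
  }
  tail <- rev(cumsum(rev(pdf)))
  list(int_scores = int_scores, scale = scale, offset = col_min,
       pdf = pdf, tail = tail,
       score_of = function(s_int) s_int / scale + sum(col_min))
}

# encode a DNA string as integers 1..4 (N and others -> NA)
encode_seq <- function(s) {
  v <- match(strsplit(toupper(s), "")[[1]], NUCS)
  v
}

#' Scan sequences for significant motif occurrences
#'
#' Every offset x strand whose exact upper-tail p-value is below `p_max` is
#' reported (`p_max >= 1` reports every offset). Reverse-strand scores are
#' computed on the reverse complement; offsets are always on the forward
#' sequence. Positions containing N are skipped; sequences shorter than the
#' motif are skipped and counted.
#'
#' @param sequences named character vector (or `DNAStringSet`) of sequences
#'   over {A,C,G,T,N}
#' @param pwm a `pwm` object
#' @param p_max significance threshold (strict: p < p_max)
#' @param strands "both" (default), "+" or "-"
#' @param granularity discretization steps for [score_distribution()]
#' @param dist optional precomputed [score_distribution()]
#' @return data.frame (seq_id, offset, strand, score, p) ordered by
#'   (sequence, offset, strand); attribute `n_skipped_seqs`
#' @export
scan_motif <- function(sequences, pwm, p_max = 1e-4, strands = "both",
                       granularity = 10000, dist = NULL) {
  if (methods::is(sequences, "DNAStringSet"))
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  if (is.null(names(sequences)))
    names(sequences) <- sprintf("seq%d", seq_along(sequences))
  if (is.null(dist)) dist <- score_distribution(pwm, granularity)
  w <- pwm$w
  do_strand <- switch(strands, both = c("+", "-"), `+` = "+", `-` = "-",
                      abort("strands must be 'both', '+' or '-'"))
  n_skipped <- 0L
  hits <- list()
  for (sid in names(sequences)) {
    x <- encode_seq(sequences[[sid]])
    L <- length(x)
    if (L < w) { n_skipped <- n_skipped + 1L; next }
    n_off <- L - w + 1L
    for (std in do_strand) {
      xs <- if (std == "+") x else rev(5L - x)  # reverse complement encoding
      # integer score per offset: sum over motif columns
      sc <- integer(n_off)
      ok <- rep(TRUE, n_off)
      for (j in seq_len(w)) {
        v <- xs[j:(j + n_off - 1L)]
        na <- is.na(v)
        ok <- ok & !na
        v[na] <- 1L
        sc <- sc + dist$int_scores[cbind(v, j)]
      }
      p <- dist$tail[pmin(sc, length(dist$tail) - 1L) + 1L]
      keep <- ok & (p < p_max | p_max >= 1)
      if (!any(keep)) next
      off_fwd <- if (std == "+") which(keep) - 1L else (L - w + 1L) - which(keep)
      hits[[length(hits) + 1]] <- data.frame(
        seq_id = sid, offset = off_fwd, strand = std,
        score = dist$score_of(sc[keep]), p = p[keep], stringsAsFactors = FALSE)
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(seq_id = character(), offset = integer(), strand = character(),
               score = numeric(), p = numeric(), stringsAsFactors = FALSE)
  out <- out[order(out$seq_id, out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped_seqs") <- n_skipped
  out
}

#' Extract DHS sequences from a genome
#'
#' @param genome [Biostrings::DNAStringSet]
#' @param peaks peak data.frame (chrom, start, end, name)
#' @return named character vector of peak sequences
#' @export
peak_sequences <- function(genome, peaks) {
  out <- vapply(seq_len(nrow(peaks)), function(i) {
    as.character(Biostrings::subseq(genome[[peaks$chrom[i]]],
                                    peaks$start[i] + 1L, peaks$end[i]))
  }, character(1))
  stats::setNames(out, if (!is.null(peaks$name)) peaks$name
                  else sprintf("peak%d", seq_len(nrow(peaks))))
}

#' Estimate 0-order background frequencies from sequences
#' @param sequences character vector of DNA sequences
#' @return length-4 frequency vector over A, C, G, T
#' @export
background_frequencies <- function(sequences) {
  counts <- colSums(Biostrings::alphabetFrequency(
    Biostrings::DNAStringSet(sequences))[, NUCS, drop = FALSE])
  counts / sum(counts)
}
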