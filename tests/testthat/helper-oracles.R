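# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use exhaustive enumeration, not the package's
# seed-and-extend / Biostrings code paths.

# all maximal repeated pairs by exhaustive diagonal scanning
oracle_maximal_pairs <- function(seq, orientation, min_length) {
  n <- nchar(seq)
  xv <- strsplit(seq, "")[[1]]
  yv <- switch(orientation,
               F = xv,
               P = strsplit(plastex::revcomp(seq), "")[[1]],
               R = rev(xv))
  rows <- list()
  dd <- if (orientation == "F") seq_len(n - 1) else -(n - 1):(n - 1)
  for (d in dd) {
    i1 <- max(1L, 1L - d); i2 <- min(n, n - d)
    if (i2 - i1 + 1L < min_length) next
    eq <- xv[i1:i2] == yv[(i1:i2) + d]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ok <- r$values & r$lengths >= min_length
    for (k in which(ok)) {
      i0 <- i1 + starts[k] - 1L
      l <- r$lengths[k]
      p0 <- i0 + d
      if (orientation == "F") {
        rows[[length(rows) + 1L]] <- data.frame(pos1 = i0, pos2 = p0, length = l)
      } else {
        b <- n - p0 - l + 2L
        if (i0 == b) next    # self-palindromic interval
        rows[[length(rows) + 1L]] <- data.frame(pos1 = min(i0, b),
                                                pos2 = max(i0, b), length = l)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(pos1 = integer(), pos2 = integer(), length = integer()))
  }
  out <- unique(do.call(rbind, rows))
  out[order(-out$length, out$pos1, out$pos2), , drop = FALSE]
}

# naive all-positions Hamming mapper (both strands, circular wrap)
oracle_map_read <- function(rseq, genome_seq, max_mismatch, circular = TRUE) {
  n <- nchar(genome_seq)
  len <- nchar(rseq)
  ext <- if (circular) paste0(genome_seq, substr(genome_seq, 1, len - 1)) else genome_seq
  ev <- strsplit(ext, "")[[1]]
  hits <- list()
  for (strand in c("+", "-")) {
    pv <- strsplit(if (strand == "+") rseq else plastex::revcomp(rseq), "")[[1]]
    for (s in seq_len(if (circular) n else n - len + 1L)) {
      mm <- sum(pv != ev[s:(s + len - 1L)])
      if (mm <= max_mismatch) {
        hits[[length(hits) + 1L]] <- data.frame(start = s, strand = strand,
                                                mismatches = mm)
      }
    }
  }
  if (length(hits) == 0) return(data.frame(start = integer(), strand = character(),
                                           mismatches = integer()))
  h <- do.call(rbind, hits)
  h <- h[h$mismatches == min(h$mismatches), , drop = FALSE]
  h[order(h$start, h$strand), , drop = FALSE]
}

# independent per-position coverage from alignment intervals
oracle_coverage <- function(alignments, n) {
  cov <- numeric(n)
  for (i in seq_len(nrow(alignments))) {
    for (k in seq_len(alignments$read_length[i])) {
      pos <- ((alignments$start[i] + k - 2L) %% n) + 1L
      cov[pos] <- cov[pos] + 1
    }
  }
  cov
}

comp_char <- function(ch) chartr("ACGT", "TGCA", ch)

random_seq <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = ""))
}

# small shared fixture: genome + gene catalogue
tiny_world <- function(seed = 42, lsc = 8000, ssc = 1500, ir = 1200, ...) {
  sim <- plastex::make_plastome(lsc, ssc, ir, seed = seed)
  genes <- plastex::plant_genes(sim$genome, sim$partition, seed = seed + 1, ...)
  list(genome = sim$genome, partition = sim$partition, genes = genes)
}
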