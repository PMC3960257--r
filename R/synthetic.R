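# Seeded synthetic data: quadripartite genomes, annotations, RNA-seq reads
# with planted editing sites, and small-RNA read sets with planted
# footprints. Every generator is deterministic given its seed and returns
# its ground truth alongside the data, so downstream recovery tests read
# truth only from the returned objects.

random_bases <- function(n, gc = 0.38) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Ensure a single-copy segment cannot extend the planted IR match by
# chance: if its last base complements its first, the IR pair flanked by
# this segment would be extendable, so the planted boundary would not be
# the maximal match. Setting the last base equal to the first always breaks
# the complement (no DNA base is its own complement) and is deterministic.
break_self_complement <- function(s) {
  n <- nchar(s)
  if (n >= 2 && substr(s, n, n) == comp(substr(s, 1, 1))) {
    substr(s, n, n) <- substr(s, 1, 1)
  }
  s
}

#' Generate a quadripartite plastome
#'
#' Builds `LSC + IR + SSC + revcomp(IR)` from i.i.d. bases at the target GC
#' content, so the IRa copy is exactly the reverse complement of IRb.
#'
#' @param lsc_len,ssc_len,ir_len Region lengths in bp.
#' @param gc Target GC fraction (default 0.38, typical for grass plastomes).
#' @param seed Integer seed; identical seeds give byte-identical genomes.
#' @return List with `genome` (a [plastome()]) and `partition` (the ground
#'   truth [region_partition()]).
#' @examples
#' sim <- make_plastome(5000, 800, 1000, seed = 7)
#' plastome_length(sim$genome)  # 7800
#' @export
make_plastome <- function(lsc_len, ssc_len, ir_len, gc = 0.38, seed = 1) {
  stopifnot(lsc_len > 0, ssc_len > 0, ir_len > 0, gc > 0, gc < 1)
  with_seed(seed, {
    lsc <- break_self_complement(random_bases(lsc_len, gc))
    ir <- random_bases(ir_len, gc)
    ssc <- break_self_complement(random_bases(ssc_len, gc))
    genome <- plastome(paste0(lsc, ir, ssc, revcomp(ir)),
                       id = sprintf("synthetic_plastome_seed%d", as.integer(seed)))
    part <- region_partition(lsc_len = lsc_len, ssc_len = ssc_len,
                             ir_len = ir_len, genome_id = genome$id)
    part$rotation_offset <- 0L
    list(genome = genome, partition = part)
  })
}

#' Plant a gene catalogue on a synthetic plastome
#'
#' Distributes non-overlapping CDS genes over the single-copy regions, gives
#' the requested number of them introns (two exons), mirrors the requested
#' number of genes into both inverted-repeat copies (the IRa copy on the
#' opposite strand, linked via `ir_copy_of`), and optionally adds one
#' two-part trans-spliced gene. CDS lengths are multiples of 3.
#'
#' @param genome A [plastome()].
#' @param partition Ground-truth [region_partition()]; detected from the
#'   genome when `NULL`.
#' @param n_genes Number of single-copy genes (default 8).
#' @param n_intron_genes How many of them carry one intron (default 2).
#' @param n_ir_duplicates Genes duplicated across the IRs (default 1).
#' @param include_trans_spliced Add one trans-spliced gene (default `FALSE`)?
#' @param exon_len Baseline exon length in bp, a multiple of 3 (default 300).
#' @param seed Integer seed.
#' @return A [gene_models()] tibble (the catalogue is its own ground truth).
#' @export
plant_genes <- function(genome, partition = NULL, n_genes = 8, n_intron_genes = 2,
                        n_ir_duplicates = 1, include_trans_spliced = FALSE,
                        exon_len = 300, seed = 1) {
  genome <- as_plastome(genome)
  if (is.null(partition)) partition <- detect_quadripartite(genome)
  stopifnot(n_intron_genes <= n_genes, exon_len %% 3 == 0)
  lsc <- region_interval(partition, "LSC")
  ssc <- region_interval(partition, "SSC")
  irb <- region_interval(partition, "IRb")
  ira <- region_interval(partition, "IRa")

  with_seed(seed, {
    gap <- 60L
    # per-gene footprint: intron genes hold two exons plus the intron gap
    widths <- ifelse(seq_len(n_genes) <= n_intron_genes,
                     2L * exon_len + gap, exon_len) + 2L * gap
    if (include_trans_spliced) widths <- c(widths, exon_len + 2L * gap)
    offsets <- cumsum(c(0L, widths[-length(widths)]))
    if (lsc[1] + sum(widths) - 1L > lsc[2]) {
      px_abort("LSC too short for the requested genes", "insufficient_space")
    }
    rows <- list()
    strands <- sample(c("+", "-"), n_genes, replace = TRUE)
    for (g in seq_len(n_genes)) {
      s <- lsc[1] + offsets[g] + gap
      if (g <= n_intron_genes) {
        exons <- tibble::tibble(start = c(s, s + exon_len + gap),
                                end = c(s + exon_len - 1L, s + exon_len + gap + exon_len - 1L),
                                strand = strands[g], part = 1L)
      } else {
        exons <- tibble::tibble(start = s, end = s + exon_len - 1L,
                                strand = strands[g], part = 1L)
      }
      rows[[g]] <- tibble::tibble(
        gene = sprintf("sg%02d", g), type = "CDS", strand = strands[g],
        exons = list(exons), trans_spliced = FALSE,
        ir_copy_of = NA_character_, region = "LSC", pseudo = FALSE
      )
    }
    if (include_trans_spliced) {
      # 5' exon in the last LSC slot, 3' exon in the SSC, independent strands
      s1 <- lsc[1] + offsets[n_genes + 1L] + gap
      s2 <- ssc[1] + gap
      if (s2 + exon_len - 1L > ssc[2]) px_abort("SSC too short for trans-spliced part", "insufficient_space")
      exons <- tibble::tibble(start = c(s1, s2), end = c(s1 + exon_len - 1L, s2 + exon_len - 1L),
                              strand = c("+", "-"), part = c(1L, 2L))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        gene = "sg_trans", type = "CDS", strand = "+", exons = list(exons),
        trans_spliced = TRUE, ir_copy_of = NA_character_, region = "LSC",
        pseudo = FALSE
      )
    }
    if (n_ir_duplicates > 0) {
      ir_len <- irb[2] - irb[1] + 1L
      dup_slot <- exon_len + 2L * gap
      if (n_ir_duplicates * dup_slot > ir_len) {
        px_abort("IR too short for the requested duplicates", "insufficient_space")
      }
      for (d in seq_len(n_ir_duplicates)) {
        s <- irb[1] + (d - 1L) * dup_slot + gap
        e <- s + exon_len - 1L
        name_b <- sprintf("ir%02d", d)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          gene = name_b, type = "CDS", strand = "+",
          exons = list(tibble::tibble(start = s, end = e, strand = "+", part = 1L)),
          trans_spliced = FALSE, ir_copy_of = NA_character_, region = "IR",
          pseudo = FALSE
        )
        # mirrored coordinates in IRa, opposite strand
        ms <- ira[2] - (e - irb[1])
        me <- ira[2] - (s - irb[1])
        rows[[length(rows) + 1L]] <- tibble::tibble(
          gene = paste0(name_b, "_ira"), type = "CDS", strand = "-",
          exons = list(tibble::tibble(start = ms, end = me, strand = "-", part = 1L)),
          trans_spliced = FALSE, ir_copy_of = name_b, region = "IR",
          pseudo = FALSE
        )
      }
    }
    gene_models(dplyr::bind_rows(rows))
  })
}

#' Simulate a paired-end RNA-seq library with planted editing sites
#'
#' Fragments are drawn per gene with probability proportional to
#' `rate * coding_length` and placed uniformly so that the whole fragment
#' lies inside one exon. Each fragment covering a planted editing site
#' carries the alternate base with probability equal to the site's
#' efficiency (decided once per fragment — both mates agree), then uniform
#' substitution errors are added per read base.
#'
#' @param genome A [plastome()].
#' @param annotation A [gene_models()] tibble.
#' @param expression_rates Named per-base transcription rates (names = gene
#'   names; default 1 for every unique gene record).
#' @param editing_sites Tibble `position`, `alt`, `efficiency` (genomic
#'   coordinates and forward-strand alternate base; efficiencies in `[0,1]`).
#' @param n_fragments Library size (default 2000).
#' @param read_len Read length (default 100).
#' @param fragment_len Fragment length (default 300; shrunk to the exon when
#'   an exon is shorter).
#' @param error_rate Per-base substitution error rate (default 0.001).
#' @param seed Integer seed.
#' @return List: `reads` (tibble `id`, `seq`; mates tagged `/1`, `/2`),
#'   `truth` (list with `fragment_counts` per gene, and per-site `editing`
#'   tallies `n_covering`, `n_alt`).
#' @export
simulate_rnaseq <- function(genome, annotation, expression_rates = NULL,
                            editing_sites = NULL, n_fragments = 2000,
                            read_len = 100, fragment_len = 300,
                            error_rate = 0.001, seed = 1) {
  genome <- as_plastome(genome)
  use <- annotation[is.na(annotation$ir_copy_of), ]
  rates <- rep(1, nrow(use))
  names(rates) <- use$gene
  if (!is.null(expression_rates)) {
    stopifnot(all(names(expression_rates) %in% use$gene))
    rates[names(expression_rates)] <- expression_rates
  }
  lens <- coding_length(use)
  weights <- rates * lens
  if (!is.null(editing_sites)) {
    editing_sites <- tibble::as_tibble(editing_sites)
    stopifnot(all(editing_sites$efficiency >= 0 & editing_sites$efficiency <= 1))
  }

  with_seed(seed, {
    gene_idx <- sample.int(nrow(use), n_fragments, replace = TRUE,
                           prob = weights / sum(weights))
    reads <- vector("list", n_fragments)
    edit_truth <- if (!is.null(editing_sites)) {
      cbind(editing_sites, n_covering = 0L, n_alt = 0L)
    } else NULL
    for (f in seq_len(n_fragments)) {
      rec <- use[gene_idx[f], ]
      ex <- rec$exons[[1]]
      # choose an exon (by length), then a fragment fully inside it
      ei <- sample.int(nrow(ex), 1L, prob = ex$end - ex$start + 1)
      flen <- min(fragment_len, ex$end[ei] - ex$start[ei] + 1L)
      fstart <- ex$start[ei] + sample.int(ex$end[ei] - ex$start[ei] + 1L - flen + 1L, 1L) - 1L
      fseq <- substr(genome$seq, fstart, fstart + flen - 1L)
      if (!is.null(edit_truth)) {
        cover <- which(editing_sites$position >= fstart &
                         editing_sites$position <= fstart + flen - 1L)
        for (s in cover) {
          edit_truth$n_covering[s] <- edit_truth$n_covering[s] + 1L
          if (stats::runif(1) < editing_sites$efficiency[s]) {
            off <- editing_sites$position[s] - fstart + 1L
            substr(fseq, off, off) <- editing_sites$alt[s]
            edit_truth$n_alt[s] <- edit_truth$n_alt[s] + 1L
          }
        }
      }
      # transcript-strand fragment; mate 1 from the 5' end, mate 2 reverse
      tseq <- if (rec$strand == "-") revcomp(fseq) else fseq
      rlen <- min(read_len, flen)
      r1 <- substr(tseq, 1L, rlen)
      r2 <- revcomp(substr(tseq, flen - rlen + 1L, flen))
      reads[[f]] <- tibble::tibble(
        id = sprintf("frag%06d/%d", f, 1:2), seq = c(r1, r2)
      )
    }
    reads <- dplyr::bind_rows(reads)
    if (error_rate > 0) reads$seq <- add_substitution_errors(reads$seq, error_rate)
    truth <- list(
      fragment_counts = tibble::tibble(gene = use$gene,
                                       fragment_count = tabulate(gene_idx, nrow(use))),
      editing = if (!is.null(edit_truth)) tibble::as_tibble(edit_truth) else NULL
    )
    list(reads = reads, truth = truth)
  })
}

add_substitution_errors <- function(seqs, error_rate) {
  vapply(seqs, function(s) {
    v <- strsplit(s, "")[[1]]
    hit <- which(stats::runif(length(v)) < error_rate)
    for (i in hit) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1L)
    paste(v, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate a small-RNA library with planted footprints
#'
#' Each footprint contributes `depth` reads of 20-24 nt sharing its core
#' sequence, with up to +/- 2 nt of end jitter (the exact core is the most
#' common form). Background reads of 31-35 nt are tiled across the given
#' background intervals, emulating degradation fragments of abundant
#' transcripts.
#'
#' @param genome A [plastome()].
#' @param footprints Tibble `start`, `end` (core span, 18-24 nt wide),
#'   `depth`, optional `strand` (default `+`).
#' @param background Tibble of `start`, `end` intervals to tile with long
#'   reads (e.g. exon spans of abundant genes); may be `NULL`.
#' @param background_step Tiling step in bp (default 3).
#' @param seed Integer seed.
#' @return List: `reads` (tibble `id`, `seq`), `truth` (footprint tibble
#'   with the planted `core_sequence` and read counts, plus
#'   `n_short_reads`, `n_long_reads`).
#' @export
simulate_srna <- function(genome, footprints, background = NULL,
                          background_step = 3, seed = 1) {
  genome <- as_plastome(genome)
  footprints <- tibble::as_tibble(footprints)
  if (!"strand" %in% names(footprints)) footprints$strand <- "+"
  n <- plastome_length(genome)
  stopifnot(all(footprints$start >= 1), all(footprints$end <= n))

  with_seed(seed, {
    reads <- list()
    footprints$core_sequence <- NA_character_
    for (i in seq_len(nrow(footprints))) {
      s <- footprints$start[i]; e <- footprints$end[i]
      core <- substr(genome$seq, s, e)
      if (footprints$strand[i] == "-") core <- revcomp(core)
      footprints$core_sequence[i] <- core
      depth <- footprints$depth[i]
      # at least half the stack is the exact core; the rest jitters +/- 2 nt
      jitter_s <- ifelse(stats::runif(depth) < 0.5, 0L,
                         sample(-2:2, depth, replace = TRUE))
      jitter_e <- ifelse(jitter_s == 0L & stats::runif(depth) < 0.8, 0L,
                         sample(-2:2, depth, replace = TRUE))
      rs <- pmax(1L, s + jitter_s)
      re <- pmin(n, e + jitter_e)
      len <- re - rs + 1L
      bad <- len < 20L | len > 24L
      rs[bad] <- s; re[bad] <- e
      seqs <- substring(genome$seq, rs, re)
      if (footprints$strand[i] == "-") seqs <- revcomp(seqs)
      reads[[length(reads) + 1L]] <- tibble::tibble(
        id = sprintf("fp%02d_%04d", i, seq_len(depth)), seq = seqs
      )
    }
    n_short <- sum(footprints$depth)
    n_long <- 0L
    if (!is.null(background) && nrow(background) > 0) {
      background <- tibble::as_tibble(background)
      for (b in seq_len(nrow(background))) {
        starts <- seq(background$start[b], max(background$start[b], background$end[b] - 35L),
                      by = background_step)
        lens <- sample(31:35, length(starts), replace = TRUE)
        ends <- pmin(starts + lens - 1L, n)
        seqs <- substring(genome$seq, starts, ends)
        keep <- nchar(seqs) > 30L
        n_long <- n_long + sum(keep)
        reads[[length(reads) + 1L]] <- tibble::tibble(
          id = sprintf("bg%02d_%04d", b, seq_len(sum(keep))), seq = seqs[keep]
        )
      }
    }
    list(reads = dplyr::bind_rows(reads),
         truth = list(footprints = footprints,
                      n_short_reads = n_short, n_long_reads = n_long))
  })
}
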