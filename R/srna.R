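# Small-RNA footprint discovery from size-stratified coverage.
# Footprints (e.g. PPR-protected transcript termini) show up as stacks of
# 20-24 nt reads with a shared core sequence, against a background of longer
# RNA degradation fragments (> 30 nt).

#' Size-stratified coverage of small-RNA reads
#'
#' Maps reads with zero mismatches (multi-mapped reads contribute to every
#' placement) and accumulates per-base coverage separately for the short
#' (20-24 nt) and long (> 30 nt) size classes.
#'
#' @param reads Tibble with `id`, `seq`.
#' @param genome A [plastome()].
#' @param short_range Inclusive length bounds of the short class (default 20-24).
#' @param long_min Long class is every read strictly longer than this (default 30).
#' @return List with per-base numeric vectors `short_cov` and `long_cov`
#'   (length = genome length) and the short-class `alignments` tibble for
#'   downstream locus support.
#' @export
size_stratified_coverage <- function(reads, genome, short_range = c(20, 24),
                                     long_min = 30) {
  genome <- as_plastome(genome)
  n <- plastome_length(genome)
  short <- filter_reads_by_length(reads, short_range[1], short_range[2])
  long <- filter_reads_by_length(reads, long_min + 1, NULL)
  aln_short <- map_reads(short, genome, max_mismatch = 0, report_multi = TRUE)
  aln_long <- map_reads(long, genome, max_mismatch = 0, report_multi = TRUE)
  list(
    short_cov = coverage_vector(aln_short, n),
    long_cov = coverage_vector(aln_long, n),
    alignments = aln_short
  )
}

coverage_vector <- function(alignments, n) {
  cov <- numeric(n)
  for (i in seq_len(nrow(alignments))) {
    pos <- ((alignments$start[i] + seq_len(alignments$read_length[i]) - 2L) %% n) + 1L
    cov[pos] <- cov[pos] + 1
  }
  cov
}

#' Call small-RNA footprint loci from size-stratified coverage
#'
#' A position belongs to a locus when short-class coverage reaches
#' `min_reads` and exceeds the long-class background by
#' `short / (long + 1) >= enrichment_ratio` (the pseudo-count tolerates zero
#' long-read coverage). Maximal qualifying runs closer than `merge_gap`
#' are merged.
#'
#' @param short_cov,long_cov Per-base coverage vectors (same length).
#' @param min_reads Minimum short-read coverage (default 20).
#' @param enrichment_ratio Minimum short/long enrichment (default 5).
#' @param merge_gap Merge runs separated by fewer than this many bases
#'   (default 10).
#' @return Tibble of loci: `start`, `end`, `peak_cov`.
#' @export
call_srna_loci <- function(short_cov, long_cov, min_reads = 20,
                           enrichment_ratio = 5, merge_gap = 10) {
  stopifnot(length(short_cov) == length(long_cov))
  mask <- short_cov >= min_reads & short_cov / (long_cov + 1) >= enrichment_ratio
  if (!any(mask)) return(tibble::tibble(start = integer(), end = integer(),
                                        peak_cov = double()))
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- tibble::tibble(start = starts[r$values], end = ends[r$values])
  # merge runs separated by small gaps
  merged <- runs[1, ]
  for (i in seq_len(nrow(runs))[-1]) {
    if (runs$start[i] - merged$end[nrow(merged)] - 1L < merge_gap) {
      merged$end[nrow(merged)] <- runs$end[i]
    } else {
      merged <- dplyr::bind_rows(merged, runs[i, ])
    }
  }
  merged$peak_cov <- vapply(seq_len(nrow(merged)), function(i) {
    max(short_cov[seq(merged$start[i], merged$end[i])])
  }, numeric(1))
  merged
}

#' Core sequence of a small-RNA locus
#'
#' The most abundant unique read sequence among short-class reads whose
#' alignment overlaps the locus; ties break lexicographically. The reported
#' strand is the majority alignment strand of the supporting reads (`+` on
#' a tie).
#'
#' @param locus One-row tibble with `start`, `end`.
#' @param reads Tibble with `id`, `seq`.
#' @param alignments Short-class alignments (from [size_stratified_coverage()]).
#' @return One-row tibble `core_sequence`, `core_length`, `read_count`
#'   (supporting reads), `core_reads` (reads with the core sequence), `strand`.
#' @export
core_sequence <- function(locus, reads, alignments) {
  ov <- alignments$start <= locus$end &
    (alignments$start + alignments$read_length - 1L) >= locus$start
  sup <- alignments[ov, ]
  if (nrow(sup) == 0) px_abort("locus has no supporting reads", "empty_locus")
  seqs <- stats::setNames(toupper(reads$seq), reads$id)[sup$read_id]
  tab <- sort(table(seqs), decreasing = TRUE)
  top <- names(tab)[tab == max(tab)]
  core <- sort(top)[1]
  strand_tab <- table(factor(sup$strand, levels = c("+", "-")))
  tibble::tibble(
    core_sequence = core,
    core_length = nchar(core),
    read_count = nrow(sup),
    core_reads = as.integer(max(tab)),
    strand = if (strand_tab[["-"]] > strand_tab[["+"]]) "-" else "+"
  )
}

#' Classify a small-RNA locus by genomic context
#'
#' The locus midpoint decides the class: `CDS` when inside an exon, `intron`
#' when inside an intron, otherwise intergenic — sub-classified as
#' `intergenic_5prime` when within `window_5prime` of a same-strand start
#' codon (5' end of a gene), `intergenic_3prime` when within `end_window`
#' of a stop codon, else `intergenic_other`. The 5' window takes precedence.
#'
#' @param locus One-row tibble with `start`, `end` and optionally `strand`.
#' @param annotation A [gene_models()] tibble.
#' @param window_5prime Window around the start codon, `c(upstream, downstream)`
#'   offsets in gene orientation (default `c(-150, 50)`).
#' @param end_window Maximum distance from a stop codon (default 100).
#' @return Location class string.
#' @export
classify_locus_location <- function(locus, annotation,
                                    window_5prime = c(-150, 50), end_window = 100) {
  mid <- as.integer(floor((locus$start + locus$end) / 2))
  cls <- location_class_vector(annotation, max(mid, max(purrr::map_int(annotation$exons, ~max(.x$end)))))
  base_class <- cls[mid]
  if (base_class %in% c("CDS", "intron")) return(base_class)
  strand <- locus$strand %||% NULL
  for (g in seq_len(nrow(annotation))) {
    rec <- annotation[g, ]
    ex <- rec$exons[[1]]
    if (!is.null(strand) && !is.na(strand) && rec$strand != strand) next
    if (rec$strand == "+") {
      start_codon <- min(ex$start)
      if (mid >= start_codon + window_5prime[1] && mid <= start_codon + window_5prime[2]) {
        return("intergenic_5prime")
      }
    } else {
      start_codon <- max(ex$end)
      if (mid <= start_codon - window_5prime[1] && mid >= start_codon - window_5prime[2]) {
        return("intergenic_5prime")
      }
    }
  }
  for (g in seq_len(nrow(annotation))) {
    rec <- annotation[g, ]
    ex <- rec$exons[[1]]
    if (!is.null(strand) && !is.na(strand) && rec$strand != strand) next
    stop_codon <- if (rec$strand == "+") max(ex$end) else min(ex$start)
    if (abs(mid - stop_codon) <= end_window) return("intergenic_3prime")
  }
  "intergenic_other"
}

#' Full small-RNA footprint profile of a read set
#'
#' Pipeline convenience: size-stratified mapping, locus calling, core
#' sequence extraction and location classification in one call.
#'
#' @inheritParams size_stratified_coverage
#' @inheritParams call_srna_loci
#' @param annotation Optional [gene_models()] tibble for location classes.
#' @param ... Passed to [classify_locus_location()].
#' @return Tibble of loci with core sequences, support and location class;
#'   the coverage vectors are attached as attribute `coverage`.
#' @export
srna_profile <- function(reads, genome, annotation = NULL, min_reads = 20,
                         enrichment_ratio = 5, merge_gap = 10, ...) {
  cov <- size_stratified_coverage(reads, genome)
  loci <- call_srna_loci(cov$short_cov, cov$long_cov, min_reads,
                         enrichment_ratio, merge_gap)
  if (nrow(loci) > 0) {
    cores <- purrr::map_dfr(seq_len(nrow(loci)),
                            function(i) core_sequence(loci[i, ], reads, cov$alignments))
    loci <- dplyr::bind_cols(loci, cores)
    if (!is.null(annotation)) {
      loci$location_class <- vapply(seq_len(nrow(loci)), function(i) {
        classify_locus_location(loci[i, ], annotation, ...)
      }, character(1))
    }
  }
  attr(loci, "coverage") <- cov[c("short_cov", "long_cov")]
  loci
}

#' Match small RNAs against a reference set by global-alignment identity
#'
#' For each query the best reference under unit-cost global alignment is
#' reported; identity is matches divided by alignment length (gaps
#' included). Pairs reaching `min_identity` are flagged as matched.
#'
#' @param query,reference Tibbles with `name`, `seq` (15-30 nt sequences;
#'   RNA or DNA alphabet).
#' @param min_identity Identity threshold for a match (default 0.90).
#' @return Tibble `query`, `reference`, `identity`, `matched`, one row per
#'   query (best reference), sorted by decreasing identity.
#' @export
ortholog_match <- function(query, reference, min_identity = 0.90) {
  query <- tibble::as_tibble(query); reference <- tibble::as_tibble(reference)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  rows <- purrr::map_dfr(seq_len(nrow(query)), function(i) {
    q <- Biostrings::DNAString(to_dna(toupper(query$seq[i])))
    best <- NULL
    for (j in seq_len(nrow(reference))) {
      r <- Biostrings::DNAString(to_dna(toupper(reference$seq[j])))
      aln <- Biostrings::pairwiseAlignment(q, r, type = "global",
                                           substitutionMatrix = mat,
                                           gapOpening = 0, gapExtension = 1)
      alen <- nchar(as.character(Biostrings::alignedPattern(aln)))
      ident <- Biostrings::nmatch(aln) / alen
      if (is.null(best) || ident > best$identity) {
        best <- tibble::tibble(query = query$name[i], reference = reference$name[j],
                               identity = ident)
      }
    }
    best
  })
  rows$matched <- rows$identity >= min_identity
  dplyr::arrange(rows, dplyr::desc(.data$identity))
}
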