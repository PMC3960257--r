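# Exhaustive, mismatch-bounded, ungapped read mapping and pileups.
# Deliberately simple: every placement on both strands is scored by Hamming
# distance (Biostrings does the inner scan), which is exact and fast enough
# for desk-scale genomes; there is no heuristic seeding to miss placements.

#' Map reads to a plastome by exhaustive ungapped search
#'
#' Each read is scored at every position on both strands by Hamming
#' distance; placements with more than `max_mismatch` mismatches are
#' discarded, and among the rest only the equally-best placements are kept.
#' `N` in read or genome counts as a mismatch. On circular genomes
#' placements may wrap the origin (reported start in `1..n`).
#'
#' @param reads Tibble with columns `id` and `seq`.
#' @param genome A [plastome()].
#' @param max_mismatch Maximum mismatches tolerated (default 2).
#' @param report_multi Report all equally-best placements (default `TRUE`)?
#'   Otherwise one deterministic placement: lowest start, `+` strand first.
#' @param min_read_length Reads shorter than this are left unmapped (default 15).
#' @return Tibble of alignments: `read_id`, `start`, `strand`, `mismatches`,
#'   `multi_hits` (count of equally-best placements of that read),
#'   `read_length`. Unmapped read ids are attached as attribute `unmapped`
#'   and retrievable with [unmapped_reads()].
#' @examples
#' sim <- make_plastome(400, 100, 100, seed = 1)
#' rd <- tibble::tibble(id = "r1", seq = substr(sim$genome$seq, 101, 130))
#' map_reads(rd, sim$genome)
#' @export
map_reads <- function(reads, genome, max_mismatch = 2, report_multi = TRUE,
                      min_read_length = 15) {
  genome <- as_plastome(genome)
  reads <- tibble::as_tibble(reads)
  stopifnot(all(c("id", "seq") %in% names(reads)))
  n <- plastome_length(genome)
  max_len <- if (nrow(reads)) max(nchar(reads$seq)) else 0L
  subject_seq <- if (genome$circular && max_len > 1L) {
    paste0(genome$seq, substr(genome$seq, 1L, min(max_len - 1L, n)))
  } else genome$seq
  subject <- Biostrings::DNAString(subject_seq)

  # identical read sequences share one scan (footprint stacks, mate pairs)
  useq <- unique(toupper(reads$seq))
  lens <- nchar(useq)
  eligible <- lens >= min_read_length & lens <= n

  # exact matching is batched per width through an Aho-Corasick dictionary;
  # the mismatch-tolerant scan stays per sequence
  fast <- max_mismatch == 0 & eligible & !grepl("N", useq, fixed = TRUE)
  fast_hits <- list()
  if (any(fast)) {
    idx_fast <- which(fast)
    for (w in unique(lens[idx_fast])) {
      grp <- idx_fast[lens[idx_fast] == w]
      for (strand in c("+", "-")) {
        pats <- if (strand == "+") useq[grp] else revcomp(useq[grp])
        pd <- Biostrings::PDict(Biostrings::DNAStringSet(pats))
        ml <- Biostrings::matchPDict(pd, subject)
        starts_list <- IRanges::start(ml)
        all_starts <- unlist(starts_list, use.names = FALSE)
        idx <- rep(grp, S4Vectors::elementNROWS(starts_list))
        keep <- all_starts <= n
        if (any(keep)) {
          fast_hits[[length(fast_hits) + 1L]] <- tibble::tibble(
            seq_idx = idx[keep], start = all_starts[keep],
            strand = strand, mismatches = 0L
          )
        }
      }
    }
  }
  fast_hits <- dplyr::bind_rows(fast_hits)
  fast_res <- NULL
  if (nrow(fast_hits) > 0) {
    # every exact placement is equally best; rank and count in bulk
    fast_res <- dplyr::arrange(fast_hits, .data$seq_idx, .data$start, .data$strand)
    fast_res <- dplyr::group_by(fast_res, .data$seq_idx)
    fast_res <- dplyr::mutate(fast_res, multi_hits = dplyr::n())
    if (!report_multi) fast_res <- dplyr::slice_head(fast_res, n = 1)
    fast_res <- dplyr::ungroup(fast_res)
    fast_res$seq_key <- useq[fast_res$seq_idx]
    fast_res$read_length <- lens[fast_res$seq_idx]
    fast_res$seq_idx <- NULL
  }

  res <- vector("list", length(useq))
  for (i in which(eligible & !fast)) {
    rseq <- useq[i]
    len <- lens[i]
    {
      hits <- list()
      for (strand in c("+", "-")) {
        pat <- Biostrings::DNAString(if (strand == "+") rseq else revcomp(rseq))
        m <- Biostrings::matchPattern(pat, subject, max.mismatch = max_mismatch,
                                      with.indels = FALSE, fixed = TRUE)
        starts <- BiocGenerics::start(m)
        starts <- starts[starts <= n]        # wrap placements start within 1..n
        if (length(starts) == 0) next
        mm <- if (max_mismatch == 0) integer(length(starts)) else {
          Biostrings::neditStartingAt(pat, subject, starting.at = starts,
                                      with.indels = FALSE, fixed = TRUE)
        }
        keep <- mm <= max_mismatch
        if (!any(keep)) next
        hits[[strand]] <- tibble::tibble(start = starts[keep], strand = strand,
                                         mismatches = as.integer(mm[keep]))
      }
      hits <- dplyr::bind_rows(hits)
    }
    if (nrow(hits) == 0) next
    best <- min(hits$mismatches)
    hits <- hits[hits$mismatches == best, , drop = FALSE]
    hits <- hits[order(hits$start, hits$strand), , drop = FALSE]
    k <- nrow(hits)
    if (!report_multi) hits <- hits[1L, , drop = FALSE]
    hits$seq_key <- rseq
    hits$multi_hits <- k
    hits$read_length <- len
    res[[i]] <- hits
  }
  out <- dplyr::bind_rows(c(list(fast_res), res))
  if (nrow(out) > 0) {
    # fan the per-sequence placements back out to every read carrying it
    key <- tibble::tibble(read_id = reads$id, seq_key = toupper(reads$seq))
    out <- dplyr::inner_join(key, out, by = "seq_key",
                             relationship = "many-to-many")
    out$seq_key <- NULL
  }
  if (nrow(out) == 0) {
    out <- tibble::tibble(read_id = character(), start = integer(),
                          strand = character(), mismatches = integer(),
                          multi_hits = integer(), read_length = integer())
  } else {
    out <- out[, c("read_id", "start", "strand", "mismatches", "multi_hits",
                   "read_length")]
  }
  attr(out, "unmapped") <- setdiff(reads$id, out$read_id)
  out
}

#' Read ids left unmapped by [map_reads()]
#'
#' @param alignments Result of [map_reads()].
#' @return Character vector of unmapped read ids.
#' @export
unmapped_reads <- function(alignments) attr(alignments, "unmapped") %||% character(0)

#' Per-position, per-strand base counts from alignments
#'
#' Minus-strand read bases are complemented into genome-strand space, so a
#' column's counts always refer to forward-strand base identities; the
#' `strand` column records which strand the supporting read aligned to.
#'
#' @param alignments Tibble from [map_reads()] (or [read_sam()]).
#' @param reads Tibble with `id`, `seq` for the aligned reads.
#' @param genome A [plastome()].
#' @return Tibble `position`, `strand`, `base`, `count` (only non-zero rows).
#' @export
build_pileup <- function(alignments, reads, genome) {
  genome <- as_plastome(genome)
  n <- plastome_length(genome)
  if (nrow(alignments) == 0) {
    return(tibble::tibble(position = integer(), strand = character(),
                          base = character(), count = integer()))
  }
  seqs <- stats::setNames(toupper(reads$seq), reads$id)
  if (!all(alignments$read_id %in% names(seqs))) {
    px_abort("alignment references an unknown read id", "unknown_read")
  }
  lens <- nchar(seqs[alignments$read_id])
  pos_list <- vector("list", nrow(alignments))
  base_list <- vector("list", nrow(alignments))
  for (i in seq_len(nrow(alignments))) {
    len <- lens[[i]]
    rseq <- seqs[[alignments$read_id[i]]]
    oriented <- if (alignments$strand[i] == "+") rseq else revcomp(rseq)
    pos <- ((alignments$start[i] + seq_len(len) - 2L) %% n) + 1L
    pos_list[[i]] <- pos
    base_list[[i]] <- strsplit(oriented, "")[[1]]
  }
  long <- tibble::tibble(
    position = unlist(pos_list),
    strand = rep(alignments$strand, times = lens),
    base = unlist(base_list)
  )
  dplyr::count(long, .data$position, .data$strand, .data$base, name = "count")
}

#' Collapse a pileup to per-position base totals
#'
#' Sums the two strands into one named count per base, wide format, for
#' consumers that do not need strand resolution (e.g. editing calling on an
#' unstranded library).
#'
#' @param pileup Tibble from [build_pileup()].
#' @return Tibble `position`, `A`, `C`, `G`, `T`, `N`, `coverage`.
#' @export
pileup_totals <- function(pileup) {
  if (nrow(pileup) == 0) {
    return(tibble::tibble(position = integer(), A = integer(), C = integer(),
                          G = integer(), T = integer(), N = integer(),
                          coverage = integer()))
  }
  wide <- tidyr::pivot_wider(
    dplyr::count(pileup, .data$position, .data$base, wt = .data$count, name = "count"),
    names_from = "base", values_from = "count", values_fill = 0L
  )
  for (b in c("A", "C", "G", "T", "N")) if (!b %in% names(wide)) wide[[b]] <- 0L
  wide <- wide[, c("position", "A", "C", "G", "T", "N")]
  wide$coverage <- wide$A + wide$C + wide$G + wide$T + wide$N
  dplyr::arrange(wide, .data$position)
}

#' Filter reads by length
#'
#' @param reads Tibble with `id`, `seq`.
#' @param min_len,max_len Inclusive length bounds (either may be `NULL`).
#' @return The subset of `reads` in order, with the complement subset
#'   attached as attribute `rejected`.
#' @export
filter_reads_by_length <- function(reads, min_len = NULL, max_len = NULL) {
  reads <- tibble::as_tibble(reads)
  len <- nchar(reads$seq)
  keep <- rep(TRUE, nrow(reads))
  if (!is.null(min_len)) keep <- keep & len >= min_len
  if (!is.null(max_len)) keep <- keep & len <= max_len
  out <- reads[keep, ]
  attr(out, "rejected") <- reads[!keep, ]
  out
}
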