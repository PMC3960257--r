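# Fragment counting and FPKM expression profiling.

# Collapse mate alignments into candidate fragment placements. Mates share a
# fragment id (read ids with a trailing /1 or /2); alignments of one fragment
# are clustered by genomic proximity (gap > max_insert starts a new cluster,
# so IR-duplicated placements stay separate), and each cluster becomes one
# candidate placement spanning its alignments.
fragment_placements <- function(alignments, max_insert = 1000) {
  if (nrow(alignments) == 0) {
    return(tibble::tibble(fragment_id = character(), start = integer(),
                          end = integer(), midpoint = integer()))
  }
  al <- tibble::as_tibble(alignments)
  al$fragment_id <- sub("/[12]$", "", al$read_id)
  al$end <- al$start + al$read_length - 1L
  al <- dplyr::arrange(al, .data$fragment_id, .data$start)
  al <- dplyr::group_by(al, .data$fragment_id)
  al <- dplyr::mutate(al, cluster = cumsum(
    c(1L, as.integer(.data$start[-1] > cummax(.data$end)[-dplyr::n()] + max_insert))
  ))
  out <- dplyr::summarise(
    dplyr::group_by(dplyr::ungroup(al), .data$fragment_id, .data$cluster),
    start = min(.data$start), end = max(.data$end), .groups = "drop"
  )
  out$midpoint <- as.integer(floor((out$start + out$end) / 2))
  out[, c("fragment_id", "start", "end", "midpoint")]
}

#' Count fragments per gene by midpoint assignment
#'
#' Paired alignments are collapsed to fragments (mates counted once); a
#' fragment is assigned to a gene when its placement midpoint lies within an
#' exon of that gene. With `multimap_policy = "all"` (default) a fragment
#' with several equally-best placements is counted in every gene it hits —
#' IR-duplicated gene copies therefore each receive the fragment, mirroring
#' how expression tables list both IR copies. With `"primary"` only the
#' lowest-coordinate placement is counted.
#'
#' @param alignments Tibble from [map_reads()].
#' @param annotation A [gene_models()] tibble.
#' @param multimap_policy `"all"` or `"primary"`.
#' @return Tibble `gene`, `fragment_count` covering every annotation record
#'   (zeroes included), in annotation order.
#' @export
count_fragments <- function(alignments, annotation, multimap_policy = c("all", "primary")) {
  multimap_policy <- match.arg(multimap_policy)
  frags <- fragment_placements(alignments)
  if (multimap_policy == "primary" && nrow(frags) > 0) {
    frags <- dplyr::slice_min(dplyr::group_by(frags, .data$fragment_id),
                              order_by = .data$start, n = 1, with_ties = FALSE)
    frags <- dplyr::ungroup(frags)
  }
  counts <- stats::setNames(integer(nrow(annotation)), annotation$gene)
  if (nrow(frags) > 0) {
    for (g in seq_len(nrow(annotation))) {
      ex <- annotation$exons[[g]]
      inside <- rep(FALSE, nrow(frags))
      for (j in seq_len(nrow(ex))) {
        inside <- inside | (frags$midpoint >= ex$start[j] & frags$midpoint <= ex$end[j])
      }
      counts[g] <- sum(inside)
    }
  }
  tibble::tibble(gene = annotation$gene, fragment_count = unname(counts))
}

#' Fragments per kilobase of exon per million mapped fragments
#'
#' `fpkm = count / ((coding_length / 1e3) * (total_mapped / 1e6))`. Gene
#' length is the exonic (spliced) length; the library size is the number of
#' fragments aligned anywhere on the plastome.
#'
#' @param count Fragment count(s) for the gene(s); vectorised.
#' @param coding_length_bp Exonic gene length(s) in bp.
#' @param total_mapped_fragments Total fragments mapped to the genome.
#' @return Numeric FPKM value(s).
#' @examples
#' fpkm(100, 1000, 1e6)
#' @export
fpkm <- function(count, coding_length_bp, total_mapped_fragments) {
  if (any(coding_length_bp <= 0)) px_abort("gene length must be positive", "zero_length_gene")
  if (length(total_mapped_fragments) != 1L || total_mapped_fragments <= 0) {
    px_abort("library size must be a single positive count", "empty_library")
  }
  count / ((coding_length_bp / 1e3) * (total_mapped_fragments / 1e6))
}

#' Per-gene expression table (counts + FPKM)
#'
#' Convenience wrapper: counts fragments with [count_fragments()], derives
#' the library size as the number of distinct mapped fragments, and computes
#' FPKM per gene record.
#'
#' @inheritParams count_fragments
#' @return An `expression_profile` tibble: `gene`, `start`, `end`,
#'   `coding_length`, `fragment_count`, `fpkm`, sorted by decreasing FPKM
#'   (ties by gene name).
#' @export
expression_profile <- function(alignments, annotation, multimap_policy = "all") {
  counts <- count_fragments(alignments, annotation, multimap_policy)
  total <- dplyr::n_distinct(sub("/[12]$", "", alignments$read_id))
  span <- purrr::map_dfr(annotation$exons,
                         function(e) tibble::tibble(start = min(e$start), end = max(e$end)))
  out <- tibble::tibble(
    gene = annotation$gene,
    start = span$start, end = span$end,
    coding_length = coding_length(annotation),
    fragment_count = counts$fragment_count
  )
  out$fpkm <- if (total > 0) fpkm(out$fragment_count, out$coding_length, total) else 0
  out <- dplyr::arrange(out, dplyr::desc(.data$fpkm), .data$gene)
  attr(out, "total_mapped_fragments") <- total
  class(out) <- c("expression_profile", class(out))
  out
}

#' Rank genes by expression
#'
#' @param records Tibble with `gene` and `fpkm` columns.
#' @param top_k Optional: keep only the first `top_k` records.
#' @return The records sorted by descending FPKM, ties broken by gene name.
#' @export
rank_genes <- function(records, top_k = NULL) {
  out <- dplyr::arrange(tibble::as_tibble(records), dplyr::desc(.data$fpkm), .data$gene)
  if (!is.null(top_k)) out <- utils::head(out, top_k)
  out
}

#' @export
glance.expression_profile <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x),
    total_mapped_fragments = attr(x, "total_mapped_fragments"),
    top_gene = x$gene[which.max(x$fpkm)],
    max_fpkm = max(x$fpkm)
  )
}
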