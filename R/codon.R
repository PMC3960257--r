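# Codon usage accounting under the plastid genetic code (table 11).

#' Codon usage across the protein-coding genes of a plastome
#'
#' Counts every complete codon of every unique CDS gene exactly once:
#' records flagged as IR duplicates (`ir_copy_of` set) and pseudogenes are
#' skipped, minus-strand genes are reverse-complemented and trans-spliced
#' parts concatenated in transcript order before codon extraction. A coding
#' sequence whose length is not a multiple of 3 is truncated with a warning;
#' codons containing N are skipped with a warning.
#'
#' @param annotation A [gene_models()] tibble.
#' @param genome A [plastome()].
#' @return A `codon_usage` tibble with columns `codon` (RNA alphabet),
#'   `amino_acid` (three-letter, stops as `"stop"`) and `count`, one row per
#'   codon of the genetic code, with the processed-codon total as an
#'   attribute `total`.
#' @export
codon_usage <- function(annotation, genome) {
  genome <- as_plastome(genome)
  use <- annotation[annotation$type == "CDS" & is.na(annotation$ir_copy_of) &
                      !annotation$pseudo, ]
  all_codons <- names(plastid_code())
  full <- stats::setNames(integer(length(all_codons)), all_codons)
  n_skipped <- 0L
  for (i in seq_len(nrow(use))) {
    cds <- cds_sequence(use[i, ], genome)
    if (nchar(cds) %% 3 != 0) {
      px_warn(sprintf("%s: coding length %d not a multiple of 3; trailing bases dropped",
                      use$gene[i], nchar(cds)), "length_not_multiple_of_three")
      cds <- substr(cds, 1L, nchar(cds) - nchar(cds) %% 3)
    }
    cod <- substring(cds, seq(1L, nchar(cds), by = 3L), seq(3L, nchar(cds), by = 3L))
    has_n <- !cod %in% all_codons
    n_skipped <- n_skipped + sum(has_n)
    tab <- table(cod[!has_n])
    full[names(tab)] <- full[names(tab)] + as.integer(tab)
  }
  if (n_skipped > 0) {
    px_warn(sprintf("%d codons containing N skipped", n_skipped), "ambiguous_codon")
  }
  codon_usage_from_counts(tibble::tibble(codon = to_rna(all_codons),
                                         count = as.integer(full)))
}

#' Build a codon-usage table from per-codon counts
#'
#' Accepts counts in either DNA or RNA codon spelling (e.g. from a published
#' codon-usage table), attaches plastid-code amino acids, and optionally a
#' codon-to-tRNA (anticodon recognition) map via a `trna` column.
#'
#' @param counts Data frame with columns `codon`, `count` and optionally `trna`.
#' @return A `codon_usage` tibble (see [codon_usage()]).
#' @examples
#' codon_usage_from_counts(data.frame(codon = c("AUG", "UAA"), count = c(1, 1)))
#' @export
codon_usage_from_counts <- function(counts) {
  counts <- tibble::as_tibble(counts)
  stopifnot(all(c("codon", "count") %in% names(counts)))
  counts$codon <- to_rna(toupper(counts$codon))
  if (anyDuplicated(counts$codon)) px_abort("duplicated codon rows", "bad_codon_table")
  counts$amino_acid <- translate_codon(counts$codon)
  counts$count <- as.integer(counts$count)
  cols <- c("codon", "amino_acid", "count", intersect("trna", names(counts)))
  out <- counts[order(counts$codon), cols]
  attr(out, "total") <- sum(out$count)
  class(out) <- c("codon_usage", class(out))
  out
}

#' Aggregate codon counts into amino-acid totals
#'
#' Percentages are computed from this table's own total (stop codons
#' included in the denominator).
#'
#' @param usage A `codon_usage` tibble.
#' @return Tibble `amino_acid`, `count`, `percent`, sorted by decreasing count.
#' @examples
#' u <- codon_usage_from_counts(data.frame(codon = c("UUA", "UUG"), count = c(2, 3)))
#' amino_acid_totals(u)
#' @export
amino_acid_totals <- function(usage) {
  out <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(usage), .data$amino_acid),
                          count = sum(.data$count), .groups = "drop")
  out$percent <- 100 * out$count / sum(out$count)
  dplyr::arrange(out, dplyr::desc(.data$count))
}

#' @export
tidy.codon_usage <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.codon_usage <- function(x, ...) {
  aa <- amino_acid_totals(x)
  coding <- aa[aa$amino_acid != "stop", ]
  tibble::tibble(
    total_codons = attr(x, "total"),
    n_codons_observed = sum(x$count > 0),
    most_used_aa = coding$amino_acid[which.max(coding$count)],
    least_used_aa = coding$amino_acid[which.min(coding$count)]
  )
}
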