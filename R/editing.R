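# RNA-editing detection: DNA reference vs RNA pileup comparison, per-site
# conversion efficiency, and codon/amino-acid impact under the plastid code.

#' Per-site editing efficiency (conversion rate)
#'
#' The ratio of reads carrying the alternate base to all reads observed at
#' the site, as a percentage: `100 * alt_count / sum(base_counts)`. The
#' denominator is every observed base at the column, not just ref + alt, so
#' a third base at the site lowers both percentages.
#'
#' @param base_counts Named numeric vector of per-base read counts at the
#'   site (names are bases, DNA or RNA alphabet).
#' @param ref_base,alt_base Reference and alternate base (same alphabet).
#' @return Percentage in `[0, 100]`, rounded to one decimal.
#' @examples
#' editing_efficiency(c(U = 11, C = 27), "C", "U")  # 28.9
#' @export
editing_efficiency <- function(base_counts, ref_base, alt_base) {
  total <- sum(base_counts)
  if (total <= 0) px_abort("no reads observed at the site", "zero_coverage")
  nm <- to_rna(toupper(names(base_counts)))
  alt <- sum(base_counts[nm == to_rna(toupper(alt_base))])
  round(100 * alt / total, 1)
}

#' Call RNA-editing sites from an RNA pileup against the DNA reference
#'
#' A site is emitted where coverage reaches `min_coverage` and the most
#' frequent non-reference base accounts for at least `min_alt_fraction` of
#' all observed bases. Bases are reported in transcript orientation (RNA
#' alphabet; minus-strand genes complemented); sites outside annotated genes
#' are labelled `intergenic` with empty codon fields, mirroring UTR entries
#' in published editing tables.
#'
#' @param pileup Tibble from [build_pileup()] (RNA reads).
#' @param genome A [plastome()] — the DNA reference.
#' @param annotation A [gene_models()] tibble.
#' @param min_coverage Minimum reads at the site (default 5).
#' @param min_alt_fraction Minimum alternate-base fraction (default 0.1).
#' @return Tibble of editing sites: `gene`, `position_in_gene`,
#'   `genomic_position`, `ref_base`, `alt_base` (RNA, transcript strand),
#'   `conversion`, `efficiency`, per-base counts `n_A`, `n_C`, `n_G`, `n_U`
#'   (transcript orientation), `codon_ref`, `codon_alt`, `aa_ref`, `aa_alt`,
#'   `synonymous`.
#' @export
call_editing_sites <- function(pileup, genome, annotation,
                               min_coverage = 5, min_alt_fraction = 0.1) {
  genome <- as_plastome(genome)
  totals <- pileup_totals(pileup)
  empty <- tibble::tibble(
    gene = character(), position_in_gene = integer(), genomic_position = integer(),
    ref_base = character(), alt_base = character(), conversion = character(),
    efficiency = double(), n_A = integer(), n_C = integer(), n_G = integer(),
    n_U = integer(), codon_ref = character(), codon_alt = character(),
    aa_ref = character(), aa_alt = character(), synonymous = logical()
  )
  if (nrow(totals) == 0) return(empty)
  totals <- totals[totals$coverage >= min_coverage, , drop = FALSE]
  if (nrow(totals) == 0) return(empty)

  rows <- vector("list", nrow(totals))
  for (i in seq_len(nrow(totals))) {
    pos <- totals$position[i]
    ref <- substr(genome$seq, pos, pos)
    counts <- c(A = totals$A[i], C = totals$C[i], G = totals$G[i], T = totals$T[i])
    alt_counts <- counts[setdiff(names(counts), ref)]
    if (sum(alt_counts) == 0) next
    alt <- names(alt_counts)[order(-alt_counts, names(alt_counts))][1]
    if (alt_counts[[alt]] / totals$coverage[i] < min_alt_fraction) next

    hit <- locate_gene(annotation, pos)
    if (is.null(hit)) {
      gene_name <- "intergenic"; strand <- "+"; pos_in_gene <- NA_integer_
    } else {
      gene_name <- hit$gene
      strand <- hit$record$exons[[1]]$strand[hit$exon_idx]
      pos_in_gene <- genomic_to_gene_position(hit$record, pos)
    }
    flip <- strand == "-"
    ref_t <- if (flip) comp(ref) else ref
    alt_t <- if (flip) comp(alt) else alt
    counts_t <- if (flip) counts[c(T = "A", G = "C", C = "G", A = "T")[names(counts)]] else counts
    names(counts_t) <- c("A", "C", "G", "T")

    site <- tibble::tibble(
      gene = gene_name,
      position_in_gene = pos_in_gene,
      genomic_position = pos,
      ref_base = to_rna(ref_t), alt_base = to_rna(alt_t),
      conversion = paste0(to_rna(ref_t), "-to-", to_rna(alt_t)),
      efficiency = editing_efficiency(counts, ref, alt),
      n_A = counts_t[["A"]], n_C = counts_t[["C"]],
      n_G = counts_t[["G"]], n_U = counts_t[["T"]],
      codon_ref = NA_character_, codon_alt = NA_character_,
      aa_ref = NA_character_, aa_alt = NA_character_, synonymous = NA
    )
    if (!is.null(hit) && hit$record$type == "CDS" && !is.na(pos_in_gene)) {
      site <- annotate_codon_change(site, hit$record, genome)
    }
    rows[[i]] <- site
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) empty else out
}

# find the annotation record whose exon contains the position; unique CDS
# genes are preferred over IR duplicates and over tRNA/rRNA
locate_gene <- function(annotation, pos) {
  cand <- list()
  for (g in seq_len(nrow(annotation))) {
    ex <- annotation$exons[[g]]
    j <- which(pos >= ex$start & pos <= ex$end)
    if (length(j)) {
      cand[[length(cand) + 1L]] <- list(idx = g, exon_idx = j[1])
    }
  }
  if (length(cand) == 0) return(NULL)
  score <- vapply(cand, function(cc) {
    rec <- annotation[cc$idx, ]
    (rec$type != "CDS") * 2L + !is.na(rec$ir_copy_of)
  }, numeric(1))
  best <- cand[[order(score)[1]]]
  rec <- annotation[best$idx, ]
  list(gene = rec$gene, record = rec, exon_idx = best$exon_idx)
}

#' Annotate the codon and amino-acid impact of an editing site
#'
#' Reads the reference codon from the genome through the gene's exon
#' structure, substitutes the edited base at the in-codon offset, and
#' translates both codons with the plastid genetic code (table 11); stop
#' codons are labelled `"stop"`. A site outside the coding region raises a
#' `position_not_in_cds` condition.
#'
#' @param site One-row editing-site tibble (see [call_editing_sites()]).
#' @param gene The one-row [gene_models()] record containing the site.
#' @param genome A [plastome()].
#' @return The site with `codon_ref`, `codon_alt`, `aa_ref`, `aa_alt`,
#'   `synonymous` filled in (codons in the RNA alphabet).
#' @export
annotate_codon_change <- function(site, gene, genome) {
  gene <- as_gene_record(gene)
  if (gene$type != "CDS" || is.na(site$position_in_gene)) {
    px_abort("site is not inside a coding sequence", "position_not_in_cds")
  }
  cds <- cds_sequence(gene, genome)
  map <- gene_position_to_codon(gene, site$position_in_gene)
  cstart <- (map$codon_index - 1L) * 3L + 1L
  codon_ref <- substr(cds, cstart, cstart + 2L)
  codon_alt <- codon_ref
  substr(codon_alt, map$offset_in_codon, map$offset_in_codon) <- to_dna(site$alt_base)
  site$codon_ref <- to_rna(codon_ref)
  site$codon_alt <- to_rna(codon_alt)
  site$aa_ref <- translate_codon(codon_ref)
  site$aa_alt <- translate_codon(codon_alt)
  site$synonymous <- identical(site$aa_ref, site$aa_alt)
  site
}

#' Tally editing sites by conversion type
#'
#' @param sites Tibble with a `conversion` column (e.g. `"C-to-U"`).
#' @return Tibble `conversion`, `n`, `percent`, sorted by decreasing count.
#' @export
summarize_conversion_spectrum <- function(sites) {
  if (nrow(sites) == 0) {
    return(tibble::tibble(conversion = character(), n = integer(), percent = double()))
  }
  out <- dplyr::count(tibble::as_tibble(sites), .data$conversion, sort = TRUE)
  out$percent <- 100 * out$n / sum(out$n)
  out
}

#' Intersect predicted and observed editing sites
#'
#' Compares two sets of genomic positions by exact match.
#'
#' @param predicted_sites Integer vector of predicted positions.
#' @param called_sites Integer vector of called positions (or a tibble with
#'   a `genomic_position` column).
#' @return List of sorted position vectors: `confirmed`, `predicted_only`,
#'   `called_only`.
#' @export
confirm_predictions <- function(predicted_sites, called_sites) {
  if (is.data.frame(called_sites)) called_sites <- called_sites$genomic_position
  predicted_sites <- unique(as.integer(predicted_sites))
  called_sites <- unique(as.integer(called_sites))
  list(
    confirmed = sort(intersect(predicted_sites, called_sites)),
    predicted_only = sort(setdiff(predicted_sites, called_sites)),
    called_only = sort(setdiff(called_sites, predicted_sites))
  )
}
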