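# Published reference tables for the Deschampsia antarctica plastome
# (GenBank accession KF887484), shipped as plain TSV so that the package's
# accounting functions can be exercised on real printed values.

#' Reference tables for the D. antarctica plastome (KF887484)
#'
#' Returns one of the bundled reference tables derived from the published
#' characterisation of the *Deschampsia antarctica* chloroplast genome:
#'
#' * `"codon_usage"`: per-codon counts over the 81 unique protein-coding
#'   genes, with the codon-anticodon (tRNA) recognition map.
#' * `"editing_sites"`: the catalogued RNA-editing sites with gene lengths,
#'   transcript positions, codon/amino-acid changes and per-base read counts
#'   (transcript orientation, RNA alphabet).
#' * `"expression"`: the per-gene FPKM expression table (both IR copies of
#'   duplicated genes listed).
#' * `"introns"`: exon/intron lengths of the intron-containing genes (the
#'   trans-spliced gene's part junction carries no intron).
#' * `"srna_loci"`: the small-RNA footprint loci with core sequences and
#'   read support (IR-duplicated loci carry their mirror coordinates).
#' * `"region_lengths"`: the quadripartite region lengths in bp.
#'
#' @param which Table name (see above).
#' @return A tibble.
#' @examples
#' reference_table("region_lengths")
#' @export
reference_table <- function(which = c("codon_usage", "editing_sites", "expression",
                                      "introns", "srna_loci", "region_lengths")) {
  which <- match.arg(which)
  if (which == "region_lengths") {
    return(tibble::tibble(region = c("LSC", "IRb", "SSC", "IRa"),
                          length = c(79881L, 21481L, 12519L, 21481L)))
  }
  file <- c(codon_usage = "codon_usage_kf887484.tsv",
            editing_sites = "editing_sites_kf887484.tsv",
            expression = "expression_fpkm_kf887484.tsv",
            introns = "intron_genes_kf887484.tsv",
            srna_loci = "srna_loci_kf887484.tsv")[[which]]
  path <- system.file("extdata", file, package = "plastex", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, na = "NA")
}

#' Convert an exon/intron length table into gene models
#'
#' Lays each gene's exons out on a dummy coordinate axis according to its
#' printed exon and intron lengths (genes spaced far apart), so that
#' structural accounting such as [intron_catalog()] can run on published
#' length tables. A missing intron between two exons of a trans-spliced
#' gene starts a new transcript part.
#'
#' @param tbl Tibble with columns `gene`, `exon1`, `intron1`, `exon2`,
#'   `intron2`, `exon3`, `trans_spliced` (see `reference_table("introns")`).
#' @param gene_spacing Gap between consecutive genes in the layout (bp).
#' @return A [gene_models()] tibble (type `CDS` for all records; only
#'   lengths matter for interval accounting).
#' @export
length_table_to_gene_models <- function(tbl, gene_spacing = 10000L) {
  rows <- purrr::map(seq_len(nrow(tbl)), function(i) {
    r <- tbl[i, ]
    exon_lens <- c(r$exon1, r$exon2, r$exon3)
    intron_lens <- c(r$intron1, r$intron2)
    offset <- (i - 1L) * gene_spacing + 1L
    starts <- integer(0); ends <- integer(0); parts <- integer(0)
    part <- 1L
    pos <- offset
    for (e in seq_along(exon_lens)) {
      if (is.na(exon_lens[e])) break
      starts <- c(starts, pos); ends <- c(ends, pos + exon_lens[e] - 1L)
      parts <- c(parts, part)
      if (e <= length(intron_lens) && !is.na(exon_lens[e + 1] %||% NA)) {
        if (is.na(intron_lens[e])) {         # trans-spliced junction
          part <- part + 1L
          pos <- ends[length(ends)] + 2000L  # arbitrary inter-part gap
        } else {
          pos <- ends[length(ends)] + intron_lens[e] + 1L
        }
      }
    }
    tibble::tibble(gene = r$gene, type = "CDS", strand = "+",
                   exons = list(tibble::tibble(start = starts, end = ends,
                                               strand = "+", part = parts)),
                   trans_spliced = isTRUE(r$trans_spliced),
                   ir_copy_of = NA_character_,
                   region = r$region %||% NA_character_, pseudo = FALSE)
  })
  suppressWarnings(gene_models(dplyr::bind_rows(rows)))
}
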