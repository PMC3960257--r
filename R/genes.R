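# Gene models: stranded, possibly multi-exon, possibly trans-spliced genes
# kept as a tibble with one row per gene record and a list-column of exons.

#' Build a validated gene-model table
#'
#' Normalises a data frame of gene records into the annotation format used
#' throughout the package: a tibble with one row per gene record and columns
#' `gene`, `type` (`CDS`, `tRNA` or `rRNA`), `strand`, `exons` (list-column
#' of tibbles with `start`, `end`, `strand`, `part`), `trans_spliced`,
#' `ir_copy_of` (name of the gene this record duplicates in the other IR
#' copy, or `NA`), `region` and `pseudo`.
#'
#' Exons are stored in transcript order (5' to 3' of the mature transcript);
#' trans-spliced genes carry their independently transcribed parts in the
#' `part` column, each part possibly on its own strand. Single-exon input
#' may use plain `start`/`end` columns instead of an `exons` list-column.
#'
#' @param df Data frame of gene records.
#' @return A tibble of class `gene_models`.
#' @examples
#' gene_models(data.frame(gene = "psbA", type = "CDS", strand = "-",
#'                        start = 100, end = 1161))
#' @export
gene_models <- function(df) {
  df <- tibble::as_tibble(df)
  if (!"gene" %in% names(df)) px_abort("gene column required", "bad_annotation")
  if (!"type" %in% names(df)) df$type <- "CDS"
  if (!"strand" %in% names(df)) df$strand <- "+"
  if (!"trans_spliced" %in% names(df)) df$trans_spliced <- FALSE
  if (!"ir_copy_of" %in% names(df)) df$ir_copy_of <- NA_character_
  if (!"region" %in% names(df)) df$region <- NA_character_
  if (!"pseudo" %in% names(df)) df$pseudo <- FALSE
  if (!"exons" %in% names(df)) {
    if (!all(c("start", "end") %in% names(df))) {
      px_abort("need either an exons list-column or start/end columns", "bad_annotation")
    }
    df$exons <- purrr::pmap(list(df$start, df$end, df$strand),
                            function(s, e, st) tibble::tibble(start = s, end = e,
                                                              strand = st, part = 1L))
    df$start <- NULL; df$end <- NULL
  }
  if (!all(df$type %in% c("CDS", "tRNA", "rRNA"))) {
    px_abort("gene type must be CDS, tRNA or rRNA", "bad_annotation")
  }
  df$exons <- purrr::map2(df$exons, df$strand, normalize_exons)
  bad <- df$type == "CDS" & !df$pseudo &
    vapply(df$exons, function(e) sum(e$end - e$start + 1L), numeric(1)) %% 3 != 0
  if (any(bad)) {
    px_warn(sprintf("CDS length not a multiple of 3 for: %s",
                    paste(df$gene[bad], collapse = ", ")),
            "length_not_multiple_of_three")
  }
  class(df) <- c("gene_models", class(df))
  df
}

normalize_exons <- function(ex, gene_strand) {
  ex <- tibble::as_tibble(ex)
  if (!"strand" %in% names(ex)) ex$strand <- gene_strand
  if (!"part" %in% names(ex)) ex$part <- 1L
  ex$start <- as.integer(ex$start); ex$end <- as.integer(ex$end)
  ex$part <- as.integer(ex$part)
  if (any(ex$end < ex$start)) px_abort("exon end precedes start", "bad_annotation")
  # transcript order within each part: ascending for '+', descending for '-'
  ord <- order(ex$part, ifelse(ex$strand == "+", 1L, -1L) * ex$start)
  ex <- ex[ord, c("start", "end", "strand", "part")]
  # non-overlap within a part
  for (p in unique(ex$part)) {
    sub <- ex[ex$part == p, ]
    sub <- sub[order(sub$start), ]
    if (nrow(sub) > 1L && any(sub$start[-1] <= sub$end[-nrow(sub)])) {
      px_abort("overlapping exons within one transcript part", "bad_annotation")
    }
  }
  ex
}

#' Coding (exonic) length of each gene record
#'
#' @param annotation A [gene_models()] tibble.
#' @return Integer vector of summed exon lengths, one per record.
#' @export
coding_length <- function(annotation) {
  vapply(annotation$exons, function(e) sum(e$end - e$start + 1L), integer(1))
}

# genomic gaps between consecutive exons of the same transcript part
exon_gaps <- function(ex) {
  out <- list()
  for (p in unique(ex$part)) {
    sub <- ex[ex$part == p, ]
    sub <- sub[order(sub$start), ]
    if (nrow(sub) > 1L) {
      out[[length(out) + 1L]] <- tibble::tibble(
        start = sub$end[-nrow(sub)] + 1L, end = sub$start[-1] - 1L
      )
    }
  }
  if (length(out) == 0) tibble::tibble(start = integer(), end = integer())
  else dplyr::bind_rows(out)
}

#' Count unique genes, resolving inverted-repeat duplicates
#'
#' Gene records linked to another record through `ir_copy_of` are counted
#' once. Returns the unique total, a per-type breakdown and the number of
#' IR-duplicated records.
#'
#' @param annotation A [gene_models()] tibble.
#' @return A list with `unique_total`, `by_type` (tibble `type`, `n`) and
#'   `ir_duplicated` (count of duplicate records collapsed).
#' @export
unique_gene_accounting <- function(annotation) {
  if (nrow(annotation) == 0) px_abort("empty annotation", "bad_annotation")
  links <- annotation$ir_copy_of[!is.na(annotation$ir_copy_of)]
  if (!all(links %in% annotation$gene)) {
    px_abort("ir_copy_of names a gene absent from the annotation",
             "dangling_duplicate_link")
  }
  uniq <- annotation[is.na(annotation$ir_copy_of), ]
  by_type <- dplyr::count(tibble::as_tibble(uniq), .data$type)
  list(
    unique_total = nrow(uniq),
    by_type = by_type,
    ir_duplicated = sum(!is.na(annotation$ir_copy_of))
  )
}

#' Catalogue exon and intron lengths per gene
#'
#' Introns are gaps between consecutive exons of the same transcript part,
#' in transcript order. The junction between the parts of a trans-spliced
#' gene is never an intron. Use [largest_intron()] on the result for the
#' genome-wide maximum.
#'
#' @param annotation A [gene_models()] tibble.
#' @return A tibble `gene`, `feature`, `index`, `length` with one row per
#'   exon/intron in transcript order.
#' @export
intron_catalog <- function(annotation) {
  purrr::map_dfr(seq_len(nrow(annotation)), function(i) {
    ex <- annotation$exons[[i]]
    exon_len <- ex$end - ex$start + 1L
    rows <- tibble::tibble(gene = annotation$gene[i], feature = "exon",
                           index = seq_along(exon_len), length = exon_len)
    if (nrow(ex) > 1L) {
      same_part <- ex$part[-1] == ex$part[-nrow(ex)]
      gap <- abs(ifelse(ex$strand[-1] == "+",
                        ex$start[-1] - ex$end[-nrow(ex)],
                        ex$start[-nrow(ex)] - ex$end[-1])) - 1L
      intr <- tibble::tibble(gene = annotation$gene[i], feature = "intron",
                             index = which(same_part), length = gap[same_part])
      rows <- dplyr::bind_rows(rows, intr)
    }
    rows
  })
}

#' Largest intron in an intron catalogue
#'
#' @param catalog Tibble from [intron_catalog()].
#' @return One-row tibble with `gene` and `length`, or zero rows if intronless.
#' @export
largest_intron <- function(catalog) {
  intr <- catalog[catalog$feature == "intron", ]
  if (nrow(intr) == 0) return(intr[, c("gene", "length")])
  intr[which.max(intr$length), c("gene", "length")]
}

#' Map a transcript position to its codon and genomic position
#'
#' For a CDS gene, position `p` (1-based from the start codon along the
#' spliced transcript) lies in codon `ceiling(p / 3)` at offset
#' `((p - 1) %% 3) + 1`; the genomic position is computed through the exon
#' structure and strand.
#'
#' @param gene One gene record (one-row [gene_models()] slice).
#' @param position_in_gene 1-based position along the coding sequence.
#' @return A one-row tibble `codon_index`, `offset_in_codon`, `genomic_position`.
#' @export
gene_position_to_codon <- function(gene, position_in_gene) {
  gene <- as_gene_record(gene)
  len <- sum(gene$exons[[1]]$end - gene$exons[[1]]$start + 1L)
  p <- as.integer(position_in_gene)
  if (p < 1L || p > len) px_abort("position outside the gene", "position_out_of_gene")
  tibble::tibble(
    codon_index = ceiling(p / 3),
    offset_in_codon = ((p - 1L) %% 3L) + 1L,
    genomic_position = gene_to_genomic_position(gene, p)
  )
}

as_gene_record <- function(gene) {
  if (inherits(gene, "data.frame")) {
    if (nrow(gene) != 1L) px_abort("expected exactly one gene record", "bad_input")
    return(gene)
  }
  px_abort("expected a one-row gene_models slice", "bad_input")
}

# transcript position -> genomic position, through exon structure and strand
gene_to_genomic_position <- function(gene, p) {
  ex <- gene$exons[[1]]
  widths <- ex$end - ex$start + 1L
  ends <- cumsum(widths)
  i <- which(p <= ends)[1]
  off <- p - c(0L, ends)[i]   # 1-based offset within exon i
  if (ex$strand[i] == "+") ex$start[i] + off - 1L else ex$end[i] - off + 1L
}

#' Map a genomic position into transcript coordinates
#'
#' Inverse of [gene_position_to_codon()]'s genomic mapping. Returns `NA`
#' when the position falls outside every exon of the gene.
#'
#' @param gene One gene record.
#' @param genomic_position 1-based genome position.
#' @return 1-based position along the spliced transcript, or `NA`.
#' @export
genomic_to_gene_position <- function(gene, genomic_position) {
  gene <- as_gene_record(gene)
  ex <- gene$exons[[1]]
  widths <- ex$end - ex$start + 1L
  offset_before <- c(0L, cumsum(widths))[seq_len(nrow(ex))]
  for (i in seq_len(nrow(ex))) {
    if (genomic_position >= ex$start[i] && genomic_position <= ex$end[i]) {
      within <- if (ex$strand[i] == "+") genomic_position - ex$start[i] + 1L
                else ex$end[i] - genomic_position + 1L
      return(offset_before[i] + within)
    }
  }
  NA_integer_
}

#' Extract the spliced coding sequence of a gene
#'
#' Exon sequences are taken from the genome, reverse-complemented for
#' minus-strand exons, and concatenated in transcript order (trans-spliced
#' parts joined in part order).
#'
#' @param gene One gene record.
#' @param genome A [plastome()].
#' @return DNA string of the spliced transcript.
#' @export
cds_sequence <- function(gene, genome) {
  gene <- as_gene_record(gene)
  genome <- as_plastome(genome)
  ex <- gene$exons[[1]]
  pieces <- vapply(seq_len(nrow(ex)), function(i) {
    s <- substr(genome$seq, ex$start[i], ex$end[i])
    if (ex$strand[i] == "-") revcomp(s) else s
  }, character(1))
  paste(pieces, collapse = "")
}
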