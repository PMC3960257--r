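# Standard-format readers and writers. All internal coordinates are 1-based
# inclusive; GFF3 shares that convention, BED export converts to 0-based
# half-open at the boundary.

#' Read a genome from a FASTA file
#'
#' @param path FASTA file with a single sequence record.
#' @param circular Flag the molecule as circular (default `TRUE`).
#' @return A [plastome()].
#' @export
read_fasta <- function(path, circular = TRUE) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) != 1L) px_abort("expected exactly one FASTA record", "malformed_record")
  plastome(as.character(set[[1]]), id = sub("\\s.*$", "", names(set)[1]),
           circular = circular)
}

#' Write a plastome to FASTA
#'
#' @param genome A [plastome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  genome <- as_plastome(genome)
  set <- Biostrings::DNAStringSet(stats::setNames(genome$seq, genome$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write gene models to GFF3
#'
#' One `gene` feature per record (attributes `ID`, `gene_type`,
#' `trans_splicing`, `ir_copy_of`, `region`, `pseudo`) plus `exon` children
#' carrying `Parent` and `part`. Coordinates are 1-based inclusive per the
#' GFF3 standard.
#'
#' @param annotation A [gene_models()] tibble.
#' @param path Output path.
#' @param seqname Sequence name for column 1 (default `"plastome"`).
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotation, path, seqname = "plastome") {
  n <- nrow(annotation)
  spans <- purrr::map_dfr(annotation$exons,
                          function(e) tibble::tibble(start = min(e$start), end = max(e$end)))
  gene_gr <- GenomicRanges::GRanges(
    seqname, IRanges::IRanges(spans$start, spans$end), strand = annotation$strand
  )
  S4Vectors::mcols(gene_gr) <- S4Vectors::DataFrame(
    type = "gene", ID = annotation$gene, gene_type = annotation$type,
    trans_splicing = ifelse(annotation$trans_spliced, "true", NA_character_),
    ir_copy_of = annotation$ir_copy_of, region = annotation$region,
    pseudo = ifelse(annotation$pseudo, "true", NA_character_),
    Parent = IRanges::CharacterList(vector("list", n)),
    part = NA_integer_
  )
  ex <- tidyr::unnest(
    tibble::tibble(gene = annotation$gene, exons = annotation$exons), "exons"
  )
  exon_gr <- GenomicRanges::GRanges(seqname, IRanges::IRanges(ex$start, ex$end),
                                    strand = ex$strand)
  S4Vectors::mcols(exon_gr) <- S4Vectors::DataFrame(
    type = "exon", ID = NA_character_, gene_type = NA_character_,
    trans_splicing = NA_character_, ir_copy_of = NA_character_,
    region = NA_character_, pseudo = NA_character_,
    Parent = IRanges::CharacterList(as.list(ex$gene)),
    part = ex$part
  )
  rtracklayer::export(c(gene_gr, exon_gr), path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Inverse of [write_gff3()]: reconstructs the [gene_models()] tibble,
#' honouring the `trans_splicing`, `ir_copy_of` and `pseudo` attributes and
#' exon `part` numbering.
#'
#' @param path GFF3 file.
#' @return A [gene_models()] tibble.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  is_gene <- mc$type == "gene"
  is_exon <- mc$type == "exon"
  if (!any(is_gene)) px_abort("no gene features in GFF3", "malformed_record")
  exon_parent <- vapply(as.list(mc$Parent[is_exon]), function(p) {
    if (length(p)) p[[1]] else NA_character_
  }, character(1))
  exon_tbl <- tibble::tibble(
    parent = exon_parent,
    start = BiocGenerics::start(gr[is_exon]),
    end = BiocGenerics::end(gr[is_exon]),
    strand = as.character(BiocGenerics::strand(gr[is_exon])),
    part = if (!is.null(mc$part)) as.integer(mc$part[is_exon]) else 1L
  )
  exon_tbl$part[is.na(exon_tbl$part)] <- 1L
  genes <- tibble::tibble(
    gene = as.character(mc$ID[is_gene]),
    type = as.character(mc$gene_type[is_gene]),
    strand = as.character(BiocGenerics::strand(gr[is_gene])),
    trans_spliced = !is.na(mc$trans_splicing[is_gene]) & mc$trans_splicing[is_gene] == "true",
    ir_copy_of = if (!is.null(mc$ir_copy_of)) as.character(mc$ir_copy_of[is_gene]) else NA_character_,
    region = if (!is.null(mc$region)) as.character(mc$region[is_gene]) else NA_character_,
    pseudo = if (!is.null(mc$pseudo)) {
      !is.na(mc$pseudo[is_gene]) & mc$pseudo[is_gene] == "true"
    } else FALSE
  )
  genes$exons <- purrr::map(genes$gene, function(g) {
    e <- exon_tbl[exon_tbl$parent == g, c("start", "end", "strand", "part")]
    if (nrow(e) == 0) px_abort(sprintf("gene %s has no exons", g), "malformed_record")
    e
  })
  gene_models(genes)
}

#' Read a FASTQ file into a read tibble
#'
#' The file structure is validated first (4-line records, `+` separator,
#' equal sequence/quality lengths) so that malformed input is reported with
#' its line number; parsing then goes through Biostrings.
#'
#' @param path FASTQ file.
#' @return Tibble `id`, `seq`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4 != 0) {
    px_abort(sprintf("truncated FASTQ record at line %d", length(lines) + 1L),
             "malformed_record")
  }
  for (i in seq(1L, length(lines), by = 4L)) {
    if (!startsWith(lines[i], "@")) {
      px_abort(sprintf("expected @header at line %d", i), "malformed_record")
    }
    if (!startsWith(lines[i + 2L], "+")) {
      px_abort(sprintf("expected + separator at line %d", i + 2L), "malformed_record")
    }
    if (nchar(lines[i + 1L]) != nchar(lines[i + 3L])) {
      px_abort(sprintf("sequence/quality length mismatch at line %d", i + 3L),
               "malformed_record")
    }
  }
  set <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble::tibble(id = sub("\\s.*$", "", names(set)), seq = unname(as.character(set)))
}

#' Write reads to FASTQ (constant quality)
#'
#' @param reads Tibble `id`, `seq`.
#' @param path Output path.
#' @param quality_char Quality character used for every base (default `"I"`).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, quality_char = "I") {
  lines <- as.vector(rbind(
    paste0("@", reads$id), reads$seq, "+",
    vapply(nchar(reads$seq), function(n) strrep(quality_char, n), character(1))
  ))
  writeLines(lines, path)
  invisible(path)
}

#' Write alignments to SAM
#'
#' Minimal dialect: `@HD`/`@SQ` header, flag 0/16 for strand, `<len>M`
#' CIGAR, `NM:i:` mismatch tag. Following the SAM convention, minus-strand
#' records store the reverse-complemented read sequence.
#'
#' @param alignments Tibble from [map_reads()].
#' @param reads Tibble `id`, `seq` for the aligned reads.
#' @param genome A [plastome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, reads, genome, path) {
  genome <- as_plastome(genome)
  seqs <- stats::setNames(toupper(reads$seq), reads$id)
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", genome$id, plastome_length(genome)))
  body <- vapply(seq_len(nrow(alignments)), function(i) {
    rseq <- seqs[[alignments$read_id[i]]]
    minus <- alignments$strand[i] == "-"
    paste(alignments$read_id[i], if (minus) 16L else 0L, genome$id,
          alignments$start[i], 255L, paste0(nchar(rseq), "M"), "*", 0L, 0L,
          if (minus) revcomp(rseq) else rseq, strrep("I", nchar(rseq)),
          paste0("NM:i:", alignments$mismatches[i]), sep = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read alignments from SAM
#'
#' Parses through Rsamtools (text SAM converted in a temporary directory),
#' recovering the original read sequences (minus-strand records are stored
#' reverse-complemented in SAM) and the `NM` mismatch tag.
#'
#' @param path SAM file.
#' @return List: `alignments` tibble (`read_id`, `start`, `strand`,
#'   `mismatches`, `multi_hits`, `read_length`) and `reads` tibble (`id`, `seq`).
#' @export
read_sam <- function(path) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "pos", "seq"), tag = "NM")
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  minus <- bitwAnd(x$flag, 16L) > 0L
  stored <- as.character(x$seq)
  orig <- ifelse(minus, revcomp(stored), stored)
  al <- tibble::tibble(
    read_id = x$qname, start = x$pos,
    strand = ifelse(minus, "-", "+"),
    mismatches = as.integer(x$tag$NM %||% rep(NA_integer_, length(x$qname))),
    read_length = nchar(stored)
  )
  al <- dplyr::add_count(al, .data$read_id, name = "multi_hits")
  al <- al[, c("read_id", "start", "strand", "mismatches", "multi_hits", "read_length")]
  reads <- dplyr::distinct(tibble::tibble(id = x$qname, seq = orig))
  list(alignments = al, reads = reads)
}

#' Convert 1-based inclusive intervals to BED (0-based half-open)
#'
#' @param tbl Tibble with `start`, `end` (1-based inclusive) and optionally
#'   `name`, `score`, `strand`.
#' @param seqname Chromosome name for column 1.
#' @return Tibble with BED columns `chrom`, `chromStart`, `chromEnd`,
#'   `name`, `score`, `strand`.
#' @export
as_bed <- function(tbl, seqname = "plastome") {
  tibble::tibble(
    chrom = seqname,
    chromStart = as.integer(tbl$start - 1L),
    chromEnd = as.integer(tbl$end),
    name = if ("name" %in% names(tbl)) tbl$name else ".",
    score = if ("score" %in% names(tbl)) tbl$score else 0L,
    strand = if ("strand" %in% names(tbl)) tbl$strand else "."
  )
}

#' Write a report table as TSV with a reproducibility stamp
#'
#' The first line is a `#` comment naming the package version, the stage
#' and the parameter values used, so every report is self-describing.
#'
#' @param tbl Tibble to write.
#' @param path Output path.
#' @param stage Stage name for the stamp.
#' @param params Named list of parameter values recorded in the stamp.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(tbl, path, stage = "report", params = list()) {
  stamp <- sprintf("# plastex %s; stage=%s%s",
                   as.character(utils::packageVersion("plastex")), stage,
                   if (length(params)) paste0("; ", paste(names(params), unlist(params),
                                                          sep = "=", collapse = "; "))
                   else "")
  writeLines(stamp, path)
  suppressWarnings(readr::write_tsv(tbl, path, append = TRUE, col_names = TRUE))
  invisible(path)
}

#' Read a stamped report TSV
#'
#' @param path File written by [write_report_tsv()].
#' @return Tibble (stamp lines skipped).
#' @export
read_report_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE)
}
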