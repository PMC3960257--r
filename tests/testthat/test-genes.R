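make_cds_genome <- function(cds, pad = 60, pad_seed = 1) {
  # embed a coding sequence in random flanks at a known offset
  left <- random_seq(pad, pad_seed)
  right <- random_seq(pad, pad_seed + 1)
  list(genome = plastome(paste0(left, cds, right), circular = FALSE),
       start = pad + 1L, end = pad + nchar(cds))
}

test_that("unique gene accounting collapses IR duplicates", {
  one <- gene_models(data.frame(gene = "g1", type = "CDS", strand = "+",
                                start = 1, end = 300))
  acc <- unique_gene_accounting(one)
  expect_equal(acc$unique_total, 1)
  expect_equal(acc$ir_duplicated, 0)

  w <- tiny_world(seed = 10, n_genes = 6, n_intron_genes = 2, n_ir_duplicates = 2)
  acc <- unique_gene_accounting(w$genes)
  expect_equal(acc$unique_total, nrow(w$genes) - 2)
  expect_equal(acc$ir_duplicated, 2)
  expect_equal(sum(acc$by_type$n), acc$unique_total)

  bad <- w$genes
  bad$ir_copy_of[nrow(bad)] <- "no_such_gene"
  expect_error(unique_gene_accounting(bad),
               class = "plastex_error_dangling_duplicate_link")
})

test_that("intron catalogue reports gaps in transcript order, none at trans junctions", {
  genes <- gene_models(tibble::tibble(
    gene = c("plain", "two_exon", "trans"),
    type = "CDS", strand = c("+", "+", "+"),
    trans_spliced = c(FALSE, FALSE, TRUE),
    exons = list(
      tibble::tibble(start = 1, end = 300, strand = "+", part = 1),
      tibble::tibble(start = c(401, 1001), end = c(700, 1300), strand = "+", part = 1),
      tibble::tibble(start = c(2001, 5001), end = c(2150, 5150), strand = c("+", "-"),
                     part = c(1, 2))
    )
  ))
  cat <- intron_catalog(genes)
  expect_equal(nrow(cat[cat$gene == "plain" & cat$feature == "intron", ]), 0)
  expect_equal(cat$length[cat$gene == "two_exon" & cat$feature == "intron"], 300)
  expect_equal(nrow(cat[cat$gene == "trans" & cat$feature == "intron", ]), 0)
  expect_equal(largest_intron(cat)$gene, "two_exon")
})

test_that("intron lengths are strand-aware for minus-strand genes", {
  genes <- gene_models(tibble::tibble(
    gene = "minus", type = "CDS", strand = "-", trans_spliced = FALSE,
    exons = list(tibble::tibble(start = c(1001, 401), end = c(1300, 700),
                                strand = "-", part = 1))
  ))
  cat <- intron_catalog(genes)
  expect_equal(cat$length[cat$feature == "intron"], 300)
  expect_equal(cat$length[cat$feature == "exon"], c(300, 300))
})

test_that("transcript position maps to codon index, offset and genomic position", {
  g <- gene_models(data.frame(gene = "g", type = "CDS", strand = "+",
                              start = 101, end = 400))
  expect_equal(gene_position_to_codon(g[1, ], 1),
               tibble::tibble(codon_index = 1, offset_in_codon = 1,
                              genomic_position = 101))
  m <- gene_position_to_codon(g[1, ], 100)
  expect_equal(m$codon_index, 34); expect_equal(m$offset_in_codon, 1)
  expect_error(gene_position_to_codon(g[1, ], 301),
               class = "plastex_error_position_out_of_gene")
})

test_that("gene<->genome position mapping round-trips on a spliced minus-strand gene", {
  g <- gene_models(tibble::tibble(
    gene = "m", type = "CDS", strand = "-", trans_spliced = FALSE,
    exons = list(tibble::tibble(start = c(501, 101), end = c(800, 220),
                                strand = "-", part = 1))
  ))
  len <- coding_length(g)
  expect_equal(len, 420)
  for (p in seq_len(len)) {
    gp <- gene_position_to_codon(g[1, ], p)$genomic_position
    expect_equal(genomic_to_gene_position(g[1, ], gp), p)
  }
  # positions outside exons map to NA
  expect_true(is.na(genomic_to_gene_position(g[1, ], 300)))
})

test_that("codon usage counts each unique CDS once under the plastid code", {
  fix <- make_cds_genome("ATGTAA")
  genes <- gene_models(data.frame(gene = "g", type = "CDS", strand = "+",
                                  start = fix$start, end = fix$end))
  u <- codon_usage(genes, fix$genome)
  expect_equal(attr(u, "total"), 2)
  expect_equal(u$count[u$codon == "AUG"], 1)
  expect_equal(u$count[u$codon == "UAA"], 1)
  expect_equal(u$amino_acid[u$codon == "UAA"], "stop")

  # minus-strand gene: same codons read through the reverse complement
  rc_fix <- make_cds_genome(revcomp("ATGTAA"))
  genes_m <- gene_models(data.frame(gene = "g", type = "CDS", strand = "-",
                                    start = rc_fix$start, end = rc_fix$end))
  u_m <- codon_usage(genes_m, rc_fix$genome)
  expect_equal(tibble::as_tibble(u_m), tibble::as_tibble(u))
})

test_that("codon totals equal the summed floor(length/3) over unique CDS genes", {
  w <- tiny_world(seed = 11, n_genes = 5, n_intron_genes = 2, n_ir_duplicates = 2,
                  include_trans_spliced = TRUE)
  u <- codon_usage(w$genes, w$genome)
  uniq <- w$genes[is.na(w$genes$ir_copy_of), ]
  expect_equal(attr(u, "total"), sum(coding_length(uniq) %/% 3))
  # IR duplicates must not inflate the total
  u_all_dup <- codon_usage(w$genes[!is.na(w$genes$ir_copy_of), ][0, ], w$genome)
  expect_equal(attr(u_all_dup, "total"), 0)
})

test_that("trailing bases of a non-multiple-of-three CDS are dropped with a warning", {
  fix <- make_cds_genome("ATGTAAC")
  genes <- suppressWarnings(
    gene_models(data.frame(gene = "g", type = "CDS", strand = "+",
                           start = fix$start, end = fix$end))
  )
  expect_warning(u <- codon_usage(genes, fix$genome),
                 class = "plastex_warning_length_not_multiple_of_three")
  expect_equal(attr(u, "total"), 2)
})

test_that("amino-acid aggregation uses the table's own total", {
  u <- codon_usage_from_counts(data.frame(codon = c("UUA", "UUG", "UGU"),
                                          count = c(2, 3, 5)))
  aa <- amino_acid_totals(u)
  expect_equal(aa$count[aa$amino_acid == "Leu"], 5)
  expect_equal(aa$count[aa$amino_acid == "Cys"], 5)
  expect_equal(sum(aa$percent), 100)
})

test_that("published-style length tables rebuild as gene models", {
  tbl <- tibble::tibble(gene = c("a", "b"), region = "LSC",
                        exon1 = c(126, 117), intron1 = c(749, NA),
                        exon2 = c(228, 231), intron2 = c(728, NA),
                        exon3 = c(159, NA), trans_spliced = c(FALSE, TRUE))
  gm <- length_table_to_gene_models(tbl)
  expect_equal(coding_length(gm), c(513, 348))
  cat <- intron_catalog(gm)
  expect_equal(cat$length[cat$gene == "a" & cat$feature == "intron"], c(749, 728))
  expect_equal(nrow(cat[cat$gene == "b" & cat$feature == "intron", ]), 0)
})
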