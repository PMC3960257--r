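test_that("editing efficiency divides alt reads by all observed reads", {
  expect_equal(editing_efficiency(c(U = 11, C = 27), "C", "U"), 28.9)
  expect_equal(editing_efficiency(c(C = 2, U = 66), "C", "U"), 97.1)
  expect_equal(editing_efficiency(c(A = 55, U = 28), "U", "A"), 66.3)
  # a third base at the site enters the denominator
  expect_equal(editing_efficiency(c(C = 2, U = 10, G = 1), "C", "U"), 76.9)
  # DNA spelling is accepted
  expect_equal(editing_efficiency(c(T = 11, C = 27), "C", "U"), 28.9)
  expect_error(editing_efficiency(c(C = 0, U = 0), "C", "U"),
               class = "plastex_error_zero_coverage")
})

test_that("per-base percentages at a site sum to 100", {
  counts <- c(A = 3, C = 10, G = 2, U = 5)
  shares <- vapply(names(counts), function(b) {
    editing_efficiency(counts, ref_base = "C", alt_base = b)
  }, numeric(1))
  expect_equal(sum(shares), 100, tolerance = 0.02)
})

# a small world with one plus- and one minus-strand gene and a planted edit in each
editing_world <- function(seed = 90, eff = c(0.9, 0.75)) {
  w <- tiny_world(seed = seed, n_genes = 4, n_intron_genes = 0, n_ir_duplicates = 0)
  plus <- which(w$genes$strand == "+")[1]
  minus <- which(w$genes$strand == "-")[1]
  stopifnot(!is.na(plus), !is.na(minus))
  pos <- c(w$genes$exons[[plus]]$start[1] + 32L,
           w$genes$exons[[minus]]$start[1] + 61L)
  ref <- vapply(pos, function(p) substr(w$genome$seq, p, p), character(1))
  alt <- unname(vapply(ref, function(r) setdiff(c("A", "C", "G", "T"), r)[1],
                       character(1)))
  sites <- tibble::tibble(position = pos, alt = alt, efficiency = eff)
  rs <- simulate_rnaseq(w$genome, w$genes, editing_sites = sites,
                        n_fragments = 1200, error_rate = 0, seed = seed + 1)
  al <- map_reads(rs$reads, w$genome, max_mismatch = 2)
  pile <- build_pileup(al, rs$reads, w$genome)
  list(w = w, sites = sites, truth = rs$truth$editing, pile = pile,
       plus = plus, minus = minus)
}

# one shared simulation for the recovery tests below
ew <- editing_world(seed = 90, eff = c(0.9, 0.5))

test_that("planted edits are recovered with no false positives on clean reads", {
  called <- call_editing_sites(ew$pile, ew$w$genome, ew$w$genes,
                               min_coverage = 5, min_alt_fraction = 0.1)
  expect_setequal(called$genomic_position, ew$sites$position)
  # estimated efficiency equals the realised planted fraction
  for (i in seq_len(nrow(ew$truth))) {
    row <- called[called$genomic_position == ew$truth$position[i], ]
    expect_equal(row$efficiency,
                 round(100 * ew$truth$n_alt[i] / ew$truth$n_covering[i], 1))
  }
})

test_that("recovered efficiencies sit inside the 99% binomial interval of the target", {
  called <- call_editing_sites(ew$pile, ew$w$genome, ew$w$genes)
  for (i in seq_len(nrow(ew$sites))) {
    row <- called[called$genomic_position == ew$sites$position[i], ]
    n <- sum(row[, c("n_A", "n_C", "n_G", "n_U")])
    ci <- stats::binom.test(round(row$efficiency / 100 * n), n,
                            conf.level = 0.99)$conf.int
    expect_true(ew$sites$efficiency[i] >= ci[1] && ew$sites$efficiency[i] <= ci[2])
  }
})

test_that("bases are reported in transcript orientation for minus-strand genes", {
  called <- call_editing_sites(ew$pile, ew$w$genome, ew$w$genes)
  minus_site <- called[called$gene == ew$w$genes$gene[ew$minus], ]
  i <- which(ew$sites$position == minus_site$genomic_position)
  ref_fwd <- substr(ew$w$genome$seq, ew$sites$position[i], ew$sites$position[i])
  expect_equal(minus_site$ref_base, plastex:::to_rna(comp_char(ref_fwd)))
  expect_equal(minus_site$alt_base, plastex:::to_rna(comp_char(ew$sites$alt[i])))
  # codon annotation is consistent with the in-codon offset
  map <- gene_position_to_codon(ew$w$genes[ew$minus, ], minus_site$position_in_gene)
  expect_equal(substr(minus_site$codon_ref, map$offset_in_codon, map$offset_in_codon),
               minus_site$ref_base)
  expect_equal(substr(minus_site$codon_alt, map$offset_in_codon, map$offset_in_codon),
               minus_site$alt_base)
})

test_that("a column with no alternate base is not a site", {
  g <- plastome(random_seq(200, seed = 96), circular = FALSE)
  genes <- gene_models(data.frame(gene = "g", type = "CDS", strand = "+",
                                  start = 31, end = 180))
  pile <- tibble::tibble(position = 100L, strand = "+",
                         base = substr(g$seq, 100, 100), count = 30L)
  expect_equal(nrow(call_editing_sites(pile, g, genes)), 0)
})

test_that("codon impact annotation labels stops and synonymous changes", {
  # gene: ATG TAT TGA -> codon 3 is a UGA stop; editing A->G at position 9
  # turns it into UGG (Trp)
  fixture <- paste0(random_seq(30, 97), "ATGTATTGA", random_seq(30, 98))
  g <- plastome(fixture, circular = FALSE)
  genes <- gene_models(data.frame(gene = "g", type = "CDS", strand = "+",
                                  start = 31, end = 39))
  site <- tibble::tibble(gene = "g", position_in_gene = 9L, genomic_position = 39L,
                         ref_base = "A", alt_base = "G")
  out <- annotate_codon_change(site, genes[1, ], g)
  expect_equal(out$codon_ref, "UGA"); expect_equal(out$codon_alt, "UGG")
  expect_equal(out$aa_ref, "stop"); expect_equal(out$aa_alt, "Trp")
  expect_false(out$synonymous)
  # Tyr -> stop at a third codon position (UAU -> UAA)
  site2 <- tibble::tibble(gene = "g", position_in_gene = 6L, genomic_position = 36L,
                          ref_base = "U", alt_base = "A")
  out2 <- annotate_codon_change(site2, genes[1, ], g)
  expect_equal(out2$codon_ref, "UAU"); expect_equal(out2$codon_alt, "UAA")
  expect_equal(c(out2$aa_ref, out2$aa_alt), c("Tyr", "stop"))
  # synonymous third-position change
  fixture3 <- paste0(random_seq(30, 99), "TTCTAA", random_seq(30, 100))
  g3 <- plastome(fixture3, circular = FALSE)
  genes3 <- gene_models(data.frame(gene = "g3", type = "CDS", strand = "+",
                                   start = 31, end = 36))
  site3 <- tibble::tibble(gene = "g3", position_in_gene = 3L, genomic_position = 33L,
                          ref_base = "C", alt_base = "U")
  out3 <- annotate_codon_change(site3, genes3[1, ], g3)
  expect_equal(c(out3$aa_ref, out3$aa_alt), c("Phe", "Phe"))
  expect_true(out3$synonymous)
  # sites outside a CDS refuse annotation
  utr <- tibble::tibble(gene = "g3", position_in_gene = NA_integer_,
                        genomic_position = 10L, ref_base = "A", alt_base = "C")
  expect_error(annotate_codon_change(utr, genes3[1, ], g3),
               class = "plastex_error_position_not_in_cds")
})

test_that("the conversion spectrum partitions called sites", {
  sites <- tibble::tibble(conversion = c(rep("C-to-U", 10), rep("A-to-G", 2)))
  spec <- summarize_conversion_spectrum(sites)
  expect_equal(spec$n[spec$conversion == "C-to-U"], 10)
  expect_equal(spec$n[spec$conversion == "A-to-G"], 2)
  expect_equal(sum(spec$n), nrow(sites))
  expect_equal(nrow(summarize_conversion_spectrum(sites[0, ])), 0)
})

test_that("prediction confirmation is exact set algebra", {
  out <- confirm_predictions(c(100, 200), c(200, 300))
  expect_equal(out, list(confirmed = 200L, predicted_only = 100L, called_only = 300L))
  same <- confirm_predictions(c(5, 7), c(7, 5))
  expect_equal(same$confirmed, c(5L, 7L))
  expect_equal(length(same$predicted_only), 0)
  withr::with_seed(101, {
    for (i in 1:5) {
      a <- sample(50, 20); b <- sample(50, 20)
      out <- confirm_predictions(a, b)
      expect_equal(out$confirmed, sort(unique(a[a %in% b])))
      expect_equal(sort(c(out$confirmed, out$predicted_only)), sort(unique(a)))
      expect_equal(sort(c(out$confirmed, out$called_only)), sort(unique(b)))
    }
  })
})
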