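test_that("size-stratified coverage separates the 20-24 nt and >30 nt classes", {
  g <- plastome(random_seq(500, seed = 110), circular = FALSE)
  rd <- tibble::tibble(id = c("short", "long"),
                       seq = c(substr(g$seq, 100, 120), substr(g$seq, 300, 333)))
  cov <- size_stratified_coverage(rd, g)
  expect_equal(which(cov$short_cov > 0), 100:120)
  expect_true(all(cov$short_cov[100:120] == 1))
  expect_equal(which(cov$long_cov > 0), 300:333)
  empty <- size_stratified_coverage(rd[0, ], g)
  expect_true(all(empty$short_cov == 0) && all(empty$long_cov == 0))
})

test_that("coverage vectors equal independent overlap counting", {
  sim <- make_plastome(2000, 400, 500, seed = 111)
  fp <- tibble::tibble(start = c(301, 901), end = c(321, 921), depth = c(40, 30))
  sr <- simulate_srna(sim$genome, fp, tibble::tibble(start = 1200, end = 1500),
                      seed = 112)
  cov <- size_stratified_coverage(sr$reads, sim$genome)
  short <- filter_reads_by_length(sr$reads, 20, 24)
  al <- map_reads(short, sim$genome, max_mismatch = 0)
  expect_equal(cov$short_cov, oracle_coverage(al, plastome_length(sim$genome)))
})

test_that("locus calling requires enrichment over the long-read background", {
  short <- c(rep(0, 50), rep(30, 21), rep(0, 50))
  long <- rep(0, 121)
  loci <- call_srna_loci(short, long, min_reads = 20, enrichment_ratio = 5)
  expect_equal(nrow(loci), 1)
  expect_equal(c(loci$start, loci$end), c(51, 71))
  # uniform long-read-only coverage yields nothing
  expect_equal(nrow(call_srna_loci(rep(0, 200), rep(50, 200))), 0)
  # stacked short reads over an equally deep long background fail the ratio
  expect_equal(nrow(call_srna_loci(rep(30, 100), rep(30, 100))), 0)
})

test_that("nearby qualifying runs merge within merge_gap", {
  short <- rep(0, 100)
  short[11:30] <- 25
  short[36:55] <- 25   # 5 bp gap
  short[80:99] <- 25   # far away
  loci <- call_srna_loci(short, rep(0, 100), min_reads = 20,
                         enrichment_ratio = 5, merge_gap = 10)
  expect_equal(nrow(loci), 2)
  expect_equal(c(loci$start[1], loci$end[1]), c(11, 55))
  loci2 <- call_srna_loci(short, rep(0, 100), min_reads = 20,
                          enrichment_ratio = 5, merge_gap = 3)
  expect_equal(nrow(loci2), 3)
})

test_that("locus calling is invariant under read order permutation", {
  sim <- make_plastome(2000, 400, 500, seed = 113)
  fp <- tibble::tibble(start = 501, end = 521, depth = 50)
  sr <- simulate_srna(sim$genome, fp, seed = 114)
  prof1 <- srna_profile(sr$reads, sim$genome)
  shuffled <- withr::with_seed(1, sr$reads[sample(nrow(sr$reads)), ])
  prof2 <- srna_profile(shuffled, sim$genome)
  expect_equal(prof1[, c("start", "end", "core_sequence", "read_count")],
               prof2[, c("start", "end", "core_sequence", "read_count")])
})

test_that("planted footprints are recovered with precision = recall = 1", {
  sim <- make_plastome(6000, 1000, 800, seed = 115)
  genes <- plant_genes(sim$genome, sim$partition, n_genes = 5, n_intron_genes = 0,
                       n_ir_duplicates = 0, seed = 116)
  # footprints in the gene-free tail of the LSC; background over gene bodies
  fp <- tibble::tibble(start = c(4301, 4601, 4901), end = c(4321, 4621, 4921),
                       depth = c(100, 120, 100), strand = c("+", "-", "+"))
  bg <- purrr::map_dfr(genes$exons, function(e) {
    tibble::tibble(start = min(e$start), end = max(e$end))
  })
  sr <- simulate_srna(sim$genome, fp, bg, seed = 117)
  loci <- srna_profile(sr$reads, sim$genome, genes,
                       min_reads = 20, enrichment_ratio = 5, merge_gap = 10)
  expect_equal(nrow(loci), nrow(fp))          # precision and recall both 1
  for (i in seq_len(nrow(fp))) {
    hit <- loci[loci$start <= fp$start[i] & loci$end >= fp$end[i], ]
    expect_equal(nrow(hit), 1)
    expect_equal(hit$core_sequence, sr$truth$footprints$core_sequence[i])
    expect_equal(hit$strand, fp$strand[i])
    expect_gte(hit$read_count, fp$depth[i])
  }
  # every locus is genuinely enriched at one position or more
  cov <- attr(loci, "coverage")
  for (i in seq_len(nrow(loci))) {
    idx <- loci$start[i]:loci$end[i]
    expect_true(any(cov$short_cov[idx] / (cov$long_cov[idx] + 1) >= 5))
  }
})

test_that("core sequence selection is by abundance with lexicographic ties", {
  reads <- tibble::tibble(id = paste0("r", 1:10),
                          seq = c(rep("CCCCCCCCCCCCCCCCCCCC", 5),
                                  rep("AAAAAAAAAAAAAAAAAAAA", 5)))
  al <- tibble::tibble(read_id = reads$id, start = 1L, strand = "+",
                       mismatches = 0L, multi_hits = 1L, read_length = 20L)
  out <- core_sequence(tibble::tibble(start = 1, end = 20), reads, al)
  expect_equal(out$core_sequence, strrep("A", 20))  # tie -> lexicographically first
  expect_equal(out$read_count, 10)
  reads$seq[10] <- strrep("C", 20)                  # now C wins 6 to 4
  out2 <- core_sequence(tibble::tibble(start = 1, end = 20), reads, al)
  expect_equal(out2$core_sequence, strrep("C", 20))
  expect_error(core_sequence(tibble::tibble(start = 500, end = 520), reads, al),
               class = "plastex_error_empty_locus")
})

test_that("locus location classes use the 5' and 3' windows", {
  genes <- gene_models(tibble::tibble(
    gene = c("fwd", "rev", "spliced"), type = "CDS",
    strand = c("+", "-", "+"), trans_spliced = FALSE,
    exons = list(
      tibble::tibble(start = 1000, end = 1599, strand = "+", part = 1),
      tibble::tibble(start = 3000, end = 3599, strand = "-", part = 1),
      tibble::tibble(start = c(5000, 5600), end = c(5200, 5800), strand = "+", part = 1)
    )
  ))
  loc <- function(s, e, strand = NA) {
    classify_locus_location(tibble::tibble(start = s, end = e, strand = strand), genes)
  }
  expect_equal(loc(1200, 1220), "CDS")
  expect_equal(loc(5300, 5320), "intron")
  expect_equal(loc(930, 950, "+"), "intergenic_5prime")    # 60 bp upstream of fwd
  expect_equal(loc(3630, 3650, "-"), "intergenic_5prime")  # upstream of rev start
  expect_equal(loc(1650, 1670, "+"), "intergenic_3prime")  # just past the fwd stop
  expect_equal(loc(2300, 2320, "+"), "intergenic_other")
})

test_that("ortholog matching scores unit-cost global-alignment identity", {
  q <- tibble::tibble(name = "q1", seq = "ACGTACGTACGTACGTACGTA")
  r_same <- tibble::tibble(name = "r1", seq = q$seq)
  expect_equal(ortholog_match(q, r_same)$identity, 1.0)
  # two substitutions in a 21-mer: 19/21
  mut <- q$seq
  substr(mut, 5, 5) <- "T"; substr(mut, 15, 15) <- "C"
  out <- ortholog_match(q, tibble::tibble(name = "r2", seq = mut))
  expect_equal(out$identity, 19 / 21, tolerance = 1e-9)
  expect_true(out$matched)
  # unrelated sequences stay below the threshold
  neg <- ortholog_match(
    tibble::tibble(name = "q", seq = "ATATATATTAATATATATATA"),
    tibble::tibble(name = "r", seq = "GCGCGGCCGCGCGGCCGCGCG")
  )
  expect_false(any(neg$matched))
})
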